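#' Build a topologically sorted pedigree
#'
#' Orders animals so that every parent precedes its offspring, which is the
#' precondition for the tabular relationship-matrix recurrences and the
#' recursive inbreeding algorithm. Parent ids that never appear as animals
#' ("danglers") are treated as unknown, with a warning, so that imported
#' ledgers with incomplete ancestry still evaluate.
#'
#' @param animals either the `animals` table of a [flock_dataset()] (or the
#'   dataset itself), or a data frame with columns `animal_id`, `sire_id`,
#'   `dam_id` (`NA` = unknown).
#' @return An object of class `pedigree`: list with `ids` (sorted order),
#'   `sire` and `dam` (integer indices into `ids`, `NA` when unknown) and
#'   `orig_order` (position of each sorted id in the input).
#' @export
build_pedigree <- function(animals) {
  if (inherits(animals, "flock_dataset")) animals <- animals$animals
  ids <- as.character(animals$animal_id)
  n <- length(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate animal_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sire <- match(as.character(animals$sire_id), ids)
  dam <- match(as.character(animals$dam_id), ids)
  dangling <- (!is.na(animals$sire_id) & is.na(sire)) |
    (!is.na(animals$dam_id) & is.na(dam))
  if (any(dangling)) {
    warning(sum(dangling), " animal(s) with unregistered parent(s) treated ",
            "as having unknown parents", call. = FALSE)
  }
  if (any(!is.na(sire) & sire == seq_len(n)) ||
      any(!is.na(dam) & dam == seq_len(n))) {
    stop("animal recorded as its own parent", call. = FALSE)
  }

  # Kahn topological sort over parent -> offspring edges.
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- find_pedigree_cycle(sire, dam, setdiff(seq_len(n), order))
    stop("pedigree cycle involving: ", paste(ids[cyc], collapse = ", "),
         call. = FALSE)
  }
  pos <- match(seq_len(n), order)  # pos[i] = rank of input animal i
  structure(list(ids = ids[order],
                 sire = pos[sire[order]],
                 dam = pos[dam[order]],
                 orig_order = order),
            class = "pedigree")
}

# Walk parent links from an unsorted node until a repeat is seen.
find_pedigree_cycle <- function(sire, dam, in_cycle) {
  start <- in_cycle[1]
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      return(seen[which(seen == v)[1]:length(seen)])
    }
    seen <- c(seen, v)
    nxt <- c(sire[v], dam[v])
    nxt <- nxt[!is.na(nxt) & nxt %in% in_cycle]
    if (!length(nxt)) return(seen)
    v <- nxt[1]
  }
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$ids), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  invisible(x)
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes the dense additive (numerator) relationship matrix A by the
#' tabular recurrences over a sorted pedigree:
#' `a_ij = (a_{j,s(i)} + a_{j,d(i)}) / 2` for `j < i` (unknown-parent terms
#' contribute 0) and `a_ii = 1 + a_{s(i),d(i)} / 2` (0 when either parent is
#' unknown). The diagonal is `1 + F`.
#'
#' @param ped a [build_pedigree()] result.
#' @param max_n refuse to build a dense matrix above this many animals
#'   (use [ainverse()] for large evaluations).
#' @return A symmetric matrix with dimnames `ped$ids`.
#' @export
amatrix <- function(ped, max_n = 5000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$ids)
  if (n > max_n) {
    stop("refusing to build a dense A for ", n, " animals (> ", max_n,
         "); use ainverse()", call. = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(ped$ids, ped$ids))
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(si)) row <- row + A[j, si]
      if (!is.na(di)) row <- row + A[j, di]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
  }
  A
}

#' Inbreeding coefficients by the recursive tabular route
#'
#' Computes per-animal inbreeding coefficients `F = a_{s,d} / 2` (half the
#' additive relationship between the parents) using the Meuwissen–Luo
#' ancestor-sweep algorithm, which never materializes the full relationship
#' matrix and therefore scales to large pedigrees. Animals with one or both
#' parents unknown are treated as non-inbred founders.
#'
#' @param ped a [build_pedigree()] result.
#' @return Named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$ids)
  s <- ped$sire; d <- ped$dam
  F <- numeric(n)
  # Dm: Mendelian-sampling variance; an unknown parent enters with F = -1,
  # which yields D = 1 for founders and D = 3/4 - F_p/4 with one known parent.
  Dm <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (!is.na(s[i])) F[s[i]] else -1
    Fd <- if (!is.na(d[i])) F[d[i]] else -1
    Dm[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (is.na(s[i]) || is.na(d[i])) { F[i] <- 0; next }
    # a_ii = sum_j L_ij^2 D_j over i's ancestors (L = Cholesky contributions),
    # accumulated by one backward sweep; then F_i = a_ii - 1.
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * Dm[j]
      if (!is.na(s[j])) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (!is.na(d[j])) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$ids
  F
}

#' Inbreeding by Wright's path-counting rule
#'
#' Enumerates all paths that run from the sire up to a common ancestor and
#' down to the dam without repeating any animal, and sums
#' `(1/2)^(n+1) * (1 + F_A)` over them, where `n` is the number of
#' segregations (links) in the path and `F_A` the common ancestor's own
#' inbreeding coefficient. Exponential in pedigree depth; retained as the
#' independent oracle for [inbreeding()] on small pedigrees.
#'
#' @param ped a [build_pedigree()] result.
#' @param x animal id.
#' @param max_ancestors guard: refuse when either parent has more than this
#'   many ancestors.
#' @return The inbreeding coefficient of `x`.
#' @export
inbreeding_wright <- function(ped, x, max_ancestors = 25L) {
  stopifnot(inherits(ped, "pedigree"))
  i <- match(x, ped$ids)
  if (is.na(i)) stop("unknown animal id: ", x, call. = FALSE)
  s <- ped$sire[i]; d <- ped$dam[i]
  if (is.na(s) || is.na(d)) return(0)
  anc_s <- ancestor_set(ped, s)
  anc_d <- ancestor_set(ped, d)
  if (length(anc_s) > max_ancestors || length(anc_d) > max_ancestors) {
    stop("ancestor-count guard exceeded; use the recursive method ",
         "(inbreeding())", call. = FALSE)
  }
  common <- intersect(anc_s, anc_d)
  if (!length(common)) return(0)
  Fvec <- inbreeding(ped)  # ancestors' own F for the (1 + F_A) factor
  total <- 0
  for (a in common) {
    up <- paths_to_ancestor(ped, s, a)    # sire -> a
    down <- paths_to_ancestor(ped, d, a)  # dam -> a
    for (p1 in up) for (p2 in down) {
      # the two legs may share only the common ancestor itself
      if (length(intersect(setdiff(p1, a), setdiff(p2, a))) == 0) {
        nseg <- (length(p1) - 1) + (length(p2) - 1)
        total <- total + 0.5^(nseg + 1) * (1 + Fvec[a])
      }
    }
  }
  unname(total)
}

ancestor_set <- function(ped, i) {
  stack <- i; seen <- integer(0)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    for (p in c(ped$sire[v], ped$dam[v])) if (!is.na(p)) stack <- c(stack, p)
  }
  seen
}

# All simple ancestral paths from `from` up to `anc`, as index vectors.
paths_to_ancestor <- function(ped, from, anc) {
  if (from == anc) return(list(from))
  out <- list()
  for (p in c(ped$sire[from], ped$dam[from])) {
    if (is.na(p)) next
    for (tail in paths_to_ancestor(ped, p, anc)) {
      out[[length(out) + 1]] <- c(from, tail)
    }
  }
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's per-animal
#' rank-one updates, with Mendelian-sampling variances
#' `d_i = 1/2 - (F_s + F_d)/4` when both parents are known, `3/4 - F_p/4`
#' with one known parent, and 1 for founders. Never forms A itself, so it is
#' the route the mixed-model equations use at scale.
#'
#' @param ped a [build_pedigree()] result.
#' @param F optional precomputed [inbreeding()] vector (computed if omitted).
#' @return A sparse symmetric [Matrix::dsCMatrix-class] with dimnames
#'   `ped$ids`.
#' @export
ainverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(F)) F <- inbreeding(ped)
  n <- length(ped$ids)
  s <- ped$sire; d <- ped$dam
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    both <- !is.na(si) && !is.na(di)
    one <- xor(is.na(si), is.na(di))
    dm <- if (both) 0.5 - 0.25 * (F[si] + F[di])
          else if (one) 0.75 - 0.25 * F[c(si, di)[!is.na(c(si, di))]]
          else 1
    al <- 1 / dm
    add(i, i, al)
    for (p in c(si, di)) {
      if (is.na(p)) next
      add(i, p, -al / 2); add(p, i, -al / 2)
    }
    ps <- c(si, di)[!is.na(c(si, di))]
    for (p in ps) for (q in ps) add(p, q, al / 4)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$ids, ped$ids))
  Matrix::forceSymmetric(M)
}

#' Ancestor tree (pedigree sheet) for one animal
#'
#' Extracts the ancestor tree of an animal to a requested depth. Unknown
#' parents are rendered as explicit `UNKNOWN` leaves so the printed sheet
#' always shows both parent slots.
#'
#' @param ped a [build_pedigree()] result.
#' @param x animal id.
#' @param generations depth (>= 1): 1 shows parents, 2 grandparents, ...
#' @param sex optional named character vector (id -> sex) to annotate nodes.
#' @return Nested list of class `pedigree_sheet`: each node has `id`, `F`,
#'   `sex` (possibly `NA`), and `sire`/`dam` subtrees or `"UNKNOWN"` markers.
#' @export
pedigree_sheet <- function(ped, x, generations, sex = NULL) {
  stopifnot(inherits(ped, "pedigree"), generations >= 1)
  i <- match(x, ped$ids)
  if (is.na(i)) stop("unknown animal id: ", x, call. = FALSE)
  F <- inbreeding(ped)
  node <- function(idx, depth) {
    if (is.na(idx)) return(list(id = "UNKNOWN"))
    out <- list(id = ped$ids[idx], F = unname(F[idx]),
                sex = if (!is.null(sex)) unname(sex[ped$ids[idx]]) else NA)
    if (depth > 0) {
      out$sire <- node(ped$sire[idx], depth - 1)
      out$dam <- node(ped$dam[idx], depth - 1)
    }
    out
  }
  structure(node(i, generations), class = "pedigree_sheet")
}

#' @export
print.pedigree_sheet <- function(x, ...) {
  rec <- function(node, prefix, label) {
    if (identical(node$id, "UNKNOWN")) {
      cat(prefix, label, "UNKNOWN\n")
      return(invisible())
    }
    cat(prefix, label, node$id,
        if (!is.null(node$F)) sprintf("(F = %.4f)", node$F) else "", "\n")
    if (!is.null(node$sire)) {
      rec(node$sire, paste0(prefix, "  "), "S:")
      rec(node$dam, paste0(prefix, "  "), "D:")
    }
  }
  rec(x, "", "")
  invisible(x)
}

#' Animal history sheet
#'
#' Collates everything recorded about one animal: identity and disposal,
#' its own trait records, the reproduction events it took part in, its
#' progeny (animals naming it as sire or dam) with per-trait progeny means,
#' and its health events. All sections are date-sorted.
#'
#' @param ds a [flock_dataset()].
#' @param x animal id.
#' @return List of class `history_sheet` with elements `identity`, `traits`,
#'   `repro`, `progeny`, `progeny_trait_means`, `health`.
#' @export
history_sheet <- function(ds, x) {
  stopifnot(inherits(ds, "flock_dataset"))
  a <- ds$animals
  row <- a[a$animal_id == x, , drop = FALSE]
  if (!nrow(row)) stop("unknown animal id: ", x, call. = FALSE)
  tr <- ds$traits[ds$traits$animal_id == x, , drop = FALSE]
  tr <- tr[order(tr$record_date, tr$trait_code), , drop = FALSE]
  re <- ds$repro[ds$repro$ewe_id == x | ds$repro$ram_id == x, , drop = FALSE]
  re <- re[order(re$mating_date), , drop = FALSE]
  prog <- a[(!is.na(a$sire_id) & a$sire_id == x) |
              (!is.na(a$dam_id) & a$dam_id == x), , drop = FALSE]
  prog <- prog[order(prog$birth_date, prog$animal_id), , drop = FALSE]
  ptr <- ds$traits[ds$traits$animal_id %in% prog$animal_id, , drop = FALSE]
  pmeans <- if (nrow(ptr)) {
    agg <- aggregate(value ~ trait_code, data = ptr,
                     FUN = function(v) c(mean = mean(v), n = length(v)))
    data.frame(trait_code = agg$trait_code, mean = agg$value[, "mean"],
               n = as.integer(agg$value[, "n"]), stringsAsFactors = FALSE)
  } else {
    data.frame(trait_code = character(), mean = numeric(), n = integer(),
               stringsAsFactors = FALSE)
  }
  he <- ds$health[ds$health$animal_id == x, , drop = FALSE]
  he <- he[order(he$date), , drop = FALSE]
  rownames(tr) <- rownames(re) <- rownames(prog) <- rownames(he) <- NULL
  structure(list(identity = row, traits = tr, repro = re, progeny = prog,
                 progeny_trait_means = pmeans, health = he),
            class = "history_sheet")
}

#' @export
print.history_sheet <- function(x, ...) {
  cat("history sheet:", x$identity$animal_id, "—", x$identity$sex,
      x$identity$breed, "born", format(x$identity$birth_date), "\n")
  cat(" trait records:", nrow(x$traits), "; repro events:", nrow(x$repro),
      "; progeny:", nrow(x$progeny), "; health events:", nrow(x$health), "\n")
  invisible(x)
}
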