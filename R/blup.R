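#' Variance ratio for the mixed-model equations
#'
#' The shrinkage ratio multiplying the inverse relationship matrix in
#' Henderson's equations. Under the sire model the random effect is the
#' sire's transmitting ability (a quarter of the additive variance), giving
#' `lambda = (4 - h2) / h2`; under the animal model the effect is the
#' animal's own breeding value, giving `lambda = (1 - h2) / h2`.
#'
#' @param h2 heritability, strictly inside (0, 1).
#' @param random_unit `"ANIMAL"` or `"SIRE"`.
#' @return The ratio `sigma2_e / sigma2_u`.
#' @export
lambda_from_h2 <- function(h2, random_unit = c("ANIMAL", "SIRE")) {
  random_unit <- match.arg(random_unit)
  if (!is.numeric(h2) || length(h2) != 1 || is.na(h2) || h2 <= 0 || h2 >= 1) {
    stop("h2 must lie strictly inside (0, 1)", call. = FALSE)
  }
  switch(random_unit, SIRE = (4 - h2) / h2, ANIMAL = (1 - h2) / h2)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the symmetric coefficient matrix
#' `[X'X, X'Z; Z'X, Z'Z + lambda * Ainv]` and right-hand side
#' `[X'y; Z'y]`, with no centering or scaling of `y`. Units that carry no
#' records enter only through the relationship structure (`lambda * Ainv`).
#'
#' @param y,X,Z response and incidence matrices.
#' @param Ainv inverse relationship matrix among the units (sparse or
#'   dense); an identity corresponds to unrelated units.
#' @param lambda positive variance ratio (see [lambda_from_h2()]).
#' @return Object of class `mme_system`: `C` (sparse symmetric), `rhs`,
#'   `n_fixed`, `fixed_names`, `unit_ids`.
#' @export
assemble_mme <- function(y, X, Z, Ainv, lambda) {
  X <- as.matrix(X)
  Z <- methods::as(Matrix::Matrix(Z, sparse = TRUE), "CsparseMatrix")
  stopifnot(lambda > 0)
  n <- length(y)
  if (nrow(X) != n) stop("dimension mismatch in block X'X: nrow(X) != length(y)",
                         call. = FALSE)
  if (nrow(Z) != n) stop("dimension mismatch in block Z'Z: nrow(Z) != length(y)",
                         call. = FALSE)
  if (nrow(Ainv) != ncol(Z) || ncol(Ainv) != ncol(Z)) {
    stop("dimension mismatch in block Z'Z + lambda*Ainv: Ainv is ",
         nrow(Ainv), "x", ncol(Ainv), " but there are ", ncol(Z), " units",
         call. = FALSE)
  }
  Xs <- as(X, "CsparseMatrix")
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
             cbind(Matrix::crossprod(Z, Xs),
                   Matrix::crossprod(Z) + lambda * Ainv))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  structure(list(C = C, rhs = rhs, n_fixed = ncol(X),
                 fixed_names = colnames(X),
                 unit_ids = colnames(Z)),
            class = "mme_system")
}

#' Solve the mixed-model equations
#'
#' Direct sparse symmetric solve of the assembled system. With the fixed
#' effects coded full-rank (reference-level dropping) and `lambda > 0` the
#' coefficient matrix is nonsingular, so the solution is unique and
#' reproducible; the random-effect solutions are invariant to the choice of
#' fixed-effect constraint.
#'
#' @param sys an [assemble_mme()] system.
#' @return List with `b` (named fixed-effect solutions) and `u` (named
#'   random-effect predictions).
#' @export
solve_mme <- function(sys) {
  stopifnot(inherits(sys, "mme_system"))
  sol <- tryCatch(
    as.numeric(Matrix::solve(sys$C, sys$rhs)),
    error = function(e) stop("singular mixed-model equations: ",
                             conditionMessage(e), call. = FALSE))
  p <- sys$n_fixed
  list(b = setNames(sol[seq_len(p)], sys$fixed_names),
       u = setNames(sol[-seq_len(p)], sys$unit_ids))
}

#' Breeding values by individual (mass) selection
#'
#' The textbook single-record predictor
#' `EBV = P_m + h2 * (P_i - P_m)`, where `P_m` is the mean of all included
#' phenotypes. Note the result is on the trait scale (a predicted
#' phenotypic merit), unlike BLUP solutions, which are deviations.
#'
#' @param phenotypes named numeric vector: one phenotype per animal.
#' @param h2 heritability between 0 and 1.
#' @param trait optional trait code carried into the output.
#' @return An EBV table: data frame with `animal_id`, `trait`, `method`
#'   (`"INDIVIDUAL"`), `ebv`.
#' @export
individual_ebv <- function(phenotypes, h2, trait = NA_character_) {
  if (!length(phenotypes)) stop("no phenotypes supplied", call. = FALSE)
  stopifnot(h2 >= 0, h2 <= 1)
  pm <- mean(phenotypes)
  data.frame(animal_id = names(phenotypes), trait = trait,
             method = "INDIVIDUAL", ebv = unname(pm + h2 * (phenotypes - pm)),
             stringsAsFactors = FALSE)
}

#' BLUP breeding values for a flock
#'
#' End-to-end genetic evaluation: builds design matrices for the trait,
#' sorts the pedigree, forms the sparse inverse relationship matrix,
#' derives the variance ratio from the supplied heritability, assembles and
#' solves Henderson's equations, and returns a prediction for every
#' pedigree member — including unrecorded ancestors, whose solutions are
#' driven entirely by their relatives' records.
#'
#' @param ds a [flock_dataset()].
#' @param trait trait code.
#' @param h2 heritability used for the variance ratio (e.g. from
#'   [heritability()]; an `h2_estimate` object is also accepted).
#' @param fixed fixed factors (see [build_design_matrices()]).
#' @param model `"animal"` (default: every animal evaluated through the
#'   full relationship matrix) or `"sire"` (sires evaluated from progeny
#'   records, `lambda = (4 - h2)/h2`).
#' @return An EBV table: data frame with `animal_id`, `farm_id`, `trait`,
#'   `method` (`"BLUP"`), `ebv`; attribute `b` holds the fixed-effect
#'   solutions.
#' @export
blup_ebv <- function(ds, trait, h2, fixed = c("sex", "year"),
                     model = c("animal", "sire")) {
  stopifnot(inherits(ds, "flock_dataset"))
  model <- match.arg(model)
  if (inherits(h2, "h2_estimate")) h2 <- h2$h2_clamped
  if (model == "animal") {
    ped <- build_pedigree(ds$animals)
    dm <- build_design_matrices(ds, trait, fixed, "ANIMAL", unit_ids = ped$ids)
    Ai <- ainverse(ped)
    lambda <- lambda_from_h2(h2, "ANIMAL")
  } else {
    dm <- build_design_matrices(ds, trait, fixed, "SIRE")
    Ai <- Matrix::Diagonal(length(dm$unit_ids))
    dimnames(Ai) <- list(dm$unit_ids, dm$unit_ids)
    lambda <- lambda_from_h2(h2, "SIRE")
  }
  sol <- solve_mme(assemble_mme(dm$y, dm$X, dm$Z, Ai, lambda))
  farm <- ds$animals$farm_id[match(names(sol$u), ds$animals$animal_id)]
  out <- data.frame(animal_id = names(sol$u), farm_id = farm, trait = trait,
                    method = "BLUP", ebv = unname(sol$u),
                    stringsAsFactors = FALSE)
  attr(out, "b") <- sol$b
  attr(out, "h2") <- h2
  out
}

#' Rank animals on genetic merit across farms
#'
#' Merges one or more EBV (or index) tables and ranks descending on the
#' value column. Ties are broken by ascending animal id for a reproducible
#' row order; ranks are 1-based and dense (tied values share a rank).
#'
#' @param tables a single EBV table or a list of them (e.g. one per farm);
#'   all must share `trait` and `method`.
#' @param key column to rank on (default `"ebv"`).
#' @return The concatenated table, row-ordered by rank, with a `rank`
#'   column appended.
#' @export
rank_animals <- function(tables, key = "ebv") {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  if ("trait" %in% names(tab) && length(unique(tab$trait)) > 1) {
    stop("cannot rank across different traits: ",
         paste(unique(tab$trait), collapse = ", "), call. = FALSE)
  }
  if ("method" %in% names(tab) && length(unique(tab$method)) > 1) {
    stop("cannot rank across different methods", call. = FALSE)
  }
  v <- tab[[key]]
  ord <- order(-v, tab$animal_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- match(tab[[key]], sort(unique(tab[[key]]), decreasing = TRUE))
  rownames(tab) <- NULL
  tab
}
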