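#' Nested ANOVA for a hierarchical sib design
#'
#' Partitions phenotypic variation into between-sire, between-dam-within-
#' sire, and within-dam (full-sib) strata, the classical paternal half-sib /
#' maternal full-sib analysis. Handles unbalanced designs through the
#' expected-mean-square coefficients
#' `k1 = (N - sum_ij n_ij^2 / n_i.) / (D - S)`,
#' `k2 = (sum_ij n_ij^2 / n_i. - sum_ij n_ij^2 / N) / (S - 1)`,
#' `k3 = (N - sum_i n_i.^2 / N) / (S - 1)`,
#' so that `E(MS_w) = s2w`, `E(MS_d) = s2w + k1 s2d`,
#' `E(MS_s) = s2w + k2 s2d + k3 s2s`. In a balanced `s x d x n` design these
#' reduce to `k1 = k2 = n`, `k3 = d n`.
#'
#' Negative component solutions are truncated to zero and flagged (the raw
#' solutions stay available as attribute `raw`).
#'
#' @param design data frame with columns `sire`, `dam`, `value`; each dam
#'   label must appear under exactly one sire.
#' @return Object of class `anova_table`: degrees of freedom, sums of
#'   squares, mean squares, `k1/k2/k3`, variance components
#'   `sigma2_s/sigma2_d/sigma2_w`, and `truncated` flags.
#' @export
nested_anova <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("sire", "dam", "value") %in% names(design)))
  y <- design$value
  if (any(!is.finite(y))) stop("non-finite phenotype", call. = FALSE)
  sire <- as.character(design$sire)
  dam <- as.character(design$dam)
  if (any(tapply(sire, dam, function(s) length(unique(s))) > 1)) {
    stop("a dam appears under more than one sire; the design must be nested",
         call. = FALSE)
  }
  S <- length(unique(sire))
  if (S < 2) stop("need at least 2 sires", call. = FALSE)
  N <- length(y)
  D <- length(unique(dam))
  if (N - D < 1) {
    stop("no dam has 2 or more progeny: within-dam df is zero", call. = FALSE)
  }
  if (var(y) == 0) stop("TOTAL_VARIANCE_ZERO: all phenotypes equal",
                        call. = FALSE)

  gmean <- mean(y)
  sire_mean <- tapply(y, sire, mean)
  sire_n <- tapply(y, sire, length)
  dam_mean <- tapply(y, dam, mean)
  dam_n <- tapply(y, dam, length)
  dam_sire <- tapply(sire, dam, function(s) s[1])

  ss_s <- sum(sire_n * (sire_mean - gmean)^2)
  ss_d <- sum(dam_n * (dam_mean - sire_mean[dam_sire])^2)
  ss_w <- sum((y - dam_mean[dam])^2)
  df_s <- S - 1L
  df_d <- D - S
  df_w <- N - D
  ms_s <- ss_s / df_s
  ms_d <- ss_d / df_d
  ms_w <- ss_w / df_w

  nij2 <- dam_n^2
  sum_nij2_over_ni <- sum(nij2 / sire_n[dam_sire])
  sum_nij2_over_N <- sum(nij2) / N
  k1 <- (N - sum_nij2_over_ni) / (D - S)
  k2 <- (sum_nij2_over_ni - sum_nij2_over_N) / (S - 1)
  k3 <- (N - sum(sire_n^2) / N) / (S - 1)
  if (k1 <= 0 || k2 < 0 || k3 <= 0) {
    stop("degenerate design: non-positive expected-mean-square coefficient",
         call. = FALSE)
  }

  s2w <- ms_w
  s2d_raw <- (ms_d - ms_w) / k1
  s2s_raw <- (ms_s - ms_w - k2 * s2d_raw) / k3
  trunc_d <- s2d_raw < 0
  trunc_s <- s2s_raw < 0
  structure(list(
    df_s = df_s, df_d = df_d, df_w = df_w,
    ss_s = ss_s, ss_d = ss_d, ss_w = ss_w,
    ms_s = ms_s, ms_d = ms_d, ms_w = ms_w,
    k1 = k1, k2 = k2, k3 = k3,
    sigma2_s = max(s2s_raw, 0), sigma2_d = max(s2d_raw, 0), sigma2_w = s2w,
    truncated = c(sire = trunc_s, dam = trunc_d, within = FALSE),
    n = N, n_sires = S, n_dams = D),
    class = "anova_table", raw = c(sigma2_s = s2s_raw, sigma2_d = s2d_raw))
}

#' @export
print.anova_table <- function(x, ...) {
  tab <- data.frame(
    stratum = c("sire", "dam within sire", "within dam"),
    df = c(x$df_s, x$df_d, x$df_w),
    SS = c(x$ss_s, x$ss_d, x$ss_w),
    MS = c(x$ms_s, x$ms_d, x$ms_w))
  print(tab, row.names = FALSE)
  cat(sprintf("k1 = %.4f, k2 = %.4f, k3 = %.4f\n", x$k1, x$k2, x$k3))
  cat(sprintf("sigma2_s = %.5g, sigma2_d = %.5g, sigma2_w = %.5g\n",
              x$sigma2_s, x$sigma2_d, x$sigma2_w))
  invisible(x)
}

#' Heritability from a nested ANOVA table
#'
#' Converts sib-analysis variance components to heritability: the sire
#' component estimates `h2 = 4 s2s / s2p`, the dam component
#' `4 s2d / s2p` (inflated by maternal and dominance variance when present),
#' and the combined form `2 (s2s + s2d) / s2p`, with
#' `s2p = s2s + s2d + s2w`. Both the raw estimate and its clamp to the unit interval
#' are reported.
#'
#' @param table an [nested_anova()] result.
#' @param component one of `"SIRE"`, `"DAM"`, `"SIRE_DAM"`.
#' @return List of class `h2_estimate`: `method`, `h2_raw`, `h2_clamped`,
#'   `components`.
#' @export
h2_from_anova <- function(table, component = c("SIRE", "DAM", "SIRE_DAM")) {
  stopifnot(inherits(table, "anova_table"))
  component <- match.arg(component)
  s2p <- table$sigma2_s + table$sigma2_d + table$sigma2_w
  if (s2p <= 0) stop("phenotypic variance is zero", call. = FALSE)
  h2 <- switch(component,
    SIRE = 4 * table$sigma2_s / s2p,
    DAM = 4 * table$sigma2_d / s2p,
    SIRE_DAM = 2 * (table$sigma2_s + table$sigma2_d) / s2p)
  structure(list(method = component, h2_raw = h2,
                 h2_clamped = min(max(h2, 0), 1),
                 components = c(sigma2_s = table$sigma2_s,
                                sigma2_d = table$sigma2_d,
                                sigma2_w = table$sigma2_w, sigma2_p = s2p)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 (%s) = %.4f", x$method, x$h2_clamped))
  if (x$h2_raw != x$h2_clamped) cat(sprintf(" (raw %.4f)", x$h2_raw))
  cat("\n")
  invisible(x)
}

#' Build a nested sib design from flock records
#'
#' Extracts one phenotype per animal for a trait (the animal's first record)
#' and groups by known sire and dam. Optionally pre-adjusts phenotypes by
#' fixed-effect subclass means (subtract the subclass mean, add back the
#' grand mean); this is off by default.
#'
#' @param ds a [flock_dataset()].
#' @param trait trait code.
#' @param adjust_fixed `NULL`, or a character vector drawn from
#'   `c("sex", "year", "farm")`.
#' @return A design data frame suitable for [nested_anova()].
#' @export
sib_design <- function(ds, trait, adjust_fixed = NULL) {
  stopifnot(inherits(ds, "flock_dataset"))
  t <- ds$traits[ds$traits$trait_code == trait, , drop = FALSE]
  if (!nrow(t)) stop("no records for trait ", trait, call. = FALSE)
  t <- t[!duplicated(t$animal_id), , drop = FALSE]
  a <- ds$animals
  i <- match(t$animal_id, a$animal_id)
  df <- data.frame(sire = a$sire_id[i], dam = a$dam_id[i], value = t$value,
                   sex = a$sex[i], farm = a$farm_id[i],
                   year = format(t$record_date, "%Y"),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$sire) & !is.na(df$dam), , drop = FALSE]
  if (!nrow(df)) stop("no records with both parents known", call. = FALSE)
  if (!is.null(adjust_fixed)) {
    key <- do.call(paste, c(df[adjust_fixed], sep = "\r"))
    sub_mean <- tapply(df$value, key, mean)
    df$value <- df$value - sub_mean[key] + mean(df$value)
  }
  df[c("sire", "dam", "value")]
}

#' Design matrices for the mixed (animal/sire) model
#'
#' Builds the response and incidence matrices for one trait. Fixed effects
#' are coded with a global mean column plus treatment contrasts dropping the
#' alphabetically first level of each factor, which keeps `X` full rank.
#' `year` is the calendar year of the record date, `sex` comes from the
#' animal register, and a `farm` factor is added automatically whenever the
#' records span more than one farm. Factors with a single observed level are
#' dropped with a message. `Z` maps each record to its evaluation unit: the
#' animal itself under the animal model, or its sire under the sire model
#' (records with unknown sire are then dropped with a message).
#'
#' @param ds a [flock_dataset()].
#' @param trait trait code.
#' @param fixed character vector of factor names from
#'   `c("sex", "year", "farm")`.
#' @param random_unit `"ANIMAL"` or `"SIRE"`.
#' @param unit_ids optional id vector fixing the unit order (e.g. pedigree
#'   order, so `Z` aligns with [ainverse()]); defaults to the register order
#'   for the animal model and sorted sires for the sire model.
#' @return List with `y`, `X`, `Z` (sparse), `unit_ids`, `records`.
#' @export
build_design_matrices <- function(ds, trait, fixed = c("sex", "year"),
                                  random_unit = c("ANIMAL", "SIRE"),
                                  unit_ids = NULL) {
  stopifnot(inherits(ds, "flock_dataset"))
  random_unit <- match.arg(random_unit)
  t <- ds$traits[ds$traits$trait_code == trait, , drop = FALSE]
  if (!nrow(t)) stop("no records for trait ", trait, call. = FALSE)
  a <- ds$animals
  i <- match(t$animal_id, a$animal_id)
  rec <- data.frame(animal_id = t$animal_id, value = t$value,
                    sex = a$sex[i], farm = a$farm_id[i], sire = a$sire_id[i],
                    year = format(t$record_date, "%Y"),
                    stringsAsFactors = FALSE)

  if (length(unique(rec$farm)) > 1 && !"farm" %in% fixed) {
    fixed <- c(fixed, "farm")
  }
  keep <- character(0)
  for (f in fixed) {
    if (length(unique(rec[[f]])) > 1) keep <- c(keep, f)
    else message("dropping single-level fixed factor: ", f)
  }
  X <- matrix(1, nrow(rec), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(keep)) {
    fml <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
    X <- stats::model.matrix(fml, data = as.data.frame(
      lapply(rec[keep], factor)))
  }

  if (random_unit == "SIRE") {
    drop <- is.na(rec$sire)
    if (any(drop)) {
      message("dropping ", sum(drop), " record(s) with unknown sire")
      rec <- rec[!drop, , drop = FALSE]
      X <- X[!drop, , drop = FALSE]
    }
    if (is.null(unit_ids)) unit_ids <- sort(unique(rec$sire))
    zi <- match(rec$sire, unit_ids)
  } else {
    if (is.null(unit_ids)) unit_ids <- a$animal_id
    zi <- match(rec$animal_id, unit_ids)
  }
  if (anyNA(zi)) stop("record refers to a unit outside unit_ids", call. = FALSE)
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(rec)), j = zi, x = 1,
                            dims = c(nrow(rec), length(unit_ids)),
                            dimnames = list(NULL, unit_ids))
  list(y = rec$value, X = X, Z = Z, unit_ids = unit_ids, records = rec)
}

#' EM-REML for the animal (or sire) model
#'
#' Restricted maximum-likelihood estimation of the additive and residual
#' variances by expectation-maximization on Henderson's mixed-model
#' equations. Each iteration solves the MME at the current variance ratio,
#' then updates
#' `s2u <- (u' Ainv u + s2e * tr(Ainv Cuu)) / q` and
#' `s2e <- (y - X b - Z u)' y / (n - rank(X))`,
#' where `Cuu` is the random-effect block of the inverse MME coefficient
#' matrix. Both updates are non-negative by construction, so estimates stay
#' in the parameter space; convergence is declared when both relative
#' component changes fall below `tol`.
#'
#' @param y,X,Z response and incidence matrices (see
#'   [build_design_matrices()]).
#' @param Ainv (sparse) inverse relationship matrix among the units.
#' @param init length-2 positive numeric: starting `(s2u, s2e)`; defaults to
#'   an even split of the phenotypic variance.
#' @param tol relative-change convergence tolerance.
#' @param maxit maximum EM iterations.
#' @return List of class `reml_fit`: `sigma2_u`, `sigma2_e`, `h2`,
#'   `iterations`, `converged`, `b`, `u`.
#' @export
reml_animal <- function(y, X, Z, Ainv, init = NULL, tol = 1e-6,
                        maxit = 200L) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  Ainv <- as.matrix(Ainv)
  n <- length(y)
  p <- ncol(X)
  q <- ncol(Z)
  stopifnot(nrow(X) == n, nrow(Z) == n, nrow(Ainv) == q, ncol(Ainv) == q)
  if (is.null(init)) init <- rep(max(var(y), 1e-8) / 2, 2)
  if (any(init <= 0)) stop("init components must be positive", call. = FALSE)
  rX <- qr(X)$rank

  XtX <- crossprod(X)
  XtZ <- as.matrix(crossprod(X, Z))
  ZtZ <- as.matrix(crossprod(Z))
  Xty <- crossprod(X, y)
  Zty <- as.numeric(crossprod(Z, y))
  yty <- sum(y^2)

  XtX_inv <- tryCatch(solve(XtX), error = function(e)
    stop("singular mixed-model equations: X not full rank", call. = FALSE))
  # Schur complement pieces reused every iteration
  W <- XtX_inv %*% XtZ                     # p x q
  S0 <- ZtZ - crossprod(XtZ, W)            # Z'Z - Z'X (X'X)^-1 X'Z
  r0 <- Zty - as.numeric(crossprod(W, Xty))

  s2u <- init[1]; s2e <- init[2]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    lambda <- s2e / s2u
    # random-effect block of the inverse MME coefficient matrix
    ch <- tryCatch(chol(S0 + lambda * Ainv), error = function(e)
      stop("singular mixed-model equations", call. = FALSE))
    Cuu <- chol2inv(ch)
    u <- as.numeric(Cuu %*% r0)
    b <- as.numeric(XtX_inv %*% (Xty - XtZ %*% u))

    s2u_new <- (sum(u * (Ainv %*% u)) + s2e * sum(Ainv * t(Cuu))) / q
    s2e_new <- (yty - sum(b * Xty) - sum(u * Zty)) / (n - rX)
    s2e_new <- max(s2e_new, 1e-12)
    s2u_new <- max(s2u_new, 1e-12)
    rel <- c(abs(s2u_new - s2u) / max(s2u, 1e-12),
             abs(s2e_new - s2e) / max(s2e, 1e-12))
    s2u <- s2u_new; s2e <- s2e_new
    if (all(rel < tol)) { converged <- TRUE; break }
  }
  structure(list(sigma2_u = s2u, sigma2_e = s2e, h2 = s2u / (s2u + s2e),
                 iterations = it, converged = converged,
                 b = b, u = setNames(u, colnames(Z))),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "EM-REML: sigma2_u = %.5g, sigma2_e = %.5g, h2 = %.4f (%d iterations%s)\n",
    x$sigma2_u, x$sigma2_e, x$h2, x$iterations,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Heritability from flock records
#'
#' One-call wrapper used by the command-line interface: either nested-ANOVA
#' sib analysis (`method = "sib"`) or the EM-REML animal/sire model
#' (`method = "animal"`) with sex/year (and, across farms, farm) fixed
#' effects.
#'
#' @param ds a [flock_dataset()].
#' @param trait trait code.
#' @param method `"sib"` or `"animal"`.
#' @param component sib-analysis component (see [h2_from_anova()]).
#' @param fixed fixed factors for the animal model.
#' @param random_unit `"ANIMAL"` or `"SIRE"` for the REML route.
#' @return An `h2_estimate` (sib) or a list with the `h2_estimate` plus the
#'   full `reml_fit` (animal).
#' @export
heritability <- function(ds, trait, method = c("sib", "animal"),
                         component = "SIRE", fixed = c("sex", "year"),
                         random_unit = "ANIMAL") {
  method <- match.arg(method)
  if (method == "sib") {
    return(h2_from_anova(nested_anova(sib_design(ds, trait)), component))
  }
  ped <- build_pedigree(ds$animals)
  if (random_unit == "ANIMAL") {
    dm <- build_design_matrices(ds, trait, fixed, "ANIMAL",
                                unit_ids = ped$ids)
    Ai <- ainverse(ped)
  } else {
    dm <- build_design_matrices(ds, trait, fixed, "SIRE")
    # sires treated as unrelated when evaluated as a sire model
    Ai <- Matrix::Diagonal(length(dm$unit_ids))
    dimnames(Ai) <- list(dm$unit_ids, dm$unit_ids)
  }
  fit <- reml_animal(dm$y, dm$X, dm$Z, Ai)
  h2 <- if (random_unit == "SIRE") {
    # sire variance is a quarter of the additive variance
    4 * fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e)
  } else fit$h2
  est <- structure(list(method = "ANIMAL_MODEL", h2_raw = h2,
                        h2_clamped = min(max(h2, 0), 1),
                        components = c(sigma2_u = fit$sigma2_u,
                                       sigma2_e = fit$sigma2_e)),
                   class = "h2_estimate")
  list(estimate = est, fit = fit)
}
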