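# Shared fixtures and independent oracles, built in code at test time.

# -- small hand-written flock exercised by records/report/CLI tests ----------
fixture_flock <- function() {
  animals <- data.frame(
    animal_id = c("R1", "R2", "E1", "E2", "W1", "L1", "L2", "L3"),
    sire_id = c(NA, NA, NA, NA, NA, "R1", "R1", "R2"),
    dam_id = c(NA, NA, NA, NA, NA, "E1", "E1", "E2"),
    sex = c("MALE", "MALE", "FEMALE", "FEMALE", "WETHER",
            "MALE", "FEMALE", "FEMALE"),
    breed = c("Corriedale", "Rambouillet", "Corriedale", "Rambouillet",
              "Corriedale", "Corriedale", "Corriedale", "Rambouillet"),
    birth_date = as.Date(c("2013-03-10", "2013-04-02", "2013-03-20",
                           "2013-04-15", "2013-05-01", "2016-03-05",
                           "2016-03-05", "2016-04-01")),
    farm_id = c("F1", "F1", "F1", "F2", "F1", "F1", "F1", "F2"),
    entry_date = as.Date(c("2013-03-10", "2013-04-02", "2013-03-20",
                           "2013-04-15", "2013-05-01", "2016-03-05",
                           "2016-03-05", "2016-04-01")),
    disposal_date = as.Date(c(NA, NA, NA, NA, NA, NA, NA, "2016-11-20")),
    disposal_reason = c(NA, NA, NA, NA, NA, NA, NA, "DEATH"),
    stringsAsFactors = FALSE)
  traits <- data.frame(
    animal_id = c("L1", "L1", "L2", "R1", "R1", "E1", "E1"),
    trait_code = c("BWT", "WWT", "BWT", "GFY", "GFY", "FD", "SL"),
    value = c(3.1, 14.5, 2.9, 1.2, 1.4, 24.5, 8.2),
    record_date = as.Date(c("2016-03-05", "2016-06-04", "2016-03-05",
                            "2015-06-01", "2016-06-01", "2016-06-01",
                            "2016-06-01")),
    stringsAsFactors = FALSE)
  repro <- data.frame(
    ewe_id = c("E1", "E2", "E1"),
    ram_id = c("R1", "R2", "R1"),
    mating_date = as.Date(c("2015-10-05", "2015-11-01", "2014-10-05")),
    outcome = c("LAMBING", "LAMBING", "ABORTION"),
    outcome_date = as.Date(c("2016-03-05", "2016-04-01", "2015-03-01")),
    lamb_ids = c("L1;L2", "L3", ""),
    stringsAsFactors = FALSE)
  health <- data.frame(
    animal_id = c("L1", "L2", "W1"),
    date = as.Date(c("2016-04-01", "2016-04-01", "2013-06-01")),
    kind = c("VACCINATION", "DEWORMING", "CASTRATION"),
    detail = c("clostridial", "oral drench", "ring method"),
    drug = c("CDT", "albendazole", ""),
    stringsAsFactors = FALSE)
  flock_dataset(animals, traits, repro, health)
}

# -- random pedigree generator (parents always earlier in the list) ----------
random_pedigree_frame <- function(n, p_known = 0.8) {
  ids <- sprintf("P%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < p_known) {
      sire[i] <- ids[sample.int(i - 1, 1)]
      dam_cand <- setdiff(seq_len(i - 1), match(sire[i], ids))
      if (length(dam_cand)) dam[i] <- ids[dam_cand[sample.int(length(dam_cand), 1)]]
    }
  }
  data.frame(animal_id = ids, sire_id = sire, dam_id = dam,
             stringsAsFactors = FALSE)
}

# -- independent kinship oracle: phi(i,j) by textbook recursion --------------
kinship_oracle <- function(frame) {
  ids <- frame$animal_id
  s <- match(frame$sire_id, ids)
  d <- match(frame$dam_id, ids)
  n <- length(ids)
  phi <- matrix(NA_real_, n, n)
  get <- function(i, j) {
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + if (!is.na(s[i]) && !is.na(d[i])) get(s[i], d[i]) else 0)
    } else {
      # recurse on the later-listed animal (parents precede offspring)
      a <- max(i, j); b <- min(i, j)
      val <- 0
      if (!is.na(s[a])) val <- val + 0.5 * get(b, s[a])
      if (!is.na(d[a])) val <- val + 0.5 * get(b, d[a])
      val
    }
    phi[i, j] <<- v; phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) get(i, j)
  dimnames(phi) <- list(ids, ids)
  phi
}

# -- GLS/BLUP closed-form oracle via the phenotypic covariance matrix --------
vmatrix_blup_oracle <- function(y, X, Z, A, s2u, s2e) {
  Z <- as.matrix(Z); X <- as.matrix(X); A <- as.matrix(A)
  V <- Z %*% A %*% t(Z) * s2u + diag(length(y)) * s2e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2u * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = as.numeric(b), u = as.numeric(u))
}

# -- REML log-likelihood by direct dense algebra -----------------------------
reml_loglik_oracle <- function(y, X, Z, A, s2u, s2e) {
  Z <- as.matrix(Z); X <- as.matrix(X); A <- as.matrix(A)
  V <- Z %*% A %*% t(Z) * s2u + diag(length(y)) * s2e
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(y) %*% P %*% y)[1]
}

# -- definitional nested sums of squares (double loop) -----------------------
nested_ss_oracle <- function(design) {
  y <- design$value
  gm <- mean(y)
  ss_s <- ss_d <- ss_w <- 0
  for (s in unique(design$sire)) {
    ys <- y[design$sire == s]
    ss_s <- ss_s + length(ys) * (mean(ys) - gm)^2
    for (dm in unique(design$dam[design$sire == s])) {
      yd <- y[design$dam == dm]
      ss_d <- ss_d + length(yd) * (mean(yd) - mean(ys))^2
      ss_w <- ss_w + sum((yd - mean(yd))^2)
    }
  }
  list(ss_s = ss_s, ss_d = ss_d, ss_w = ss_w)
}
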