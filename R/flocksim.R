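#' Simulation parameters for a synthetic flock
#'
#' Defaults describe a mid-sized organized sheep farm network: a modest
#' founder sire battery reused across dams (creating half-sib structure),
#' moderate yearling-weight heritability, phenotypic variance typical of
#' 12-month body weight in medium-frame breeds (kg scale), a male growth
#' advantage, mild year trends, multiple farms sharing the pedigree, and
#' pre-yearling survival of 90%.
#'
#' @param n_founder_sires,n_founder_dams founder counts.
#' @param n_generations total generations including the founders (>= 1).
#' @param progeny_per_dam lambs per dam per generation.
#' @param h2_true narrow-sense heritability of the genetic trait (W12M).
#' @param sigma2_p phenotypic variance of W12M (kg^2).
#' @param mu W12M population mean (kg).
#' @param sex_effect additive shift for males (kg).
#' @param year_effects per-generation fixed shifts (kg); recycled/truncated
#'   to `n_generations`.
#' @param n_farms farms assigned round-robin.
#' @param survival_to_12m probability a lamb survives to 12 months.
#' @param allow_close_mating if `TRUE`, dams may be mated to related sires
#'   of any earlier generation (inbreeding-focused fixtures); by default
#'   mating is within the parental generation, which excludes
#'   parent-offspring pairs.
#' @param seed integer seed; every stochastic draw is governed by it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_founder_sires = 10L, n_founder_dams = 50L,
                       n_generations = 3L, progeny_per_dam = 2L,
                       h2_true = 0.3, sigma2_p = 25, mu = 30,
                       sex_effect = 2, year_effects = c(0, 0.5, 1, 1.5, 2),
                       n_farms = 2L, survival_to_12m = 0.9,
                       allow_close_mating = FALSE, seed = 1L) {
  stopifnot(n_founder_sires >= 1, n_founder_dams >= 1, n_generations >= 1,
            progeny_per_dam >= 1, h2_true > 0, h2_true < 1, sigma2_p > 0,
            n_farms >= 1, survival_to_12m > 0, survival_to_12m <= 1)
  year_effects <- rep_len(year_effects, n_generations)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a pedigreed multi-farm flock with known genetic parameters
#'
#' Generates a complete flock ledger (animals, trait records, reproduction
#' and health events) together with the simulation truth (true breeding
#' values and realized inbreeding), so that every estimation routine in the
#' package can be checked against ground truth.
#'
#' Genetics follow the standard additive infinitesimal model: founder
#' breeding values are `N(0, h2 * sigma2_p)`; each offspring receives the
#' parental average plus a Mendelian-sampling deviation
#' `N(0, sigma2_A/2 * (1 - (F_s + F_d)/2))`. Phenotypes are
#' `mu + sex_effect * [MALE] + year_effect + a + e` with
#' `e ~ N(0, (1 - h2) * sigma2_p)`, recorded as `W12M` at 365 days for
#' animals that survive; every animal also gets a birth-weight (`BWT`)
#' record carrying a scaled share of the same genetic merit. Lambs that die
#' before 12 months receive a `DEATH` disposal and no yearling record.
#'
#' @param p a [sim_params()] object.
#' @return List with `dataset` (a [flock_dataset()]) and `truth` (data frame
#'   `animal_id`, `true_bv`, `F`, `generation`).
#' @export
simulate_flock <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  sigma2_A <- p$h2_true * p$sigma2_p
  sigma2_E <- (1 - p$h2_true) * p$sigma2_p
  base_year <- 2015L

  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0); a_bv <- numeric(0)
  birth <- as.Date(character(0)); dead <- logical(0)
  death_date <- as.Date(character(0))
  repro_rows <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("A%05d", counter)
  }

  # founders (generation 1)
  nf <- p$n_founder_sires + p$n_founder_dams
  for (k in seq_len(nf)) {
    id <- c(id, new_id())
    sire <- c(sire, NA_character_); dam <- c(dam, NA_character_)
    sex <- c(sex, if (k <= p$n_founder_sires) "MALE" else "FEMALE")
    gen <- c(gen, 1L)
    a_bv <- c(a_bv, rnorm(1, 0, sqrt(sigma2_A)))
    birth <- c(birth, as.Date(sprintf("%d-03-01", base_year)) +
                 sample.int(30, 1) - 1L)
    dead <- c(dead, FALSE)
    death_date <- c(death_date, as.Date(NA))
  }

  for (g in seq_len(p$n_generations)[-1]) {
    # realized inbreeding of everyone so far drives Mendelian variances
    ped <- build_pedigree(data.frame(animal_id = id, sire_id = sire,
                                     dam_id = dam, stringsAsFactors = FALSE))
    Fall <- inbreeding(ped)[id]
    if (p$allow_close_mating) {
      sire_pool <- which(sex == "MALE" & !dead & gen < g)
      dam_pool <- which(sex == "FEMALE" & !dead & gen < g)
    } else {
      sire_pool <- which(sex == "MALE" & !dead & gen == g - 1L)
      dam_pool <- which(sex == "FEMALE" & !dead & gen == g - 1L)
    }
    if (!length(sire_pool) || !length(dam_pool)) {
      stop("infeasible mating structure: no surviving sires or dams for ",
           "generation ", g, call. = FALSE)
    }
    sire_pool <- sire_pool[seq_len(min(length(sire_pool), p$n_founder_sires))]
    dam_pool <- dam_pool[seq_len(min(length(dam_pool), p$n_founder_dams))]
    yr <- base_year + (g - 1L)
    for (dm in dam_pool) {
      sr <- sire_pool[sample.int(length(sire_pool), 1)]
      bdate <- as.Date(sprintf("%d-03-01", yr)) + sample.int(30, 1) - 1L
      lambs <- character(0)
      for (l in seq_len(p$progeny_per_dam)) {
        cid <- new_id()
        msd <- sqrt(0.5 * sigma2_A * (1 - 0.5 * (Fall[id[sr]] + Fall[id[dm]])))
        id <- c(id, cid)
        sire <- c(sire, id[sr]); dam <- c(dam, id[dm])
        sex <- c(sex, sample(c("MALE", "FEMALE"), 1))
        gen <- c(gen, g)
        a_bv <- c(a_bv, 0.5 * (a_bv[sr] + a_bv[dm]) + rnorm(1, 0, msd))
        birth <- c(birth, bdate)
        dies <- runif(1) > p$survival_to_12m
        dead <- c(dead, dies)
        death_date <- c(death_date,
                        if (dies) bdate + sample.int(364, 1) else as.Date(NA))
        lambs <- c(lambs, cid)
      }
      repro_rows[[length(repro_rows) + 1]] <- data.frame(
        ewe_id = id[dm], ram_id = id[sr], mating_date = bdate - 150L,
        outcome = "LAMBING", outcome_date = bdate,
        lamb_ids = paste(lambs, collapse = ";"), stringsAsFactors = FALSE)
    }
  }

  n <- length(id)
  farms <- paste0("F", (seq_len(n) - 1L) %% p$n_farms + 1L)
  animals <- data.frame(
    animal_id = id, sire_id = sire, dam_id = dam, sex = sex,
    breed = "Corriedale", birth_date = birth, farm_id = farms,
    entry_date = birth, disposal_date = death_date,
    disposal_reason = ifelse(dead, "DEATH", NA_character_),
    stringsAsFactors = FALSE)

  e12 <- rnorm(n, 0, sqrt(sigma2_E))
  y12 <- p$mu + ifelse(sex == "MALE", p$sex_effect, 0) +
    p$year_effects[gen] + a_bv + e12
  bwt <- pmax(0.8, 3 + 0.05 * a_bv + rnorm(n, 0, 0.3))
  traits <- rbind(
    data.frame(animal_id = id, trait_code = "BWT", value = bwt,
               record_date = birth, stringsAsFactors = FALSE),
    data.frame(animal_id = id[!dead], trait_code = "W12M",
               value = pmax(0.5, y12[!dead]), record_date = birth[!dead] + 365L,
               stringsAsFactors = FALSE))
  traits <- traits[order(traits$animal_id, traits$trait_code), ]
  rownames(traits) <- NULL

  repro <- if (length(repro_rows)) do.call(rbind, repro_rows) else empty_repro()
  # one routine vaccination per animal at 21 days (before any simulated death)
  hdate <- as.Date(ifelse(!is.na(death_date) & death_date < birth + 21L,
                          death_date, birth + 21L), origin = "1970-01-01")
  health <- data.frame(animal_id = id, date = hdate, kind = "VACCINATION",
                       detail = "routine clostridial vaccine", drug = "CDT",
                       stringsAsFactors = FALSE)

  ds <- flock_dataset(animals, traits, repro, health)
  ped <- build_pedigree(animals)
  Fall <- inbreeding(ped)[id]
  truth <- data.frame(animal_id = id, true_bv = a_bv, F = unname(Fall),
                      generation = gen, stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Simulate a balanced or unbalanced nested sib design
#'
#' Draws phenotypes from `y_ijk = mu + s_i + d_ij + e_ijk` with sire and dam
#' variance each `h2 * sigma2_p / 4` (the half-sib expectation with no
#' maternal or dominance inflation) and residual variance making up the
#' remainder of `sigma2_p`.
#'
#' @param s number of sires (>= 2).
#' @param d dams per sire.
#' @param n progeny per dam.
#' @param h2 true heritability (must satisfy `h2 < 2` so the within-dam
#'   variance stays positive).
#' @param sigma2_p phenotypic variance.
#' @param mu overall mean.
#' @param seed integer seed.
#' @return Data frame with columns `sire`, `dam`, `value`; attribute
#'   `truth` holds the variance components used.
#' @export
simulate_sib_design <- function(s, d, n, h2, sigma2_p = 1, mu = 30,
                                seed = 1L) {
  stopifnot(s >= 2, d >= 1, n >= 2, sigma2_p > 0)
  s2s <- h2 * sigma2_p / 4
  s2d <- h2 * sigma2_p / 4
  s2w <- sigma2_p - s2s - s2d
  if (s2w <= 0) stop("impossible partition: h2 >= 2", call. = FALSE)
  set.seed(seed)
  sire_eff <- rnorm(s, 0, sqrt(s2s))
  rows <- vector("list", s * d)
  k <- 0L
  for (i in seq_len(s)) {
    dam_eff <- rnorm(d, 0, sqrt(s2d))
    for (j in seq_len(d)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        sire = sprintf("S%03d", i), dam = sprintf("S%03d.D%03d", i, j),
        value = mu + sire_eff[i] + dam_eff[j] + rnorm(n, 0, sqrt(s2w)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(sigma2_s = s2s, sigma2_d = s2d, sigma2_w = s2w,
                             h2 = h2, sigma2_p = sigma2_p)
  out
}

#' Simulate a wool market price table
#'
#' Draws fibre diameter uniformly over 18–36 micrometres and staple length
#' over 5–12 cm (typical apparel-to-carpet wool ranges), then prices each
#' clip as `intercept + slope_fd * FD + slope_sl * SL + noise`. Used to
#' exercise the price-regression economic values.
#'
#' @param slope_fd price change per micrometre (typically negative: finer
#'   wool is worth more).
#' @param slope_sl price change per cm of staple length.
#' @param intercept base price per kg.
#' @param noise_sd residual price noise.
#' @param n number of observations (>= 3).
#' @param seed integer seed.
#' @return Data frame with columns `price`, `fibre_diameter`,
#'   `staple_length`.
#' @export
simulate_wool_market <- function(slope_fd = -1.5, slope_sl = 2,
                                 intercept = 200, noise_sd = 3, n = 200L,
                                 seed = 1L) {
  stopifnot(n >= 3)
  set.seed(seed)
  fd <- runif(n, 18, 36)
  sl <- runif(n, 5, 12)
  price <- intercept + slope_fd * fd + slope_sl * sl + rnorm(n, 0, noise_sd)
  data.frame(price = price, fibre_diameter = fd, staple_length = sl)
}
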