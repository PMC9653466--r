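#' Selection index over multiple traits
#'
#' The merit index `I = v1*EBV1 + ... + vn*EBVn`: a weighted sum of
#' estimated breeding values, with the (economic) weights supplied per
#' trait. Animals missing an EBV for any index trait are excluded with a
#' message. The EBVs are meant to come from [blup_ebv()] (or
#' [individual_ebv()]), not typed by hand.
#'
#' @param ebvs data frame with column `animal_id` and one column per index
#'   trait, or a list of EBV tables (one per trait) to be joined.
#' @param traits ordered character vector of trait codes.
#' @param weights numeric weights `v`, one per trait, at least one nonzero.
#' @return Data frame with `animal_id`, `index`, and a dense `rank` column
#'   (descending index, ties by ascending id).
#' @export
selection_index <- function(ebvs, traits, weights) {
  if (!length(traits)) stop("empty trait list", call. = FALSE)
  if (length(weights) != length(traits)) {
    stop("weights and traits differ in length", call. = FALSE)
  }
  if (all(weights == 0)) stop("at least one weight must be nonzero",
                              call. = FALSE)
  if (is.list(ebvs) && !is.data.frame(ebvs)) {
    wide <- NULL
    for (tb in ebvs) {
      tr <- unique(tb$trait)
      stopifnot(length(tr) == 1)
      part <- data.frame(animal_id = tb$animal_id, v = tb$ebv,
                         stringsAsFactors = FALSE)
      names(part)[2] <- tr
      wide <- if (is.null(wide)) part else merge(wide, part, by = "animal_id",
                                                 all = TRUE)
    }
    ebvs <- wide
  }
  missing_tr <- setdiff(traits, names(ebvs))
  if (length(missing_tr)) {
    stop("no EBV column for trait(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  M <- as.matrix(ebvs[traits])
  complete <- stats::complete.cases(M)
  if (any(!complete)) {
    message("excluding ", sum(!complete),
            " animal(s) missing an EBV for an index trait")
  }
  M <- M[complete, , drop = FALSE]
  idx <- as.numeric(M %*% weights)
  out <- data.frame(animal_id = ebvs$animal_id[complete], index = idx,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$index, out$animal_id), , drop = FALSE]
  out$rank <- match(out$index, sort(unique(out$index), decreasing = TRUE))
  rownames(out) <- NULL
  out
}

#' Relative economic value of a body-weight trait
#'
#' `((book_value / trait_mean) / days_to_attain) * survivability`: the
#' market value per kg of the trait, amortized over the days taken to reach
#' it and discounted by the probability the animal survives to express it.
#'
#' @param book_value market value of the trait (currency).
#' @param trait_mean population mean of the trait (kg).
#' @param days_to_attain days to reach the trait age.
#' @param survivability survival probability in (0, 1].
#' @return The economic value (currency per kg per day scale).
#' @export
econ_value_weight <- function(book_value, trait_mean, days_to_attain,
                              survivability = 1) {
  if (trait_mean <= 0) stop("trait_mean must be positive", call. = FALSE)
  if (days_to_attain <= 0) stop("days_to_attain must be positive",
                                call. = FALSE)
  stopifnot(book_value > 0, survivability > 0, survivability <= 1)
  ((book_value / trait_mean) / days_to_attain) * survivability
}

#' Relative economic value of fleece weight
#'
#' `(book_value / days_to_attain) * mean_fleece_weight`: the per-day wool
#' income scaled by the flock's mean annual greasy fleece yield.
#'
#' @param book_value market value per kg of wool.
#' @param days_to_attain days over which the fleece is grown (typically a
#'   365-day clip cycle).
#' @param mean_fleece mean greasy fleece weight (kg).
#' @return The economic value.
#' @export
econ_value_fleece <- function(book_value, days_to_attain, mean_fleece) {
  if (days_to_attain <= 0) stop("days_to_attain must be positive",
                                call. = FALSE)
  stopifnot(book_value > 0, mean_fleece >= 0)
  (book_value / days_to_attain) * mean_fleece
}

#' Simple linear regression fit
#'
#' Ordinary least squares of `y` on a single predictor: slope
#' `a = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)` and intercept
#' `b = ybar - a * xbar`, so the fitted line always passes through
#' `(xbar, ybar)`.
#'
#' @param x,y numeric vectors of equal length (>= 2); `x` must vary.
#' @return List with `a` (slope), `b` (intercept), `r2`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (var(x) == 0) stop("degenerate predictor: x has no variation",
                        call. = FALSE)
  fit <- lm(y ~ x)
  cf <- coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(a = unname(cf[2]), b = unname(cf[1]), r2 = r2)
}

#' Relative economic value of a wool quality trait
#'
#' Regresses price per kg of wool on fibre diameter or staple length across
#' market observations; the slope is taken as the trait's relative economic
#' value (per micrometre or per cm), sign preserved — finer fibre typically
#' carries a negative slope because it commands a premium.
#'
#' @param obs data frame with columns `price`, `fibre_diameter`,
#'   `staple_length` (at least 3 rows).
#' @param trait `"FIBRE_DIAMETER"` or `"STAPLE_LENGTH"`.
#' @return The regression slope.
#' @export
econ_value_wool_quality <- function(obs,
                                    trait = c("FIBRE_DIAMETER",
                                              "STAPLE_LENGTH")) {
  trait <- match.arg(trait)
  stopifnot(is.data.frame(obs), nrow(obs) >= 3,
            all(c("price", "fibre_diameter", "staple_length") %in% names(obs)))
  x <- switch(trait, FIBRE_DIAMETER = obs$fibre_diameter,
              STAPLE_LENGTH = obs$staple_length)
  ols_fit(x, obs$price)$a
}

#' Survivability to a trait age from flock records
#'
#' Optional helper for the survivability input of [econ_value_weight()]:
#' the fraction of animals born that were still present `age_days` after
#' birth (disposal strictly after the target date counts as present).
#'
#' @param ds a [flock_dataset()].
#' @param age_days target age in days (default 365).
#' @return Proportion between 0 and 1.
#' @export
survivability_from_records <- function(ds, age_days = 365L) {
  stopifnot(inherits(ds, "flock_dataset"))
  a <- ds$animals
  born <- !is.na(a$birth_date)
  target <- a$birth_date + age_days
  alive <- is.na(a$disposal_date) | a$disposal_date > target
  sum(born & alive) / sum(born)
}
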