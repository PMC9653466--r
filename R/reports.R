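report_table <- function(df, type, as_of = NULL, filters = list(),
                         extra = list()) {
  rownames(df) <- NULL
  attr(df, "report_type") <- type
  attr(df, "as_of") <- as_of
  attr(df, "filters") <- filters
  for (k in names(extra)) attr(df, k) <- extra[[k]]
  class(df) <- c("report_table", "data.frame")
  df
}

#' Write a report table as CSV with metadata comment lines
#'
#' Metadata (report type, as-of date, filters, optional generation
#' timestamp) goes into `#`-prefixed header lines; the table body below is
#' a plain CSV whose bytes depend only on the data, so golden-file
#' comparisons can ignore the comment lines.
#'
#' @param tab a report table.
#' @param path output file (or `""` for stdout).
#' @param timestamp include a generation timestamp line.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(tab, path, timestamp = FALSE) {
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  meta <- c(sprintf("# report: %s", attr(tab, "report_type") %||% "table"))
  if (!is.null(attr(tab, "as_of"))) {
    meta <- c(meta, sprintf("# as_of: %s", format(attr(tab, "as_of"))))
  }
  fl <- attr(tab, "filters")
  for (k in names(fl)) {
    if (!is.null(fl[[k]])) meta <- c(meta, sprintf("# %s: %s", k, fl[[k]]))
  }
  if (timestamp) meta <- c(meta, sprintf("# generated: %s", Sys.time()))
  writeLines(meta, con)
  df <- as.data.frame(tab)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        format(df[[j]], digits = 10, trim = TRUE,
                               scientific = FALSE))
    }
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_filters <- function(snap, breed = NULL, farm = NULL) {
  if (!is.null(breed)) {
    if (!breed %in% snap$breed) stop("unknown breed filter: ", breed,
                                     call. = FALSE)
    snap <- snap[snap$breed == breed, , drop = FALSE]
  }
  if (!is.null(farm)) snap <- snap[snap$farm_id == farm, , drop = FALSE]
  snap
}

#' Flock inventory on a date
#'
#' Counts the animals present on `as_of` by class: total, breedable ewes
#' (females at or above breedable age), breedable rams (entire males at or
#' above breedable age), wethers (castrates of any age), and lambs (under
#' 12 months), overall and per breed. Castration events recorded in the
#' health table reclassify males before counting.
#'
#' @param ds a [flock_dataset()].
#' @param as_of date.
#' @param breed,farm optional filters.
#' @param config configuration (age thresholds); see [default_config()].
#' @return A report table with one row per breed plus an `ALL` row.
#' @export
inventory_report <- function(ds, as_of, breed = NULL, farm = NULL,
                             config = default_config()) {
  as_of <- as.Date(as_of)
  snap <- apply_filters(snapshot(ds, as_of, config), breed, farm)
  count_block <- function(s, label) {
    adult <- s$age_days >= config$breedable_age_days
    data.frame(breed = label, TOTAL = nrow(s),
               EWES = sum(s$sex_effective == "FEMALE" & adult),
               RAMS = sum(s$sex_effective == "MALE" & adult),
               WETHERS = sum(s$sex_effective == "WETHER"),
               LAMBS = sum(s$age_days < config$lamb_age_days),
               stringsAsFactors = FALSE)
  }
  breeds <- sort(unique(snap$breed))
  rows <- lapply(breeds, function(b)
    count_block(snap[snap$breed == b, , drop = FALSE], b))
  rows[[length(rows) + 1]] <- count_block(snap, "ALL")
  report_table(do.call(rbind, rows), "inventory", as_of,
               list(breed = breed, farm = farm))
}

period_of <- function(as_of) as.Date(format(as_of, "%Y-01-01"))

#' Lambing and abortion report for the year of a date
#'
#' One row per reproduction event with an outcome date inside the calendar
#' year of `as_of` (up to `as_of` itself), with the ewe's running parity
#' (cumulative lambings through `as_of`). The lambing rate is the number of
#' lambing events in the period divided by the breedable ewes present at
#' the period start; it is `NA` when that denominator is zero.
#'
#' @inheritParams inventory_report
#' @return A report table; attributes `lambing_rate`, `n_lambings`,
#'   `n_abortions`, `n_breedable_ewes`.
#' @export
reproduction_report <- function(ds, as_of, farm = NULL,
                                config = default_config()) {
  as_of <- as.Date(as_of)
  start <- period_of(as_of)
  r <- ds$repro
  if (!is.null(farm)) {
    ewes_on_farm <- ds$animals$animal_id[ds$animals$farm_id == farm]
    r <- r[r$ewe_id %in% ewes_on_farm, , drop = FALSE]
  }
  in_period <- !is.na(r$outcome_date) & r$outcome_date >= start &
    r$outcome_date <= as_of
  rows <- r[in_period, , drop = FALSE]
  n_lambs <- ifelse(nzchar(rows$lamb_ids) & !is.na(rows$lamb_ids),
                    lengths(strsplit(rows$lamb_ids, ";", fixed = TRUE)), 0L)
  parity <- vapply(seq_len(nrow(rows)), function(i) {
    sum(r$ewe_id == rows$ewe_id[i] & r$outcome == "LAMBING" &
          !is.na(r$outcome_date) & r$outcome_date <= as_of)
  }, integer(1))
  out <- data.frame(ewe_id = rows$ewe_id, ram_id = rows$ram_id,
                    outcome = rows$outcome, outcome_date = rows$outcome_date,
                    n_lambs = as.integer(n_lambs), parity = parity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$outcome_date, out$ewe_id), , drop = FALSE]

  snap0 <- apply_filters(snapshot(ds, start, config), NULL, farm)
  breedable <- sum(snap0$sex_effective == "FEMALE" &
                     snap0$age_days >= config$breedable_age_days)
  n_lambings <- sum(out$outcome == "LAMBING")
  rate <- if (breedable > 0) n_lambings / breedable else NA_real_
  report_table(out, "reproduction", as_of, list(farm = farm),
               list(lambing_rate = rate, n_lambings = n_lambings,
                    n_abortions = sum(out$outcome == "ABORTION"),
                    n_breedable_ewes = breedable))
}

#' Body weights at standard ages
#'
#' For each animal, places the weight record nearest each standard age
#' point (birth, 90, 180, 270, 365 days) into that age's column, provided
#' the record's age is within the window `age * age_window_frac` of the
#' point (a birth-weight record must be on the birth day); records outside
#' every window are left out. Breed-wise column means are attached as the
#' `breed_means` attribute.
#'
#' @inheritParams inventory_report
#' @return A report table with one row per animal having any assigned
#'   record.
#' @export
production_report <- function(ds, as_of = NULL, breed = NULL, farm = NULL,
                              config = default_config()) {
  a <- apply_filters(ds$animals, breed, farm)
  t <- ds$traits[ds$traits$trait_code %in%
                   c("BWT", "WWT", "W6M", "W9M", "W12M"), , drop = FALSE]
  if (!is.null(as_of)) t <- t[t$record_date <= as.Date(as_of), , drop = FALSE]
  t <- t[t$animal_id %in% a$animal_id, , drop = FALSE]
  ages <- config$standard_ages
  cols <- paste0("W", ages, "D")
  birth <- setNames(a$birth_date, a$animal_id)
  t$age <- as.integer(t$record_date - birth[t$animal_id])

  rows <- lapply(split(t, t$animal_id), function(tt) {
    vals <- rep(NA_real_, length(ages))
    for (k in seq_along(ages)) {
      win <- ages[k] * config$age_window_frac
      cand <- tt[abs(tt$age - ages[k]) <= win, , drop = FALSE]
      if (nrow(cand)) {
        vals[k] <- cand$value[which.min(abs(cand$age - ages[k]))]
      }
    }
    if (all(is.na(vals))) return(NULL)
    cbind(data.frame(animal_id = tt$animal_id[1],
                     breed = a$breed[match(tt$animal_id[1], a$animal_id)],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(vals, cols))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(animal_id = character(), breed = character(),
                     stringsAsFactors = FALSE),
          as.data.frame(sapply(cols, function(x) numeric(0),
                               simplify = FALSE)))
  out <- out[order(out$animal_id), , drop = FALSE]
  bm <- if (nrow(out)) {
    do.call(rbind, lapply(split(out, out$breed), function(g) {
      cbind(data.frame(breed = g$breed[1], stringsAsFactors = FALSE),
            as.data.frame(as.list(colMeans(g[cols], na.rm = TRUE))))
    }))
  } else NULL
  report_table(out, "production", if (is.null(as_of)) NULL else as.Date(as_of),
               list(breed = breed, farm = farm), list(breed_means = bm))
}

#' Wool clip report
#'
#' Per animal: number of greasy-fleece (GFY) clips, total and mean clip
#' weight, and the most recent fibre diameter and staple length
#' measurements. Animals with no wool records are retained with zero clips.
#'
#' @inheritParams inventory_report
#' @return A report table with one row per animal.
#' @export
wool_report <- function(ds, as_of = NULL, breed = NULL, farm = NULL,
                        config = default_config()) {
  a <- apply_filters(ds$animals, breed, farm)
  t <- ds$traits
  if (!is.null(as_of)) t <- t[t$record_date <= as.Date(as_of), , drop = FALSE]
  latest <- function(id, code) {
    tt <- t[t$animal_id == id & t$trait_code == code, , drop = FALSE]
    if (!nrow(tt)) return(NA_real_)
    tt$value[which.max(tt$record_date)]
  }
  rows <- lapply(a$animal_id, function(id) {
    g <- t[t$animal_id == id & t$trait_code == "GFY", , drop = FALSE]
    data.frame(animal_id = id, clips = nrow(g),
               total_gfy = if (nrow(g)) sum(g$value) else 0,
               mean_gfy = if (nrow(g)) mean(g$value) else NA_real_,
               latest_fd = latest(id, "FD"), latest_sl = latest(id, "SL"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal_id), , drop = FALSE]
  report_table(out, "wool", if (is.null(as_of)) NULL else as.Date(as_of),
               list(breed = breed, farm = farm))
}

#' Health event report for the year of a date
#'
#' Events (vaccination, deworming, treatment, castration) with dates inside
#' the calendar year of `as_of` up to `as_of`, date-sorted, with per-kind
#' counts attached.
#'
#' @inheritParams inventory_report
#' @return A report table; attribute `counts_by_kind`.
#' @export
health_report <- function(ds, as_of, farm = NULL,
                          config = default_config()) {
  as_of <- as.Date(as_of)
  start <- period_of(as_of)
  h <- ds$health
  if (!is.null(farm)) {
    ids <- ds$animals$animal_id[ds$animals$farm_id == farm]
    h <- h[h$animal_id %in% ids, , drop = FALSE]
  }
  h <- h[h$date >= start & h$date <= as_of, , drop = FALSE]
  h <- h[order(h$date, h$animal_id), , drop = FALSE]
  counts <- table(factor(h$kind, levels = HEALTH_KINDS))
  report_table(h, "health", as_of, list(farm = farm),
               list(counts_by_kind = counts))
}

#' Disposal and mortality report for the year of a date
#'
#' Disposals dated inside the calendar year of `as_of` up to `as_of`, with
#' breed-wise death counts and a mortality rate defined as deaths in the
#' period divided by the animals present at the period start.
#'
#' @inheritParams inventory_report
#' @return A report table; attributes `mortality`, `deaths_by_breed`,
#'   `disposals_by_reason`.
#' @export
disposal_report <- function(ds, as_of, farm = NULL,
                            config = default_config()) {
  as_of <- as.Date(as_of)
  start <- period_of(as_of)
  a <- if (!is.null(farm)) ds$animals[ds$animals$farm_id == farm, , drop = FALSE]
       else ds$animals
  disp <- a[!is.na(a$disposal_date) & a$disposal_date >= start &
              a$disposal_date <= as_of, , drop = FALSE]
  out <- disp[c("animal_id", "breed", "farm_id", "disposal_date",
                "disposal_reason")]
  out <- out[order(out$disposal_date, out$animal_id), , drop = FALSE]
  deaths <- out[out$disposal_reason == "DEATH", , drop = FALSE]
  snap0 <- apply_filters(snapshot(ds, start), NULL, farm)
  mortality <- if (nrow(snap0)) nrow(deaths) / nrow(snap0) else NA_real_
  report_table(out, "disposal", as_of, list(farm = farm),
               list(mortality = mortality,
                    deaths_by_breed = table(deaths$breed),
                    disposals_by_reason = table(out$disposal_reason)))
}

#' Yearly trend of a flock metric
#'
#' Evaluates a metric once per calendar year: flock size at year end,
#' lambing rate or mortality over the year, or the mean yearling weight
#' recorded in the year. Years with no data yield `NA` — no interpolation.
#'
#' @param ds a [flock_dataset()].
#' @param metric one of `"TOTAL"`, `"LAMBING_RATE"`, `"MORTALITY"`,
#'   `"MEAN_W12M"`.
#' @param years integer vector of calendar years.
#' @param config configuration list.
#' @return A report table with columns `year`, `value`.
#' @export
trend_report <- function(ds, metric = c("TOTAL", "LAMBING_RATE", "MORTALITY",
                                        "MEAN_W12M"),
                         years, config = default_config()) {
  metric <- match.arg(metric)
  stopifnot(length(years) >= 1)
  vals <- vapply(years, function(yr) {
    eoy <- as.Date(sprintf("%d-12-31", yr))
    switch(metric,
      TOTAL = nrow(snapshot(ds, eoy, config)),
      LAMBING_RATE = attr(reproduction_report(ds, eoy, config = config),
                          "lambing_rate") %||% NA_real_,
      MORTALITY = attr(disposal_report(ds, eoy, config = config),
                       "mortality") %||% NA_real_,
      MEAN_W12M = {
        t <- ds$traits
        sel <- t$trait_code == "W12M" & format(t$record_date, "%Y") == as.character(yr)
        if (any(sel)) mean(t$value[sel]) else NA_real_
      })
  }, numeric(1))
  report_table(data.frame(year = as.integer(years), value = vals),
               paste0("trend_", tolower(metric)), NULL, list())
}
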