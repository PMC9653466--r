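#' @useDynLib flockBLUP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd cor rnorm runif lm coef setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head
NULL

SEX_LEVELS <- c("MALE", "FEMALE", "WETHER")
DISPOSAL_REASONS <- c("DEATH", "SALE", "TRANSFER", "CULL")
REPRO_OUTCOMES <- c("LAMBING", "ABORTION", "NONE")
HEALTH_KINDS <- c("VACCINATION", "DEWORMING", "TREATMENT", "CASTRATION")
TRAIT_CODES <- c("BWT", "WWT", "W6M", "W9M", "W12M", "GFY", "FD", "SL")

# Weight-type traits (kg, must be > 0); FD is micrometres, SL centimetres.
WEIGHT_TRAITS <- c("BWT", "WWT", "W6M", "W9M", "W12M", "GFY")

parse_iso_date <- function(x, file = "", column = "") {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  nonblank <- !is.na(x) & nzchar(x)
  if (any(nonblank)) {
    d <- as.Date(x[nonblank], format = "%Y-%m-%d")
    bad <- is.na(d)
    if (any(bad)) {
      i <- which(nonblank)[which(bad)[1]]
      stop(sprintf("malformed date '%s' in %s, line %d, column %s",
                   x[i], file, i + 1L, column), call. = FALSE)
    }
    out[nonblank] <- d
  }
  out
}

canon_parent <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

empty_animals <- function() {
  data.frame(animal_id = character(), sire_id = character(),
             dam_id = character(), sex = character(), breed = character(),
             birth_date = as.Date(character()), farm_id = character(),
             entry_date = as.Date(character()),
             disposal_date = as.Date(character()),
             disposal_reason = character(), stringsAsFactors = FALSE)
}

empty_traits <- function() {
  data.frame(animal_id = character(), trait_code = character(),
             value = numeric(), record_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

empty_repro <- function() {
  data.frame(ewe_id = character(), ram_id = character(),
             mating_date = as.Date(character()), outcome = character(),
             outcome_date = as.Date(character()), lamb_ids = character(),
             stringsAsFactors = FALSE)
}

empty_health <- function() {
  data.frame(animal_id = character(), date = as.Date(character()),
             kind = character(), detail = character(), drug = character(),
             stringsAsFactors = FALSE)
}

#' Construct a flock dataset
#'
#' Bundles the four record tables of a flock (animal registrations, trait
#' measurements, reproduction events, health events) into a single object
#' that all evaluation and reporting functions consume.
#'
#' @param animals data frame with columns `animal_id`, `sire_id`, `dam_id`
#'   (`NA` for unknown parents), `sex` (`MALE`/`FEMALE`/`WETHER`), `breed`,
#'   `birth_date`, `farm_id`, `entry_date`, `disposal_date`,
#'   `disposal_reason` (dates of class `Date`, `NA` when absent).
#' @param traits data frame with columns `animal_id`, `trait_code`, `value`,
#'   `record_date`.
#' @param repro data frame with columns `ewe_id`, `ram_id`, `mating_date`,
#'   `outcome`, `outcome_date`, `lamb_ids` (semicolon-joined ids).
#' @param health data frame with columns `animal_id`, `date`, `kind`,
#'   `detail`, `drug`.
#' @return An object of class `flock_dataset`.
#' @export
flock_dataset <- function(animals = empty_animals(), traits = empty_traits(),
                          repro = empty_repro(), health = empty_health()) {
  animals$animal_id <- as.character(animals$animal_id)
  if (anyDuplicated(animals$animal_id)) {
    dups <- unique(animals$animal_id[duplicated(animals$animal_id)])
    stop("duplicate animal_id: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(animals$animal_id))) {
    stop("empty animal_id", call. = FALSE)
  }
  if (is.null(animals$entry_date)) animals$entry_date <- animals$birth_date
  animals$entry_date[is.na(animals$entry_date)] <-
    animals$birth_date[is.na(animals$entry_date)]
  self_parent <- !is.na(animals$sire_id) & animals$sire_id == animals$animal_id |
    !is.na(animals$dam_id) & animals$dam_id == animals$animal_id
  if (any(self_parent)) {
    stop("animal recorded as its own parent: ",
         paste(animals$animal_id[self_parent], collapse = ", "), call. = FALSE)
  }
  structure(list(animals = animals, traits = traits, repro = repro,
                 health = health), class = "flock_dataset")
}

#' @export
print.flock_dataset <- function(x, ...) {
  cat("flock_dataset:", nrow(x$animals), "animals,",
      nrow(x$traits), "trait records,",
      nrow(x$repro), "reproduction events,",
      nrow(x$health), "health events\n")
  invisible(x)
}

read_table_checked <- function(path, required_cols, optional_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = character())
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in optional_cols) if (is.null(df[[col]])) df[[col]] <- ""
  df
}

#' Read a flock dataset from CSV files
#'
#' Reads the four flat-file tables of a flock ledger. Dates must be ISO-8601
#' (`YYYY-MM-DD`). Unknown parents may be written as an empty cell or a
#' literal `"0"`; both are canonicalized to `NA`. A missing `entry_date`
#' column (or blank cells in it) defaults to the birth date, matching the
#' on-farm-birth case.
#'
#' @param animals_csv path to the animal registration table.
#' @param traits_csv optional path to the trait record table.
#' @param repro_csv optional path to the reproduction event table.
#' @param health_csv optional path to the health event table.
#' @return A [flock_dataset()].
#' @seealso [write_flock()], [validate_flock()]
#' @export
read_flock <- function(animals_csv, traits_csv = NULL, repro_csv = NULL,
                       health_csv = NULL) {
  a <- read_table_checked(animals_csv,
                          c("animal_id", "sire_id", "dam_id", "sex", "breed",
                            "birth_date", "farm_id"),
                          c("entry_date", "disposal_date", "disposal_reason"))
  animals <- data.frame(
    animal_id = trimws(a$animal_id),
    sire_id = canon_parent(a$sire_id),
    dam_id = canon_parent(a$dam_id),
    sex = trimws(a$sex),
    breed = trimws(a$breed),
    birth_date = parse_iso_date(a$birth_date, animals_csv, "birth_date"),
    farm_id = trimws(a$farm_id),
    entry_date = parse_iso_date(a$entry_date, animals_csv, "entry_date"),
    disposal_date = parse_iso_date(a$disposal_date, animals_csv, "disposal_date"),
    disposal_reason = ifelse(nzchar(trimws(a$disposal_reason)),
                             trimws(a$disposal_reason), NA_character_),
    stringsAsFactors = FALSE)
  bad_sex <- !animals$sex %in% SEX_LEVELS
  if (any(bad_sex)) {
    stop(sprintf("malformed row in %s, line %d, column sex: '%s'",
                 animals_csv, which(bad_sex)[1] + 1L,
                 animals$sex[which(bad_sex)[1]]), call. = FALSE)
  }

  traits <- empty_traits()
  if (!is.null(traits_csv)) {
    t <- read_table_checked(traits_csv,
                            c("animal_id", "trait_code", "value", "record_date"))
    value <- suppressWarnings(as.numeric(t$value))
    bad <- is.na(value) | !is.finite(value)
    if (any(bad)) {
      stop(sprintf("malformed row in %s, line %d, column value: '%s'",
                   traits_csv, which(bad)[1] + 1L, t$value[which(bad)[1]]),
           call. = FALSE)
    }
    traits <- data.frame(animal_id = trimws(t$animal_id),
                         trait_code = trimws(t$trait_code), value = value,
                         record_date = parse_iso_date(t$record_date, traits_csv,
                                                      "record_date"),
                         stringsAsFactors = FALSE)
  }

  repro <- empty_repro()
  if (!is.null(repro_csv)) {
    r <- read_table_checked(repro_csv,
                            c("ewe_id", "ram_id", "mating_date", "outcome"),
                            c("outcome_date", "lamb_ids"))
    repro <- data.frame(ewe_id = trimws(r$ewe_id), ram_id = trimws(r$ram_id),
                        mating_date = parse_iso_date(r$mating_date, repro_csv,
                                                     "mating_date"),
                        outcome = trimws(r$outcome),
                        outcome_date = parse_iso_date(r$outcome_date, repro_csv,
                                                      "outcome_date"),
                        lamb_ids = trimws(r$lamb_ids),
                        stringsAsFactors = FALSE)
    bad <- !repro$outcome %in% REPRO_OUTCOMES
    if (any(bad)) {
      stop(sprintf("malformed row in %s, line %d, column outcome: '%s'",
                   repro_csv, which(bad)[1] + 1L, repro$outcome[which(bad)[1]]),
           call. = FALSE)
    }
  }

  health <- empty_health()
  if (!is.null(health_csv)) {
    h <- read_table_checked(health_csv, c("animal_id", "date", "kind"),
                            c("detail", "drug"))
    health <- data.frame(animal_id = trimws(h$animal_id),
                         date = parse_iso_date(h$date, health_csv, "date"),
                         kind = trimws(h$kind), detail = h$detail,
                         drug = h$drug, stringsAsFactors = FALSE)
    bad <- !health$kind %in% HEALTH_KINDS
    if (any(bad)) {
      stop(sprintf("malformed row in %s, line %d, column kind: '%s'",
                   health_csv, which(bad)[1] + 1L, health$kind[which(bad)[1]]),
           call. = FALSE)
    }
  }

  flock_dataset(animals, traits, repro, health)
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
fmt_chr <- function(x) ifelse(is.na(x), "", x)

#' Write a flock dataset to canonical CSV files
#'
#' Writes the four tables in the canonical dialect: ISO-8601 dates, unknown
#' parents as empty cells, numeric trait values with up to 15 significant
#' digits. Re-reading the written files reproduces the dataset field for
#' field, and re-writing a read canonical file is byte-identical.
#'
#' @param ds a [flock_dataset()].
#' @param dir output directory (created if needed). Files are named
#'   `animals.csv`, `traits.csv`, `repro.csv`, `health.csv`.
#' @return The directory path, invisibly.
#' @export
write_flock <- function(ds, dir) {
  stopifnot(inherits(ds, "flock_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- ds$animals
  out_a <- data.frame(animal_id = a$animal_id, sire_id = fmt_chr(a$sire_id),
                      dam_id = fmt_chr(a$dam_id), sex = a$sex, breed = a$breed,
                      birth_date = fmt_date(a$birth_date), farm_id = a$farm_id,
                      entry_date = fmt_date(a$entry_date),
                      disposal_date = fmt_date(a$disposal_date),
                      disposal_reason = fmt_chr(a$disposal_reason),
                      stringsAsFactors = FALSE)
  write.csv(out_a, file.path(dir, "animals.csv"), row.names = FALSE,
            quote = FALSE)
  t <- ds$traits
  out_t <- data.frame(animal_id = t$animal_id, trait_code = t$trait_code,
                      value = format(t$value, digits = 15, trim = TRUE,
                                     scientific = FALSE),
                      record_date = fmt_date(t$record_date),
                      stringsAsFactors = FALSE)
  write.csv(out_t, file.path(dir, "traits.csv"), row.names = FALSE,
            quote = FALSE)
  r <- ds$repro
  out_r <- data.frame(ewe_id = r$ewe_id, ram_id = r$ram_id,
                      mating_date = fmt_date(r$mating_date), outcome = r$outcome,
                      outcome_date = fmt_date(r$outcome_date),
                      lamb_ids = fmt_chr(r$lamb_ids), stringsAsFactors = FALSE)
  write.csv(out_r, file.path(dir, "repro.csv"), row.names = FALSE, quote = FALSE)
  h <- ds$health
  out_h <- data.frame(animal_id = h$animal_id, date = fmt_date(h$date),
                      kind = h$kind, detail = fmt_chr(h$detail),
                      drug = fmt_chr(h$drug), stringsAsFactors = FALSE)
  write.csv(out_h, file.path(dir, "health.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Default configuration
#'
#' Trait bounds used by [validate_flock()], age-class thresholds used by the
#' report functions, and standard weighing ages. All values can be overridden
#' via [read_config()] or by editing the returned list.
#'
#' Bounds are wide plausibility screens for medium-frame sheep breeds
#' (weights in kg, fibre diameter in micrometres, staple length in cm), not
#' breed standards.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    trait_bounds = list(
      BWT = c(0.5, 10), WWT = c(5, 40), W6M = c(8, 60), W9M = c(10, 70),
      W12M = c(10, 80), GFY = c(0.2, 10), FD = c(10, 50), SL = c(2, 25)),
    breedable_age_days = 548L,   # 18 months
    lamb_age_days = 365L,        # under 12 months counts as a lamb
    standard_ages = c(0L, 90L, 180L, 270L, 365L),
    age_window_frac = 0.15)
}

#' Read a key-value configuration file
#'
#' Parses a plain-text `key = value` file. Trait bounds use keys of the form
#' `bound_<TRAIT>_lower` / `bound_<TRAIT>_upper`; any other key overrides the
#' matching entry of [default_config()]. Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path file path.
#' @return A configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    if (grepl("^bound_", key)) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      trait <- parts[2]; side <- parts[3]
      if (is.null(cfg$trait_bounds[[trait]])) cfg$trait_bounds[[trait]] <- c(-Inf, Inf)
      cfg$trait_bounds[[trait]][if (side == "lower") 1 else 2] <- num
    } else {
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  cfg
}

finding <- function(code, severity, id, message) {
  data.frame(code = code, severity = severity, animal_id = id,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a flock dataset
#'
#' Screens the dataset for referential and biological inconsistencies:
#' dangling parent or event references, sires that are not male, dams that
#' are not female, trait values outside configured bounds, and event dates
#' before the animal's birth. Findings are returned as data, never raised as
#' errors, so a report can list every problem at once.
#'
#' @param ds a [flock_dataset()].
#' @param config configuration list; see [default_config()].
#' @return A data frame of findings with columns `code`, `severity`,
#'   `animal_id`, `message`; zero rows when the dataset is clean.
#' @export
validate_flock <- function(ds, config = default_config()) {
  stopifnot(inherits(ds, "flock_dataset"))
  a <- ds$animals
  out <- list()
  ids <- a$animal_id
  sex_of <- setNames(a$sex, ids)
  birth_of <- setNames(a$birth_date, ids)

  dang_s <- !is.na(a$sire_id) & !a$sire_id %in% ids
  for (i in which(dang_s)) out[[length(out) + 1]] <-
    finding("DANGLING_SIRE", "WARNING", a$animal_id[i],
            sprintf("sire '%s' not registered", a$sire_id[i]))
  dang_d <- !is.na(a$dam_id) & !a$dam_id %in% ids
  for (i in which(dang_d)) out[[length(out) + 1]] <-
    finding("DANGLING_DAM", "WARNING", a$animal_id[i],
            sprintf("dam '%s' not registered", a$dam_id[i]))

  sire_sex <- sex_of[a$sire_id]
  bad <- !is.na(a$sire_id) & !is.na(sire_sex) & sire_sex != "MALE"
  for (i in which(bad)) out[[length(out) + 1]] <-
    finding("SIRE_SEX", "ERROR", a$animal_id[i],
            sprintf("sire '%s' has sex %s", a$sire_id[i], sire_sex[i]))
  dam_sex <- sex_of[a$dam_id]
  bad <- !is.na(a$dam_id) & !is.na(dam_sex) & dam_sex != "FEMALE"
  for (i in which(bad)) out[[length(out) + 1]] <-
    finding("DAM_SEX", "ERROR", a$animal_id[i],
            sprintf("dam '%s' has sex %s", a$dam_id[i], dam_sex[i]))

  bad <- !is.na(a$birth_date) & a$entry_date < a$birth_date
  for (i in which(bad)) out[[length(out) + 1]] <-
    finding("ENTRY_BEFORE_BIRTH", "ERROR", a$animal_id[i],
            "entry_date precedes birth_date")
  bad <- !is.na(a$disposal_date) & a$disposal_date < a$entry_date
  for (i in which(bad)) out[[length(out) + 1]] <-
    finding("DISPOSAL_BEFORE_ENTRY", "ERROR", a$animal_id[i],
            "disposal_date precedes entry_date")
  bad <- !is.na(a$disposal_reason) & !a$disposal_reason %in% DISPOSAL_REASONS
  for (i in which(bad)) out[[length(out) + 1]] <-
    finding("DISPOSAL_REASON", "ERROR", a$animal_id[i],
            sprintf("unknown disposal reason '%s'", a$disposal_reason[i]))

  t <- ds$traits
  if (nrow(t)) {
    bad <- !t$animal_id %in% ids
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("DANGLING_TRAIT", "ERROR", t$animal_id[i],
              sprintf("trait %s for unregistered animal", t$trait_code[i]))
    for (i in seq_len(nrow(t))) {
      b <- config$trait_bounds[[t$trait_code[i]]]
      if (!is.null(b) && (t$value[i] < b[1] || t$value[i] > b[2])) {
        out[[length(out) + 1]] <- finding("VALUE_RANGE", "WARNING",
          t$animal_id[i],
          sprintf("%s = %g outside [%g, %g]", t$trait_code[i], t$value[i],
                  b[1], b[2]))
      }
      if (t$trait_code[i] %in% WEIGHT_TRAITS && t$value[i] <= 0) {
        out[[length(out) + 1]] <- finding("NONPOSITIVE_WEIGHT", "ERROR",
          t$animal_id[i], sprintf("%s = %g", t$trait_code[i], t$value[i]))
      }
    }
    bd <- birth_of[t$animal_id]
    bad <- !is.na(bd) & !is.na(t$record_date) & t$record_date < bd
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("RECORD_BEFORE_BIRTH", "ERROR", t$animal_id[i],
              sprintf("%s record on %s precedes birth", t$trait_code[i],
                      format(t$record_date[i])))
  }

  r <- ds$repro
  if (nrow(r)) {
    for (col in c("ewe_id", "ram_id")) {
      bad <- !r[[col]] %in% ids
      for (i in which(bad)) out[[length(out) + 1]] <-
        finding("DANGLING_REPRO", "ERROR", r[[col]][i],
                sprintf("%s not registered", col))
    }
    bad <- !is.na(r$outcome_date) & r$outcome_date < r$mating_date
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("OUTCOME_BEFORE_MATING", "ERROR", r$ewe_id[i],
              "outcome_date precedes mating_date")
    has_lambs <- !is.na(r$lamb_ids) & nzchar(r$lamb_ids)
    bad <- (r$outcome == "LAMBING") != has_lambs
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("LAMB_IDS_OUTCOME", "ERROR", r$ewe_id[i],
              "lamb_ids must be nonempty iff outcome is LAMBING")
    for (i in which(has_lambs)) {
      lambs <- strsplit(r$lamb_ids[i], ";", fixed = TRUE)[[1]]
      miss <- setdiff(lambs, ids)
      for (m in miss) out[[length(out) + 1]] <-
        finding("DANGLING_LAMB", "ERROR", m, "lamb id not registered")
    }
  }

  h <- ds$health
  if (nrow(h)) {
    bad <- !h$animal_id %in% ids
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("DANGLING_HEALTH", "ERROR", h$animal_id[i],
              "health event for unregistered animal")
    bd <- birth_of[h$animal_id]
    bad <- !is.na(bd) & h$date < bd
    for (i in which(bad)) out[[length(out) + 1]] <-
      finding("EVENT_BEFORE_BIRTH", "ERROR", h$animal_id[i],
              sprintf("%s on %s precedes birth", h$kind[i], format(h$date[i])))
  }

  if (!length(out)) return(finding(character(), character(), character(),
                                   character())[0, ])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Farm state on a given date
#'
#' Reconstructs which animals were present on the farm on any (current or
#' past) date. An animal is present when `entry_date <= as_of` and it has no
#' disposal dated on or before `as_of` — i.e. a disposed animal is counted
#' through the day before its disposal. Ages are integer days. A `CASTRATION`
#' health event dated on or before `as_of` reclassifies a male as `WETHER`
#' in the `sex_effective` column.
#'
#' @param ds a [flock_dataset()].
#' @param as_of a `Date` (or ISO-8601 string).
#' @return Data frame of live animals with `age_days`, `age_class`
#'   (`LAMB`/`ADULT`) and `sex_effective` columns appended.
#' @param config configuration list; see [default_config()].
#' @export
snapshot <- function(ds, as_of, config = default_config()) {
  stopifnot(inherits(ds, "flock_dataset"))
  as_of <- as.Date(as_of)
  a <- ds$animals
  live <- a$entry_date <= as_of &
    (is.na(a$disposal_date) | a$disposal_date > as_of)
  snap <- a[live, , drop = FALSE]
  snap$age_days <- as.integer(as_of - snap$birth_date)
  snap$age_class <- ifelse(snap$age_days < config$lamb_age_days, "LAMB", "ADULT")
  snap$sex_effective <- snap$sex
  h <- ds$health
  if (nrow(h)) {
    cast <- unique(h$animal_id[h$kind == "CASTRATION" & h$date <= as_of])
    snap$sex_effective[snap$animal_id %in% cast & snap$sex == "MALE"] <- "WETHER"
  }
  rownames(snap) <- NULL
  snap
}
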