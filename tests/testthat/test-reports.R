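# fixture as of 2016-12-31: R1, R2 adult rams; E1, E2 adult ewes; W1 wether;
# L1, L2 lambs; L3 died 2016-11-20.
AS_OF <- as.Date("2016-12-31")

test_that("inventory classifies by effective sex and age", {
  inv <- inventory_report(fixture_flock(), AS_OF)
  all_row <- inv[inv$breed == "ALL", ]
  expect_equal(all_row$TOTAL, 7)
  expect_equal(all_row$EWES, 2)
  expect_equal(all_row$RAMS, 2)
  expect_equal(all_row$WETHERS, 1)
  expect_equal(all_row$LAMBS, 2)
  # breed partition identity
  breed_rows <- inv[inv$breed != "ALL", ]
  for (col in c("TOTAL", "EWES", "RAMS", "WETHERS", "LAMBS")) {
    expect_equal(sum(breed_rows[[col]]), all_row[[col]])
  }
  expect_error(inventory_report(fixture_flock(), AS_OF, breed = "Merino"),
               "unknown breed")
})

test_that("castration reclassifies males in later snapshots", {
  ds <- fixture_flock()
  # before W1's castration event it still counts as recorded (WETHER by sex);
  # castrate R2 mid-2016 and watch it move between columns
  ds$health <- rbind(ds$health, data.frame(
    animal_id = "R2", date = as.Date("2016-06-15"), kind = "CASTRATION",
    detail = "", drug = ""))
  before <- inventory_report(ds, "2016-06-14")
  after <- inventory_report(ds, "2016-06-16")
  b <- before[before$breed == "ALL", ]; a <- after[after$breed == "ALL", ]
  expect_equal(b$RAMS - 1, a$RAMS)
  expect_equal(b$WETHERS + 1, a$WETHERS)
})

test_that("inventory totals equal snapshot sizes on simulated flocks", {
  sim <- simulate_flock(sim_params(n_generations = 3, seed = 14))
  ds <- sim$dataset
  for (d in as.Date(c("2016-06-01", "2017-06-01", "2018-06-01"))) {
    inv <- inventory_report(ds, d)
    expect_equal(inv$TOTAL[inv$breed == "ALL"], nrow(snapshot(ds, d)))
  }
})

test_that("reproduction report computes rate and parity by definition", {
  rep <- reproduction_report(fixture_flock(), AS_OF)
  # both 2016 lambings are in the period; the 2015 abortion is not
  expect_equal(nrow(rep), 2)
  expect_equal(attr(rep, "n_lambings"), 2)
  expect_equal(attr(rep, "n_abortions"), 0)
  # 2 breedable ewes at 2016-01-01 -> rate 1.0
  expect_equal(attr(rep, "lambing_rate"), 1.0)
  expect_equal(rep$n_lambs[rep$ewe_id == "E1"], 2L)
  expect_equal(rep$parity[rep$ewe_id == "E1"], 1L)
  # lamb count in rows equals animals born in the period
  sim <- simulate_flock(sim_params(n_generations = 3, seed = 4))
  yr <- format(max(sim$dataset$animals$birth_date), "%Y")
  eoy <- as.Date(paste0(yr, "-12-31"))
  rp <- reproduction_report(sim$dataset, eoy)
  born <- sum(format(sim$dataset$animals$birth_date, "%Y") == yr)
  expect_equal(sum(rp$n_lambs), born)
})

test_that("zero breedable ewes yields an undefined rate, not an error", {
  ds <- fixture_flock()
  ds$animals <- ds$animals[ds$animals$sex != "FEMALE" |
                             ds$animals$animal_id %in% c("L2", "L3"), ]
  ds$repro <- ds$repro[0, ]
  rep <- reproduction_report(ds, AS_OF)
  expect_true(is.na(attr(rep, "lambing_rate")))
})

test_that("standard-age windows assign weight records correctly", {
  a <- data.frame(animal_id = c("X1", "X2"), sire_id = NA, dam_id = NA,
                  sex = "FEMALE", breed = "Corriedale",
                  birth_date = as.Date("2016-01-01"), farm_id = "F1",
                  entry_date = as.Date("2016-01-01"),
                  disposal_date = as.Date(NA), disposal_reason = NA)
  t <- data.frame(animal_id = c("X1", "X2"),
                  trait_code = c("WWT", "WWT"),
                  value = c(14, 15),
                  record_date = as.Date("2016-01-01") + c(91, 140))
  ds <- flock_dataset(a, t)
  pr <- production_report(ds)
  expect_equal(pr$W90D[pr$animal_id == "X1"], 14)   # 91 d inside +-13.5 d
  expect_false("X2" %in% pr$animal_id)              # 140 d outside all windows
  bm <- attr(pr, "breed_means")
  expect_equal(bm$W90D[bm$breed == "Corriedale"], 14)
})

test_that("column means match direct per-age means on exact-age records", {
  sim <- simulate_flock(sim_params(n_founder_sires = 4, n_founder_dams = 10,
                                   n_generations = 2, survival_to_12m = 1,
                                   seed = 23))
  pr <- production_report(sim$dataset)
  t <- sim$dataset$traits
  expect_equal(mean(pr$W0D), mean(t$value[t$trait_code == "BWT"]))
  expect_equal(mean(pr$W365D, na.rm = TRUE),
               mean(t$value[t$trait_code == "W12M"]))
})

test_that("wool report aggregates clips and keeps zero-clip animals", {
  wr <- wool_report(fixture_flock())
  r1 <- wr[wr$animal_id == "R1", ]
  expect_equal(r1$clips, 2)
  expect_equal(r1$total_gfy, 2.6)
  expect_equal(r1$mean_gfy, 1.3)
  expect_equal(wr$clips[wr$animal_id == "E2"], 0)
  e1 <- wr[wr$animal_id == "E1", ]
  expect_equal(e1$latest_fd, 24.5)
  expect_equal(e1$latest_sl, 8.2)
  t <- fixture_flock()$traits
  expect_equal(sum(wr$total_gfy), sum(t$value[t$trait_code == "GFY"]))
})

test_that("health and disposal reports partition their periods", {
  ds <- fixture_flock()
  hr <- health_report(ds, AS_OF)
  expect_equal(nrow(hr), 2)  # 2016 vaccination + deworming; 2013 castration out
  expect_equal(sum(attr(hr, "counts_by_kind")), nrow(hr))

  dr <- disposal_report(ds, AS_OF)
  expect_equal(nrow(dr), 1)
  # 8 animals present at 2016-01-01 minus lambs born later: R1,R2,E1,E2,W1 = 5
  expect_equal(attr(dr, "mortality"), 1 / 5)
  expect_equal(sum(attr(dr, "disposals_by_reason")), nrow(dr))

  sim <- simulate_flock(sim_params(n_generations = 3, survival_to_12m = 0.8,
                                   seed = 31))
  eoy <- as.Date("2017-12-31")
  dr2 <- disposal_report(sim$dataset, eoy)
  expect_equal(sum(attr(dr2, "disposals_by_reason")), nrow(dr2))
  expect_equal(sum(attr(dr2, "deaths_by_breed")),
               sum(dr2$disposal_reason == "DEATH"))
})

test_that("yearly trends reproduce the single-year reports", {
  sim <- simulate_flock(sim_params(n_generations = 3, seed = 41))
  ds <- sim$dataset
  tr <- trend_report(ds, "TOTAL", 2015:2018)
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$value[i],
                 nrow(snapshot(ds, as.Date(sprintf("%d-12-31", tr$year[i])))))
  }
  lr <- trend_report(ds, "LAMBING_RATE", 2016:2017)
  expect_equal(lr$value[1],
               attr(reproduction_report(ds, as.Date("2016-12-31")),
                    "lambing_rate"))
  # a year with no yearling records yields an explicit NA
  mw <- trend_report(ds, "MEAN_W12M", c(2014, 2016))
  expect_true(is.na(mw$value[1]))
  expect_false(is.na(mw$value[2]))
})

test_that("farm filtering commutes with reporting", {
  sim <- simulate_flock(sim_params(n_generations = 3, n_farms = 2, seed = 52))
  ds <- sim$dataset
  inv_filtered <- inventory_report(ds, "2017-12-31", farm = "F1")
  ds_f1 <- ds
  keep <- ds$animals$farm_id == "F1"
  ids <- ds$animals$animal_id[keep]
  ds_f1$animals <- ds$animals[keep, ]
  ds_f1$animals$sire_id[!ds_f1$animals$sire_id %in% ids] <- NA
  ds_f1$animals$dam_id[!ds_f1$animals$dam_id %in% ids] <- NA
  ds_f1$traits <- ds$traits[ds$traits$animal_id %in% ids, ]
  ds_f1$health <- ds$health[ds$health$animal_id %in% ids, ]
  ds_f1$repro <- ds$repro[ds$repro$ewe_id %in% ids, ]
  inv_sub <- inventory_report(ds_f1, "2017-12-31")
  expect_equal(inv_filtered[inv_filtered$breed == "ALL", -1],
               inv_sub[inv_sub$breed == "ALL", -1], ignore_attr = TRUE)
})

test_that("report CSV bytes are deterministic and match the golden copy", {
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_report_csv(inventory_report(fixture_flock(), AS_OF), p1)
  write_report_csv(inventory_report(fixture_flock(), AS_OF), p2)
  expect_identical(readLines(p1), readLines(p2))
  strip <- function(x) x[!startsWith(x, "#")]
  golden <- readLines(test_path("_golden", "inventory_2016-12-31.csv"))
  expect_identical(strip(readLines(p1)), strip(golden))
})
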