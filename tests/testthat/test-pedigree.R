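test_that("pedigrees are topologically sorted and cycles reported", {
  ped <- build_pedigree(data.frame(
    animal_id = c("B", "A"), sire_id = c("A", NA), dam_id = c(NA, NA)))
  expect_equal(ped$ids, c("A", "B"))
  expect_true(all(ped$sire < seq_along(ped$ids), na.rm = TRUE))

  expect_error(build_pedigree(data.frame(
    animal_id = c("A", "B"), sire_id = c("B", "A"), dam_id = c(NA, NA))),
    "cycle.*A.*B|cycle.*B.*A")

  expect_warning(build_pedigree(data.frame(
    animal_id = "X", sire_id = "GHOST", dam_id = NA)), "unregistered")
})

test_that("parent indices precede offspring on simulated pedigrees", {
  sim <- simulate_flock(sim_params(n_generations = 4, seed = 2))
  ped <- build_pedigree(sim$dataset$animals)
  idx <- seq_along(ped$ids)
  expect_true(all(ped$sire < idx, na.rm = TRUE))
  expect_true(all(ped$dam < idx, na.rm = TRUE))
  # original order recoverable
  expect_equal(ped$ids[match(seq_along(idx), ped$orig_order)],
               sim$dataset$animals$animal_id)
})

test_that("relationship matrix reproduces textbook values", {
  founders <- build_pedigree(data.frame(
    animal_id = c("A", "B"), sire_id = NA_character_,
    dam_id = NA_character_))
  expect_equal(amatrix(founders), diag(2), ignore_attr = TRUE)

  trio <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C"), sire_id = c(NA, NA, "A"),
    dam_id = c(NA, NA, "B")))
  A <- amatrix(trio)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["C", "C"], 1.0)
})

test_that("relationship matrix equals twice the kinship oracle", {
  set.seed(101)
  for (case in 1:30) {
    frame <- random_pedigree_frame(sample(5:12, 1))
    A <- amatrix(build_pedigree(frame))[frame$animal_id, frame$animal_id]
    expect_equal(unname(A), unname(2 * kinship_oracle(frame)),
                 tolerance = 1e-12)
  }
})

test_that("inbreeding matches the canonical mating designs", {
  # full-sib mating
  fs <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C", "D", "E"), sire_id = c(NA, NA, "A", "A", "C"),
    dam_id = c(NA, NA, "B", "B", "D")))
  expect_equal(unname(inbreeding(fs)["E"]), 0.25)
  # parent-offspring mating
  po <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C", "X"), sire_id = c(NA, NA, "A", "A"),
    dam_id = c(NA, NA, "B", "C")))
  expect_equal(unname(inbreeding(po)["X"]), 0.25)
  # half-sib mating
  hs <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C", "D", "E", "X"),
    sire_id = c(NA, NA, NA, "A", "A", "D"),
    dam_id = c(NA, NA, NA, "B", "C", "E")))
  expect_equal(unname(inbreeding(hs)["X"]), 0.125)
  # two consecutive generations of full-sib mating
  fs2 <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C", "D", "E", "F", "X"),
    sire_id = c(NA, NA, "A", "A", "C", "C", "E"),
    dam_id = c(NA, NA, "B", "B", "D", "D", "F")))
  expect_equal(unname(inbreeding(fs2)["X"]), 0.375)
})

test_that("path counting agrees with the recursive route", {
  po <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C", "X"), sire_id = c(NA, NA, "A", "A"),
    dam_id = c(NA, NA, "B", "C")))
  expect_equal(inbreeding_wright(po, "X"), 0.25)

  set.seed(77)
  for (case in 1:20) {
    frame <- random_pedigree_frame(sample(6:12, 1))
    ped <- build_pedigree(frame)
    F <- inbreeding(ped)
    for (id in frame$animal_id) {
      expect_equal(inbreeding_wright(ped, id), unname(F[id]),
                   tolerance = 1e-12)
    }
  }
})

test_that("sparse A-inverse multiplies back to the identity", {
  founders <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C"), sire_id = NA_character_,
    dam_id = NA_character_))
  expect_equal(as.matrix(ainverse(founders)), diag(3), ignore_attr = TRUE)

  trio <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C"), sire_id = c(NA, NA, "A"),
    dam_id = c(NA, NA, "B")))
  expect_lt(max(abs(as.matrix(amatrix(trio) %*% ainverse(trio)) - diag(3))),
            1e-12)

  sim <- simulate_flock(sim_params(n_founder_sires = 5, n_founder_dams = 20,
                                   n_generations = 3, seed = 9))
  ped <- build_pedigree(sim$dataset$animals)
  n <- length(ped$ids)
  expect_lt(max(abs(as.matrix(amatrix(ped) %*% ainverse(ped)) - diag(n))),
            1e-8)
})

test_that("A stays positive semi-definite on generated pedigrees", {
  set.seed(55)
  for (case in 1:10) {
    frame <- random_pedigree_frame(12)
    ev <- eigen(amatrix(build_pedigree(frame)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("removing a non-ancestor leaves other inbreeding unchanged", {
  set.seed(31)
  frame <- random_pedigree_frame(12)
  ped <- build_pedigree(frame)
  F <- inbreeding(ped)
  # leaf: an animal that is nobody's parent
  parents <- c(frame$sire_id, frame$dam_id)
  leaf <- setdiff(frame$animal_id, parents[!is.na(parents)])[1]
  frame2 <- frame[frame$animal_id != leaf, ]
  F2 <- inbreeding(build_pedigree(frame2))
  expect_equal(F2, F[names(F2)], tolerance = 1e-14)
})

test_that("pedigree sheets truncate at depth and mark unknown parents", {
  trio <- build_pedigree(data.frame(
    animal_id = c("A", "B", "C"), sire_id = c(NA, NA, "A"),
    dam_id = c(NA, NA, "B")))
  sheet <- pedigree_sheet(trio, "A", generations = 3)
  expect_equal(sheet$sire$id, "UNKNOWN")
  expect_equal(sheet$dam$id, "UNKNOWN")

  sheet <- pedigree_sheet(trio, "C", generations = 1)
  expect_equal(sheet$sire$id, "A")
  expect_equal(sheet$dam$id, "B")
  # over-deep request bottoms out at founders
  sheet <- pedigree_sheet(trio, "C", generations = 5)
  expect_equal(sheet$sire$sire$id, "UNKNOWN")
  expect_error(pedigree_sheet(trio, "NOPE", 2), "unknown")
})

test_that("history sheets collate progeny and their trait means", {
  ds <- fixture_flock()
  hs <- history_sheet(ds, "E1")
  expect_equal(sort(hs$progeny$animal_id), c("L1", "L2"))
  expect_equal(nrow(hs$repro), 2)
  bwt <- hs$progeny_trait_means
  expect_equal(bwt$mean[bwt$trait_code == "BWT"], mean(c(3.1, 2.9)))
  expect_error(history_sheet(ds, "ZZ"), "unknown")

  sim <- simulate_flock(sim_params(n_founder_sires = 2, n_founder_dams = 10,
                                   n_generations = 2, seed = 13))
  ram <- sim$dataset$animals$animal_id[1]
  hs <- history_sheet(sim$dataset, ram)
  prog <- sim$dataset$animals$animal_id[
    !is.na(sim$dataset$animals$sire_id) & sim$dataset$animals$sire_id == ram]
  expect_setequal(hs$progeny$animal_id, prog)
  tr <- sim$dataset$traits
  direct <- mean(tr$value[tr$animal_id %in% prog & tr$trait_code == "BWT"])
  expect_equal(hs$progeny_trait_means$mean[
    hs$progeny_trait_means$trait_code == "BWT"], direct)
})
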