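# Reading, validation, cleaning and pair aggregation of litter records.

fixture_path <- function() {
  system.file("extdata", "toy_breeding_records.csv", package = "colonykin",
              mustWork = TRUE)
}

test_that("records round-trip through read with missingness preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mating_id,dam_id,sire_id,mating_date,birth_date,born,weaned,males_weaned,females_weaned,stock",
               "A,D1,S1,2020-01-01,2020-03-01,5,4,2,2,BW",
               "B,,S2,2020-01-01,2020-04-01,3,3,1,2,BW",
               "C,D3,S3,2020-01-01,2020-13-40,4,4,2,2,BW"), path)
  rec <- readBreedingRecords(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$born, c(5, 3, 4))
  expect_true(is.na(rec$dam_id[2]))               # blank cell kept as unknown
  expect_true(rec$invalid_birth_date[3])          # flagged, not dropped
  expect_false(any(rec$invalid_birth_date[1:2]))
  expect_equal(rec$dead[1], 1)
})

test_that("schema errors name the missing column and empty files error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mating_id,dam_id,sire_id,birth_date,born",
               "A,D,S,2020-01-01,5"), path)
  expect_error(readBreedingRecords(path), "weaned")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("mating_id,dam_id,sire_id,birth_date,born,weaned", path2)
  expect_error(readBreedingRecords(path2), "no data rows")
  expect_error(readBreedingRecords(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("cleaning applies dedup, completeness, capping and dead derivation", {
  rec <- readBreedingRecords(fixture_path())
  out <- cleanRecords(rec)
  rep <- out$report
  expect_s4_class(rep, "CleaningReport")
  expect_equal(rep@n_rows_in, 20L)
  expect_equal(rep@n_duplicates_removed, 1L)
  expect_equal(rep@n_incomplete_removed, 4L)
  expect_equal(rep@n_capped, 1L)
  expect_equal(rep@n_rows_retained, 15L)
  expect_equal(rep@n_pairs_in, 6L)
  expect_equal(rep@n_pairs_retained, 5L)
  expect_equal(rep@n_pairs_removed, 1L)
  # capped row: born 5, weaned 6 -> weaned 5, dead 0
  capped <- out$records[out$records$mating_id == "M1" &
                          out$records$birth_date == as.Date("2014-04-15"), ]
  expect_equal(capped$weaned, 5)
  expect_equal(capped$dead, 0)
  expect_equal(capped$males_weaned + capped$females_weaned, 5)
  # dead = born - weaned everywhere
  expect_equal(out$records$dead, out$records$born - out$records$weaned)
  expect_true(all(out$records$weaned <= out$records$born))
})

test_that("cleaning is idempotent and conserves dead counts", {
  rec <- readBreedingRecords(fixture_path())
  once <- cleanRecords(rec)
  twice <- cleanRecords(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report@n_duplicates_removed, 0L)
  expect_equal(twice$report@n_incomplete_removed, 0L)
  expect_equal(twice$report@n_capped, 0L)
  expect_equal(sum(once$records$dead),
               sum(once$records$born) - sum(once$records$weaned))
})

test_that("pairwise filtering removes whole cages touched by a bad row", {
  rec <- readBreedingRecords(fixture_path())
  rowwise <- cleanRecords(rec, pairwise = FALSE)
  pairwise <- cleanRecords(rec, pairwise = TRUE)
  # M2 has invalid rows; pair-wise mode drops its good rows too
  expect_true("M2" %in% rowwise$records$mating_id)
  expect_false("M2" %in% pairwise$records$mating_id)
  expect_gte(pairwise$report@n_incomplete_removed,
             rowwise$report@n_incomplete_removed)
})

test_that("pair summaries aggregate litters with delivery intervals", {
  rec <- toy_records()
  rec$dead <- rec$born - rec$weaned
  rec$year <- as.integer(format(rec$birth_date, "%Y"))
  pairs <- summarizePairs(rec)
  m1 <- pairs[pairs$mating_id == "M1", ]
  expect_equal(m1$n_litters, 3L)
  expect_equal(m1$total_born, 15)
  expect_equal(m1$total_dead, 2)
  expect_equal(m1$n_litters_with_loss, 1L)
  # births at day 0, 30, 62 -> gaps 30 and 32, mean 31
  expect_equal(m1$mean_delivery_interval, 31)
  # single-litter pair has no interval
  expect_true(is.na(pairs$mean_delivery_interval[pairs$mating_id == "M3"]))
  # threshold filter
  expect_false("M3" %in% summarizePairs(rec, minLitters = 2)$mating_id)
  expect_false("M2" %in% summarizePairs(rec, minLitters = 3)$mating_id)
  expect_error(summarizePairs(rec, minLitters = 0), "positive")
})

test_that("pair summaries partition all litters exactly once", {
  set.seed(11)
  sim <- simulateColony(colonySimConfig(n_years = 8L, pairs_active = 6L),
                        seed = 3)
  rec <- simRecords(sim)
  pairs <- summarizePairs(rec, minLitters = 1)
  expect_equal(sum(pairs$n_litters), nrow(rec))
  expect_equal(sum(pairs$total_born), sum(rec$born))
  expect_equal(sum(pairs$total_dead), sum(rec$dead))
  expect_setequal(pairs$mating_id, unique(rec$mating_id))
})
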