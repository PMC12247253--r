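# Cumulative windows, phase annotation, sex-loss imputation and the
# exhaustive changepoint search.

small_colony <- function(seed = 2, years = 12L, pairs = 8L, ...) {
  simulateColony(colonySimConfig(n_years = years, pairs_active = pairs, ...),
                 seed = seed)
}

test_that("data confined to one year yields a single estimated point", {
  sim <- small_colony(seed = 4, years = 2L)
  rec <- simRecords(sim)
  rec <- rec[rec$year == min(rec$year), , drop = FALSE]
  sc <- cumulativeScan(rec, simPairs(sim), outcome = "loss_by_mice",
                       minPairs = 3, boundaries = numeric(0))
  pts <- sc@points
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$cutoff_year, min(rec$year))
  expect_error(cumulativeScan(rec, simPairs(sim), outcome = "loss_by_mice",
                              startYear = 2000, endYear = 1990),
               "startYear")
})

test_that("scan points nest and the final cutoff equals the pooled analysis", {
  sim <- small_colony(seed = 6, years = 10L)
  rec <- simRecords(sim)
  tp <- simPairs(sim)
  sc <- cumulativeScan(rec, tp, outcome = "loss_by_mice", minPairs = 3)
  pts <- sc@points
  ok <- which(!is.na(pts$r))
  expect_true(all(diff(pts$n_pairs[ok]) >= 0))        # nestedness
  # final point must equal a direct pooled computation
  pairs <- summarizePairs(rec)
  pairs$relatedness_pct <- tp$relatedness_pct[match(pairs$mating_id,
                                                    tp$mating_id)]
  pe <- pearsonCorrelation(pairs$relatedness_pct, lossRatioByMice(pairs))
  fit <- fitBinomialGlm(pairs$relatedness_pct, pairs$total_dead,
                        pairs$total_born)
  last <- pts[max(ok), ]
  expect_equal(last$r, pe$r, tolerance = 1e-12)
  expect_equal(last$r_p, pe$p, tolerance = 1e-12)
  expect_equal(last$mcfadden_r2, fit@mcfadden_r2, tolerance = 1e-12)
  expect_equal(last$lrt_p, fit@lrt_p, tolerance = 1e-12)
  # cutoffs with too few pairs are missing, not zero
  expect_true(all(is.na(pts$r[pts$n_pairs < 3])))
})

test_that("sex losses follow the 1:1 birth assumption with flooring", {
  rec <- data.frame(
    mating_id = "P", birth_date = as.Date("2000-01-01") + c(0, 40, 80),
    born = c(6, 5, 4), weaned = c(5, 3, 4),
    males_weaned = c(2, 3, 2), females_weaned = c(3, 0, 2),
    stringsAsFactors = FALSE)
  rec$dead <- rec$born - rec$weaned
  sl <- sexSpecificLosses(rec)
  expect_equal(sl$expected_males, c(3, 2.5, 2))
  expect_equal(sl$male_loss, c(1, 0, 0))     # 2.5 - 3 floored to 0
  expect_equal(sl$female_loss, c(0, 2.5, 0))
  expect_equal(attr(sl, "n_floored"), 1L)
  expect_equal(sl$expected_males + sl$expected_females, rec$born)
  # unfloored variant keeps the negative shortfall
  sl2 <- sexSpecificLosses(rec, floor = FALSE)
  expect_equal(sl2$male_loss[2], -0.5)
  # male + female loss covers total deaths when nothing was floored
  nofloor <- sl2$male_loss >= 0 & sl2$female_loss >= 0
  expect_true(all((sl2$male_loss + sl2$female_loss)[nofloor] >=
                    (rec$born - rec$weaned)[nofloor]))
  # missing sex counts are skipped and tallied
  rec$males_weaned[2] <- NA
  expect_equal(attr(sexSpecificLosses(rec), "n_skipped"), 1L)
})

test_that("phase labels split eras at boundaries, boundary year goes later", {
  sim <- small_colony(seed = 8, years = 8L)
  sc <- cumulativeScan(simRecords(sim), simPairs(sim),
                       outcome = "loss_by_litter", minPairs = 3)
  y0 <- min(sc@points$cutoff_year)
  sc <- annotatePhases(sc, boundaries = c(y0 + 3, y0 + 6))
  p <- sc@points
  expect_equal(p$phase[p$cutoff_year == y0], "I")
  expect_equal(p$phase[p$cutoff_year == y0 + 3], "II")   # boundary -> later
  expect_equal(p$phase[p$cutoff_year == y0 + 5], "II")
  expect_equal(p$phase[p$cutoff_year == y0 + 7], "III")
  single <- annotatePhases(sc, boundaries = numeric(0))
  expect_true(all(single@points$phase == "I"))
  expect_error(annotatePhases(sc, boundaries = c(2000, 1990)), "increasing")
})

test_that("changepoint search finds exact steps and reports ties", {
  x <- c(0, 0, 0, 0.3, 0.3, 0.3)
  cp <- detectChangepoints(x, k = 1)
  expect_equal(as.numeric(cp), 4)              # first index of new level
  expect_false(attr(cp, "tied"))
  cp2 <- detectChangepoints(c(0, 0, 0, .2, .2, .2, .5, .5, .5), k = 2)
  expect_equal(as.numeric(cp2), c(4, 7))
  tie <- detectChangepoints(rep(1, 6), k = 1)
  expect_equal(as.numeric(tie), 2)             # earliest split on ties
  expect_true(attr(tie, "tied"))
  expect_error(detectChangepoints(c(1, 2, 3), k = 1), "at least")
  expect_error(detectChangepoints(1:10, k = 3), "k must be")
})

test_that("changepoints on noisy steps recover truth at signal/noise 3", {
  set.seed(14)
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    truth <- 12L
    x <- c(rep(0, truth - 1L), rep(0.3, 31L - truth)) + rnorm(30, 0, 0.1)
    cp <- detectChangepoints(x, k = 1)
    if (abs(as.numeric(cp) - truth) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
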