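# The generative model: determinism, internal consistency, distributional
# invariants, and agreement between the simulator's kinship bookkeeping and
# the pedigree module.

test_that("the same seed reproduces the colony exactly", {
  cfg <- colonySimConfig(n_years = 8L, pairs_active = 6L)
  a <- simulateColony(cfg, seed = 99)
  b <- simulateColony(cfg, seed = 99)
  expect_identical(simRecords(a), simRecords(b))
  expect_identical(simPairs(a), simPairs(b))
  expect_identical(pedParents(simPedigree(a)), pedParents(simPedigree(b)))
  c <- simulateColony(cfg, seed = 100)
  expect_false(identical(simRecords(a), simRecords(c)))
})

test_that("emitted records satisfy the litter invariants and clean losslessly", {
  sim <- simulateColony(colonySimConfig(n_years = 12L, pairs_active = 8L),
                        seed = 17)
  rec <- simRecords(sim)
  expect_true(all(rec$born >= rec$weaned))
  expect_true(all(rec$born >= 1))
  expect_equal(rec$males_weaned + rec$females_weaned, rec$weaned)
  expect_equal(rec$dead, rec$born - rec$weaned)
  out <- cleanRecords(rec)
  expect_equal(out$report@n_duplicates_removed, 0L)
  expect_equal(out$report@n_incomplete_removed, 0L)
  expect_equal(out$report@n_capped, 0L)
  expect_equal(nrow(out$records), nrow(rec))
})

test_that("litter sizes follow the zero-truncated Poisson mean", {
  lam <- 4
  sim <- simulateColony(colonySimConfig(n_years = 15L, pairs_active = 10L,
                                        litter_size_mean = lam,
                                        mortality_slope = 0,
                                        interval_slope = 0), seed = 23)
  born <- simRecords(sim)$born
  expect_gt(length(born), 1000)
  m_expect <- lam / (1 - exp(-lam))
  se <- sd(born) / sqrt(length(born))
  expect_lt(abs(mean(born) - m_expect), 4 * se)
})

test_that("realised mortality tracks the logistic model in relatedness", {
  b0 <- qlogis(0.15); b1 <- 1.4
  sim <- simulateColony(colonySimConfig(n_years = 20L, pairs_active = 10L,
                                        mortality_intercept = b0,
                                        mortality_slope = b1), seed = 29)
  rec <- simRecords(sim)
  tp <- simPairs(sim)
  r <- tp$relatedness_pct[match(rec$mating_id, tp$mating_id)] / 100
  # per-litter true probabilities must equal the configured model exactly
  expect_equal(sim@litter_probs, plogis(b0 + b1 * r), tolerance = 1e-12)
  # and realised deaths match binomial expectation within Monte-Carlo error
  expect_gt(nrow(rec), 1000)
  exp_dead <- sum(rec$born * sim@litter_probs)
  sd_dead <- sqrt(sum(rec$born * sim@litter_probs * (1 - sim@litter_probs)))
  expect_lt(abs(sum(rec$dead) - exp_dead), 4 * sd_dead)
})

test_that("simulator kinship bookkeeping equals the pedigree recursion", {
  sim <- simulateColony(colonySimConfig(n_years = 10L, pairs_active = 6L),
                        seed = 41)
  tp <- simPairs(sim)
  ped <- simPedigree(sim)
  redo <- pairRelatedness(ped, tp[, c("dam_id", "sire_id")],
                          maxGenerations = Inf)
  expect_equal(redo$relatedness_pct, tp$relatedness_pct, tolerance = 1e-9)
  # relatedness drifts upward in a closed colony but respects the cap
  expect_true(all(tp$relatedness_pct <
                    sim@config@pair_relatedness_cap + 1e-9))
  yr <- as.integer(format(tp$formed_date, "%Y"))
  early <- mean(tp$relatedness_pct[yr <= min(yr) + 2])
  late <- mean(tp$relatedness_pct[yr >= max(yr) - 2])
  expect_gt(late, early)
})

test_that("impossible pair formation yields an extinction report, not a crash", {
  # cap 0 forbids every non-founder pairing once founders retire
  cfg <- colonySimConfig(n_years = 20L, pairs_active = 6L, n_founders = 12L,
                         pair_relatedness_cap = 1e-9)
  sim <- simulateColony(cfg, seed = 51)
  expect_true(sim@extinct)
  expect_false(is.na(sim@extinction_year))
  expect_lte(sim@extinction_year, cfg@start_year + 20L)
})

test_that("three-phase schedules are validated and echoed in the config", {
  cfg <- colonySimConfig(n_years = 12L, pairs_active = 8L,
                         start_year = 2000L)
  sim <- makeThreePhaseColony(cfg, boundaries = c(2004, 2008), seed = 61)
  sched <- sim@config@phase_schedule
  expect_equal(nrow(sched), 3L)
  expect_equal(sched$start_year, c(2000L, 2004L, 2008L))
  expect_equal(sched$mortality_slope, c(0, cfg@mortality_slope, 0))
  # zero-length middle era collapses to a null colony schedule
  nullish <- makeThreePhaseColony(cfg, boundaries = c(2004, 2004), seed = 61)
  expect_true(all(nullish@config@phase_schedule$mortality_slope == 0))
  expect_error(makeThreePhaseColony(cfg, boundaries = c(1990, 2008)),
               "span")
})
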