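# Loss metrics, the weighted binomial-logit model, Pearson correlation and
# the binned ANOVA comparison.

pair_row <- function(born, dead, n_lit, n_loss, r = 0) {
  data.frame(total_born = born, total_dead = dead, total_weaned = born - dead,
             n_litters = n_lit, n_litters_with_loss = n_loss,
             relatedness_pct = r)
}

test_that("loss ratios follow their definitions with division guards", {
  p <- pair_row(20, 5, 3, 1)
  expect_equal(lossRatioByMice(p), 0.25)
  expect_equal(lossRatioByLitter(p), 1 / 3)
  expect_equal(lossRatioByMice(pair_row(10, 0, 2, 0)), 0)
  expect_equal(lossRatioByLitter(pair_row(8, 8, 4, 4)), 1)
  expect_error(lossRatioByMice(pair_row(0, 0, 1, 0)), "total_born")
  expect_error(lossRatioByLitter(pair_row(5, 0, 0, 0)), "litters")
})

test_that("no-association designs give zero slope, R2 and p = 1", {
  fit <- fitBinomialGlm(c(0, 50), c(5, 5), c(10, 10))
  expect_equal(fit@beta1, 0, tolerance = 1e-8)
  expect_equal(fit@mcfadden_r2, 0, tolerance = 1e-10)
  expect_equal(fit@lrt_p, 1, tolerance = 1e-6)
  expect_true(fit@converged)
  expect_error(fitBinomialGlm(c(10, 10, 10), c(1, 2, 3), c(5, 5, 5)),
               "distinct")
})

test_that("fitted coefficients match brute-force likelihood maximisation", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(5:9, 1)
    x <- round(runif(n, 0, 50), 1)
    t <- sample(5:40, n, replace = TRUE)
    p_true <- plogis(-1.2 + 0.02 * x)
    s <- rbinom(n, t, p_true)
    fit <- fitBinomialGlm(x, s, t)
    if (!fit@converged) next
    ora <- oracle_glm_grid(x, s, t)
    expect_lt(abs(fit@beta0 - ora["beta0"]), 1e-4)
    expect_lt(abs(fit@beta1 - ora["beta1"]), 1e-4)
    expect_equal(fit@loglik_model, unname(ora["loglik"]), tolerance = 1e-8)
    # LRT p equals the closed-form chi-squared tail
    expect_equal(fit@lrt_p,
                 pchisq(2 * (fit@loglik_model - fit@loglik_null), 1,
                        lower.tail = FALSE))
    expect_true(fit@mcfadden_r2 >= 0 && fit@mcfadden_r2 < 1)
  }
})

test_that("McFadden R2 is invariant to covariate rescaling", {
  set.seed(5)
  x <- runif(12, 0, 50)
  t <- sample(10:30, 12, replace = TRUE)
  s <- rbinom(12, t, plogis(-1 + 0.03 * x))
  pct <- fitBinomialGlm(x, s, t)
  prop <- fitBinomialGlm(x / 100, s, t)
  expect_equal(pct@mcfadden_r2, prop@mcfadden_r2, tolerance = 1e-7)
  expect_equal(pct@beta1 * 100, prop@beta1, tolerance = 1e-5)
  expect_equal(pct@lrt_p, prop@lrt_p, tolerance = 1e-7)
})

test_that("aggregating litters to pair totals leaves the likelihood unchanged", {
  set.seed(9)
  # per-litter rows sharing a pair's covariate value
  x_pair <- c(0, 10, 25, 40)
  litters <- do.call(rbind, lapply(seq_along(x_pair), function(i) {
    k <- sample(2:4, 1)
    t <- sample(3:8, k, replace = TRUE)
    data.frame(x = x_pair[i], s = rbinom(k, t, plogis(-1 + 0.02 * x_pair[i])),
               t = t)
  }))
  perLitter <- fitBinomialGlm(litters$x, litters$s, litters$t)
  agg <- rowsum(litters[c("s", "t")], litters$x)
  perPair <- fitBinomialGlm(as.numeric(rownames(agg)), agg$s, agg$t)
  expect_equal(perLitter@loglik_model, perPair@loglik_model, tolerance = 1e-8)
  expect_equal(perLitter@loglik_null, perPair@loglik_null, tolerance = 1e-8)
  expect_equal(perLitter@beta1, perPair@beta1, tolerance = 1e-7)
  expect_equal(perLitter@mcfadden_r2, perPair@mcfadden_r2, tolerance = 1e-8)
})

test_that("complete separation is reported, not silently returned", {
  x <- c(0, 1, 2, 10, 11, 12)
  s <- c(0, 0, 0, 5, 5, 5)
  t <- rep(5, 6)
  fit <- fitBinomialGlm(x, s, t)
  expect_false(fit@converged)
})

test_that("slope sign follows the weighted covariance on two-group designs", {
  up <- fitBinomialGlm(c(0, 40), c(2, 9), c(20, 20))
  down <- fitBinomialGlm(c(0, 40), c(9, 2), c(20, 20))
  expect_gt(up@beta1, 0)
  expect_lt(down@beta1, 0)
})

test_that("pearson matches the closed-form and rejects degenerate input", {
  x <- 1:5
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  out <- pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 5))
  r_direct <- sum((c(1,2,3,4) - 2.5) * (c(1,3,2,5) - 2.75)) /
    sqrt(sum((c(1,2,3,4) - 2.5)^2) * sum((c(1,3,2,5) - 2.75)^2))
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt((4 - 2) / (1 - r_direct^2))
  expect_equal(out$p, 2 * pt(abs(tstat), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$n, 4)
  expect_error(pearsonCorrelation(x, rep(1, 5)), "constant")
  expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")
})

test_that("relatedness bins use half-open edges and ANOVA matches arithmetic", {
  edges <- colonykin:::.relatednessBins(c(24.95, 25, 29.9, 30, 39.9, 40, 100))
  expect_equal(as.character(edges),
               c("<25", "25-29.9", "25-29.9", "30-34.9", "35-39.9",
                 ">=40", ">=40"))

  mk <- function(r, ratio) pair_row(10, round(10 * ratio), 2, 1, r)
  # equal group means give F = 0, p = 1
  same <- do.call(rbind, lapply(c(10, 27, 32), function(r)
    rbind(mk(r, 0.1), mk(r, 0.2), mk(r, 0.3))))
  res0 <- binAndAnova(same, "by_mice")
  expect_equal(res0$anova_f, 0, tolerance = 1e-12)
  expect_equal(res0$anova_p, 1, tolerance = 1e-12)

  set.seed(3)
  pairs <- do.call(rbind, lapply(runif(30, 0, 60), function(r)
    mk(r, runif(1, 0, 0.5))))
  res <- binAndAnova(pairs, "by_mice")
  y <- lossRatioByMice(pairs)
  g <- droplevels(colonykin:::.relatednessBins(pairs$relatedness_pct))
  expect_equal(res$anova_f, oracle_anova_f(y, g), tolerance = 1e-10)
  expect_equal(sum(res$bins$n), nrow(pairs))
  # single occupied bin is a comparison-impossible error
  expect_error(binAndAnova(rbind(mk(1, .1), mk(2, .2)), "by_mice"),
               "non-empty")
})
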