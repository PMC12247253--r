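#' Loss ratios of a breeding pair
#'
#' Two complementary summaries of pre-weaning offspring loss:
#' `lossRatioByMice` is the number of dead pups divided by the total pups
#' born; `lossRatioByLitter` is the proportion of litters in which at least
#' one pup was lost.
#'
#' @param pairs pair-summary data.frame from [summarizePairs()].
#' @return numeric vector of proportions in `[0, 1]`, one per pair.
#' @export
lossRatioByMice <- function(pairs) {
  if (any(pairs$total_born == 0))
    stop("loss ratio by mice undefined: pair(s) with total_born = 0")
  pairs$total_dead / pairs$total_born
}

#' @rdname lossRatioByMice
#' @export
lossRatioByLitter <- function(pairs) {
  if (any(pairs$n_litters == 0))
    stop("loss ratio by litter undefined: pair(s) with no litters")
  pairs$n_litters_with_loss / pairs$n_litters
}

#' Fit a weighted binomial-logit model of loss on relatedness
#'
#' Maximum-likelihood fit of `logit(p_i) = beta0 + beta1 * x_i` to counts of
#' losses (`successes`) out of events (`trials`, mice born or litters),
#' which weights every observation by its number of events. The intercept-
#' only null model is refit on the same data; McFadden's pseudo R-squared is
#' `1 - loglik_model / loglik_null` and the slope is tested by a likelihood
#' ratio test against chi-squared with 1 degree of freedom. Log-likelihoods
#' are Bernoulli-expanded (no binomial-coefficient term), so aggregating
#' rows that share a covariate value changes nothing.
#'
#' @param x numeric covariate (relatedness, percent by package convention;
#'   any scale works, McFadden R-squared is scale-invariant).
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @return a [BinomialGlmFit].
#' @export
fitBinomialGlm <- function(x, successes, trials) {
  stopifnot(length(x) == length(successes), length(x) == length(trials))
  keep <- !is.na(x) & !is.na(successes) & !is.na(trials) & trials > 0
  x <- x[keep]; s <- successes[keep]; t <- trials[keep]
  if (any(s < 0) || any(s > t))
    stop("need 0 <= successes <= trials elementwise")
  if (length(unique(x)) < 2L)
    stop("slope inestimable: covariate has fewer than 2 distinct values")
  prop <- s / t
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(prop ~ x, family = stats::binomial(), weights = t),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  p_hat <- stats::fitted(fit)
  p0 <- sum(s) / sum(t)                       # null MLE
  ll <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(s * log(p) + (t - s) * log(1 - p))
  }
  ll1 <- ll(p_hat)
  ll0 <- ll(rep(p0, length(s)))
  lrt <- max(0, 2 * (ll1 - ll0))
  mcf <- if (ll0 == 0) 0 else max(0, 1 - ll1 / ll0)
  separated <- any(p_hat < 1e-8 | p_hat > 1 - 1e-8)
  new("BinomialGlmFit",
      beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
      loglik_model = ll1, loglik_null = ll0,
      mcfadden_r2 = mcf, lrt_stat = lrt,
      lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      n_obs = length(s), total_weight = sum(t),
      converged = isTRUE(fit$converged) && !warned && !separated)
}

#' @describeIn BinomialGlmFit accessors
#' @export
mcfaddenR2 <- function(object) {
  stopifnot(is(object, "BinomialGlmFit")); object@mcfadden_r2
}

#' @rdname mcfaddenR2
#' @export
glmCoef <- function(object) {
  stopifnot(is(object, "BinomialGlmFit"))
  c(beta0 = object@beta0, beta1 = object@beta1)
}

#' @rdname mcfaddenR2
#' @export
lrtPValue <- function(object) {
  stopifnot(is(object, "BinomialGlmFit")); object@lrt_p
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two numeric vectors, with the usual
#' t-based two-sided p-value on `n - 2` degrees of freedom. Degenerate input
#' (constant vector, n < 3) is an error so that scans can propagate a
#' missing value rather than a spurious zero.
#'
#' @param x,y numeric vectors of equal length; pairs with any `NA` are
#'   dropped first.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("Pearson correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.relatednessBins <- function(r) {
  cut(r, breaks = c(-Inf, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("<25", "25-29.9", "30-34.9", "35-39.9", ">=40"))
}

#' Loss ratios across relatedness categories
#'
#' Groups pairs into five relatedness bands (percent, half-open at the
#' upper edge: `[0,25)`, `[25,30)`, `[30,35)`, `[35,40)`, `[40,100]`),
#' summarises the chosen loss ratio per band (n, mean, standard error, for
#' bar-plot reproduction) and compares bands by one-way fixed-effects
#' ANOVA.
#'
#' @param pairs pair-summary data.frame carrying `relatedness_pct` and the
#'   count columns used by [lossRatioByMice()] / [lossRatioByLitter()].
#' @param metric `"by_mice"` or `"by_litter"`.
#' @return list with `bins` (data.frame: bin, n, mean, se), `anova_f`,
#'   `anova_p`, `n_used`.
#' @export
binAndAnova <- function(pairs, metric = c("by_mice", "by_litter")) {
  metric <- match.arg(metric)
  keep <- !is.na(pairs$relatedness_pct)
  pairs <- pairs[keep, , drop = FALSE]
  y <- if (metric == "by_mice") lossRatioByMice(pairs) else
    lossRatioByLitter(pairs)
  bin <- .relatednessBins(pairs$relatedness_pct)
  tab <- data.frame(bin = levels(bin),
                    n = as.integer(tabulate(bin, nbins = nlevels(bin))))
  tab$mean <- as.numeric(tapply(y, bin, mean))[match(tab$bin, levels(bin))]
  tab$se <- as.numeric(tapply(y, bin, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_))
  nonempty <- droplevels(bin)
  if (nlevels(nonempty) < 2L)
    stop("comparison impossible: fewer than 2 non-empty relatedness bins")
  av <- stats::anova(stats::aov(y ~ nonempty))
  list(bins = tab,
       anova_f = av[["F value"]][1L],
       anova_p = av[["Pr(>F)"]][1L],
       n_used = length(y))
}
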