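.scanOutcomes <- c("loss_by_mice", "loss_by_litter", "born", "weaned",
                   "male_loss", "female_loss", "delivery_interval")

#' Sex-specific pre-weaning losses under a 1:1 birth sex ratio
#'
#' Sexes are recorded only at weaning, so sex-specific losses are imputed by
#' assuming an equal male:female ratio at birth: each litter is expected to
#' contribute `born / 2` pups of each sex (fractional for odd litters), and
#' the per-sex loss is the shortfall of weaned pups of that sex, floored at
#' zero (a litter weaning more males than `born / 2` contributes zero male
#' loss, not a negative one; set `floor = FALSE` for the unfloored variant).
#' Litters missing either sex count are skipped and tallied.
#'
#' @param records cleaned litter records.
#' @param floor floor per-sex losses at zero (default `TRUE`).
#' @return data.frame with one row per usable litter: `mating_id`, `year`,
#'   `expected_males`, `expected_females`, `male_loss`, `female_loss`;
#'   attributes `n_skipped` (litters without sex counts) and `n_floored`
#'   (flooring events).
#' @export
sexSpecificLosses <- function(records, floor = TRUE) {
  ok <- !is.na(records$males_weaned) & !is.na(records$females_weaned)
  d <- records[ok, , drop = FALSE]
  em <- d$born / 2
  ef <- d$born / 2
  ml <- em - d$males_weaned
  fl <- ef - d$females_weaned
  n_floored <- sum(ml < 0) + sum(fl < 0)
  if (floor) {
    ml <- pmax(0, ml)
    fl <- pmax(0, fl)
  }
  out <- data.frame(mating_id = d$mating_id,
                    year = if ("year" %in% names(d)) d$year else
                      as.integer(format(d$birth_date, "%Y")),
                    expected_males = em, expected_females = ef,
                    male_loss = ml, female_loss = fl,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "n_floored") <- n_floored
  out
}

# Per-pair (x = relatedness, value, successes, trials) for one outcome on a
# litter subset. Returns NULL when the outcome cannot be built. Aggregation
# is done with rowsum so cumulative scans stay cheap on large colonies.
.outcomeData <- function(records, relatedness, outcome, minLitters) {
  grp <- factor(records$mating_id)
  agg <- rowsum(cbind(n = rep(1, nrow(records)), born = records$born,
                      weaned = records$weaned, losslit = records$dead >= 1),
                grp)
  pairs <- data.frame(mating_id = rownames(agg),
                      n_litters = agg[, "n"], total_born = agg[, "born"],
                      total_weaned = agg[, "weaned"],
                      n_litters_with_loss = agg[, "losslit"],
                      stringsAsFactors = FALSE)
  pairs$total_dead <- pairs$total_born - pairs$total_weaned
  pairs <- pairs[pairs$n_litters >= minLitters, , drop = FALSE]
  pairs$relatedness_pct <-
    relatedness$relatedness_pct[match(pairs$mating_id, relatedness$mating_id)]
  pairs <- pairs[!is.na(pairs$relatedness_pct), , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  x <- pairs$relatedness_pct
  if (outcome == "loss_by_mice") {
    keep <- pairs$total_born > 0
    pairs <- pairs[keep, , drop = FALSE]; x <- x[keep]
    list(x = x, value = pairs$total_dead / pairs$total_born,
         successes = pairs$total_dead, trials = pairs$total_born)
  } else if (outcome == "loss_by_litter") {
    list(x = x, value = pairs$n_litters_with_loss / pairs$n_litters,
         successes = pairs$n_litters_with_loss, trials = pairs$n_litters)
  } else if (outcome == "born") {
    list(x = x, value = pairs$total_born)
  } else if (outcome == "weaned") {
    list(x = x, value = pairs$total_weaned)
  } else if (outcome == "delivery_interval") {
    iv <- computeIntervals(records)
    m <- match(pairs$mating_id, iv$mating_id)
    md <- iv$mean_delivery_interval[m]
    keep <- !is.na(md)
    list(x = x[keep], value = md[keep])
  } else if (outcome %in% c("male_loss", "female_loss")) {
    sl <- sexSpecificLosses(records)
    if (!nrow(sl)) return(NULL)
    grp <- factor(sl$mating_id)
    loss <- if (outcome == "male_loss") sl$male_loss else sl$female_loss
    expd <- if (outcome == "male_loss") sl$expected_males else
      sl$expected_females
    agg <- data.frame(mating_id = levels(grp),
                      loss = as.numeric(tapply(loss, grp, sum)),
                      expected = as.numeric(tapply(expd, grp, sum)))
    m <- match(agg$mating_id, pairs$mating_id)
    keep <- !is.na(m) & agg$expected > 0
    agg <- agg[keep, , drop = FALSE]
    xx <- pairs$relatedness_pct[m[keep]]
    # flooring keeps loss <= expected by construction
    list(x = xx, value = agg$loss / agg$expected,
         successes = pmin(agg$loss, agg$expected), trials = agg$expected)
  } else stop("unknown outcome: ", outcome)
}

.statsForCutoff <- function(dat) {
  out <- list(n_pairs = if (is.null(dat)) 0L else length(dat$x),
              r = NA_real_, r_p = NA_real_, beta1 = NA_real_,
              mcfadden_r2 = NA_real_, lrt_p = NA_real_)
  if (is.null(dat)) return(out)
  pe <- tryCatch(pearsonCorrelation(dat$x, dat$value), error = function(e) NULL)
  if (!is.null(pe)) { out$r <- pe$r; out$r_p <- pe$p }
  if (!is.null(dat$successes)) {
    fit <- tryCatch(
      fitBinomialGlm(dat$x, dat$successes, dat$trials),
      error = function(e) NULL)
    if (!is.null(fit)) {
      out$beta1 <- fit@beta1
      out$mcfadden_r2 <- fit@mcfadden_r2
      out$lrt_p <- fit@lrt_p
    }
  }
  out
}

#' Cumulative-by-year trend scan
#'
#' The longitudinal procedure at the heart of the package: for every cutoff
#' year `Y` from `startYear` to `endYear`, restrict the data to litters born
#' up to and including `Y`, aggregate to breeding pairs, and recompute the
#' association between parental relatedness and the chosen outcome (Pearson
#' correlation; for loss outcomes also the weighted binomial-logit model
#' with McFadden R-squared and LRT p). Early cutoffs with fewer than
#' `minPairs` eligible pairs yield missing points, not errors. The series is
#' annotated with breeding-phase labels from `boundaries`.
#'
#' @param records cleaned litter records (with `year`).
#' @param relatedness data.frame mapping `mating_id` to `relatedness_pct`
#'   (e.g. a pair table from [pairRelatedness()]).
#' @param outcome one of `loss_by_mice`, `loss_by_litter`, `born`, `weaned`,
#'   `male_loss`, `female_loss`, `delivery_interval`.
#' @param startYear,endYear scan range; `NULL` uses the data range.
#' @param minPairs minimum eligible pairs before a point is estimated
#'   (default 10; set to 1 to estimate from the very first year).
#' @param minLitters litter threshold passed to [summarizePairs()].
#' @param boundaries phase boundary years (default `c(1985, 2015)`).
#' @return a [TrendSeries].
#' @export
cumulativeScan <- function(records, relatedness,
                           outcome = .scanOutcomes,
                           startYear = NULL, endYear = NULL,
                           minPairs = 10L, minLitters = 1L,
                           boundaries = c(1985, 2015)) {
  outcome <- match.arg(outcome)
  if (!"year" %in% names(records))
    records$year <- as.integer(format(records$birth_date, "%Y"))
  if (is.null(startYear)) startYear <- min(records$year, na.rm = TRUE)
  if (is.null(endYear)) endYear <- max(records$year, na.rm = TRUE)
  if (startYear > endYear) stop("startYear must not exceed endYear")
  years <- seq.int(startYear, endYear)
  o <- order(records$year)
  records <- records[o, , drop = FALSE]
  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    sub <- records[records$year <= years[i], , drop = FALSE]
    dat <- if (nrow(sub)) .outcomeData(sub, relatedness, outcome, minLitters)
           else NULL
    st <- if (!is.null(dat) && length(dat$x) >= minPairs)
      .statsForCutoff(dat)
    else list(n_pairs = if (is.null(dat)) 0L else length(dat$x),
              r = NA_real_, r_p = NA_real_, beta1 = NA_real_,
              mcfadden_r2 = NA_real_, lrt_p = NA_real_)
    rows[[i]] <- data.frame(cutoff_year = years[i], n_pairs = st$n_pairs,
                            r = st$r, r_p = st$r_p, beta1 = st$beta1,
                            mcfadden_r2 = st$mcfadden_r2, lrt_p = st$lrt_p)
  }
  pts <- do.call(rbind, rows)
  # -log10 p with a floor to keep the transform finite
  pts$neglog10_p <- -log10(pmax(pts$r_p, 1e-300))
  series <- new("TrendSeries", points = pts, outcome = outcome,
                boundaries = as.numeric(boundaries))
  annotatePhases(series, boundaries)
}

#' Label trend points with breeding phases
#'
#' Assigns each cutoff year to a phase era delimited by `boundaries`
#' (Roman numerals I, II, ...). A cutoff equal to a boundary year belongs to
#' the later phase. An empty boundary vector yields a single phase.
#'
#' @param series a [TrendSeries].
#' @param boundaries sorted boundary years within the scan range.
#' @return the relabelled [TrendSeries].
#' @export
annotatePhases <- function(series, boundaries = c(1985, 2015)) {
  stopifnot(is(series, "TrendSeries"))
  boundaries <- as.numeric(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("phase boundaries must be strictly increasing")
  idx <- findInterval(series@points$cutoff_year, boundaries) + 1L
  series@points$phase <- as.character(utils::as.roman(idx))
  series@boundaries <- boundaries
  series
}

#' @describeIn cumulativeScan long-format data.frame of the series points
#' @param series a [TrendSeries]
#' @export
trendPoints <- function(series) {
  stopifnot(is(series, "TrendSeries"))
  cbind(outcome = series@outcome, series@points)
}

#' Exhaustive changepoint search on a trend series
#'
#' Fits a piecewise-constant function with `k` breakpoints (`k <= 2`) to
#' the sequence of Pearson correlations by exhaustive search over all
#' admissible splits, minimising the total squared error. A reproducible
#' counterpart to reading phase boundaries off a plot. Ties are broken
#' towards the earliest breakpoints and reported.
#'
#' @param series a [TrendSeries], or a numeric vector of statistics (then
#'   `years` indexes it).
#' @param k number of breakpoints, 1 or 2.
#' @param years optional cutoff years aligned with a numeric `series`.
#' @return numeric vector of `k` breakpoint years — each is the first year
#'   of the later segment; attribute `"tied"` flags exact ties.
#' @export
detectChangepoints <- function(series, k = 1L, years = NULL) {
  if (is(series, "TrendSeries")) {
    ok <- !is.na(series@points$r)
    x <- series@points$r[ok]
    years <- series@points$cutoff_year[ok]
  } else {
    x <- as.numeric(series)
    if (is.null(years)) years <- seq_along(x)
    ok <- !is.na(x)
    x <- x[ok]; years <- years[ok]
  }
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  n <- length(x)
  if (n < 2L * k + 2L)
    stop("need at least ", 2L * k + 2L, " non-missing points for k = ", k)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  segCost <- function(i, j) {          # SSE of x[i..j] around its mean
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  best <- Inf; best_split <- NULL; tied <- FALSE
  if (k == 1L) {
    for (b in seq_len(n - 1L)) {
      cost <- segCost(1L, b) + segCost(b + 1L, n)
      if (cost < best - 1e-12) {
        best <- cost; best_split <- b; tied <- FALSE
      } else if (abs(cost - best) <= 1e-12) tied <- TRUE
    }
    out <- years[best_split + 1L]
  } else {
    for (b1 in seq_len(n - 2L)) {
      for (b2 in seq.int(b1 + 1L, n - 1L)) {
        cost <- segCost(1L, b1) + segCost(b1 + 1L, b2) + segCost(b2 + 1L, n)
        if (cost < best - 1e-12) {
          best <- cost; best_split <- c(b1, b2); tied <- FALSE
        } else if (abs(cost - best) <= 1e-12) tied <- TRUE
      }
    }
    out <- years[best_split + 1L]
  }
  attr(out, "tied") <- tied
  out
}
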