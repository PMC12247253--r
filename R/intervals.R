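#' Mating-to-first-litter and delivery intervals per pair
#'
#' For every mating cage: the number of days from the recorded mating date
#' to the first birth (missing when no mating date is recorded, or when the
#' mating date falls after the first birth), and the day gaps between
#' consecutive births. Nonpositive gaps (same-day repeat litters) are
#' treated as data errors: excluded from the gap list and tallied, never
#' kept as zero intervals.
#'
#' @param records cleaned litter records.
#' @return data.frame with one row per pair: `mating_id`, `n_litters`,
#'   `first_litter_interval` (days), `n_gaps`, `mean_delivery_interval`
#'   (days; `NA` for single-litter pairs), plus a list column
#'   `delivery_intervals`. Attribute `"n_nonpositive_gaps"` tallies excluded
#'   gaps.
#' @export
computeIntervals <- function(records) {
  o <- order(records$mating_id, records$birth_date)
  records <- records[o, , drop = FALSE]
  grp <- factor(records$mating_id, levels = unique(records$mating_id))
  ids <- levels(grp)
  n_bad <- 0L
  gaps <- vector("list", length(ids))
  firsts <- rep(NA_real_, length(ids))
  nlit <- integer(length(ids))
  split_birth <- split(as.numeric(records$birth_date), grp)
  split_mating <- split(as.numeric(records$mating_date), grp)
  for (i in seq_along(ids)) {
    b <- sort(split_birth[[i]])
    nlit[i] <- length(b)
    g <- diff(b)
    bad <- g <= 0
    n_bad <- n_bad + sum(bad)
    gaps[[i]] <- g[!bad]
    md <- split_mating[[i]]
    md <- md[!is.na(md)]
    if (length(md)) {
      fi <- b[1L] - md[1L]
      if (fi > 0) firsts[i] <- fi
    }
  }
  out <- data.frame(mating_id = ids, n_litters = nlit,
                    first_litter_interval = firsts,
                    n_gaps = lengths(gaps),
                    mean_delivery_interval = vapply(
                      gaps, function(g) if (length(g)) mean(g) else NA_real_,
                      numeric(1)),
                    stringsAsFactors = FALSE)
  out$delivery_intervals <- I(gaps)
  attr(out, "n_nonpositive_gaps") <- n_bad
  out
}

#' Association between relatedness and breeding intervals
#'
#' Pooled mode: Pearson correlation between parental relatedness and either
#' the mating-to-first-litter interval or the per-pair mean delivery
#' interval (the per-pair mean, not per-gap rows, is the correlation unit).
#' Cumulative mode: the same association recomputed on cumulative year
#' windows via [cumulativeScan()] (delivery intervals only).
#'
#' @param records cleaned litter records.
#' @param relatedness data.frame mapping `mating_id` to `relatedness_pct`.
#' @param mode `"delivery"` (default) or `"first"`.
#' @param scope `"pooled"` (default) or `"cumulative"`.
#' @param ... passed to [cumulativeScan()] in cumulative scope.
#' @return pooled: list `r`, `p`, `n` (see [pearsonCorrelation()]);
#'   cumulative: a [TrendSeries].
#' @export
intervalRelatednessAssociation <- function(records, relatedness,
                                           mode = c("delivery", "first"),
                                           scope = c("pooled", "cumulative"),
                                           ...) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (scope == "cumulative") {
    if (mode != "delivery")
      stop("cumulative scope is defined for delivery intervals only")
    return(cumulativeScan(records, relatedness,
                          outcome = "delivery_interval", ...))
  }
  iv <- computeIntervals(records)
  iv$relatedness_pct <-
    relatedness$relatedness_pct[match(iv$mating_id, relatedness$mating_id)]
  val <- if (mode == "delivery") iv$mean_delivery_interval else
    iv$first_litter_interval
  keep <- !is.na(val) & !is.na(iv$relatedness_pct)
  if (sum(keep) < 3L)
    stop("need at least 3 pairs with relatedness and a defined interval")
  pearsonCorrelation(iv$relatedness_pct[keep], val[keep])
}
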