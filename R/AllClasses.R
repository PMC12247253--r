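#' @import methods
NULL

#' Pedigree of a closed colony
#'
#' A directed acyclic parent map over individual identifiers. Each individual
#' has at most one recorded sire and one recorded dam; individuals with both
#' parents unrecorded are founders, assumed mutually unrelated and non-inbred.
#'
#' @slot id character vector of unique individual identifiers.
#' @slot sire character vector, same length as `id`; `NA` when unknown.
#' @slot dam character vector, same length as `id`; `NA` when unknown.
#'
#' @seealso [buildPedigree()], [kinship()], [truncateAncestry()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character"))

setValidity("Pedigree", function(object) {
  msgs <- character()
  if (anyDuplicated(object@id))
    msgs <- c(msgs, "individual ids must be unique")
  if (length(object@sire) != length(object@id) ||
      length(object@dam) != length(object@id))
    msgs <- c(msgs, "id, sire and dam must have equal length")
  known <- c(object@sire, object@dam)
  known <- known[!is.na(known)]
  if (!all(known %in% object@id))
    msgs <- c(msgs, "every referenced parent must exist as a node")
  cyc <- .findCycle(object@id, object@sire, object@dam)
  if (!is.null(cyc))
    msgs <- c(msgs, paste0("pedigree contains a cycle: ",
                           paste(cyc, collapse = " -> ")))
  if (length(msgs)) msgs else TRUE
})

# Kahn peeling; returns NULL if acyclic, else one offending id chain.
.findCycle <- function(id, sire, dam) {
  n <- length(id)
  if (n == 0L) return(NULL)
  idx <- seq_len(n)
  names(idx) <- id
  pf <- ifelse(is.na(sire), NA_integer_, idx[sire])
  pm <- ifelse(is.na(dam), NA_integer_, idx[dam])
  # out-degree of i = number of parents still present
  deg <- (!is.na(pf)) + (!is.na(pm))
  children <- vector("list", n)  # parent -> child indices
  for (i in idx) {
    for (p in c(pf[i], pm[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  # peel individuals whose ancestors are fully resolved: start from founders
  queue <- which(deg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == n) return(NULL)
  # walk parent links from an unresolved node until a repeat gives the chain
  v <- which(deg > 0L)[1L]
  chain <- integer()
  repeat {
    if (v %in% chain) {
      chain <- c(chain[which(chain == v)[1L]:length(chain)], v)
      return(id[chain])
    }
    chain <- c(chain, v)
    v <- if (!is.na(pf[v]) && deg[pf[v]] > 0L) pf[v] else pm[v]
  }
}

#' @describeIn Pedigree number of individuals
#' @param x,object a `Pedigree`
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  fo <- founders(object)
  cat("Pedigree with", length(object@id), "individuals,",
      length(fo), "founders\n")
  invisible(object)
})

#' Weighted binomial-logit model fit
#'
#' Result of regressing a loss proportion on parental relatedness with a
#' binomial likelihood and logit link, weighted by the number of events
#' (mice born or litters). Carries the Bernoulli-expanded log-likelihoods of
#' the fitted and the intercept-only model, McFadden's pseudo R-squared
#' `1 - loglik_model / loglik_null`, and the likelihood-ratio test of the
#' slope against a chi-squared distribution with one degree of freedom.
#'
#' @slot beta0,beta1 intercept and slope on the logit scale.
#' @slot loglik_model,loglik_null log-likelihoods (no binomial-coefficient
#'   terms, so aggregation of rows sharing a covariate value leaves them
#'   unchanged).
#' @slot mcfadden_r2,lrt_stat,lrt_p fit and test statistics.
#' @slot n_obs number of observations; @slot total_weight sum of trials.
#' @slot converged honest convergence flag; `FALSE` under complete
#'   separation or failed IRLS.
#'
#' @seealso [fitBinomialGlm()]
#' @exportClass BinomialGlmFit
setClass("BinomialGlmFit",
  representation(beta0 = "numeric", beta1 = "numeric",
                 loglik_model = "numeric", loglik_null = "numeric",
                 mcfadden_r2 = "numeric", lrt_stat = "numeric",
                 lrt_p = "numeric", n_obs = "integer",
                 total_weight = "numeric", converged = "logical"))

setValidity("BinomialGlmFit", function(object) {
  msgs <- character()
  tol <- 1e-6
  if (object@loglik_model < object@loglik_null - tol)
    msgs <- c(msgs, "model log-likelihood below null (model nests null)")
  if (object@mcfadden_r2 < -tol || object@mcfadden_r2 >= 1)
    msgs <- c(msgs, "McFadden R2 outside [0, 1)")
  if (object@lrt_p <= 0 || object@lrt_p > 1)
    msgs <- c(msgs, "LRT p outside (0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BinomialGlmFit", function(object) {
  cat("Binomial-logit fit (n =", object@n_obs,
      ", total weight =", object@total_weight, ")\n")
  cat(sprintf("  beta0 = %.4f  beta1 = %.6f\n", object@beta0, object@beta1))
  cat(sprintf("  McFadden R2 = %.4f  LRT p = %.3g  converged = %s\n",
              object@mcfadden_r2, object@lrt_p, object@converged))
  invisible(object)
})

#' Cumulative-window trend series
#'
#' Association statistics between parental relatedness and a reproductive
#' outcome, recomputed on cumulative year windows (all litters born up to
#' each cutoff year) and annotated with breeding-phase labels.
#'
#' @slot points data.frame with one row per cutoff year: `cutoff_year`,
#'   `n_pairs`, `r`, `r_p` (Pearson), `beta1`, `mcfadden_r2`, `lrt_p`
#'   (binomial GLM; `NA` for count outcomes), `neglog10_p`, `phase`.
#' @slot outcome one of `loss_by_mice`, `loss_by_litter`, `born`, `weaned`,
#'   `male_loss`, `female_loss`, `delivery_interval`.
#' @slot boundaries phase boundary years; a cutoff equal to a boundary is
#'   assigned to the later phase.
#'
#' @seealso [cumulativeScan()], [annotatePhases()], [detectChangepoints()]
#' @exportClass TrendSeries
setClass("TrendSeries",
  representation(points = "data.frame", outcome = "character",
                 boundaries = "numeric"))

setValidity("TrendSeries", function(object) {
  msgs <- character()
  y <- object@points$cutoff_year
  if (is.unsorted(y, strictly = TRUE))
    msgs <- c(msgs, "cutoff years must be strictly increasing")
  np <- object@points$n_pairs[!is.na(object@points$n_pairs)]
  if (length(np) && is.unsorted(np))
    msgs <- c(msgs, "n_pairs must be non-decreasing in cutoff year")
  if (is.unsorted(object@boundaries, strictly = TRUE))
    msgs <- c(msgs, "phase boundaries must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TrendSeries", function(object) {
  p <- object@points
  ok <- !is.na(p$r)
  cat("TrendSeries (", object@outcome, "): ", nrow(p), " cutoffs, ",
      sum(ok), " with estimates; phases at ",
      paste(object@boundaries, collapse = ", "), "\n", sep = "")
  if (any(ok)) {
    i <- which.max(abs(p$r))
    cat(sprintf("  final r = %.4f (p = %.3g); peak |r| = %.4f at %d\n",
                p$r[max(which(ok))], p$r_p[max(which(ok))],
                abs(p$r[i]), p$cutoff_year[i]))
  }
  invisible(object)
})

#' Report of breeding-record cleaning
#'
#' Tallies of each cleaning action applied to raw litter records:
#' duplicate removal, removal of incomplete or inconsistent rows, and
#' capping of weaning counts at birth counts.
#'
#' @slot n_rows_in,n_rows_retained row counts before/after cleaning.
#' @slot n_duplicates_removed,n_incomplete_removed,n_capped action tallies.
#' @slot n_pairs_in,n_pairs_retained,n_pairs_removed breeding-pair
#'   (mating-cage) census before and after cleaning.
#'
#' @seealso [cleanRecords()]
#' @exportClass CleaningReport
setClass("CleaningReport",
  representation(n_rows_in = "integer", n_rows_retained = "integer",
                 n_duplicates_removed = "integer",
                 n_incomplete_removed = "integer", n_capped = "integer",
                 n_pairs_in = "integer", n_pairs_retained = "integer",
                 n_pairs_removed = "integer"))

setValidity("CleaningReport", function(object) {
  msgs <- character()
  counts <- c(object@n_rows_in, object@n_rows_retained,
              object@n_duplicates_removed, object@n_incomplete_removed,
              object@n_capped, object@n_pairs_in, object@n_pairs_retained,
              object@n_pairs_removed)
  if (any(counts < 0L)) msgs <- c(msgs, "all counts must be >= 0")
  if (object@n_pairs_in != object@n_pairs_retained + object@n_pairs_removed)
    msgs <- c(msgs, "n_pairs_in must equal n_pairs_retained + n_pairs_removed")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CleaningReport", function(object) {
  cat("Cleaning report:\n")
  cat("  rows:", object@n_rows_in, "in ->", object@n_rows_retained,
      "retained (", object@n_duplicates_removed, "duplicates,",
      object@n_incomplete_removed, "incomplete/invalid removed;",
      object@n_capped, "weaning counts capped )\n")
  cat("  pairs:", object@n_pairs_in, "in ->", object@n_pairs_retained,
      "retained,", object@n_pairs_removed, "removed\n")
  invisible(object)
})

#' Configuration of the synthetic closed-colony simulator
#'
#' Parameters of the discrete-event generative model: founder count, colony
#' span, kin-avoiding pair formation, zero-truncated Poisson litter sizes,
#' relatedness-dependent pre-weaning mortality on the logit scale, and
#' relatedness-dependent delivery intervals. Relatedness enters both linear
#' predictors as a proportion (twice the kinship coefficient, in [0, 1]).
#'
#' @slot n_founders founder animals, assumed unrelated (default 40).
#' @slot n_years simulated span in years; @slot start_year first calendar year.
#' @slot pairs_active breeding cages kept occupied at any time.
#' @slot pair_relatedness_cap pairs are formed only when the candidate
#'   dam-sire relatedness percentage is strictly below this cap
#'   (default 50: full siblings and closer are excluded).
#' @slot litter_rate fraction of scheduled breeding cycles that yield a
#'   recorded litter (default 1).
#' @slot litter_size_mean Poisson mean before zero truncation.
#' @slot mortality_intercept,mortality_slope logit-scale pup mortality
#'   `plogis(b0 + b1 * r)` with `r` the relatedness proportion.
#' @slot interval_base,interval_slope,interval_sd,interval_min delivery
#'   interval in days: `max(interval_min, base - slope * r + N(0, sd))`.
#' @slot phase_schedule data.frame (`start_year`, `end_year`,
#'   `mortality_slope`, `interval_slope`) of per-era overrides; zero rows
#'   means constant parameters.
#' @slot breeder_lifespan_years length-2 range; each pair's tenure is drawn
#'   uniformly from it (default 1.5 to 2 years).
#' @slot recruit_prob probability a weaned pup is registered as a breeder
#'   candidate (subject to a pool cap).
#'
#' @seealso [colonySimConfig()], [simulateColony()]
#' @exportClass ColonySimConfig
setClass("ColonySimConfig",
  representation(n_founders = "integer", n_years = "integer",
                 start_year = "integer", pairs_active = "integer",
                 pair_relatedness_cap = "numeric", litter_rate = "numeric",
                 litter_size_mean = "numeric",
                 mortality_intercept = "numeric", mortality_slope = "numeric",
                 interval_base = "numeric", interval_slope = "numeric",
                 interval_sd = "numeric", interval_min = "numeric",
                 phase_schedule = "data.frame",
                 breeder_lifespan_years = "numeric",
                 recruit_prob = "numeric"))

setValidity("ColonySimConfig", function(object) {
  msgs <- character()
  if (object@n_founders < 4L) msgs <- c(msgs, "need at least 4 founders")
  if (object@n_years < 1L) msgs <- c(msgs, "n_years must be >= 1")
  if (object@pairs_active < 1L) msgs <- c(msgs, "pairs_active must be >= 1")
  if (object@litter_size_mean <= 0) msgs <- c(msgs, "litter_size_mean must be > 0")
  if (object@pair_relatedness_cap < 0 || object@pair_relatedness_cap > 100)
    msgs <- c(msgs, "pair_relatedness_cap must be in [0, 100]")
  if (object@litter_rate <= 0 || object@litter_rate > 1)
    msgs <- c(msgs, "litter_rate must be in (0, 1]")
  if (object@interval_sd < 0) msgs <- c(msgs, "interval_sd must be >= 0")
  if (object@interval_min <= 0) msgs <- c(msgs, "interval_min must be > 0")
  if (length(object@breeder_lifespan_years) != 2L ||
      any(object@breeder_lifespan_years <= 0) ||
      diff(object@breeder_lifespan_years) < 0)
    msgs <- c(msgs, "breeder_lifespan_years must be a non-decreasing positive pair")
  if (object@recruit_prob <= 0 || object@recruit_prob > 1)
    msgs <- c(msgs, "recruit_prob must be in (0, 1]")
  ps <- object@phase_schedule
  if (nrow(ps)) {
    need <- c("start_year", "end_year", "mortality_slope", "interval_slope")
    if (!all(need %in% names(ps))) {
      msgs <- c(msgs, "phase_schedule needs start_year, end_year, mortality_slope, interval_slope")
    } else {
      ps <- ps[order(ps$start_year), , drop = FALSE]
      span <- c(object@start_year, object@start_year + object@n_years - 1L)
      if (ps$start_year[1L] > span[1L] || ps$end_year[nrow(ps)] < span[2L] ||
          (nrow(ps) > 1L && any(ps$start_year[-1L] != ps$end_year[-nrow(ps)] + 1L)))
        msgs <- c(msgs, "phase_schedule eras must partition the simulated span")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ColonySimConfig", function(object) {
  cat("Colony simulator config:", object@n_founders, "founders,",
      object@n_years, "years from", object@start_year, ",",
      object@pairs_active, "active pairs\n")
  cat(sprintf("  mortality logit %.2f + %.2f r; interval %.0f - %.0f r (sd %.0f, min %.0f) days\n",
              object@mortality_intercept, object@mortality_slope,
              object@interval_base, object@interval_slope,
              object@interval_sd, object@interval_min))
  if (nrow(object@phase_schedule))
    cat("  phase schedule with", nrow(object@phase_schedule), "eras\n")
  invisible(object)
})

#' Synthetic colony output
#'
#' Everything [simulateColony()] knows about a simulated colony: the litter
#' table in the breeding-record schema, the true pedigree, per-pair true
#' relatedness, and per-litter true mortality probabilities for oracle
#' checks.
#'
#' @slot records litter data.frame in the cleaned breeding-record schema.
#' @slot pedigree [Pedigree] over all registered individuals.
#' @slot pairs data.frame: `mating_id`, `dam_id`, `sire_id`, `formed_date`,
#'   `relatedness_pct` (truth, untruncated).
#' @slot litter_probs true pre-weaning death probability per litter row.
#' @slot config the [ColonySimConfig] used.
#' @slot extinct,extinction_year extinction flag and year (`NA` if none).
#'
#' @seealso [simulateColony()], [makeThreePhaseColony()]
#' @exportClass ColonySim
setClass("ColonySim",
  representation(records = "data.frame", pedigree = "Pedigree",
                 pairs = "data.frame", litter_probs = "numeric",
                 config = "ColonySimConfig", extinct = "logical",
                 extinction_year = "integer"))

setMethod("show", "ColonySim", function(object) {
  cat("Synthetic colony:", nrow(object@records), "litters from",
      nrow(object@pairs), "pairs;", length(object@pedigree), "pedigree nodes\n")
  if (object@extinct)
    cat("  colony went extinct in", object@extinction_year, "\n")
  invisible(object)
})
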