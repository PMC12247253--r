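#' Run the full closed-colony analysis
#'
#' Wires all stages into the end-to-end workflow: clean the litter records,
#' build the pedigree and compute dam-sire relatedness (ancestor tracing
#' truncated at `maxGenerations`), fit the relatedness-loss models (both
#' loss metrics: weighted binomial GLM, Pearson correlation, relatedness
#' bins with ANOVA), run cumulative trend scans, and analyse breeding
#' intervals. Optionally writes every table as CSV/JSON into `outDir`,
#' together with a run log echoing the configuration and the cleaning
#' report.
#'
#' @param records raw litter records (data.frame from
#'   [readBreedingRecords()]) or a path to a delimited file.
#' @param registry optional individual-level parent table for
#'   [buildPedigree()].
#' @param schema,dateFormat passed to [readBreedingRecords()] when
#'   `records` is a path.
#' @param maxGenerations kinship ancestor-tracing depth (default 5).
#' @param minLitters litter threshold for pair summaries and GLMs
#'   (default 1); bar-plot binning uses `binMinLitters` (default 3).
#' @param binMinLitters litter threshold for the binned ANOVA comparison.
#' @param minPairs minimum pairs per trend-scan point.
#' @param boundaries breeding-phase boundary years.
#' @param outDir output directory, or `NULL` to skip file output.
#' @return list with `cleaning` ([CleaningReport]), `pairs` (pair summary
#'   with relatedness), `glm_by_mice`, `glm_by_litter` ([BinomialGlmFit]),
#'   `pearson_by_mice`, `pearson_by_litter`, `bins_by_mice`,
#'   `bins_by_litter`, `scan_by_mice`, `scan_by_litter` ([TrendSeries]),
#'   `intervals` (per-pair interval table), `interval_corr_delivery`,
#'   `interval_corr_first`.
#' @export
runFullAnalysis <- function(records, registry = NULL,
                            schema = defaultSchema(), dateFormat = "ymd",
                            maxGenerations = 5L, minLitters = 1L,
                            binMinLitters = 3L, minPairs = 10L,
                            boundaries = c(1985, 2015), outDir = NULL) {
  if (is.character(records))
    records <- readBreedingRecords(records, schema = schema,
                                   dateFormat = dateFormat)
  cleaned <- cleanRecords(records)
  rec <- cleaned$records
  if (!nrow(rec)) stop("cleaning stage: no records survived cleaning")

  ped <- buildPedigree(rec, registry = registry)
  pairs <- summarizePairs(rec, minLitters = minLitters)
  pairs <- pairRelatedness(ped, pairs, maxGenerations = maxGenerations)
  withRel <- pairs[!is.na(pairs$relatedness_pct) & pairs$total_born > 0, ,
                   drop = FALSE]
  if (nrow(withRel) < 3L)
    stop("relatedness stage: fewer than 3 pairs with computable relatedness")

  glm_mice <- fitBinomialGlm(withRel$relatedness_pct, withRel$total_dead,
                             withRel$total_born)
  glm_lit <- fitBinomialGlm(withRel$relatedness_pct,
                            withRel$n_litters_with_loss, withRel$n_litters)
  pe_mice <- pearsonCorrelation(withRel$relatedness_pct,
                                lossRatioByMice(withRel))
  pe_lit <- pearsonCorrelation(withRel$relatedness_pct,
                               lossRatioByLitter(withRel))
  binPairs <- withRel[withRel$n_litters >= binMinLitters, , drop = FALSE]
  bins_mice <- tryCatch(binAndAnova(binPairs, "by_mice"),
                        error = function(e) NULL)
  bins_lit <- tryCatch(binAndAnova(binPairs, "by_litter"),
                       error = function(e) NULL)

  scan_mice <- cumulativeScan(rec, pairs, outcome = "loss_by_mice",
                              minPairs = minPairs, minLitters = minLitters,
                              boundaries = boundaries)
  scan_lit <- cumulativeScan(rec, pairs, outcome = "loss_by_litter",
                             minPairs = minPairs, minLitters = minLitters,
                             boundaries = boundaries)

  iv <- computeIntervals(rec)
  corr_del <- tryCatch(
    intervalRelatednessAssociation(rec, pairs, mode = "delivery"),
    error = function(e) NULL)
  corr_first <- tryCatch(
    intervalRelatednessAssociation(rec, pairs, mode = "first"),
    error = function(e) NULL)

  out <- list(cleaning = cleaned$report, pairs = pairs,
              glm_by_mice = glm_mice, glm_by_litter = glm_lit,
              pearson_by_mice = pe_mice, pearson_by_litter = pe_lit,
              bins_by_mice = bins_mice, bins_by_litter = bins_lit,
              scan_by_mice = scan_mice, scan_by_litter = scan_lit,
              intervals = iv, interval_corr_delivery = corr_del,
              interval_corr_first = corr_first)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    exportCleaned(cleaned, pairs, outDir)
    utils::write.csv(trendPoints(scan_mice),
                     file.path(outDir, "scan_loss_by_mice.csv"),
                     row.names = FALSE)
    utils::write.csv(trendPoints(scan_lit),
                     file.path(outDir, "scan_loss_by_litter.csv"),
                     row.names = FALSE)
    ivOut <- iv[setdiff(names(iv), "delivery_intervals")]
    utils::write.csv(ivOut, file.path(outDir, "intervals.csv"),
                     row.names = FALSE)
    summary <- list(
      config = list(maxGenerations = maxGenerations,
                    minLitters = minLitters, binMinLitters = binMinLitters,
                    minPairs = minPairs, boundaries = boundaries),
      glm_by_mice = list(beta1 = glm_mice@beta1,
                         mcfadden_r2 = glm_mice@mcfadden_r2,
                         lrt_p = glm_mice@lrt_p),
      glm_by_litter = list(beta1 = glm_lit@beta1,
                           mcfadden_r2 = glm_lit@mcfadden_r2,
                           lrt_p = glm_lit@lrt_p),
      pearson_by_mice = pe_mice, pearson_by_litter = pe_lit,
      interval_corr_delivery = corr_del, interval_corr_first = corr_first)
    jsonlite::write_json(summary, file.path(outDir, "analysis_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
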