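#' Default column mapping for breeding-record files
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a delimited breeding-record file. Override entries to
#' match a particular export; set an optional entry to `NA` to declare the
#' column absent.
#'
#' @return named character vector: canonical name -> file column name.
#' @export
defaultSchema <- function() {
  c(mating_id = "mating_id", dam_id = "dam_id", sire_id = "sire_id",
    mating_date = "mating_date", birth_date = "birth_date",
    born = "born", weaned = "weaned",
    males_weaned = "males_weaned", females_weaned = "females_weaned",
    stock = "stock")
}

.mandatoryFields <- c("mating_id", "dam_id", "sire_id", "birth_date",
                      "born", "weaned")

.parseDates <- function(x, dateFormat) {
  fmt <- switch(dateFormat, ymd = "%Y-%m-%d", mdy = "%m/%d/%Y",
                stop("dateFormat must be 'ymd' or 'mdy'"))
  as.Date(as.character(x), format = fmt)
}

.parseCount <- function(x) {
  v <- suppressWarnings(as.numeric(as.character(x)))
  v[!is.na(v) & (v < 0 | v != floor(v))] <- NA  # negative/fractional invalid
  v
}

#' Read breeding records from a delimited text file
#'
#' One row per litter (one reproductive event of a mating cage). Rows are
#' returned in file order; nothing is dropped at this stage. Unparseable
#' dates and invalid counts become `NA` and are flagged in the
#' `invalid_birth_date` / count columns so that [cleanRecords()] can tally
#' them instead of silently losing rows. Blank dam or sire cells are kept
#' with the identifier marked unknown (`NA`).
#'
#' @param path path to a CSV or TSV file (delimiter chosen by extension,
#'   overridable via `sep`).
#' @param schema column mapping, see [defaultSchema()].
#' @param sep field separator; `NULL` (default) picks `"\t"` for `.tsv`,
#'   `","` otherwise.
#' @param dateFormat `"ymd"` (ISO-8601) or `"mdy"` (US month/day/year);
#'   one dialect for the whole file, never guessed per row.
#' @return data.frame of litter records with canonical columns: `mating_id`,
#'   `dam_id`, `sire_id`, `mating_date`, `birth_date` (`Date`), `born`,
#'   `weaned`, `males_weaned`, `females_weaned`, `stock`, `dead`
#'   (born - weaned, recomputed after cleaning), and the flag
#'   `invalid_birth_date`.
#' @export
readBreedingRecords <- function(path, schema = defaultSchema(), sep = NULL,
                                dateFormat = "ymd") {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop("input file contains no data rows: ", path)
  full <- defaultSchema()
  full[names(schema)] <- schema
  missing_cols <- full[.mandatoryFields][!(full[.mandatoryFields] %in% names(raw))]
  if (length(missing_cols))
    stop("mandatory column(s) missing from input: ",
         paste(missing_cols, collapse = ", "))
  pick <- function(field) {
    col <- full[[field]]
    if (is.na(col) || !(col %in% names(raw))) rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  birth_raw <- pick("birth_date")
  birth <- .parseDates(birth_raw, dateFormat)
  mating <- .parseDates(pick("mating_date"), dateFormat)
  out <- data.frame(
    mating_id = pick("mating_id"),
    dam_id = pick("dam_id"),
    sire_id = pick("sire_id"),
    mating_date = mating,
    birth_date = birth,
    born = .parseCount(pick("born")),
    weaned = .parseCount(pick("weaned")),
    males_weaned = .parseCount(pick("males_weaned")),
    females_weaned = .parseCount(pick("females_weaned")),
    stock = pick("stock"),
    stringsAsFactors = FALSE)
  out$dead <- out$born - out$weaned
  out$invalid_birth_date <- !is.na(birth_raw) & is.na(birth)
  out
}

#' Clean breeding records
#'
#' Applies the quality-control rules in a fixed order and tallies every
#' action in a [CleaningReport]:
#' \enumerate{
#'   \item duplicate rows (identical on all canonical fields) collapse to one;
#'   \item rows with missing or invalid mating id, stock (when a stock column
#'     was mapped), birth date, born or weaned counts, or with
#'     `males_weaned + females_weaned != weaned` when both sex counts are
#'     present, are removed as incomplete/inconsistent;
#'   \item weaning counts exceeding birth counts are capped at the birth
#'     count (a data-entry safeguard), and `dead = born - weaned` is
#'     recomputed for every retained row.
#' }
#' Records with an unknown dam or sire are retained: they still carry litter
#' statistics, and simply yield a missing relatedness downstream.
#'
#' @param records data.frame from [readBreedingRecords()] (or any table with
#'   the canonical columns).
#' @param pairwise if `TRUE`, removing any row of a mating cage removes the
#'   whole cage (all its rows), mimicking pair-level quality filtering.
#' @return list with `records` (cleaned data.frame, `year` column added)
#'   and `report` (a [CleaningReport]).
#' @export
cleanRecords <- function(records, pairwise = FALSE) {
  n_in <- nrow(records)
  pairs_in <- unique(records$mating_id[!is.na(records$mating_id)])
  keyCols <- c("mating_id", "dam_id", "sire_id", "mating_date", "birth_date",
               "born", "weaned", "males_weaned", "females_weaned", "stock")
  keyCols <- intersect(keyCols, names(records))
  key <- do.call(paste, c(lapply(records[keyCols], as.character), sep = "\r"))
  dup <- duplicated(key)
  records <- records[!dup, , drop = FALSE]

  has_stock <- "stock" %in% names(records) && !all(is.na(records$stock))
  sex_present <- !is.na(records$males_weaned) & !is.na(records$females_weaned)
  bad <- is.na(records$mating_id) |
    is.na(records$birth_date) |
    (if ("invalid_birth_date" %in% names(records))
       records$invalid_birth_date %in% TRUE else FALSE) |
    is.na(records$born) | is.na(records$weaned) |
    (if (has_stock) is.na(records$stock) else FALSE) |
    (sex_present & (records$males_weaned + records$females_weaned !=
                      records$weaned))
  if (pairwise) {
    bad_pairs <- unique(records$mating_id[bad])
    bad <- bad | records$mating_id %in% bad_pairs
  }
  n_incomplete <- sum(bad)
  records <- records[!bad, , drop = FALSE]

  capped <- !is.na(records$weaned) & !is.na(records$born) &
    records$weaned > records$born
  records$weaned[capped] <- records$born[capped]
  # keep sex counts consistent with the capped total (proportional trim)
  fix <- capped & !is.na(records$males_weaned) & !is.na(records$females_weaned)
  if (any(fix)) {
    tot <- records$males_weaned[fix] + records$females_weaned[fix]
    m2 <- ifelse(tot > 0,
                 round(records$weaned[fix] * records$males_weaned[fix] / tot),
                 0)
    records$males_weaned[fix] <- m2
    records$females_weaned[fix] <- records$weaned[fix] - m2
  }
  records$dead <- records$born - records$weaned
  records$year <- as.integer(format(records$birth_date, "%Y"))
  records$invalid_birth_date <- NULL

  pairs_out <- unique(records$mating_id)
  report <- new("CleaningReport",
    n_rows_in = as.integer(n_in),
    n_rows_retained = nrow(records),
    n_duplicates_removed = as.integer(sum(dup)),
    n_incomplete_removed = as.integer(n_incomplete),
    n_capped = as.integer(sum(capped)),
    n_pairs_in = length(pairs_in),
    n_pairs_retained = length(pairs_out),
    n_pairs_removed = length(pairs_in) - length(pairs_out))
  rownames(records) <- NULL
  list(records = records, report = report)
}

#' Summarise litters per breeding pair
#'
#' Aggregates cleaned litter records to one row per mating cage: litter
#' count, totals of born/weaned/dead pups, the number of litters in which at
#' least one pup was lost, the first birth date, and the mean delivery
#' interval (days between consecutive births, defined from two litters on).
#'
#' @param records cleaned litter records.
#' @param minLitters keep only pairs with at least this many litters
#'   (default 1, i.e. all pairs).
#' @return data.frame with columns `mating_id`, `dam_id`, `sire_id`,
#'   `n_litters`, `total_born`, `total_weaned`, `total_dead`,
#'   `n_litters_with_loss`, `first_birth_date`, `mean_delivery_interval`.
#' @export
summarizePairs <- function(records, minLitters = 1L) {
  if (length(minLitters) != 1L || is.na(minLitters) || minLitters < 1L)
    stop("minLitters must be a positive integer")
  o <- order(records$mating_id, records$birth_date)
  records <- records[o, , drop = FALSE]
  grp <- factor(records$mating_id, levels = unique(records$mating_id))
  firstOf <- function(x) x[1L]
  meanGap <- function(d) {
    if (length(d) < 2L) return(NA_real_)
    mean(diff(as.numeric(sort(d))))
  }
  out <- data.frame(
    mating_id = levels(grp),
    dam_id = tapply(records$dam_id, grp, firstOf),
    sire_id = tapply(records$sire_id, grp, firstOf),
    n_litters = as.integer(tapply(records$born, grp, length)),
    total_born = as.numeric(tapply(records$born, grp, sum)),
    total_weaned = as.numeric(tapply(records$weaned, grp, sum)),
    n_litters_with_loss = as.integer(tapply(records$dead >= 1, grp, sum)),
    stringsAsFactors = FALSE)
  out$total_dead <- out$total_born - out$total_weaned
  out$first_birth_date <- as.Date(
    tapply(as.numeric(records$birth_date), grp, min), origin = "1970-01-01")
  out$mean_delivery_interval <-
    as.numeric(tapply(records$birth_date, grp, meanGap))
  out <- out[out$n_litters >= minLitters, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cleaned tables and report
#'
#' Convenience export of the cleaned litter table and pair summary as CSV
#' and the [CleaningReport] as JSON.
#'
#' @param cleaned the list returned by [cleanRecords()].
#' @param pairs a pair-summary table from [summarizePairs()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
exportCleaned <- function(cleaned, pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "litters_clean.csv")
  p2 <- file.path(dir, "pairs_summary.csv")
  p3 <- file.path(dir, "cleaning_report.json")
  utils::write.csv(cleaned$records, p1, row.names = FALSE)
  utils::write.csv(pairs, p2, row.names = FALSE)
  rep <- cleaned$report
  jsonlite::write_json(
    list(n_rows_in = rep@n_rows_in, n_rows_retained = rep@n_rows_retained,
         n_duplicates_removed = rep@n_duplicates_removed,
         n_incomplete_removed = rep@n_incomplete_removed,
         n_capped = rep@n_capped, n_pairs_in = rep@n_pairs_in,
         n_pairs_retained = rep@n_pairs_retained,
         n_pairs_removed = rep@n_pairs_removed),
    p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
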