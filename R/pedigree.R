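#' Construct a Pedigree
#'
#' @param id character vector of individual identifiers.
#' @param sire,dam parent identifiers aligned with `id`; `NA` (or `"0"`,
#'   the studbook convention) for unknown. Parents referenced but absent
#'   from `id` are added as implicit founders.
#' @return a [Pedigree].
#' @examples
#' ped <- Pedigree(id = c("A", "B"), sire = c("F1", NA), dam = c("F2", NA))
#' founders(ped)
#' @export
Pedigree <- function(id, sire = NA_character_, dam = NA_character_) {
  id <- as.character(id)
  sire <- as.character(rep_len(sire, length(id)))
  dam <- as.character(rep_len(dam, length(id)))
  sire[!is.na(sire) & (sire == "0" | sire == "")] <- NA_character_
  dam[!is.na(dam) & (dam == "0" | dam == "")] <- NA_character_
  implicit <- setdiff(c(sire, dam), c(id, NA))
  if (length(implicit)) {
    id <- c(id, implicit)
    sire <- c(sire, rep(NA_character_, length(implicit)))
    dam <- c(dam, rep(NA_character_, length(implicit)))
  }
  new("Pedigree", id = id, sire = sire, dam = dam)
}

#' @describeIn Pedigree founder identifiers (both parents unknown)
#' @export
founders <- function(object) {
  stopifnot(is(object, "Pedigree"))
  object@id[is.na(object@sire) & is.na(object@dam)]
}

#' @describeIn Pedigree parent map as a data.frame (id, sire, dam)
#' @export
pedParents <- function(object) {
  stopifnot(is(object, "Pedigree"))
  data.frame(id = object@id, sire = object@sire, dam = object@dam,
             stringsAsFactors = FALSE)
}

#' Build the colony pedigree from breeding records
#'
#' Individuals are linked to parents through the mating cage that produced
#' them: a registry table maps each individual to the cage (or directly the
#' dam and sire) it was born from. Dams and sires named in the records, and
#' any ancestor reachable through the registry, become pedigree nodes;
#' identifiers with no recorded parents become founders.
#'
#' @param records cleaned litter records (see [cleanRecords()]); their
#'   `dam_id`/`sire_id` columns seed the node set.
#' @param registry optional data.frame linking individuals to their own
#'   parents, columns `id`, `sire`, `dam` (unknown as `NA` or `"0"`).
#'   Without it, every dam and sire in `records` is a founder.
#' @return a [Pedigree].
#' @export
buildPedigree <- function(records, registry = NULL) {
  ids <- unique(c(records$dam_id, records$sire_id))
  ids <- ids[!is.na(ids) & ids != ""]
  if (is.null(registry)) {
    return(Pedigree(id = ids))
  }
  stopifnot(all(c("id", "sire", "dam") %in% names(registry)))
  reg <- registry[!duplicated(registry$id), , drop = FALSE]
  # close over ancestors reachable through the registry
  all_ids <- unique(c(ids, reg$id))
  m <- match(all_ids, reg$id)
  sire <- ifelse(is.na(m), NA_character_, as.character(reg$sire[m]))
  dam <- ifelse(is.na(m), NA_character_, as.character(reg$dam[m]))
  Pedigree(id = all_ids, sire = sire, dam = dam)
}

# Longest-path generation depth from founders; parents always shallower
# than children, which anchors the kinship recursion.
.pedDepth <- function(ped) {
  n <- length(ped@id)
  idx <- seq_len(n)
  names(idx) <- ped@id
  pf <- ifelse(is.na(ped@sire), NA_integer_, idx[ped@sire])
  pm <- ifelse(is.na(ped@dam), NA_integer_, idx[ped@dam])
  depth <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  while (any(pending)) {
    progressed <- FALSE
    for (i in which(pending)) {
      df <- if (is.na(pf[i])) -1L else depth[pf[i]]
      dm <- if (is.na(pm[i])) -1L else depth[pm[i]]
      if ((is.na(pf[i]) || !is.na(df)) && (is.na(pm[i]) || !is.na(dm))) {
        depth[i] <- max(df, dm, -1L) + 1L
        pending[i] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("pedigree contains a cycle")
  }
  depth
}

#' Truncate ancestry around a focal pair
#'
#' Extracts the sub-pedigree of all ancestors of either focal individual up
#' to `maxGenerations` meioses away (focal individuals are generation 0,
#' parents generation 1, and so on; an ancestor reachable by several paths
#' counts at its shortest). Ancestors at exactly the boundary depth have
#' their parent links severed and are treated as founders, which mirrors
#' the practice of capping ancestor tracing to keep older, less reliable
#' entries out of the kinship calculation.
#'
#' @param ped a [Pedigree].
#' @param focal character vector of one or more focal identifiers.
#' @param maxGenerations positive integer depth cap (default 5).
#' @return list with `pedigree` (the truncated [Pedigree]), `truncated`
#'   (`TRUE` if any parent link was severed), and `generations_used`
#'   (deepest generation retained).
#' @export
truncateAncestry <- function(ped, focal, maxGenerations = 5L) {
  stopifnot(is(ped, "Pedigree"))
  if (length(maxGenerations) != 1L || is.na(maxGenerations) ||
      maxGenerations < 1L)
    stop("maxGenerations must be a positive integer")
  maxGenerations <- as.integer(maxGenerations)
  miss <- setdiff(focal, ped@id)
  if (length(miss))
    stop("focal individual(s) not in pedigree: ", paste(miss, collapse = ", "))
  idx <- seq_along(ped@id)
  names(idx) <- ped@id
  pf <- ifelse(is.na(ped@sire), NA_integer_, idx[ped@sire])
  pm <- ifelse(is.na(ped@dam), NA_integer_, idx[ped@dam])
  # BFS upward: minimal meiosis count from any focal individual
  dist <- rep(NA_integer_, length(ped@id))
  frontier <- unique(idx[focal])
  dist[frontier] <- 0L
  g <- 0L
  while (length(frontier) && g < maxGenerations) {
    g <- g + 1L
    parents <- c(pf[frontier], pm[frontier])
    parents <- unique(parents[!is.na(parents)])
    frontier <- parents[is.na(dist[parents])]
    dist[frontier] <- g
  }
  keep <- which(!is.na(dist))
  sever <- dist[keep] == maxGenerations
  # a kept parent link must point at a kept node
  sire <- ped@sire[keep]
  dam <- ped@dam[keep]
  kept_ids <- ped@id[keep]
  sire[sever | !(sire %in% kept_ids)] <- NA_character_
  dam[sever | !(dam %in% kept_ids)] <- NA_character_
  had_parent <- !is.na(ped@sire[keep]) | !is.na(ped@dam[keep])
  now_parent <- !is.na(sire) | !is.na(dam)
  truncated <- any(had_parent & !now_parent)
  list(pedigree = new("Pedigree", id = kept_ids, sire = sire, dam = dam),
       truncated = truncated,
       generations_used = max(dist[keep]))
}

#' Kinship coefficient between two pedigree members
#'
#' The classical recursion: for an individual `x` with parents `f` and `m`,
#' `phi(x, x) = (1 + phi(f, m)) / 2`, and for distinct `a`, `b` with `a` not
#' an ancestor of `b`, `phi(a, b) = (phi(father(a), b) + phi(mother(a), b)) / 2`.
#' Unknown parents contribute kinship 0; founders are mutually unrelated and
#' non-inbred. The recursion is anchored on generation depth (an ancestor is
#' always shallower than its descendant) and memoised, so repeated queries on
#' the same pedigree are cheap.
#'
#' @param ped a [Pedigree].
#' @param a,b individual identifiers (may be equal: self-kinship).
#' @param cache optional environment from a previous call on the same
#'   pedigree, to share memoised values across queries.
#' @return the kinship coefficient, a number in `[0, 1]`.
#' @examples
#' ped <- Pedigree(id = c("F1", "F2", "A"), sire = c(NA, NA, "F1"),
#'                 dam = c(NA, NA, "F2"))
#' kinship(ped, "F1", "A")  # parent-offspring: 0.25
#' @export
kinship <- function(ped, a, b, cache = NULL) {
  stopifnot(is(ped, "Pedigree"))
  if (is.null(cache)) cache <- kinshipCache(ped)
  miss <- setdiff(c(a, b), ped@id)
  if (length(miss))
    stop("unknown individual id(s): ", paste(miss, collapse = ", "))
  .phi(cache, cache$idx[[a]], cache$idx[[b]])
}

#' @describeIn kinship prepare a reusable memoisation cache for a pedigree
#' @export
kinshipCache <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  e <- new.env(parent = emptyenv())
  e$idx <- as.list(stats::setNames(seq_along(ped@id), ped@id))
  idx <- seq_along(ped@id)
  names(idx) <- ped@id
  e$pf <- ifelse(is.na(ped@sire), 0L, idx[ped@sire])
  e$pm <- ifelse(is.na(ped@dam), 0L, idx[ped@dam])
  e$depth <- .pedDepth(ped)
  e$memo <- new.env(parent = emptyenv())
  e
}

.phi <- function(cc, i, j) {
  if (i == 0L || j == 0L) return(0)    # unknown parent
  key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
  hit <- cc$memo[[key]]
  if (!is.null(hit)) return(hit)
  if (i == j) {
    val <- 0.5 * (1 + .phi(cc, cc$pf[i], cc$pm[i]))
  } else {
    # recurse on the deeper individual; it cannot be an ancestor of the other
    if (cc$depth[i] < cc$depth[j]) { tmp <- i; i <- j; j <- tmp }
    if (cc$pf[i] == 0L && cc$pm[i] == 0L) {
      val <- 0                          # founder, distinct from j
    } else {
      val <- 0.5 * (.phi(cc, cc$pf[i], j) + .phi(cc, cc$pm[i], j))
    }
  }
  cc$memo[[key]] <- val
  val
}

#' Relatedness of mating pairs
#'
#' For each dam-sire pair: truncate ancestry at `maxGenerations`, run the
#' kinship recursion on the sub-pedigree, and express relatedness as twice
#' the kinship coefficient in percent (0 = no shared ancestry, 100 =
#' genetic identity). Pairs with an unknown or unregistered dam or sire get
#' a missing relatedness rather than zero.
#'
#' @param ped a [Pedigree].
#' @param pairs data.frame with columns `dam_id` and `sire_id` (a
#'   pair-summary table from [summarizePairs()] works as is).
#' @param maxGenerations ancestor-tracing depth cap (default 5); `Inf`
#'   disables truncation.
#' @return `pairs` with columns `phi`, `relatedness_pct`,
#'   `generations_used`, `truncated` appended.
#' @export
pairRelatedness <- function(ped, pairs, maxGenerations = 5L) {
  stopifnot(is(ped, "Pedigree"),
            all(c("dam_id", "sire_id") %in% names(pairs)))
  n <- nrow(pairs)
  phi <- rep(NA_real_, n)
  gens <- rep(NA_integer_, n)
  trunc <- rep(NA, n)
  untruncated <- !is.finite(maxGenerations)
  cache <- if (untruncated) kinshipCache(ped) else NULL
  for (k in seq_len(n)) {
    d <- pairs$dam_id[k]; s <- pairs$sire_id[k]
    if (is.na(d) || is.na(s) || !(d %in% ped@id) || !(s %in% ped@id)) next
    if (untruncated) {
      phi[k] <- .phi(cache, cache$idx[[d]], cache$idx[[s]])
      gens[k] <- NA_integer_
      trunc[k] <- FALSE
    } else {
      tr <- truncateAncestry(ped, c(d, s), maxGenerations)
      phi[k] <- kinship(tr$pedigree, d, s)
      gens[k] <- tr$generations_used
      trunc[k] <- tr$truncated
    }
  }
  pairs$phi <- phi
  pairs$relatedness_pct <- 200 * phi
  pairs$generations_used <- gens
  pairs$truncated <- trunc
  pairs
}

#' Read / write 4-column studbook pedigree files
#'
#' Plain-text interchange: whitespace- or tab-delimited columns
#' `id sire dam sex`, unknown parents coded `"0"`, compatible with common
#' pedigree-file conventions.
#'
#' @param path file path.
#' @return `readStudbook`: a [Pedigree] (sex is kept as an attribute
#'   `"sex"`). `writeStudbook`: the path, invisibly.
#' @export
readStudbook <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("studbook file must have columns id, sire, dam (and optionally sex)")
  ped <- Pedigree(id = df$id, sire = df$sire, dam = df$dam)
  if ("sex" %in% names(df))
    attr(ped, "sex") <- stats::setNames(df$sex, df$id)
  ped
}

#' @rdname readStudbook
#' @param ped a [Pedigree] to write.
#' @param sex optional named character vector of sexes, names matching ids.
#' @export
writeStudbook <- function(ped, path, sex = NULL) {
  stopifnot(is(ped, "Pedigree"))
  df <- data.frame(id = ped@id,
                   sire = ifelse(is.na(ped@sire), "0", ped@sire),
                   dam = ifelse(is.na(ped@dam), "0", ped@dam),
                   sex = if (is.null(sex)) "U" else as.character(sex[ped@id]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
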