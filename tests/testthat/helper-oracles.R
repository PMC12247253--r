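# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code.

# ---- path-counting kinship (Wright's method) ----------------------------
# Enumerates all upward paths and sums (1/2)^(n1+n2+1) * (1 + F_A) over
# common ancestors A reached by node-disjoint paths.

oracle_paths_up <- function(ped, x, memo = new.env(parent = emptyenv())) {
  # list of integer vectors: each path starts at x, ends at an ancestor
  key <- as.character(x)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  idx <- seq_along(ped@id)
  names(idx) <- ped@id
  out <- list(x)
  for (pid in c(ped@sire[x], ped@dam[x])) {
    if (!is.na(pid)) {
      pp <- oracle_paths_up(ped, unname(idx[pid]), memo)
      out <- c(out, lapply(pp, function(p) c(x, p)))
    }
  }
  memo[[key]] <- out
  out
}

oracle_kinship <- function(ped, a, b) {
  idx <- seq_along(ped@id)
  names(idx) <- ped@id
  Fcoef <- oracle_inbreeding_all(ped)
  ia <- unname(idx[a]); ib <- unname(idx[b])
  if (ia == ib) return(0.5 * (1 + Fcoef[ia]))
  .oracle_phi_idx(ped, ia, ib, Fcoef)
}

.oracle_phi_idx <- function(ped, ia, ib, Fcoef, memo = new.env(parent = emptyenv())) {
  pa <- oracle_paths_up(ped, ia, memo)
  pb <- oracle_paths_up(ped, ib, memo)
  tot <- 0
  for (p1 in pa) {
    A <- p1[length(p1)]
    for (p2 in pb) {
      if (p2[length(p2)] != A) next
      # paths must share only the common ancestor
      if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
      tot <- tot + 0.5^((length(p1) - 1) + (length(p2) - 1) + 1) *
        (1 + Fcoef[A])
    }
  }
  tot
}

oracle_inbreeding_all <- function(ped) {
  idx <- seq_along(ped@id)
  names(idx) <- ped@id
  ord <- order(colonykin:::.pedDepth(ped))
  Fcoef <- numeric(length(ped@id))
  memo <- new.env(parent = emptyenv())
  for (i in ord) {
    s <- ped@sire[i]; d <- ped@dam[i]
    if (is.na(s) || is.na(d)) { Fcoef[i] <- 0; next }
    Fcoef[i] <- .oracle_phi_idx(ped, unname(idx[s]), unname(idx[d]),
                                Fcoef, memo)
  }
  Fcoef
}

# ---- gene-dropping Monte Carlo ------------------------------------------
# Drops founder alleles down the pedigree; the IBD probability between two
# individuals is estimated from all four allele comparisons per drop.
# Returns estimate and its Monte-Carlo standard error.

oracle_genedrop <- function(ped, a, b, ndrops = 2e5) {
  n <- length(ped@id)
  idx <- seq_len(n)
  names(idx) <- ped@id
  pf <- ifelse(is.na(ped@sire), 0L, idx[ped@sire])
  pm <- ifelse(is.na(ped@dam), 0L, idx[ped@dam])
  ord <- order(colonykin:::.pedDepth(ped))
  A1 <- matrix(0L, ndrops, n)
  A2 <- matrix(0L, ndrops, n)
  next_allele <- 1L
  for (i in ord) {
    # each gamete independently: inherit from the known parent, or carry a
    # fresh founder allele when that parent is unrecorded
    if (pf[i] == 0L) {
      A1[, i] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::rbinom(ndrops, 1L, 0.5) == 1L
      A1[, i] <- ifelse(pick, A1[, pf[i]], A2[, pf[i]])
    }
    if (pm[i] == 0L) {
      A2[, i] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::rbinom(ndrops, 1L, 0.5) == 1L
      A2[, i] <- ifelse(pick, A1[, pm[i]], A2[, pm[i]])
    }
  }
  ia <- unname(idx[a]); ib <- unname(idx[b])
  per_drop <- ((A1[, ia] == A1[, ib]) + (A1[, ia] == A2[, ib]) +
               (A2[, ia] == A1[, ib]) + (A2[, ia] == A2[, ib])) / 4
  list(phi = mean(per_drop),
       se = stats::sd(per_drop) / sqrt(ndrops))
}

# ---- random pedigree generator ------------------------------------------

random_pedigree <- function(n = 20, n_founders = 6) {
  id <- paste0("I", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, n)) {
    pool <- seq_len(i - 1L)
    pick <- sample(pool, 2L)
    sire[i] <- id[pick[1L]]
    dam[i] <- id[pick[2L]]
    if (stats::runif(1) < 0.1) sire[i] <- NA  # occasional unknown parent
  }
  Pedigree(id = id, sire = sire, dam = dam)
}

# ---- brute-force binomial-logit likelihood maximisation ------------------
# Grid search with iterative refinement; relies only on the likelihood
# being evaluated directly, never on glm.

oracle_glm_grid <- function(x, s, t, iters = 20) {
  loglik <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(s * log(p) + (t - s) * log(1 - p))
  }
  c0 <- 0; w0 <- 8
  c1 <- 0; w1 <- 8 / max(abs(x), 1)
  for (it in seq_len(iters)) {
    g0 <- seq(c0 - w0, c0 + w0, length.out = 25)
    g1 <- seq(c1 - w1, c1 + w1, length.out = 25)
    val <- matrix(NA_real_, 25, 25)
    for (i in seq_along(g0))
      for (j in seq_along(g1))
        val[i, j] <- loglik(g0[i], g1[j])
    best <- arrayInd(which.max(val), dim(val))
    c0 <- g0[best[1L]]; c1 <- g1[best[2L]]
    # gentle shrink keeps the optimum inside the next window even when the
    # current argmax sits on a grid edge
    w0 <- w0 * 0.35
    w1 <- w1 * 0.35
  }
  c(beta0 = c0, beta1 = c1, loglik = loglik(c0, c1))
}

# ---- one-way ANOVA by direct arithmetic ----------------------------------

oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# ---- simulated litter records without the simulator ----------------------
# A tiny hand-rolled litter table for io tests.

toy_records <- function() {
  data.frame(
    mating_id = c("M1", "M1", "M1", "M2", "M2", "M3"),
    dam_id = c("D1", "D1", "D1", "D2", "D2", NA),
    sire_id = c("S1", "S1", "S1", "S2", "S2", "S3"),
    mating_date = as.Date(c("2000-01-01", NA, NA, "2001-02-01", NA, NA)),
    birth_date = as.Date(c("2000-03-01", "2000-03-31", "2000-05-02",
                           "2001-04-01", "2001-06-01", "2002-01-01")),
    born = c(4, 5, 6, 5, 3, 2),
    weaned = c(4, 3, 6, 5, 2, 2),
    males_weaned = c(2, 1, 3, 2, 1, 1),
    females_weaned = c(2, 2, 3, 3, 1, 1),
    stock = "BW",
    stringsAsFactors = FALSE)
}
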