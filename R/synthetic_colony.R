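#' Configure the synthetic closed-colony simulator
#'
#' Builds a [ColonySimConfig] with defaults emulating a closed deer-mouse
#' colony founded from a small wild-caught set: 40 founders, kin-avoiding
#' pair formation (full siblings and closer excluded), zero-truncated
#' Poisson litter sizes around 4 pups, baseline pre-weaning mortality near
#' 15 percent rising with parental relatedness, and delivery intervals of
#' roughly 40 days that shorten as relatedness grows — the compensation
#' mechanism the analysis is designed to detect.
#'
#' @param n_founders,n_years,start_year,pairs_active colony demography.
#' @param pair_relatedness_cap maximum dam-sire relatedness percentage
#'   tolerated when forming a pair (strict; default 50 excludes full sibs).
#' @param litter_rate fraction of scheduled breeding cycles yielding a
#'   recorded litter.
#' @param litter_size_mean Poisson mean before zero-truncation.
#' @param mortality_intercept,mortality_slope logit-scale pup mortality
#'   `plogis(b0 + b1 * r)`, `r` the relatedness proportion in `[0, 1]`.
#' @param interval_base,interval_slope,interval_sd,interval_min delivery
#'   interval model `max(min, base - slope * r + N(0, sd))`, days.
#' @param phase_schedule optional data.frame of per-era overrides
#'   (`start_year`, `end_year`, `mortality_slope`, `interval_slope`).
#' @param breeder_lifespan_years range a pair's tenure is drawn from.
#' @param recruit_prob probability a weaned pup enters the breeder
#'   candidate pool.
#' @return a validated [ColonySimConfig].
#' @export
colonySimConfig <- function(n_founders = 40L, n_years = 62L,
                            start_year = 1963L, pairs_active = 40L,
                            pair_relatedness_cap = 50,
                            litter_rate = 1,
                            litter_size_mean = 4,
                            mortality_intercept = qlogis(0.15),
                            mortality_slope = 1.4,
                            interval_base = 40, interval_slope = 12,
                            interval_sd = 8, interval_min = 21,
                            phase_schedule = NULL,
                            breeder_lifespan_years = c(1.5, 2),
                            recruit_prob = 0.5) {
  if (is.null(phase_schedule))
    phase_schedule <- data.frame(start_year = integer(), end_year = integer(),
                                 mortality_slope = numeric(),
                                 interval_slope = numeric())
  new("ColonySimConfig",
      n_founders = as.integer(n_founders), n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      pairs_active = as.integer(pairs_active),
      pair_relatedness_cap = pair_relatedness_cap,
      litter_rate = litter_rate, litter_size_mean = litter_size_mean,
      mortality_intercept = mortality_intercept,
      mortality_slope = mortality_slope,
      interval_base = interval_base, interval_slope = interval_slope,
      interval_sd = interval_sd, interval_min = interval_min,
      phase_schedule = phase_schedule,
      breeder_lifespan_years = breeder_lifespan_years,
      recruit_prob = recruit_prob)
}

# zero-truncated Poisson draw (a recorded litter implies >= 1 pup)
.rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  pmax(1L, stats::qpois(u, lambda))
}

#' Simulate a closed breeding colony
#'
#' Discrete-event simulation in days. Founders (assumed unrelated) seed a
#' fixed number of breeding cages; each pair delivers litters at intervals
#' drawn from the relatedness-dependent interval model, pups die before
#' weaning independently with relatedness-dependent probability, survivor
#' sexes are binomial at one half, and retired pairs (tenure drawn from
#' `breeder_lifespan_years`) are replaced by weaned offspring chosen under
#' the kin-avoidance cap. Kinship among potential breeders is tracked
#' exactly by the recursion the pedigree module implements, so the emitted
#' truth can be cross-checked against it. Relatedness drifts upward over
#' time because the colony is closed.
#'
#' @param config a [ColonySimConfig].
#' @param seed integer seed; same seed, same output.
#' @return a [ColonySim]. If the colony runs out of eligible breeders the
#'   simulation stops early and reports the extinction year instead of
#'   failing.
#' @examples
#' sim <- simulateColony(colonySimConfig(n_years = 10L, pairs_active = 8L),
#'                       seed = 1)
#' sim
#' @export
simulateColony <- function(config, seed = NULL) {
  stopifnot(is(config, "ColonySimConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  horizon <- cf@n_years * 365L
  origin <- as.Date(paste0(cf@start_year, "-01-01"))
  adult_age <- 60L          # days before an animal may be paired
  expire_age <- 540L        # candidates leave the pool past this age
  pool_cap <- max(10L, 3L * cf@pairs_active)  # per sex

  ps <- cf@phase_schedule
  eraPar <- function(year) {
    if (nrow(ps)) {
      i <- which(ps$start_year <= year & year <= ps$end_year)
      if (length(i))
        return(c(b1 = ps$mortality_slope[i[1L]],
                 g = ps$interval_slope[i[1L]]))
    }
    c(b1 = cf@mortality_slope, g = cf@interval_slope)
  }

  # ---- individual registry (grows) ----
  cap_ind <- 1024L
  ind_sex <- integer(cap_ind)        # 1 male, 2 female
  ind_birth <- integer(cap_ind)
  ind_sire <- integer(cap_ind)       # 0 = founder
  ind_dam <- integer(cap_ind)
  n_ind <- 0L
  growInd <- function() {
    cap_ind <<- cap_ind * 2L
    length(ind_sex) <<- cap_ind; length(ind_birth) <<- cap_ind
    length(ind_sire) <<- cap_ind; length(ind_dam) <<- cap_ind
  }

  # ---- active kinship matrix with slot recycling ----
  # Pairwise kinship is maintained only over individuals that can still
  # breed; a new pup's row is derived from its parents' rows, so rows of
  # retired or expired animals can be reused.
  cap_slot <- cf@n_founders + 4L * pool_cap + 4L * cf@pairs_active + 16L
  K <- matrix(0, cap_slot, cap_slot)
  slot_of <- integer(0)              # indexed by individual id
  free_slots <- rev(seq_len(cap_slot))
  active_slots <- integer(0)
  takeSlot <- function() {
    if (!length(free_slots)) {       # grow the matrix
      old <- cap_slot
      cap_slot <<- cap_slot * 2L
      K2 <- matrix(0, cap_slot, cap_slot)
      K2[seq_len(old), seq_len(old)] <- K
      K <<- K2
      free_slots <<- rev(seq.int(old + 1L, cap_slot))
    }
    s <- free_slots[length(free_slots)]
    free_slots <<- free_slots[-length(free_slots)]
    s
  }
  dropInd <- function(id) {          # individual can never breed again
    s <- slot_of[id]
    if (!is.na(s) && s > 0L) {
      active_slots <<- active_slots[active_slots != s]
      free_slots <<- c(free_slots, s)
      slot_of[id] <<- -1L
    }
  }

  registerInd <- function(sex, birth_day, sire, dam) {
    n_ind <<- n_ind + 1L
    if (n_ind > cap_ind) growInd()
    id <- n_ind
    ind_sex[id] <<- sex; ind_birth[id] <<- birth_day
    ind_sire[id] <<- sire; ind_dam[id] <<- dam
    s <- takeSlot()
    slot_of[id] <<- s
    if (sire > 0L) {
      sf <- slot_of[sire]; sm <- slot_of[dam]
      if (length(active_slots)) {
        v <- 0.5 * (K[sf, active_slots] + K[sm, active_slots])
        K[s, active_slots] <<- v
        K[active_slots, s] <<- v
      }
      K[s, s] <<- 0.5 * (1 + K[sf, sm])
    } else {
      K[s, active_slots] <<- 0
      K[active_slots, s] <<- 0
      K[s, s] <<- 0.5
    }
    active_slots <<- c(active_slots, s)
    id
  }

  # founders: adults at day 0, balanced sexes
  slot_of <- rep(NA_integer_, 64L)
  for (i in seq_len(cf@n_founders))
    registerInd(sex = 1L + (i %% 2L), birth_day = -adult_age - 300L,
                sire = 0L, dam = 0L)

  # ---- candidate pool ----
  pool <- list(m = seq_len(cf@n_founders)[ind_sex[seq_len(cf@n_founders)] == 1L],
               f = seq_len(cf@n_founders)[ind_sex[seq_len(cf@n_founders)] == 2L])
  prunePool <- function(day) {
    for (sx in c("m", "f")) {
      ids <- pool[[sx]]
      expired <- ids[day - ind_birth[ids] > expire_age]
      for (id in expired) dropInd(id)
      pool[[sx]] <<- setdiff(ids, expired)
    }
  }

  # ---- active pairs ----
  pr_dam <- integer(0); pr_sire <- integer(0); pr_r <- numeric(0)
  pr_id <- integer(0); pr_formed <- integer(0)
  pr_retire <- numeric(0); pr_next <- numeric(0)
  n_pairs_total <- 0L
  pair_meta <- list()               # truth sidecar rows

  drawInterval <- function(r, g) {
    max(cf@interval_min,
        cf@interval_base - g * r + stats::rnorm(1L, 0, cf@interval_sd))
  }

  formPair <- function(day) {
    prunePool(day)
    fem <- pool$f[day - ind_birth[pool$f] >= adult_age]
    mal <- pool$m[day - ind_birth[pool$m] >= adult_age]
    if (!length(fem) || !length(mal)) return(FALSE)
    if (length(fem) > 1L) fem <- sample(fem)
    for (dmm in fem) {
      okm <- mal[200 * K[slot_of[dmm], slot_of[mal]] < cf@pair_relatedness_cap]
      if (!length(okm)) next
      # managers avoid close kin: among a small random tournament of
      # acceptable males, take the one least related to the female
      cand <- if (length(okm) > 5L) sample(okm, 5L) else okm
      sr <- cand[which.min(K[slot_of[dmm], slot_of[cand]])]
      r <- 2 * K[slot_of[dmm], slot_of[sr]]
      pool$f <<- setdiff(pool$f, dmm)
      pool$m <<- setdiff(pool$m, sr)
      n_pairs_total <<- n_pairs_total + 1L
      tenure <- round(stats::runif(1L, cf@breeder_lifespan_years[1L],
                                   cf@breeder_lifespan_years[2L]) * 365)
      year <- cf@start_year + day %/% 365L
      g <- eraPar(year)[["g"]]
      pr_id <<- c(pr_id, n_pairs_total)
      pr_dam <<- c(pr_dam, dmm); pr_sire <<- c(pr_sire, sr)
      pr_r <<- c(pr_r, r); pr_formed <<- c(pr_formed, day)
      pr_retire <<- c(pr_retire, day + tenure)
      pr_next <<- c(pr_next, day + drawInterval(r, g))
      pair_meta[[n_pairs_total]] <<- list(id = n_pairs_total, dam = dmm,
                                          sire = sr, formed = day, r = r)
      return(TRUE)
    }
    FALSE
  }

  removePair <- function(i) {
    dropInd(pr_dam[i]); dropInd(pr_sire[i])
    pr_id <<- pr_id[-i]; pr_dam <<- pr_dam[-i]; pr_sire <<- pr_sire[-i]
    pr_r <<- pr_r[-i]; pr_formed <<- pr_formed[-i]
    pr_retire <<- pr_retire[-i]; pr_next <<- pr_next[-i]
  }

  # ---- litter store (grows) ----
  cap_lit <- 2048L
  L_pair <- integer(cap_lit); L_day <- integer(cap_lit)
  L_born <- integer(cap_lit); L_wean <- integer(cap_lit)
  L_male <- integer(cap_lit); L_prob <- numeric(cap_lit)
  n_lit <- 0L
  pushLitter <- function(pair, day, born, wean, male, prob) {
    n_lit <<- n_lit + 1L
    if (n_lit > cap_lit) {
      cap_lit <<- cap_lit * 2L
      length(L_pair) <<- cap_lit; length(L_day) <<- cap_lit
      length(L_born) <<- cap_lit; length(L_wean) <<- cap_lit
      length(L_male) <<- cap_lit; length(L_prob) <<- cap_lit
    }
    L_pair[n_lit] <<- pair; L_day[n_lit] <<- day
    L_born[n_lit] <<- born; L_wean[n_lit] <<- wean
    L_male[n_lit] <<- male; L_prob[n_lit] <<- prob
  }

  # initial pairing
  deficit <- cf@pairs_active
  while (deficit > 0L && formPair(0L)) deficit <- deficit - 1L

  extinct <- FALSE
  extinction_year <- NA_integer_

  while (length(pr_id)) {
    ev <- pmin(pr_next, pr_retire)
    i <- which.min(ev)
    day <- ev[i]
    if (day > horizon) break
    day <- as.integer(round(day))
    if (pr_retire[i] <= pr_next[i]) {
      removePair(i)
      deficit <- deficit + 1L
    } else {
      r <- pr_r[i]
      year <- cf@start_year + day %/% 365L
      par <- eraPar(year)
      if (stats::runif(1L) <= cf@litter_rate) {
        born <- .rztpois(1L, cf@litter_size_mean)
        p <- stats::plogis(cf@mortality_intercept + par[["b1"]] * r)
        dead <- stats::rbinom(1L, born, p)
        wean <- born - dead
        male <- if (wean > 0L) stats::rbinom(1L, wean, 0.5) else 0L
        pushLitter(pr_id[i], day, born, wean, male, p)
        # recruitment of weaned pups into the candidate pool
        if (wean > 0L) {
          k <- stats::rbinom(1L, wean, cf@recruit_prob)
          if (k > 0L) {
            sexes <- c(rep(1L, male), rep(2L, wean - male))
            sexes <- if (length(sexes) == 1L) sexes else sample(sexes)
            for (sx in sexes[seq_len(k)]) {
              room <- if (sx == 1L) length(pool$m) < pool_cap else
                length(pool$f) < pool_cap
              if (!room) next
              id <- registerInd(sx, day, pr_sire[i], pr_dam[i])
              if (sx == 1L) pool$m <- c(pool$m, id) else
                pool$f <- c(pool$f, id)
            }
          }
        }
      }
      pr_next[i] <- day + drawInterval(r, par[["g"]])
    }
    # refill empty cages
    while (deficit > 0L) {
      if (formPair(day)) deficit <- deficit - 1L else break
    }
    if (!length(pr_id)) {
      extinct <- TRUE
      extinction_year <- as.integer(cf@start_year + day %/% 365L)
      break
    }
  }

  # ---- assemble outputs ----
  indName <- function(id) ifelse(id == 0L, NA_character_,
                                 ifelse(id <= cf@n_founders,
                                        paste0("F", id), paste0("A", id)))
  used <- seq_len(n_ind)
  ped <- Pedigree(id = indName(used),
                  sire = indName(ind_sire[used]),
                  dam = indName(ind_dam[used]))
  attr(ped, "sex") <- stats::setNames(c("M", "F")[ind_sex[used]],
                                      indName(used))

  pm <- pair_meta[seq_len(n_pairs_total)]
  pairs <- data.frame(
    mating_id = paste0("P", vapply(pm, `[[`, integer(1), "id")),
    dam_id = indName(vapply(pm, `[[`, integer(1), "dam")),
    sire_id = indName(vapply(pm, `[[`, integer(1), "sire")),
    formed_date = origin + vapply(pm, `[[`, integer(1), "formed"),
    relatedness_pct = 100 * vapply(pm, `[[`, numeric(1), "r"),
    stringsAsFactors = FALSE)

  li <- seq_len(n_lit)
  pidx <- match(paste0("P", L_pair[li]), pairs$mating_id)
  records <- data.frame(
    mating_id = pairs$mating_id[pidx],
    dam_id = pairs$dam_id[pidx],
    sire_id = pairs$sire_id[pidx],
    mating_date = pairs$formed_date[pidx],
    birth_date = origin + L_day[li],
    born = L_born[li],
    weaned = L_wean[li],
    males_weaned = L_male[li],
    females_weaned = L_wean[li] - L_male[li],
    stock = "SIM",
    stringsAsFactors = FALSE)
  records$dead <- records$born - records$weaned
  records$year <- as.integer(format(records$birth_date, "%Y"))

  new("ColonySim", records = records, pedigree = ped, pairs = pairs,
      litter_probs = L_prob[li], config = cf,
      extinct = extinct, extinction_year = extinction_year)
}

#' @describeIn simulateColony accessors for the simulated colony
#' @param sim a [ColonySim]
#' @export
simRecords <- function(sim) { stopifnot(is(sim, "ColonySim")); sim@records }

#' @rdname simulateColony
#' @export
simPairs <- function(sim) { stopifnot(is(sim, "ColonySim")); sim@pairs }

#' @rdname simulateColony
#' @export
simPedigree <- function(sim) { stopifnot(is(sim, "ColonySim")); sim@pedigree }

#' Simulate a colony with three breeding eras
#'
#' Convenience wrapper reproducing the canonical phase structure of a
#' long-lived closed colony: no relatedness effect in the first era, both
#' the mortality and the interval-shortening effect switched on in the
#' middle era, and both switched off again in the final era. The era
#' parameters in the middle era are taken from `config`
#' (`mortality_slope`, `interval_slope`).
#'
#' @param config a [ColonySimConfig].
#' @param boundaries two years: era 2 spans `[boundaries[1], boundaries[2] - 1]`.
#'   Equal boundaries give a zero-length middle era (a null colony).
#' @param seed integer seed.
#' @return a [ColonySim]; its `config` slot echoes the era schedule.
#' @export
makeThreePhaseColony <- function(config = colonySimConfig(),
                                 boundaries = c(1985, 2015), seed = NULL) {
  stopifnot(is(config, "ColonySimConfig"), length(boundaries) == 2L)
  b <- as.integer(boundaries)
  y0 <- config@start_year
  y1 <- config@start_year + config@n_years - 1L
  if (b[1L] < y0 || b[2L] > y1 + 1L || b[1L] > b[2L])
    stop("phase boundaries must lie within the simulated span, in order")
  sched <- data.frame(
    start_year = c(y0, b[1L], b[2L]),
    end_year = c(b[1L] - 1L, b[2L] - 1L, y1),
    mortality_slope = c(0, config@mortality_slope, 0),
    interval_slope = c(0, config@interval_slope, 0))
  sched <- sched[sched$start_year <= sched$end_year, , drop = FALSE]
  config@phase_schedule <- sched
  validObject(config)
  simulateColony(config, seed = seed)
}
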