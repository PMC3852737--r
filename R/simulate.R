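#' Configuration for the synthetic community generator
#'
#' Defaults emulate a short high-arctic flowering season: a 70-day
#' season starting on day 165, 34 plants (26 core, 8 tail) and 78
#' flower visitors (27 core, 51 tail), core phenophases around 31 days
#' and tail phenophases around 6 days, a late-season burst of tail
#' visitors, and a core-core link density targeting roughly 11 percent
#' static connectance. See the methods vignette for the reasoning
#' behind each default.
#'
#' @param season_start first day of year of the season.
#' @param season_length season length in days.
#' @param n_core_plants,n_tail_plants,n_core_pollinators,n_tail_pollinators
#'   species counts per guild and role.
#' @param core_phen_mean,core_phen_sd mean/sd (days) of core phenophase
#'   lengths (truncated normal, floored at 1 day, capped at the season).
#' @param tail_phen_mean,tail_phen_sd same for tail species.
#' @param tail_burst placement of tail phenophase starts: `"late"`
#'   (burst-weighted toward the season end), `"early"`, or `"none"`
#'   (uniform).
#' @param burst_weight probability that a tail start is drawn from the
#'   burst third of the season rather than uniformly.
#' @param core_core_link_prob probability that an overlapping core
#'   plant/core visitor pair is linked.
#' @param tail_partner_count number of core partners per tail species
#'   (1 or 2, keeping intended tail `L <= 2`).
#' @param visits_per_overlap_day expected visits per pair per overlap
#'   day (Poisson rate for the observation thinning).
#' @param guarantee_pair ensure at least one record per intended link,
#'   so observed and intended networks coincide; turn off to study
#'   detection-induced phenophase shrinkage.
#' @param seed optional integer seed applied by the generator.
#' @return a validated list of class `phenonet_config`.
#' @export
phenonet_config <- function(season_start = 165L, season_length = 70L,
                            n_core_plants = 26L, n_tail_plants = 8L,
                            n_core_pollinators = 27L,
                            n_tail_pollinators = 51L,
                            core_phen_mean = 31, core_phen_sd = 8,
                            tail_phen_mean = 6, tail_phen_sd = 2,
                            tail_burst = c("late", "early", "none"),
                            burst_weight = 0.7,
                            core_core_link_prob = 0.30,
                            tail_partner_count = 2L,
                            visits_per_overlap_day = 0.5,
                            guarantee_pair = TRUE,
                            seed = NULL) {
  tail_burst <- match.arg(tail_burst)
  cfg <- list(season_start = as.integer(season_start),
              season_length = as.integer(season_length),
              n_core_plants = as.integer(n_core_plants),
              n_tail_plants = as.integer(n_tail_plants),
              n_core_pollinators = as.integer(n_core_pollinators),
              n_tail_pollinators = as.integer(n_tail_pollinators),
              core_phen_mean = core_phen_mean,
              core_phen_sd = core_phen_sd,
              tail_phen_mean = tail_phen_mean,
              tail_phen_sd = tail_phen_sd,
              tail_burst = tail_burst, burst_weight = burst_weight,
              core_core_link_prob = core_core_link_prob,
              tail_partner_count = as.integer(tail_partner_count),
              visits_per_overlap_day = visits_per_overlap_day,
              guarantee_pair = isTRUE(guarantee_pair),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$season_length >= 1L,
            cfg$core_phen_mean >= 1, cfg$tail_phen_mean >= 1,
            cfg$n_core_plants >= 1L, cfg$n_core_pollinators >= 1L,
            cfg$n_tail_plants >= 0L, cfg$n_tail_pollinators >= 0L,
            cfg$burst_weight >= 0, cfg$burst_weight <= 1,
            cfg$core_core_link_prob >= 0, cfg$core_core_link_prob <= 1,
            cfg$tail_partner_count %in% 1:2,
            cfg$visits_per_overlap_day >= 0)
  class(cfg) <- "phenonet_config"
  cfg
}

trunc_norm_lengths <- function(n, mean, sd, max_len) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), 1), max_len)
}

#' Generate a synthetic plant-visitor community
#'
#' Emulates the generative structure the temporal analysis assumes:
#' core species enter early-to-mid season with long phenophases and
#' form a densely linked backbone; tail species have short phenophases,
#' placed uniformly or burst-weighted toward one end of the season, and
#' attach to 1-2 overlapping core partners of the other guild (intended
#' tail `L <= 2`). Tail visitors carry trophic-role labels (visitor,
#' parasitoid, hyper-parasitoid) for downstream reporting.
#'
#' @param cfg a [phenonet_config()].
#' @return list of class `phenonet_truth`: `species` (id, guild, group,
#'   trophic_role, role core/tail), `phenophases`, `pairs` (the
#'   intended link set).
#' @export
generate_community <- function(cfg = phenonet_config()) {
  stopifnot(inherits(cfg, "phenonet_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  s0 <- cfg$season_start
  sl <- cfg$season_length
  s1 <- s0 + sl - 1L
  place_core <- function(len) {
    # staggered early-biased starts so core cover the whole season
    off <- round((sl - len) * stats::rbeta(length(len), 1, 2))
    pmin(s0 + off, s1 - len + 1L)
  }
  core_phen <- function(ids) {
    len <- trunc_norm_lengths(length(ids), cfg$core_phen_mean,
                              cfg$core_phen_sd, sl)
    st <- place_core(len)
    data.frame(species = ids, start = as.integer(st),
               end = as.integer(st + len - 1L), stringsAsFactors = FALSE)
  }
  draw_tail_start <- function(len) {
    hi <- s1 - len + 1L
    if (cfg$tail_burst != "none" &&
        stats::runif(1) < cfg$burst_weight) {
      third <- floor(sl / 3)
      lo <- if (cfg$tail_burst == "late")
        max(s0, s1 - third + 1L) else s0
      hi <- if (cfg$tail_burst == "early")
        min(hi, s0 + third - 1L) else hi
      lo <- min(lo, hi)
    } else lo <- s0
    sample(lo:hi, 1L)
  }
  cp_ids <- sprintf("P%02d", seq_len(cfg$n_core_plants))
  tp_ids <- if (cfg$n_tail_plants)
    sprintf("P%02d", cfg$n_core_plants + seq_len(cfg$n_tail_plants))
    else character(0)
  ca_ids <- sprintf("A%02d", seq_len(cfg$n_core_pollinators))
  ta_ids <- if (cfg$n_tail_pollinators)
    sprintf("A%02d", cfg$n_core_pollinators +
              seq_len(cfg$n_tail_pollinators)) else character(0)
  phen_cp <- core_phen(cp_ids)
  phen_ca <- core_phen(ca_ids)
  # core-core links among overlapping pairs
  cc <- expand.grid(plant = cp_ids, pollinator = ca_ids,
                    stringsAsFactors = FALSE)
  ps <- phen_cp$start[match(cc$plant, phen_cp$species)]
  pe <- phen_cp$end[match(cc$plant, phen_cp$species)]
  as_ <- phen_ca$start[match(cc$pollinator, phen_ca$species)]
  ae <- phen_ca$end[match(cc$pollinator, phen_ca$species)]
  ovl <- pmax(ps, as_) <= pmin(pe, ae)
  keep <- ovl & stats::runif(nrow(cc)) < cfg$core_core_link_prob
  pairs <- cc[keep, ]
  # tail species: short phenophase overlapping >= 1 core partner of the
  # other guild; start redrawn on failure, bounded retries
  place_tail <- function(id, partner_phen) {
    len <- trunc_norm_lengths(1L, cfg$tail_phen_mean,
                              cfg$tail_phen_sd, sl)
    for (try in seq_len(50L)) {
      st <- draw_tail_start(len)
      en <- st + len - 1L
      cand <- partner_phen$species[partner_phen$start <= en &
                                     partner_phen$end >= st]
      if (length(cand)) {
        chosen <- sample(cand, min(cfg$tail_partner_count, length(cand)))
        return(list(phen = data.frame(species = id, start = st, end = en,
                                      stringsAsFactors = FALSE),
                    partners = chosen))
      }
    }
    stop("could not place tail species ", id,
         " to overlap any core partner")
  }
  phen_tp <- pairs_tp <- NULL
  for (id in tp_ids) {
    pl <- place_tail(id, phen_ca)
    phen_tp <- rbind(phen_tp, pl$phen)
    pairs_tp <- rbind(pairs_tp, data.frame(plant = id,
                                           pollinator = pl$partners))
  }
  phen_ta <- pairs_ta <- NULL
  for (id in ta_ids) {
    pl <- place_tail(id, phen_cp)
    phen_ta <- rbind(phen_ta, pl$phen)
    pairs_ta <- rbind(pairs_ta, data.frame(plant = pl$partners,
                                           pollinator = id))
  }
  phen <- do.call(rbind, Filter(Negate(is.null), list(
    cbind(phen_cp, guild = "plant"),
    if (!is.null(phen_tp)) cbind(phen_tp, guild = "plant"),
    cbind(phen_ca, guild = "pollinator"),
    if (!is.null(phen_ta)) cbind(phen_ta, guild = "pollinator"))))
  phen$length <- phen$end - phen$start + 1L
  phen <- phen[, c("species", "guild", "start", "end", "length")]
  rownames(phen) <- NULL
  pairs <- rbind(pairs, pairs_tp, pairs_ta)
  rownames(pairs) <- NULL
  roles <- c("visitor", "parasitoid", "hyper_parasitoid")
  species <- data.frame(
    id = c(cp_ids, tp_ids, ca_ids, ta_ids),
    guild = c(rep("plant", length(cp_ids) + length(tp_ids)),
              rep("pollinator", length(ca_ids) + length(ta_ids))),
    role = c(rep("core", length(cp_ids)), rep("tail", length(tp_ids)),
             rep("core", length(ca_ids)), rep("tail", length(ta_ids))),
    group = NA_character_,
    trophic_role = c(rep(NA_character_,
                         length(cp_ids) + length(tp_ids)),
                     rep("visitor", length(ca_ids)),
                     if (length(ta_ids))
                       sample(roles, length(ta_ids), replace = TRUE,
                              prob = c(0.70, 0.25, 0.05))
                     else character(0)),
    stringsAsFactors = FALSE)
  structure(list(species = species, phenophases = phen, pairs = pairs,
                 config = cfg),
            class = "phenonet_truth")
}

#' Generate observation records from a synthetic community
#'
#' For every intended link and every day of the pair's phenophase
#' overlap, the number of recorded visits is Poisson with rate
#' `visits_per_overlap_day`; days with zero visits yield no record.
#' With `guarantee_pair` (default) every pair gets at least one record,
#' on a uniformly chosen overlap day, so the observed network equals
#' the intended one.
#'
#' @param truth a `phenonet_truth` from [generate_community()].
#' @param cfg the same [phenonet_config()] (defaults to the one stored
#'   in `truth`).
#' @return observation `data.frame` (`day`, `plant`, `pollinator`,
#'   `count`), sorted by day then species.
#' @export
generate_observations <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "phenonet_truth"))
  phen <- truth$phenophases
  rows <- vector("list", nrow(truth$pairs))
  for (i in seq_len(nrow(truth$pairs))) {
    p <- truth$pairs$plant[i]; a <- truth$pairs$pollinator[i]
    pi <- match(p, phen$species); ai <- match(a, phen$species)
    d0 <- max(phen$start[pi], phen$start[ai])
    d1 <- min(phen$end[pi], phen$end[ai])
    if (d0 > d1)
      stop("intended pair without phenophase overlap: ", p, " / ", a)
    days <- d0:d1
    n <- stats::rpois(length(days), cfg$visits_per_overlap_day)
    keep <- n > 0L
    if (!any(keep) && cfg$guarantee_pair) {
      pickd <- days[sample.int(length(days), 1L)]
      keep[match(pickd, days)] <- TRUE
      n[match(pickd, days)] <- 1L
    }
    if (any(keep))
      rows[[i]] <- data.frame(day = days[keep], plant = p,
                              pollinator = a, count = n[keep],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no observations generated")
  out <- out[order(out$day, out$plant, out$pollinator), ]
  rownames(out) <- NULL
  out
}

#' One-call synthetic dataset
#'
#' Runs [generate_community()] then [generate_observations()] under the
#' config's seed.
#'
#' @param cfg a [phenonet_config()].
#' @return list with `records`, `species`, `truth`.
#' @examples
#' sim <- simulate_phenonet(phenonet_config(seed = 42))
#' head(sim$records)
#' @export
simulate_phenonet <- function(cfg = phenonet_config()) {
  truth <- generate_community(cfg)
  records <- generate_observations(truth, cfg)
  list(records = records, species = truth$species, truth = truth)
}
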