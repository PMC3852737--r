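#' Mid-domain test of tail-visitor phenophase segregation
#'
#' For one core plant, the "domain" is the span from the earliest
#' phenophase start to the latest phenophase end among its tail
#' (`L <= 2`) flower visitors. Under the one-dimensional mid-domain
#' ("pencil box") null, each visitor's phenophase keeps its observed
#' length but is placed uniformly at random within the domain; randomly
#' placed ranges in a bounded domain overlap most near its middle, so
#' the null expects a mid-domain richness peak. The test asks whether
#' the observed daily richness curve deviates from that geometric
#' expectation more than random placements do.
#'
#' `middomain_test()` is generic: call it on a [temporal_network()] with
#' a core plant id, or directly on a `data.frame` of ranges.
#'
#' The dispersion statistic `D` of a curve is its mean daily absolute
#' deviation from the across-run mean curve. `empirical_rank` is
#' `1 + ` the number of simulated `D` values strictly below the
#' empirical `D` (ties rank low), and
#' `percentile = rank / (n_runs + 1)`; a percentile near 1 means the
#' observed curve deviates from the mid-domain null more than almost
#' all random placements (non-random segregation), while a percentile
#' near 0 means it hugs the null mean unusually tightly — both tails
#' are worth flagging.
#'
#' @param x a `temporal_network`, or a `data.frame` of ranges with
#'   columns `start`, `end` (and optionally `species`).
#' @param ... passed on to methods.
#' @return an object of class `middomain_test`: `empirical_D`,
#'   `empirical_rank`, `percentile`, `mean_D`, `min_D`, `max_D`,
#'   `n_runs`, `n_ties`, `domain`, `mean_curve`, `observed_curve`,
#'   `ranges`.
#' @examples
#' rngs <- data.frame(start = c(1, 8), end = c(3, 10))
#' middomain_test(rngs, domain = c(1, 10), n_runs = 200, seed = 1)
#' @export
middomain_test <- function(x, ...) UseMethod("middomain_test")

#' @rdname middomain_test
#' @param core_plant id of the focal core plant.
#' @param n_runs number of Monte Carlo placements (>= 100; 5000 mirrors
#'   standard practice).
#' @param seed optional integer seed.
#' @export
middomain_test.temporal_network <- function(x, core_plant,
                                            n_runs = 5000, seed = NULL,
                                            ...) {
  td <- tail_domain(x, core_plant)
  out <- middomain_test(td$ranges, domain = td$domain, n_runs = n_runs,
                        seed = seed)
  out$core_plant <- core_plant
  out
}

#' @rdname middomain_test
#' @param domain integer `c(start, end)` of the domain (days).
#' @export
middomain_test.data.frame <- function(x, domain, n_runs = 5000,
                                      seed = NULL, ...) {
  if (n_runs < 100) stop("n_runs must be >= 100")
  domain <- as.integer(domain[1:2])
  obs <- richness_curve(x, domain)
  lens <- as.integer(x$end - x$start + 1L)
  if (!is.null(seed)) set.seed(seed)
  ndays <- domain[2L] - domain[1L] + 1L
  days <- seq_len(ndays)
  curves <- matrix(0L, n_runs, ndays)
  for (len in lens) {
    if (len > ndays) stop("range length exceeds domain length")
    starts <- sample.int(ndays - len + 1L, n_runs, replace = TRUE)
    curves <- curves + (outer(starts, days, "<=") &
                        outer(starts + len - 1L, days, ">="))
  }
  mean_curve <- colMeans(curves)
  D_runs <- rowMeans(abs(sweep(curves, 2L, mean_curve)))
  empirical_D <- mean(abs(obs - mean_curve))
  rank <- 1L + sum(D_runs < empirical_D)
  structure(list(empirical_D = empirical_D, empirical_rank = rank,
                 percentile = rank / (n_runs + 1),
                 mean_D = mean(D_runs), min_D = min(D_runs),
                 max_D = max(D_runs), n_runs = n_runs,
                 n_ties = sum(D_runs == empirical_D),
                 domain = c(start = domain[1L], end = domain[2L]),
                 mean_curve = mean_curve, observed_curve = obs,
                 ranges = x),
            class = "middomain_test")
}

#' @export
print.middomain_test <- function(x, ...) {
  cat("Mid-domain randomisation test")
  if (!is.null(x$core_plant)) cat(" for core plant", x$core_plant)
  cat("\n  domain: days ", x$domain[["start"]], "-", x$domain[["end"]],
      ", ", nrow(x$ranges), " tail ranges, ", x$n_runs, " runs\n",
      sep = "")
  cat(sprintf(
    "  empirical D = %.3f  rank = %d  percentile = %.4f\n",
    x$empirical_D, x$empirical_rank, x$percentile))
  cat(sprintf("  simulated D: mean %.3f  min %.3f  max %.3f\n",
              x$mean_D, x$min_D, x$max_D))
  if (x$n_ties > 0L)
    cat("  (", x$n_ties, " simulated D value(s) tied with empirical;",
        " ties ranked low)\n", sep = "")
  invisible(x)
}

#' Domain and tail ranges of a core plant
#'
#' The phenophases of the plant's tail (`L <= 2`) flower visitors and
#' the domain spanning them.
#'
#' @param x a `temporal_network`.
#' @param core_plant plant id; must have at least one tail partner.
#' @return list with `domain` (named start/end) and `ranges`
#'   (`data.frame`: `species`, `start`, `end`, `length`).
#' @export
tail_domain <- function(x, core_plant) {
  stopifnot(inherits(x, "temporal_network"))
  if (!core_plant %in% x$static$plants)
    stop("unknown plant: ", core_plant)
  partners <- x$pairs$pollinator[x$pairs$plant == core_plant]
  ct <- x$core_tail
  tails <- partners[ct$status[match(partners, ct$species)] == "tail"]
  if (!length(tails))
    stop("plant ", core_plant, " has no tail (L<=2) visitors")
  phen <- x$phenophases
  idx <- match(tails, phen$species)
  ranges <- data.frame(species = tails, start = phen$start[idx],
                       end = phen$end[idx], length = phen$length[idx],
                       stringsAsFactors = FALSE)
  list(domain = c(start = min(ranges$start), end = max(ranges$end)),
       ranges = ranges)
}

#' Daily richness curve of a set of ranges
#'
#' Number of ranges covering each day of the domain. The sum over days
#' equals the sum of range lengths (species-days are conserved).
#'
#' @param ranges `data.frame` with `start`, `end` (closed day
#'   intervals), all within the domain.
#' @param domain integer `c(start, end)`.
#' @return integer vector of per-day counts, named by day.
#' @export
richness_curve <- function(ranges, domain) {
  domain <- as.integer(domain[1:2])
  if (any(ranges$start < domain[1L] | ranges$end > domain[2L]))
    stop("range outside domain")
  days <- domain[1L]:domain[2L]
  out <- vapply(days, function(d)
    sum(ranges$start <= d & ranges$end >= d), 0L)
  names(out) <- days
  out
}

#' Random placement of ranges within a domain
#'
#' Each range keeps its length; its start day is drawn uniformly from
#' the feasible integer positions so the whole range stays inside the
#' domain. Ranges are placed independently.
#'
#' @param lengths integer vector of range lengths (days).
#' @param domain integer `c(start, end)`; every length must fit.
#' @return `data.frame` with `start`, `end`, `length`.
#' @export
randomize_ranges <- function(lengths, domain) {
  domain <- as.integer(domain[1:2])
  ndays <- domain[2L] - domain[1L] + 1L
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("range lengths must be >= 1")
  if (any(lengths > ndays)) stop("range length exceeds domain length")
  starts <- domain[1L] - 1L +
    vapply(lengths, function(L) sample.int(ndays - L + 1L, 1L), 1L)
  data.frame(start = starts, end = starts + lengths - 1L,
             length = lengths)
}
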