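#' Assemble a temporal bipartite network from observation records
#'
#' The central constructor. From long-format visitation records it
#' infers (or accepts) species phenophases, fixes the network season,
#' extracts the observed interacting pairs, builds the static network
#' under the activity rule and classifies species into core (`L > 2`)
#' and tail (`L <= 2`). The returned object is the input to the slicing,
#' nestedness, mid-domain and time-delay analyses.
#'
#' @param records observation `data.frame` (see [read_observations()]).
#' @param species optional species metadata table (see
#'   [read_species_table()]).
#' @param phenophases optional explicit phenophase table overriding
#'   inference from the records (see [read_phenophases()]); rows for
#'   species absent from the records are kept, with guild taken from
#'   the table.
#' @param season optional explicit `c(start, end)`; wins over inference
#'   from the records. Records outside an explicit season are dropped
#'   with a warning (the count is kept in the object).
#' @return an object of class `temporal_network` with elements
#'   `records`, `species`, `phenophases`, `pairs`, `season` (named
#'   start/end/length), `static` (`bipartite_net`), `core_tail`
#'   (season-wide classification) and `n_dropped`.
#' @examples
#' sim <- simulate_phenonet(phenonet_config(seed = 1))
#' tn <- temporal_network(sim$records)
#' tn
#' @export
temporal_network <- function(records, species = NULL, phenophases = NULL,
                             season = NULL) {
  check_records(records)
  n_dropped <- 0L
  if (!is.null(season)) {
    season <- as.integer(season[1:2])
    out <- records$day < season[1L] | records$day > season[2L]
    if (any(out)) {
      n_dropped <- sum(out)
      warning("dropped ", n_dropped,
              " record(s) outside the declared season")
      records <- records[!out, , drop = FALSE]
      if (nrow(records) == 0L)
        stop("no records remain within the declared season")
    }
    season <- c(start = season[1L], end = season[2L],
                length = season[2L] - season[1L] + 1L)
  } else {
    season <- season_bounds(records)
  }
  inferred <- infer_phenophases(records)
  if (is.null(phenophases)) {
    phen <- inferred
  } else {
    phen <- phenophases
    if (!"guild" %in% names(phen)) phen$guild <- NA_character_
    fill <- is.na(phen$guild)
    phen$guild[fill] <-
      inferred$guild[match(phen$species[fill], inferred$species)]
    if (anyNA(phen$guild))
      stop("guild unknown for explicit-phenophase species: ",
           paste(phen$species[is.na(phen$guild)], collapse = ", "))
    if (!"length" %in% names(phen))
      phen$length <- phen$end - phen$start + 1L
    check_phenophases(phen)
    miss <- setdiff(inferred$species, phen$species)
    if (length(miss))
      stop("explicit phenophase table lacks observed species: ",
           paste(miss, collapse = ", "))
  }
  pairs <- unique(records[, c("plant", "pollinator")])
  rownames(pairs) <- NULL
  static <- build_network(phen, pairs,
                          window = c(season[["start"]], season[["end"]]))
  obj <- structure(list(records = records, species = species,
                        phenophases = phen, pairs = pairs,
                        season = season, static = static,
                        core_tail = core_tail(static),
                        n_dropped = n_dropped),
                   class = "temporal_network")
  obj
}

#' @export
print.temporal_network <- function(x, ...) {
  s <- x$season
  cat("Temporal bipartite network\n")
  cat("  season: days ", s[["start"]], "-", s[["end"]], " (",
      s[["length"]], " d)\n", sep = "")
  cat("  pollinators (A): ", length(x$static$pollinators),
      "  plants (P): ", length(x$static$plants),
      "  links (I): ", nrow(x$static$links), "\n", sep = "")
  cat("  static connectance: ",
      round_half_up(connectance(x$static)), "%\n", sep = "")
  ct <- x$core_tail
  cat("  tail species (L<=2): ",
      sum(ct$status == "tail" & ct$guild == "pollinator"), " pollinators, ",
      sum(ct$status == "tail" & ct$guild == "plant"), " plants\n", sep = "")
  invisible(x)
}

#' Summarise a temporal network
#'
#' With `daily = FALSE` (default) a one-row summary of the static
#' network; with `daily = TRUE` the per-day slice summaries plus their
#' means, the static-vs-dynamic comparison at the heart of the analysis.
#'
#' @param object a `temporal_network`.
#' @param daily summarise the one-day slices instead of the static
#'   network?
#' @param season_L use season-wide `L` for the daily core/tail split
#'   instead of each slice's own daily `L`?
#' @param ... unused.
#' @return a [network_summary()] object.
#' @export
summary.temporal_network <- function(object, daily = FALSE,
                                     season_L = FALSE, ...) {
  if (!daily) return(network_summary(object$static))
  slices <- slice_daily(object$phenophases, object$pairs,
                        c(object$season[["start"]], object$season[["end"]]))
  network_summary(slices,
                  L = if (season_L) linkage_level(object$static) else NULL)
}

#' Plot phenophases and daily richness of a temporal network
#'
#' Base-graphics overview: one horizontal bar per species over the
#' season (plants below, visitors above; tail species in a lighter
#' tone), with the daily active-species count traced underneath.
#'
#' @param x a `temporal_network`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.temporal_network <- function(x, ...) {
  phen <- x$phenophases
  ord <- order(phen$guild, phen$start, phen$end)
  phen <- phen[ord, ]
  st <- x$core_tail$status[match(phen$species, x$core_tail$species)]
  col <- ifelse(phen$guild == "plant",
                ifelse(st == "core", "darkgreen", "palegreen3"),
                ifelse(st == "core", "steelblue4", "lightsteelblue3"))
  days <- x$season[["start"]]:x$season[["end"]]
  rich <- vapply(days, function(d)
    sum(phen$start <= d & phen$end >= d), 0L)
  n <- nrow(phen)
  graphics::plot(NA, xlim = range(days), ylim = c(-max(rich), n),
                 xlab = "day of year", ylab = "",
                 yaxt = "n", main = "Phenophases and daily richness", ...)
  graphics::segments(phen$start, seq_len(n), phen$end, seq_len(n),
                     col = col, lwd = 2)
  graphics::lines(days, -rich, col = "grey25")
  graphics::axis(2, at = c(-max(rich), 0), labels = c(max(rich), 0),
                 las = 1)
  invisible(x)
}
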