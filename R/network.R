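#' Build a bipartite network under the phenophase-overlap activity rule
#'
#' A pair observed interacting at least once is scored as interacting
#' during its entire phenophase overlap. For a given time window, a
#' species is a member iff its phenophase intersects the window, and a
#' link is present iff the pair was observed interacting at all and the
#' three-way intersection window \eqn{\cap} plant phenophase \eqn{\cap}
#' visitor phenophase is non-empty. With the full season as window this
#' is the static network.
#'
#' @param phenophases phenophase `data.frame` (see [infer_phenophases()]).
#' @param pairs `data.frame` with columns `plant`, `pollinator`: the
#'   pairs observed interacting at least once over the season.
#' @param window integer vector `c(start, end)` (closed, in days); `NULL`
#'   uses the full span of the phenophase table.
#' @return a `bipartite_net` object: `plants` and `pollinators`
#'   (character vectors of active species), `links` (`data.frame` of
#'   active links) and `window`.
#' @export
build_network <- function(phenophases, pairs, window = NULL) {
  check_phenophases(phenophases)
  pairs <- unique(pairs[, c("plant", "pollinator")])
  unknown <- setdiff(c(pairs$plant, pairs$pollinator), phenophases$species)
  if (length(unknown))
    stop("interacting pair references species without phenophase: ",
         paste(unknown, collapse = ", "))
  if (is.null(window))
    window <- c(min(phenophases$start), max(phenophases$end))
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L])
    stop("window must be c(start, end) with start <= end")
  active <- phenophases$start <= window[2L] & phenophases$end >= window[1L]
  plants <- phenophases$species[active & phenophases$guild == "plant"]
  polls <- phenophases$species[active & phenophases$guild == "pollinator"]
  ps <- phenophases$start[match(pairs$plant, phenophases$species)]
  pe <- phenophases$end[match(pairs$plant, phenophases$species)]
  as_ <- phenophases$start[match(pairs$pollinator, phenophases$species)]
  ae <- phenophases$end[match(pairs$pollinator, phenophases$species)]
  keep <- pmax(ps, as_, window[1L]) <= pmin(pe, ae, window[2L])
  new_bipartite_net(plants, polls, pairs[keep, , drop = FALSE], window)
}

new_bipartite_net <- function(plants, pollinators, links, window = NULL) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  rownames(links) <- NULL
  stopifnot(all(links$plant %in% plants),
            all(links$pollinator %in% pollinators),
            !length(intersect(plants, pollinators)))
  structure(list(plants = plants, pollinators = pollinators,
                 links = links, window = window),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  w <- if (is.null(x$window)) "full span" else
    paste0("days ", x$window[1L], "-", x$window[2L])
  cat("Bipartite plant-visitor network (", w, ")\n", sep = "")
  cat("  plants: ", length(x$plants), "  pollinators: ",
      length(x$pollinators), "  links: ", nrow(x$links), "\n", sep = "")
  invisible(x)
}

#' Cut the season into consecutive one-day network slices
#'
#' One network per day of the season (a slice thickness of one field
#' day); days on which no species is active yield empty networks, which
#' are kept so the sequence covers the season without gaps.
#'
#' @inheritParams build_network
#' @param season integer `c(start, end)` of the season (days).
#' @return a list of `bipartite_net`, one per day, named by day.
#' @export
slice_daily <- function(phenophases, pairs, season) {
  season <- as.integer(season[1:2])
  if (season[1L] > season[2L]) stop("invalid season")
  days <- season[1L]:season[2L]
  out <- lapply(days, function(d)
    build_network(phenophases, pairs, window = c(d, d)))
  names(out) <- days
  out
}

#' Aggregate the season into consecutive fixed-width windows
#'
#' Consecutive non-overlapping windows of `window_length` days; the last
#' window may be shorter. A window equal to the season length reproduces
#' the static network; a window of 1 day equals [slice_daily()].
#'
#' @inheritParams slice_daily
#' @param window_length window width in days (>= 1).
#' @return a list of `bipartite_net`, named `start-end`.
#' @export
aggregate_window <- function(phenophases, pairs, window_length, season) {
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 1L)
    stop("window_length must be >= 1")
  season <- as.integer(season[1:2])
  starts <- seq.int(season[1L], season[2L], by = window_length)
  out <- lapply(starts, function(s)
    build_network(phenophases, pairs,
                  window = c(s, min(s + window_length - 1L, season[2L]))))
  names(out) <- vapply(out, function(n)
    paste0(n$window[1L], "-", n$window[2L]), "")
  out
}

#' Connectance of a bipartite network
#'
#' \eqn{C = 100 \cdot I / (A P)}: the realised percentage of possible
#' plant-pollinator links, with `A` pollinators, `P` plants and `I`
#' links. Reported tables round half-up to integer percent; this returns
#' full precision.
#'
#' @param net a `bipartite_net` with at least one species per guild.
#' @return connectance in percent.
#' @examples
#' # A = 78 pollinators, P = 34 plants, I = 295 links -> ~11%
#' @export
connectance <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  A <- length(net$pollinators)
  P <- length(net$plants)
  if (A < 1L || P < 1L)
    stop("connectance undefined: empty guild")
  100 * nrow(net$links) / (A * P)
}

#' Linkage level (number of distinct partners)
#'
#' A species' linkage level `L` is its number of links to species of the
#' other guild within the network. Summed over either guild it equals
#' the link count `I`.
#'
#' @param net a `bipartite_net`.
#' @param species optional single id; when given, return its `L` only.
#' @return a named integer vector over all species (plants then
#'   pollinators), or a single integer.
#' @export
linkage_level <- function(net, species = NULL) {
  stopifnot(inherits(net, "bipartite_net"))
  all_sp <- c(net$plants, net$pollinators)
  L <- integer(length(all_sp))
  names(L) <- all_sp
  if (nrow(net$links)) {
    tb <- table(c(net$links$plant, net$links$pollinator))
    L[names(tb)] <- as.integer(tb)
  }
  if (!is.null(species)) {
    if (!species %in% all_sp) stop("unknown species: ", species)
    return(L[[species]])
  }
  L
}

#' Classify species into core and tail by linkage level
#'
#' Core species have `L > 2`, tail species `L <= 2`. Species that are
#' active in the network but momentarily without any active partner
#' (`L = 0`, possible in narrow windows) are classified tail and flagged
#' `isolated`.
#'
#' @param net a `bipartite_net`.
#' @param L optional named linkage-level vector to classify by (e.g.
#'   season-wide `L` when summarising daily slices); defaults to the
#'   network's own `L`.
#' @return `data.frame` with `species`, `guild`, `L`, `status`
#'   (`"core"`/`"tail"`) and logical `isolated`.
#' @export
core_tail <- function(net, L = NULL) {
  stopifnot(inherits(net, "bipartite_net"))
  own <- linkage_level(net)
  if (is.null(L)) {
    L <- own
  } else {
    miss <- setdiff(names(own), names(L))
    if (length(miss))
      stop("L lacks species: ", paste(miss, collapse = ", "))
    L <- L[names(own)]
  }
  data.frame(species = names(own),
             guild = c(rep("plant", length(net$plants)),
                       rep("pollinator", length(net$pollinators))),
             L = as.integer(L),
             status = ifelse(L > 2L, "core", "tail"),
             isolated = own == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative tail length of one guild
#'
#' \eqn{t/(c+t)}: the fraction of a guild's species that are tail
#' species (`L <= 2`), the "length" of the thin edge of the nested
#' matrix relative to guild richness.
#'
#' @inheritParams core_tail
#' @param guild `"pollinator"` or `"plant"`.
#' @return a fraction in `[0, 1]`.
#' @examples
#' # 61 tail of 88 pollinators -> 0.693 (69% rounded)
#' @export
relative_tail_length <- function(net, guild = c("pollinator", "plant"),
                                 L = NULL) {
  guild <- match.arg(guild)
  ct <- core_tail(net, L = L)
  ct <- ct[ct$guild == guild, ]
  if (nrow(ct) == 0L) stop("no ", guild, " species in network")
  mean(ct$status == "tail")
}

#' Least-squares summary of phenophase length on linkage level
#'
#' Ordinary least-squares fit of phenophase length (days) on season-wide
#' linkage level `L`, the standard check that generalists persist longer
#' in the season than specialists.
#'
#' @param phenophases phenophase `data.frame`.
#' @param net the static `bipartite_net` providing `L`.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
phenophase_L_regression <- function(phenophases, net) {
  check_phenophases(phenophases)
  L <- linkage_level(net)
  idx <- match(names(L), phenophases$species)
  ok <- !is.na(idx)
  x <- as.numeric(L[ok])
  y <- as.numeric(phenophases$length[idx[ok]])
  if (length(x) < 3L)
    stop("need at least 3 species with phenophase and L")
  if (stats::var(x) == 0)
    stop("zero variance in L: regression undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = length(x))
}

#' Summarise a network or a sequence of networks
#'
#' Per-network structural summary: species counts `A`
#' (pollinators) and `P` (plants), link count `I`, connectance `C`
#' (percent), and per guild the tail/core counts and relative tail
#' length. Networks with an empty guild are flagged empty, excluded from
#' the sequence means and counted separately.
#'
#' @param nets a `bipartite_net` or a list of them.
#' @param L optional named season-wide linkage levels used for the
#'   core/tail split (default: each network's own, so daily summaries
#'   use daily `L`).
#' @return an object of class `network_summary`: a `data.frame` (one row
#'   per network) with attributes `means` (named numeric over non-empty
#'   networks) and `n_empty`.
#' @export
network_summary <- function(nets, L = NULL) {
  if (inherits(nets, "bipartite_net")) nets <- list(nets)
  if (!length(nets)) stop("no networks to summarise")
  one <- function(n) {
    A <- length(n$pollinators); P <- length(n$plants)
    empty <- A == 0L || P == 0L
    if (!empty) {
      ct <- core_tail(n, L = L)
      tp <- sum(ct$guild == "pollinator" & ct$status == "tail")
      cp <- sum(ct$guild == "pollinator" & ct$status == "core")
      tl <- sum(ct$guild == "plant" & ct$status == "tail")
      cl <- sum(ct$guild == "plant" & ct$status == "core")
    } else tp <- cp <- tl <- cl <- NA_integer_
    w <- n$window %||% c(NA_integer_, NA_integer_)
    data.frame(window_start = w[1L], window_end = w[2L],
               A = A, P = P, I = nrow(n$links),
               C = if (empty) NA_real_ else connectance(n),
               tail_pollinators = tp, core_pollinators = cp,
               rtl_pollinators = if (empty) NA_real_ else tp / (tp + cp),
               tail_plants = tl, core_plants = cl,
               rtl_plants = if (empty) NA_real_ else tl / (tl + cl),
               empty = empty)
  }
  df <- do.call(rbind, lapply(nets, one))
  rownames(df) <- NULL
  if (all(df$empty)) stop("all networks are empty")
  num <- df[!df$empty, setdiff(names(df), c("window_start", "window_end",
                                            "empty"))]
  structure(df, means = colMeans(num), n_empty = sum(df$empty),
            class = c("network_summary", "data.frame"))
}

#' @export
print.network_summary <- function(x, digits = 3, ...) {
  cat("Network summary over", nrow(x), "network(s);",
      attr(x, "n_empty"), "empty\n")
  print.data.frame(x, digits = digits, ...)
  cat("\nMeans over non-empty networks:\n")
  print(round(attr(x, "means"), digits))
  invisible(x)
}

#' Write a network summary as CSV and JSON
#'
#' @param x a `network_summary`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_network_summary <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "network_summary"))
  if (!is.null(csv))
    utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(per_network = as.data.frame(x),
                              means = as.list(attr(x, "means")),
                              n_empty = attr(x, "n_empty")),
                         json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
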