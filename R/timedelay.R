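#' Classify an ordered phenophase pair and its time delay
#'
#' For a directed effect from a source species to a target species, the
#' relative position of their phenophases admits exactly four
#' geometries:
#' \describe{
#'   \item{`overlap_forward`}{phenophases overlap and the target starts
#'     at or after the source; delay is the start-day difference,
#'     floored at 1 day (the clock granularity).}
#'   \item{`overlap_backward`}{phenophases overlap and the target
#'     started first; the effect can pass as soon as the source enters,
#'     so the delay is 1 day.}
#'   \item{`gap_forward`}{disjoint, target entirely after the source
#'     ends; delay is the start-day difference.}
#'   \item{`gap_impossible`}{disjoint, target ended before the source
#'     began: effects cannot travel back in time within a season, so no
#'     delay is defined.}
#' }
#' All arguments are vectorised and recycled.
#'
#' @param s_start,s_end source phenophase (closed day interval).
#' @param t_start,t_end target phenophase.
#' @return `data.frame` with `class` (character, one of the four above)
#'   and `delay` (integer days, `NA` when impossible).
#' @examples
#' delay_class(165, 200, 180, 220)  # overlap_forward, 15 d
#' delay_class(180, 220, 165, 200)  # overlap_backward, 1 d
#' delay_class(200, 220, 165, 180)  # gap_impossible
#' @export
delay_class <- function(s_start, s_end, t_start, t_end) {
  n <- max(length(s_start), length(s_end), length(t_start),
           length(t_end))
  s_start <- rep_len(as.integer(s_start), n)
  s_end <- rep_len(as.integer(s_end), n)
  t_start <- rep_len(as.integer(t_start), n)
  t_end <- rep_len(as.integer(t_end), n)
  if (any(s_start > s_end) || any(t_start > t_end))
    stop("invalid phenophase: start > end")
  overlap <- s_start <= t_end & t_start <= s_end
  cls <- ifelse(overlap,
                ifelse(t_start >= s_start, "overlap_forward",
                       "overlap_backward"),
                ifelse(t_start > s_end, "gap_forward", "gap_impossible"))
  delay <- ifelse(cls == "overlap_forward", pmax(t_start - s_start, 1L),
           ifelse(cls == "overlap_backward", 1L,
           ifelse(cls == "gap_forward", t_start - s_start, NA_integer_)))
  data.frame(class = cls, delay = as.integer(delay))
}

pair_classes <- c("overlap_forward", "overlap_backward", "gap_forward",
                  "gap_impossible")

#' Giant component of a bipartite network
#'
#' Species of the largest connected component of the static graph
#' (isolated species form their own singleton components). When two
#' components tie in size the one containing the alphabetically
#' smallest species id is returned, for reproducibility.
#'
#' @param net a `bipartite_net`.
#' @return sorted character vector of member species ids.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  if (!length(net$plants) && !length(net$pollinators))
    stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b)
      min(igraph::V(g)$name[comp$membership == b]), "")
    best <- best[order(firsts)[1L]]
  }
  sort(igraph::V(g)$name[comp$membership == best])
}

delay_records <- function(source, target, s_type, t_type, mode, phen, ct) {
  si <- match(source, phen$species); ti <- match(target, phen$species)
  if (anyNA(si) || anyNA(ti))
    stop("species missing phenophase: ",
         paste(unique(c(source[is.na(si)], target[is.na(ti)])),
               collapse = ", "))
  dc <- delay_class(phen$start[si], phen$end[si],
                    phen$start[ti], phen$end[ti])
  data.frame(source = source, target = target,
             source_guild = s_type, target_guild = t_type,
             mode = mode,
             pair_type = paste0(s_type, "_to_", t_type),
             class = dc$class, delay = dc$delay,
             source_status = ct$status[match(source, ct$species)],
             target_status = ct$status[match(target, ct$species)],
             stringsAsFactors = FALSE)
}

#' Time delays between directly linked species
#'
#' Every observed link yields two directed records (plant to visitor
#' and visitor to plant), classified by [delay_class()]. The activity
#' rule guarantees linked phenophases overlap, so direct pairs are
#' always an overlap class.
#'
#' @param x a `temporal_network`.
#' @return `data.frame` of delay records (`source`, `target`, guilds,
#'   `mode = "direct"`, `pair_type`, `class`, `delay`, core/tail
#'   status of both ends).
#' @export
direct_delays <- function(x) {
  stopifnot(inherits(x, "temporal_network"))
  lk <- x$static$links
  if (!nrow(lk)) stop("network has no links")
  phen <- x$phenophases; ct <- x$core_tail
  rbind(
    delay_records(lk$plant, lk$pollinator, "plant", "pollinator",
                  "direct", phen, ct),
    delay_records(lk$pollinator, lk$plant, "pollinator", "plant",
                  "direct", phen, ct))
}

#' Time delays between indirectly connected species
#'
#' All ordered pairs of distinct species within the giant component of
#' the static network that are not directly linked: unlinked
#' plant/visitor pairs (2-mode) and same-guild pairs (1-mode, connected
#' through couplers of the other guild). Each pair is classified by
#' phenophase geometry alone; connectivity is assumed through the giant
#' component.
#'
#' @param x a `temporal_network`.
#' @return `data.frame` of delay records with `mode = "indirect"`.
#' @export
indirect_delays <- function(x) {
  stopifnot(inherits(x, "temporal_network"))
  gc <- giant_component(x$static)
  if (length(gc) < 3L)
    stop("giant component too small for indirect analysis")
  phen <- x$phenophases; ct <- x$core_tail
  guild <- phen$guild[match(gc, phen$species)]
  idx <- expand.grid(s = seq_along(gc), t = seq_along(gc))
  idx <- idx[idx$s != idx$t, ]
  src <- gc[idx$s]; tgt <- gc[idx$t]
  sg <- guild[idx$s]; tg <- guild[idx$t]
  linked <- paste(x$static$links$plant, x$static$links$pollinator)
  key <- ifelse(sg == "plant", paste(src, tgt), paste(tgt, src))
  direct <- sg != tg & key %in% linked
  delay_records(src[!direct], tgt[!direct], sg[!direct], tg[!direct],
                "indirect", phen, ct)
}

#' Shortest time-respecting coupler chain between two species
#'
#' Finds the shortest chain of statically linked species from `source`
#' to `target` in which every consecutive step is temporally possible
#' (its delay class is not `gap_impossible`); the interior species are
#' the temporal couplers. Transmission delays specific to the couplers'
#' biology are ignored. Directly linked pairs return an empty chain.
#'
#' @param x a `temporal_network`.
#' @param source,target species ids.
#' @return character vector of coupler ids (possibly empty), or `NULL`
#'   when no time-respecting chain exists.
#' @export
coupler_chain <- function(x, source, target) {
  stopifnot(inherits(x, "temporal_network"))
  sp <- c(x$static$plants, x$static$pollinators)
  if (!source %in% sp) stop("unknown species: ", source)
  if (!target %in% sp) stop("unknown species: ", target)
  if (source == target) stop("source and target must differ")
  phen <- x$phenophases
  nbr <- split(c(x$static$links$pollinator, x$static$links$plant),
               c(x$static$links$plant, x$static$links$pollinator))
  step_ok <- function(a, b) {
    ia <- match(a, phen$species); ib <- match(b, phen$species)
    delay_class(phen$start[ia], phen$end[ia],
                phen$start[ib], phen$end[ib])$class != "gap_impossible"
  }
  # BFS over directed, time-respecting steps
  prev <- stats::setNames(rep(NA_character_, length(sp)), sp)
  seen <- stats::setNames(rep(FALSE, length(sp)), sp)
  seen[source] <- TRUE
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in nbr[[u]] %||% character(0)) {
        if (!seen[[v]] && step_ok(u, v)) {
          seen[v] <- TRUE
          prev[v] <- u
          if (v == target) {
            path <- v
            while (!is.na(prev[[path[1L]]]))
              path <- c(prev[[path[1L]]], path)
            return(path[-c(1L, length(path))])
          }
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Aggregate delay records into a summary delay table
#'
#' Summarises direct and indirect delay records: mean direct delay by
#' direction (plant to visitor, visitor to plant, overall) and by
#' core/tail block; indirect counts, percentages and mean delays per
#' delay class (pooled over 1- and 2-mode pair types, with a per-type
#' breakdown); and the percentage of temporally impossible indirect
#' connections within each core/tail block. Impossible pairs are
#' excluded from mean delays.
#'
#' @param records `data.frame` of delay records from [direct_delays()]
#'   and/or [indirect_delays()] (rbind them for the full table), or a
#'   `temporal_network` (computes both).
#' @return object of class `delay_table` (a list of data.frames:
#'   `direct_by_direction`, `direct_by_block`, `indirect_by_class`,
#'   `indirect_by_type`, `impossible_by_block`).
#' @export
delay_table <- function(records) {
  if (inherits(records, "temporal_network"))
    records <- rbind(direct_delays(records), indirect_delays(records))
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  dir <- records[records$mode == "direct", ]
  ind <- records[records$mode == "indirect", ]
  direct_by_direction <- direct_by_block <- NULL
  if (nrow(dir)) {
    mw <- function(sel) if (any(sel)) mean(dir$delay[sel]) else NA_real_
    direct_by_direction <- data.frame(
      direction = c("plant_to_pollinator", "pollinator_to_plant", "mean"),
      mean_delay = c(mw(dir$pair_type == "plant_to_pollinator"),
                     mw(dir$pair_type == "pollinator_to_plant"),
                     mean(dir$delay)))
    blocks <- expand.grid(from = c("core", "tail"), to = c("core", "tail"),
                          stringsAsFactors = FALSE)
    direct_by_block <- cbind(blocks, mean_delay = mapply(
      function(f, t) mw(dir$source_status == f & dir$target_status == t),
      blocks$from, blocks$to))
  }
  indirect_by_class <- indirect_by_type <- impossible_by_block <- NULL
  if (nrow(ind)) {
    by_class <- function(d) {
      cnt <- vapply(pair_classes, function(cl) sum(d$class == cl), 0L)
      data.frame(class = pair_classes, count = cnt,
                 pct = 100 * cnt / nrow(d),
                 mean_delay = vapply(pair_classes, function(cl) {
                   v <- d$delay[d$class == cl & !is.na(d$delay)]
                   if (length(v)) mean(v) else NA_real_
                 }, 0), row.names = NULL)
    }
    indirect_by_class <- by_class(ind)
    indirect_by_type <- do.call(rbind, lapply(
      split(ind, ind$pair_type),
      function(d) cbind(pair_type = d$pair_type[1L], by_class(d))))
    rownames(indirect_by_type) <- NULL
    blocks <- expand.grid(from = c("core", "tail"), to = c("core", "tail"),
                          stringsAsFactors = FALSE)
    impossible_by_block <- cbind(blocks, pct_impossible = mapply(
      function(f, t) {
        sel <- ind$source_status == f & ind$target_status == t
        if (!any(sel)) return(NA_real_)
        100 * mean(ind$class[sel] == "gap_impossible")
      }, blocks$from, blocks$to))
  }
  structure(list(direct_by_direction = direct_by_direction,
                 direct_by_block = direct_by_block,
                 indirect_by_class = indirect_by_class,
                 indirect_by_type = indirect_by_type,
                 impossible_by_block = impossible_by_block),
            class = "delay_table")
}

#' @export
print.delay_table <- function(x, digits = 1, ...) {
  rnd <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits)
    df
  }
  cat("Time-delay table\n")
  if (!is.null(x$direct_by_direction)) {
    cat("\nA. Delay between directly linked species (days)\n")
    print(rnd(x$direct_by_direction), row.names = FALSE)
    cat("\nB. Direct delay by core/tail block (days)\n")
    print(rnd(x$direct_by_block), row.names = FALSE)
  }
  if (!is.null(x$indirect_by_class)) {
    cat("\nC. Indirect linkage by delay class (pooled 1- and 2-mode)\n")
    print(rnd(x$indirect_by_class), row.names = FALSE)
    cat("\nD. Temporally impossible indirect links by block (%)\n")
    print(rnd(x$impossible_by_block), row.names = FALSE)
  }
  invisible(x)
}
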