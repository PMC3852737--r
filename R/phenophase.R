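#' Infer species phenophases from observation records
#'
#' A species' network phenophase is the closed interval of integer days
#' between its first and last observed interaction: for a plant, the
#' first and last visit it received; for a flower visitor, its first and
#' last visit to any flower. Species never observed do not appear.
#'
#' @param records observation `data.frame` as from [read_observations()].
#' @return a `data.frame` with one row per species: `species`, `guild`
#'   (`plant`/`pollinator`), `start`, `end`, `length` (days, closed
#'   interval so `length = end - start + 1`).
#' @examples
#' rec <- data.frame(day = c(170, 175, 190), plant = "P1",
#'                   pollinator = c("A1", "A1", "A2"))
#' infer_phenophases(rec)
#' @export
infer_phenophases <- function(records) {
  check_records(records)
  one_guild <- function(ids, guild) {
    start <- tapply(records$day, ids, min)
    end <- tapply(records$day, ids, max)
    data.frame(species = names(start), guild = guild,
               start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_guild(records$plant, "plant"),
               one_guild(records$pollinator, "pollinator"))
  both <- intersect(out$species[out$guild == "plant"],
                    out$species[out$guild == "pollinator"])
  if (length(both))
    stop("identifier(s) used in both guilds: ",
         paste(both, collapse = ", "))
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Season bounds of an observation set
#'
#' The network season runs from the first to the last observed
#' visitation day, inclusive.
#'
#' @param records observation `data.frame`.
#' @return named integer vector `c(start, end, length)` with
#'   `length = end - start + 1`.
#' @examples
#' season_bounds(data.frame(day = c(165, 200, 234), plant = "P",
#'                          pollinator = "A"))  # length 70
#' @export
season_bounds <- function(records) {
  check_records(records)
  s <- min(records$day)
  e <- max(records$day)
  c(start = as.integer(s), end = as.integer(e),
    length = as.integer(e - s + 1L))
}

check_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame of observations")
  for (col in c("day", "plant", "pollinator"))
    if (!col %in% names(records))
      stop("records lack column '", col, "'")
  if (any(is.na(records$day))) stop("records contain missing days")
  invisible(records)
}

check_phenophases <- function(phen) {
  stopifnot(is.data.frame(phen))
  for (col in c("species", "guild", "start", "end"))
    if (!col %in% names(phen)) stop("phenophase table lacks '", col, "'")
  if (any(phen$start > phen$end))
    stop("phenophase with start > end")
  if (anyDuplicated(phen$species))
    stop("duplicated species in phenophase table")
  invisible(phen)
}
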