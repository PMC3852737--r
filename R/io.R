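#' Read flower-visitation observation records
#'
#' Parses a long-format table of daily visitation events: one row per
#' observed plant/flower-visitor contact with an integer day-of-year.
#' Column mapping is explicit, so any header names (or positions in a
#' headerless file) can be used; both comma- and tab-separated files are
#' accepted and the delimiter is sniffed from the first line when not
#' given.
#'
#' @param file path to a CSV or TSV file, or a connection.
#' @param columns named character or integer vector mapping the required
#'   fields `day`, `plant`, `pollinator` (and optionally `count`) to
#'   column names or 1-based positions.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma.
#' @param header does the file have a header line?
#' @return a `data.frame` with columns `day` (integer), `plant`,
#'   `pollinator` (character) and `count` (integer, default 1), in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("day,plant,poll", "170,P1,A1", "171,P1,A2"), f)
#' read_observations(f, columns = c(day = "day", plant = "plant",
#'                                  pollinator = "poll"))
#' @export
read_observations <- function(file,
                              columns = c(day = "day", plant = "plant",
                                          pollinator = "pollinator"),
                              sep = NULL, header = TRUE) {
  required <- c("day", "plant", "pollinator")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map))
    stop("column mapping must name: ", paste(missing_map, collapse = ", "))
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(file, sep = sep, header = header,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  pick <- function(field, optional = FALSE) {
    key <- columns[[field]]
    if (is.null(key)) {
      if (optional) return(NULL)
      stop("no column mapped for '", field, "'")
    }
    idx <- if (is.numeric(key)) as.integer(key) else match(key, names(raw))
    if (is.na(idx) || idx < 1L || idx > ncol(raw))
      stop("configuration error: column '", key, "' for field '", field,
           "' not found in input")
    raw[[idx]]
  }
  day_chr <- pick("day")
  bad <- which(!grepl("^\\s*-?[0-9]+\\s*$", day_chr))
  if (length(bad)) {
    line <- bad[1L] + if (header) 1L else 0L
    stop("non-integer day value '", day_chr[bad[1L]], "' at line ", line)
  }
  out <- data.frame(day = as.integer(day_chr),
                    plant = pick("plant"),
                    pollinator = pick("pollinator"),
                    stringsAsFactors = FALSE)
  if ("count" %in% names(columns)) {
    cnt <- pick("count", optional = TRUE)
    badc <- which(!grepl("^\\s*[0-9]+\\s*$", cnt))
    if (length(badc))
      stop("non-integer count value '", cnt[badc[1L]], "' at line ",
           badc[1L] + if (header) 1L else 0L)
    out$count <- as.integer(cnt)
  } else {
    out$count <- 1L
  }
  out
}

#' Read a species table
#'
#' An optional companion table of species metadata: identifier, guild
#' (`plant` or `pollinator`), and optional free-text taxon `group` and
#' `trophic_role` (`visitor`, `parasitoid`, `hyper_parasitoid`).
#'
#' @param file path to a CSV/TSV file with at least columns `id`, `guild`.
#' @param sep field separator; `NULL` sniffs.
#' @return a `data.frame` with columns `id`, `guild`, `group`,
#'   `trophic_role` (missing optional columns filled with `NA`).
#' @export
read_species_table <- function(file, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("id", "guild"))
    if (!col %in% names(df)) stop("species table lacks column '", col, "'")
  if (anyDuplicated(df$id))
    stop("duplicated species ids in species table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- setdiff(unique(df$guild), c("plant", "pollinator"))
  if (length(bad))
    stop("unknown guild value(s): ", paste(bad, collapse = ", "))
  for (col in c("group", "trophic_role"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df[, c("id", "guild", "group", "trophic_role")]
}

#' Read a phenophase table
#'
#' Phenophases supplied explicitly (overriding inference from records):
#' columns `id`, `start_day`, `end_day`, optional `guild`.
#'
#' @param file path to CSV/TSV.
#' @param sep separator; `NULL` sniffs.
#' @return a phenophase `data.frame` (`species`, `guild`, `start`, `end`,
#'   `length`); `guild` is `NA` when absent and is filled in later from
#'   the observation records.
#' @export
read_phenophases <- function(file, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("id", "start_day", "end_day"))
    if (!col %in% names(df)) stop("phenophase table lacks column '", col, "'")
  out <- data.frame(species = as.character(df$id),
                    guild = if ("guild" %in% names(df))
                      as.character(df$guild) else NA_character_,
                    start = as.integer(df$start_day),
                    end = as.integer(df$end_day),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("phenophase with start_day > end_day for species: ",
         paste(out$species[out$start > out$end], collapse = ", "))
  out$length <- out$end - out$start + 1L
  out
}

#' Write a network as an edge list
#'
#' One row per link: `plant`, `pollinator`, `window_start`, `window_end`.
#' A list of networks (e.g. daily slices) is concatenated into one file.
#'
#' @param net a `bipartite_net` or a list of them.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_edge_list <- function(net, file) {
  nets <- if (inherits(net, "bipartite_net")) list(net) else net
  rows <- lapply(nets, function(n) {
    if (nrow(n$links) == 0L) return(NULL)
    w <- n$window %||% c(NA_integer_, NA_integer_)
    data.frame(plant = n$links$plant, pollinator = n$links$pollinator,
               window_start = w[1L], window_end = w[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(plant = character(), pollinator = character(),
                      window_start = integer(), window_end = integer())
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a network as GraphML
#'
#' Writes the bipartite graph with a `guild` vertex attribute, readable
#' by any GraphML-aware tool.
#'
#' @param net a `bipartite_net`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_graphml <- function(net, file) {
  stopifnot(inherits(net, "bipartite_net"))
  g <- as_igraph(net)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

# shared igraph view of a bipartite_net (vertices include isolated species)
as_igraph <- function(net) {
  verts <- data.frame(
    name = c(net$plants, net$pollinators),
    guild = c(rep("plant", length(net$plants)),
              rep("pollinator", length(net$pollinators))),
    stringsAsFactors = FALSE)
  edges <- net$links[, c("plant", "pollinator")]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
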