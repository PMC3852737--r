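#' Incidence matrix of a bipartite network
#'
#' Binary presence/absence matrix with flower visitors in rows and
#' plants in columns; cell (i, j) is 1 iff the pair is linked, so the
#' number of 1s equals the link count `I`.
#'
#' @param net a `bipartite_net`.
#' @return an integer 0/1 matrix with species ids as dimnames.
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  m <- matrix(0L, nrow = length(net$pollinators),
              ncol = length(net$plants),
              dimnames = list(net$pollinators, net$plants))
  if (nrow(net$links))
    m[cbind(net$links$pollinator, net$links$plant)] <- 1L
  m
}

#' Read / write a dense incidence matrix as CSV
#'
#' Row names are visitor ids, the header holds plant ids.
#'
#' @param file path.
#' @return `read_incidence`: an integer 0/1 matrix.
#' @export
read_incidence <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("incidence matrix must be binary")
  m
}

#' @rdname read_incidence
#' @param m a binary matrix.
#' @export
write_incidence <- function(m, file) {
  utils::write.csv(m, file, quote = FALSE)
  invisible(file)
}

#' Sort an incidence matrix into nested display order
#'
#' Rows and columns are ordered by descending marginal total (linkage
#' level), from the upper-left corner. Lines with equal totals are
#' ordered by increasing mean linkage level of their interacting
#' partners (so species whose partners are more specialised come
#' first); remaining ties keep their original order.
#'
#' @param m binary incidence matrix.
#' @return the reordered matrix.
#' @export
sort_incidence <- function(m) {
  if (!is.matrix(m) || !nrow(m) || !ncol(m)) stop("empty matrix")
  partner_mean <- function(line, partner_tot) {
    if (!any(line == 1L)) return(Inf)
    mean(partner_tot[line == 1L])
  }
  rs <- rowSums(m); cs <- colSums(m)
  rkey <- apply(m, 1L, partner_mean, partner_tot = cs)
  ckey <- apply(m, 2L, partner_mean, partner_tot = rs)
  ro <- order(-rs, rkey, seq_len(nrow(m)))
  co <- order(-cs, ckey, seq_len(ncol(m)))
  m[ro, co, drop = FALSE]
}

# NODF over one orientation: mean paired overlap over all unordered line
# pairs. Pairs with equal fill, or whose sparser line is empty,
# contribute 0 (decreasing-fill requirement).
nodf_lines <- function(m) {
  k <- rowSums(m)
  n <- length(k)
  if (n < 2L) return(c(sum = 0, pairs = 0))
  S <- tcrossprod(m)          # shared 1s per line pair
  kmin <- outer(k, k, pmin)
  sel <- outer(k, k, "!=") & kmin > 0 & upper.tri(S)
  c(sum = sum(100 * S[sel] / kmin[sel]), pairs = n * (n - 1L) / 2)
}

# lenient NODF used for null matrices: degenerate (all-zero) input gives 0
nodf_value <- function(m) {
  r <- nodf_lines(m)
  cl <- nodf_lines(t(m))
  npairs <- r[["pairs"]] + cl[["pairs"]]
  if (npairs == 0) return(0)
  (r[["sum"]] + cl[["sum"]]) / npairs
}

#' NODF nestedness of a binary matrix
#'
#' Nestedness measure based on Overlap and Decreasing Fill. For every
#' unordered pair of rows (and of columns) whose marginal totals
#' strictly decrease, the paired term is the percentage of the sparser
#' line's 1s that coincide with 1s of the denser line; equal-fill pairs
#' contribute 0. NODF is the mean over all row pairs and column pairs,
#' in `[0, 100]`, and is invariant to the input ordering of lines.
#'
#' @param m binary incidence matrix with at least 2 rows, 2 columns and
#'   one 1.
#' @return the NODF score.
#' @examples
#' nodf(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0)))  # 66.67
#' @export
nodf <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("NODF needs at least 2 rows and 2 columns")
  if (!all(m %in% c(0, 1))) stop("matrix must be binary")
  if (sum(m) == 0) stop("matrix has no links")
  nodf_value(m)
}

#' Draw a null incidence matrix
#'
#' Two classical binary null models. `equiprobable`: every cell is 1
#' with the same probability `fill / (R C)`. `degree_proportional`
#' (default elsewhere): cell (i, j) is 1 with probability
#' `(k_i / C + k_j / R) / 2`, the mean of the observed row and column
#' fill fractions, so expected marginal totals track the observed
#' degrees and expected fill equals the observed fill.
#'
#' @param m observed binary matrix.
#' @param model `"degree_proportional"` or `"equiprobable"`.
#' @return a random binary matrix of the same shape (possibly with
#'   empty lines; callers computing NODF on nulls treat those as
#'   contributing 0).
#' @export
null_matrix <- function(m, model = c("degree_proportional",
                                     "equiprobable")) {
  model <- match.arg(model)
  R <- nrow(m); C <- ncol(m)
  p <- switch(model,
    equiprobable = matrix(sum(m) / (R * C), R, C),
    degree_proportional = (matrix(rowSums(m) / C, R, C) +
                           matrix(colSums(m) / R, R, C, byrow = TRUE)) / 2)
  out <- matrix(as.integer(stats::runif(R * C) < p), R, C,
                dimnames = dimnames(m))
  out
}

#' Null-model significance test of NODF nestedness
#'
#' Monte Carlo test: the observed NODF is compared with NODF scores of
#' `n_reps` null matrices; the one-sided p-value (is the matrix more
#' nested than the null?) uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (n_reps + 1)`, so it is never
#' exactly zero.
#'
#' By default the null model's cell probabilities are derived from the
#' observed matrix itself (the usual plug-in practice). For calibration
#' studies — where the observed matrix is itself a draw from a known
#' null — `margins_from` supplies the reference matrix whose margins
#' define that null, making the test exactly exchangeable; the
#' degree-proportional plug-in is mildly anticonservative when the
#' observed matrix is a null draw, because its realised margins inherit
#' sampling noise.
#'
#' @param m binary incidence matrix.
#' @inheritParams null_matrix
#' @param n_reps number of null replicates (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @param margins_from matrix supplying the null model's margins;
#'   defaults to `m`.
#' @return an object of class `nodf_test`: `nodf`, `null_model`,
#'   `n_reps`, `null_mean`, `null_sd`, `p_value`, `null_values`.
#' @export
nodf_test <- function(m, model = c("degree_proportional", "equiprobable"),
                      n_reps = 1000, seed = NULL, margins_from = m) {
  model <- match.arg(model)
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (!all(dim(margins_from) == dim(m)))
    stop("margins_from must have the shape of m")
  obs <- nodf(m)
  if (!is.null(seed)) set.seed(seed)
  nulls <- vapply(seq_len(n_reps),
                  function(i) nodf_value(null_matrix(margins_from, model)),
                  0)
  structure(list(nodf = obs, null_model = model, n_reps = n_reps,
                 null_mean = mean(nulls), null_sd = stats::sd(nulls),
                 p_value = (1 + sum(nulls >= obs)) / (n_reps + 1),
                 null_values = nulls),
            class = "nodf_test")
}

#' @export
print.nodf_test <- function(x, ...) {
  cat("NODF nestedness test (", x$null_model, " null, ",
      x$n_reps, " reps)\n", sep = "")
  cat(sprintf("  NODF = %.2f   null mean = %.2f (sd %.2f)   P = %.4g\n",
              x$nodf, x$null_mean, x$null_sd, x$p_value))
  invisible(x)
}
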