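# Independent oracles and small fixture builders used across the suite.

# Brute-force NODF straight from the definition: loop over every
# unordered pair of rows and of columns; pairs with strictly decreasing
# fill contribute the percentage of the sparser line's 1s shared with
# the denser line, all other pairs contribute 0.
nodf_bruteforce <- function(m) {
  line_pairs <- function(mm) {
    n <- nrow(mm)
    vals <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      fi <- sum(mm[i, ]); fj <- sum(mm[j, ])
      if (fi == fj) { vals <- c(vals, 0); next }
      dense <- if (fi > fj) mm[i, ] else mm[j, ]
      sparse <- if (fi > fj) mm[j, ] else mm[i, ]
      vals <- c(vals, if (sum(sparse) == 0) 0 else
        100 * sum(dense == 1 & sparse == 1) / sum(sparse))
    }
    vals
  }
  vals <- c(line_pairs(m), line_pairs(t(m)))
  mean(vals)
}

# Row-orientation NODF component only (for the subset-flip property).
nodf_rows_bruteforce <- function(m) {
  n <- nrow(m)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    fi <- sum(m[i, ]); fj <- sum(m[j, ])
    if (fi == fj || min(fi, fj) == 0) { vals <- c(vals, 0); next }
    dense <- if (fi > fj) m[i, ] else m[j, ]
    sparse <- if (fi > fj) m[j, ] else m[i, ]
    vals <- c(vals, 100 * sum(dense & sparse) / sum(sparse))
  }
  if (!length(vals)) 0 else mean(vals)
}

# Closed-form OLS via the normal equations, independent of stats::lm.
ols_closed_form <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# A perfect stair matrix: line i's 1s are a prefix of line (i-1)'s,
# all fills distinct -> NODF = 100 by construction.
stair_matrix <- function(n) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) m[i, seq_len(n - i + 1L)] <- 1L
  m
}

# Five staggered species: a small community whose daily slices change
# composition as species enter and leave the season.
staggered_fixture <- function() {
  phen <- data.frame(
    species = c("P1", "P2", "A1", "A2", "A3"),
    guild = c("plant", "plant", rep("pollinator", 3)),
    start = c(165L, 185L, 165L, 180L, 200L),
    end = c(200L, 220L, 190L, 210L, 220L))
  phen$length <- phen$end - phen$start + 1L
  pairs <- data.frame(
    plant = c("P1", "P1", "P2", "P2"),
    pollinator = c("A1", "A2", "A2", "A3"))
  list(phenophases = phen, pairs = pairs, season = c(165L, 220L))
}

# Records whose inferred phenophases equal full-season spans for all
# species (every species observed on the first and last day it is used).
full_span_records <- function() {
  data.frame(day = c(165L, 234L, 165L, 234L, 165L, 234L),
             plant = c("P1", "P1", "P2", "P2", "P1", "P1"),
             pollinator = c("A1", "A1", "A2", "A2", "A2", "A2"))
}

# A network with given guild sizes where `n_tail` pollinators have one
# link each and the rest are linked to 3 plants (core).
core_tail_net <- function(n_poll, n_tail, n_plants = 4L) {
  plants <- sprintf("P%d", seq_len(n_plants))
  polls <- sprintf("A%d", seq_len(n_poll))
  tail_ids <- polls[seq_len(n_tail)]
  core_ids <- setdiff(polls, tail_ids)
  links <- rbind(
    if (n_tail > 0L) data.frame(plant = "P1", pollinator = tail_ids),
    do.call(rbind, lapply(core_ids, function(a)
      data.frame(plant = plants[1:3], pollinator = a))))
  phenonet:::new_bipartite_net(plants, polls, links, window = NULL)
}

write_temp_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
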