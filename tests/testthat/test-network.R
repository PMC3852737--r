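test_that("the activity rule controls link and species membership", {
  phen <- data.frame(species = c("P1", "A1"),
                     guild = c("plant", "pollinator"),
                     start = c(165L, 180L), end = c(200L, 220L),
                     length = c(36L, 41L))
  pairs <- data.frame(plant = "P1", pollinator = "A1")
  d190 <- build_network(phen, pairs, window = c(190L, 190L))
  expect_equal(nrow(d190$links), 1L)   # both active, overlap covers day
  d210 <- build_network(phen, pairs, window = c(210L, 210L))
  expect_equal(nrow(d210$links), 0L)   # plant left the season
  expect_false("P1" %in% d210$plants)
  expect_true("A1" %in% d210$pollinators)

  expect_error(build_network(phen, data.frame(plant = "P9",
                                              pollinator = "A1")),
               "P9")
})

test_that("a link needs overlap with the window, not just membership", {
  # the pair overlaps on days 180-185, entirely outside the window, so
  # the link (and the plant, whose phenophase has ended) is absent even
  # though the visitor is still active
  phen <- data.frame(species = c("P1", "A1"),
                     guild = c("plant", "pollinator"),
                     start = c(165L, 180L), end = c(185L, 220L),
                     length = c(21L, 41L))
  pairs <- data.frame(plant = "P1", pollinator = "A1")
  w <- build_network(phen, pairs, window = c(190L, 200L))
  expect_false("P1" %in% w$plants)
  expect_true("A1" %in% w$pollinators)
  expect_equal(nrow(w$links), 0L)
  # boundary day of the joint overlap: link present
  w2 <- build_network(phen, pairs, window = c(185L, 200L))
  expect_equal(nrow(w2$links), 1L)
})

test_that("daily slices union back to the static network", {
  fx <- staggered_fixture()
  static <- build_network(fx$phenophases, fx$pairs)
  slices <- slice_daily(fx$phenophases, fx$pairs, fx$season)
  expect_length(slices, diff(fx$season) + 1L)
  # oracle: enumerate every daily slice and union species and links
  u_plants <- sort(unique(unlist(lapply(slices, `[[`, "plants"))))
  u_polls <- sort(unique(unlist(lapply(slices, `[[`, "pollinators"))))
  u_links <- unique(do.call(rbind, lapply(slices, `[[`, "links")))
  expect_equal(u_plants, sort(static$plants))
  expect_equal(u_polls, sort(static$pollinators))
  expect_setequal(paste(u_links$plant, u_links$pollinator),
                  paste(static$links$plant, static$links$pollinator))
  # link sets change as species enter and leave
  n_links <- vapply(slices, function(n) nrow(n$links), 0L)
  expect_gt(length(unique(n_links)), 1L)
  # day before any phenophase: empty network
  pre <- build_network(fx$phenophases, fx$pairs, window = c(100L, 100L))
  expect_equal(length(pre$plants) + length(pre$pollinators), 0L)
})

test_that("identical full-season phenophases make every slice static", {
  rec <- full_span_records()
  phen <- infer_phenophases(rec)
  pairs <- unique(rec[, c("plant", "pollinator")])
  slices <- slice_daily(phen, pairs, c(165L, 234L))
  static <- build_network(phen, pairs)
  for (s in slices[c(1, 35, 70)])
    expect_setequal(paste(s$links$plant, s$links$pollinator),
                    paste(static$links$plant, static$links$pollinator))
})

test_that("windowed aggregation partitions the season", {
  fx <- staggered_fixture()
  season <- c(165L, 234L)                      # 70 days
  w10 <- aggregate_window(fx$phenophases, fx$pairs, 10, season)
  expect_length(w10, 7L)
  expect_equal(w10[[7]]$window, c(225L, 234L))
  w1 <- aggregate_window(fx$phenophases, fx$pairs, 1, fx$season)
  d <- slice_daily(fx$phenophases, fx$pairs, fx$season)
  expect_equal(unname(lapply(w1, `[[`, "links")),
               unname(lapply(d, `[[`, "links")))
  wall <- aggregate_window(fx$phenophases, fx$pairs, 56, fx$season)
  expect_length(wall, 1L)
  static <- build_network(fx$phenophases, fx$pairs)
  expect_equal(wall[[1]]$links, static$links)
  expect_error(aggregate_window(fx$phenophases, fx$pairs, 0, fx$season),
               ">= 1")
})

test_that("connectance is 100 I/(AP) with the study's worked values", {
  set.seed(11)
  all_pairs <- expand.grid(plant = sprintf("P%02d", 1:34),
                           pollinator = sprintf("A%02d", 1:78),
                           stringsAsFactors = FALSE)
  links <- all_pairs[sample.int(nrow(all_pairs), 295L), ]
  net <- phenonet:::new_bipartite_net(sprintf("P%02d", 1:34),
                                      sprintf("A%02d", 1:78), links)
  expect_equal(connectance(net), 100 * 295 / (78 * 34))
  expect_equal(phenonet:::round_half_up(connectance(net)), 11)

  tiny <- phenonet:::new_bipartite_net("P1", "A1",
                                       data.frame(plant = "P1",
                                                  pollinator = "A1"))
  expect_equal(connectance(tiny), 100)
  half <- core_tail_net(5, 0, 4)  # 5 pollinators x 4 plants, ...
  expect_true(connectance(half) <= 100)
  empty <- phenonet:::new_bipartite_net(character(0), "A1",
                                        data.frame(plant = character(0),
                                                   pollinator = character(0)))
  expect_error(connectance(empty), "empty guild")
})

test_that("linkage levels sum to the link count over either guild", {
  fx <- staggered_fixture()
  net <- build_network(fx$phenophases, fx$pairs)
  L <- linkage_level(net)
  I <- nrow(net$links)
  expect_equal(sum(L[net$plants]), I)       # oracle: count links twice
  expect_equal(sum(L[net$pollinators]), I)
  expect_equal(linkage_level(net, "P1"), 2L)
  expect_error(linkage_level(net, "Z9"), "unknown species")
})

test_that("core/tail is a partition at the L = 2 boundary", {
  net <- core_tail_net(6, 3, 4)  # 3 tail (L=1), 3 core (L=3), P4 isolated
  ct <- core_tail(net)
  expect_equal(sort(unique(ct$status)), c("core", "tail"))
  expect_equal(nrow(ct), length(net$plants) + length(net$pollinators))
  expect_true(all(ct$status[ct$L <= 2] == "tail"))
  expect_true(all(ct$status[ct$L > 2] == "core"))
  expect_true(ct$isolated[ct$species == "P4"])
  expect_equal(ct$status[ct$species == "P4"], "tail")
  # explicit boundary values
  expect_equal(unname(ifelse(c(2, 3) > 2, "core", "tail")),
               c("tail", "core"))
  b <- core_tail_net(4, 2, 4)
  bb <- core_tail(b)
  expect_true(all(bb$L[bb$status == "tail" & bb$guild == "pollinator"]
                  <= 2))
})

test_that("relative tail length matches the study's fractions", {
  net88 <- core_tail_net(88, 61, 4)
  expect_equal(relative_tail_length(net88, "pollinator"), 61 / 88)
  expect_equal(phenonet:::round_half_up(
    100 * relative_tail_length(net88, "pollinator")), 69)
  net0 <- core_tail_net(5, 0, 4)
  expect_equal(relative_tail_length(net0, "pollinator"), 0)
  # 8 tail of 32 plants -> 0.25 (by formula, not the printed 28%)
  plants <- sprintf("P%02d", 1:32)
  polls <- sprintf("A%02d", 1:9)
  links <- rbind(
    do.call(rbind, lapply(plants[1:24], function(p)
      data.frame(plant = p, pollinator = polls[1:3]))),
    data.frame(plant = plants[25:32], pollinator = polls[4]))
  net32 <- phenonet:::new_bipartite_net(plants, polls, links)
  expect_equal(relative_tail_length(net32, "plant"), 0.25)
})

test_that("phenophase-length regression matches closed-form least squares", {
  phen <- data.frame(species = c("A1", "A2", "A3", "P1"),
                     guild = c(rep("pollinator", 3), "plant"),
                     start = 1L, end = c(2L, 4L, 6L, 10L))
  phen$length <- phen$end - phen$start + 1L
  plants <- c("P1", "P2", "P3")
  links <- data.frame(plant = c("P1", "P1", "P2", "P1", "P2", "P3"),
                      pollinator = c("A1", "A2", "A2", "A3", "A3", "A3"))
  phen2 <- rbind(phen[phen$guild == "pollinator", ],
                 data.frame(species = plants, guild = "plant",
                            start = 1L, end = 10L, length = 10L))
  net2 <- phenonet:::new_bipartite_net(plants, c("A1", "A2", "A3"), links)
  fit <- phenophase_L_regression(phen2, net2)
  x <- as.numeric(linkage_level(net2))
  y <- phen2$length[match(names(linkage_level(net2)), phen2$species)]
  oracle <- ols_closed_form(x, as.numeric(y))
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-9)

  # synthetic community: against the closed-form oracle again
  sim <- simulate_phenonet(phenonet_config(seed = 5))
  tn <- temporal_network(sim$records)
  fit2 <- phenophase_L_regression(tn$phenophases, tn$static)
  L <- linkage_level(tn$static)
  xx <- as.numeric(L)
  yy <- as.numeric(tn$phenophases$length[match(names(L),
                                               tn$phenophases$species)])
  o2 <- ols_closed_form(xx, yy)
  expect_equal(fit2$r_squared, o2$r_squared, tolerance = 1e-9)
  expect_true(fit2$slope > 0)  # generalists persist longer

  # degenerate inputs
  same <- phen2; net_same <- phenonet:::new_bipartite_net(
    plants, c("A1", "A2", "A3"),
    data.frame(plant = rep(plants, each = 3),
               pollinator = rep(c("A1", "A2", "A3"), 3)))
  expect_error(phenophase_L_regression(same, net_same), "zero variance")
})

test_that("sequence summaries skip and count empty networks", {
  fx <- staggered_fixture()
  slices <- slice_daily(fx$phenophases, fx$pairs, c(160L, 220L))
  s <- network_summary(slices)
  expect_equal(attr(s, "n_empty"), 5L)   # days 160-164 precede the season
  expect_true(all(is.na(s$C[s$empty])))
  expect_false(anyNA(attr(s, "means")))
  expect_error(network_summary(slices[1:3]), "all networks are empty")
  one <- network_summary(build_network(fx$phenophases, fx$pairs))
  expect_equal(nrow(one), 1L)
  expect_equal(one$I, 4L)
})

test_that("daily tail counts fall well below the static tail count", {
  sim <- simulate_phenonet(phenonet_config(seed = 2))
  tn <- temporal_network(sim$records)
  st <- summary(tn)
  dy <- summary(tn, daily = TRUE)
  expect_lt(attr(dy, "means")[["tail_pollinators"]],
            st$tail_pollinators / 2)
})
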