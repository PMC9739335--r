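test_that("environment grid has the arithmetic extent and is seed-deterministic", {
  cfg <- scenario_config() # lon span 2 deg, lat span 3.9 deg at 0.05 deg
  env <- make_environment(cfg)
  expect_equal(env$n_cols, 40)
  expect_equal(env$n_rows, 78)
  env2 <- make_environment(cfg)
  expect_identical(env$layers, env2$layers)
  env3 <- make_environment(scenario_config(rng_seed = 99))
  expect_false(identical(env$layers$temp, env3$layers$temp))
})

test_that("gradient layer increases toward the northern edge", {
  env <- make_environment(small_config())
  expect_gt(mean(env$layers$temp[1, ]), mean(env$layers$temp[env$n_rows, ]))
  # west-east layer increases toward the east
  expect_gt(mean(env$layers$precip[, env$n_cols]),
            mean(env$layers$precip[, 1]))
})

test_that("true suitability peaks at the optimum and respects limits", {
  cfg <- small_config()
  env <- make_environment(cfg)
  s <- true_suitability(cfg, env, "A")
  expect_equal(max(s$values, na.rm = TRUE), 1)
  expect_true(all(s$values >= 0 & s$values <= 1, na.rm = TRUE))
  # infinite breadth in every layer -> flat surface of 1
  cfg_flat <- scenario_config(species = c("A", "B"),
                              niche_optima = cbind(temp = c(0.3, 0.7)),
                              niche_breadths = cbind(temp = c(Inf, Inf)),
                              rng_seed = 5)
  envf <- make_environment(cfg_flat)
  expect_true(all(true_suitability(cfg_flat, envf, "A")$values == 1))
  # identical niche parameters -> identical surfaces
  cfg_same <- scenario_config(species = c("A", "B"),
                              niche_optima = cbind(temp = c(0.5, 0.5)),
                              niche_breadths = cbind(temp = c(0.1, 0.1)),
                              rng_seed = 5)
  envs <- make_environment(cfg_same)
  expect_equal(true_suitability(cfg_same, envs, "A")$values,
               true_suitability(cfg_same, envs, "B")$values)
  expect_error(true_suitability(cfg, env, "Z"), "unknown species")
})

test_that("simulated occurrences stay on positive-suitability cells and are reproducible", {
  cfg <- small_config()
  env <- make_environment(cfg)
  occ <- simulate_occurrences(cfg, env, "B")
  expect_equal(nrow(occ), 60)
  vals <- ribarriers:::extract_env(env, occ$lon, occ$lat)
  suit <- true_suitability(cfg, env, "B")
  rc <- ribarriers:::grid_cell_of(env, occ$lon, occ$lat)
  expect_true(all(suit$values[cbind(rc[, "row"], rc[, "col"])] > 0))
  expect_identical(occ, simulate_occurrences(cfg, env, "B"))
  expect_error(simulate_occurrences(cfg, env, "B", n = 1e6), "exceeds")
})

test_that("an exhaustive draw samples every positive-suitability cell once", {
  cfg <- scenario_config(species = c("A", "B"),
                         grid_extent = c(34, 34.5, 31, 31.5),
                         grid_resolution = 0.1,
                         niche_optima = cbind(temp = c(0.5, 0.5)),
                         niche_breadths = cbind(temp = c(1, 1)),
                         n_presences = 25, env_noise_sd = 0, rng_seed = 3)
  env <- make_environment(cfg) # 5 x 5 grid, all cells positive
  occ <- simulate_occurrences(cfg, env, "A")
  rc <- ribarriers:::grid_cell_of(env, occ$lon, occ$lat)
  expect_equal(nrow(unique(as.data.frame(rc))), 25)
})

test_that("flowering onsets follow the configured truncated-normal regime", {
  cfg <- small_config(flowering_sd = 0.001,
                      flowering_mean = c(A = 40, B = 75, C = 110))
  expect_error(simulate_flowering(small_config(flowering_sd = 8), "A", 0),
               "n_records")
  # degenerate sd: every onset equals the rounded mean
  rec <- simulate_flowering(cfg, "A", 30, "garden")
  expect_true(all(rec$onset_day == round(cfg$flowering_mean[["A"]])))
  expect_true(all(rec$block %in% paste0("B", 1:4)))
  # bounds and determinism on a spread-out regime
  cfg2 <- small_config()
  rec2 <- simulate_flowering(cfg2, "B", 200, "wild")
  expect_true(all(rec2$onset_day >= 1 & rec2$onset_day <= cfg2$season_length))
  expect_identical(rec2, simulate_flowering(cfg2, "B", 200, "wild"))
})

test_that("well-separated flowering means give near-zero weekly overlap, identical ones near one", {
  cfg <- scenario_config(species = c("early", "late"),
                         flowering_mean = c(early = 30, late = 90),
                         flowering_sd = 5, season_length = 150,
                         rng_seed = 21)
  rec <- rbind(simulate_flowering(cfg, "early", 10000, "garden"),
               simulate_flowering(cfg, "late", 10000, "garden"))
  d <- phenology_overlap(
    phenology_distribution(rec, "early", "garden"),
    phenology_distribution(rec, "late", "garden"))
  expect_lt(d, 0.01)

  cfg2 <- scenario_config(species = c("one", "two"),
                          flowering_mean = c(one = 60, two = 60),
                          flowering_sd = 5, season_length = 150,
                          rng_seed = 22)
  rec2 <- rbind(simulate_flowering(cfg2, "one", 10000, "garden"),
                simulate_flowering(cfg2, "two", 10000, "garden"))
  d2 <- phenology_overlap(
    phenology_distribution(rec2, "one", "garden"),
    phenology_distribution(rec2, "two", "garden"))
  expect_gt(d2, 0.95)
})

test_that("cross records respect count invariants and degenerate probabilities", {
  cfg <- small_config(fruit_prob_within = 0, fruit_prob_between = 0.5)
  cr <- simulate_crosses(cfg, "A", "A", 20)
  expect_equal(cr$n_fruits, 0L)
  expect_equal(cr$n_seeds_total, 0L)
  expect_equal(cr$treatment, "within")

  cfg2 <- small_config()
  tab <- simulate_cross_table(cfg2, acceptors = "A", n_within = 10,
                              n_between = 7, n_batches = 3)
  expect_true(all(tab$n_fruits <= tab$n_pollinations))
  expect_true(all(tab$n_seeds_viable <= tab$n_seeds_total))
  expect_true(all(tab$n_pollen_germinated <= tab$n_pollen_total))
  expect_true(all((tab$treatment == "within") == (tab$acceptor == tab$donor)))
  expect_equal(sum(tab$n_pollinations[tab$treatment == "within"]), 10)
  expect_error(simulate_crosses(cfg2, "A", "Z", 5), "unknown species")
})

test_that("blocked heterospecific pollen makes the pollen barrier absolute", {
  cfg <- small_config(pollen_germ_within = 0.6, pollen_germ_between = 0)
  tab <- simulate_cross_table(cfg, acceptors = "A")
  cs <- cross_summaries(tab, "A", "B")
  expect_gt(cs$Gw, 0)
  expect_equal(cs$Gb, 0)
  expect_equal(ri_asymmetric(cs$Gw, cs$Gb), 1)
})

test_that("simulated trees are valid Newick, reproducible, with matching leaves", {
  nwk <- simulate_tree(2, rng_seed = 7, labels = c("A", "B"))
  expect_match(nwk, "^\\(.*:.*,.*:.*\\);$")
  tr <- parse_newick(nwk)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_true(all(tr$edge.length > 0))
  expect_identical(simulate_tree(8, rng_seed = 5), simulate_tree(8, rng_seed = 5))
  expect_equal(length(parse_newick(simulate_tree(8, rng_seed = 5))$tip.label), 8)
  expect_error(simulate_tree(1), "at least two")
})
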