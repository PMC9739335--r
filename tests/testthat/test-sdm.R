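test_that("pseudo-absences honor the ratio and the exclusion buffer", {
  cfg <- small_config()
  env <- make_environment(cfg)
  pres <- simulate_occurrences(cfg, env, "A", n = 10)
  abs <- generate_pseudo_absences(pres, env, buffer_deg = 0.15, ratio = 4,
                                  rng_seed = 2)
  expect_equal(nrow(abs), 40)
  dmin <- vapply(seq_len(nrow(abs)), function(i) {
    min(sqrt((abs$lon[i] - pres$lon)^2 + (abs$lat[i] - pres$lat)^2))
  }, numeric(1))
  expect_true(all(dmin > 0.15))
  expect_equal(unique(abs$role), "pseudo_absence")
})

test_that("a zero buffer excludes exactly the presence-occupied cells", {
  cfg <- small_config()
  env <- make_environment(cfg)
  pres <- simulate_occurrences(cfg, env, "A", n = 5)
  occ_cells <- unique(as.data.frame(ribarriers:::grid_cell_of(env, pres$lon,
                                                              pres$lat)))
  n_eligible <- env$n_rows * env$n_cols - nrow(occ_cells)
  abs <- generate_pseudo_absences(pres, env, buffer_deg = 0,
                                  ratio = n_eligible %/% 5, rng_seed = 2)
  abs_cells <- as.data.frame(ribarriers:::grid_cell_of(env, abs$lon, abs$lat))
  expect_equal(nrow(merge(abs_cells, occ_cells)), 0)
})

test_that("an impossible absence request errors with the shortfall", {
  cfg <- small_config()
  env <- make_environment(cfg)
  pres <- simulate_occurrences(cfg, env, "A", n = 50)
  expect_error(
    generate_pseudo_absences(pres, env, buffer_deg = 10, ratio = 4),
    "short by")
})

test_that("AUC matches rank-based enumeration, handles ties, rejects one class", {
  expect_equal(evaluate_auc(c(0.9, 0.8), c(1, 0)), 1)
  expect_equal(evaluate_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  # enumerate the 4 presence-absence pairs: 3 concordant of 4
  expect_equal(evaluate_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_error(evaluate_auc(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(31)
  for (i in 1:20) {
    s <- rnorm(40)
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(evaluate_auc(exp(s), l), evaluate_auc(s, l))
    expect_equal(evaluate_auc(qlogis(plogis(s)), l), evaluate_auc(s, l))
  }
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(17)
  scores <- runif(200)
  aucs <- replicate(200, {
    evaluate_auc(scores, sample(rep(c(0, 1), each = 100)))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("TSS scans thresholds correctly and is bounded", {
  expect_equal(evaluate_tss(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1)),
               list(tss = 1, threshold = 0.5))
  expect_equal(evaluate_tss(c(0.3, 0.3, 0.3), c(0, 1, 0))$tss, 0)
  # exhaustive scan oracle on random score sets
  set.seed(23)
  for (i in 1:20) {
    s <- round(runif(30), 2)
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    got <- evaluate_tss(s, l)
    u <- sort(unique(s))
    brute <- if (length(u) < 2) 0 else max(vapply(
      (u[-length(u)] + u[-1]) / 2,
      function(t) mean(s[l == 1] >= t) + mean(s[l == 0] < t) - 1, numeric(1)))
    expect_equal(got$tss, max(brute, if (length(u) < 2) 0 else -Inf))
    expect_true(got$tss >= -1 && got$tss <= 1)
  }
})

test_that("the SDM separates a clean one-predictor gradient", {
  # presences strictly higher on one predictor than absences
  k <- 10
  env <- env_grid(c(0, 1, 0, 1), 1 / k,
                  layers = list(g = matrix(seq(1, 0, length.out = k),
                                           k, k)))
  pres <- data.frame(species = "S",
                     lon = runif(30, 0, 1), lat = runif(30, 0.75, 0.95))
  abs <- data.frame(species = "S",
                    lon = runif(30, 0, 1), lat = runif(30, 0.05, 0.25))
  fit <- fit_sdm(pres, abs, env, rng_seed = 4)
  expect_gt(fit$coefficients[["g"]], 0) # monotone likelihood: positive slope
  expect_equal(fit$auc, 1)              # perfectly separated held-out data
  expect_equal(fit$tss, 1)
})

test_that("predicted surfaces invert the logit cell by cell", {
  k <- 4
  env <- env_grid(c(0, 0.4, 0, 0.4), 0.1,
                  layers = list(a = matrix(seq(-2, 2, length.out = k * k), k, k),
                                b = matrix(1, k, k)))
  fit0 <- list(species = "S",
               coefficients = c("(Intercept)" = 0, a = 0, b = 0),
               predictor_names = c("a", "b"))
  expect_true(all(predict_surface(fit0, env)$values == 0.5))
  fit_sat <- list(species = "S",
                  coefficients = c("(Intercept)" = 1e4, a = 0, b = 0),
                  predictor_names = c("a", "b"))
  expect_true(all(predict_surface(fit_sat, env)$values > 1 - 1e-12))
  fit1 <- list(species = "S",
               coefficients = c("(Intercept)" = 0.5, a = -1.2, b = 2),
               predictor_names = c("a", "b"))
  surf <- predict_surface(fit1, env)
  for (cell in list(c(1, 1), c(2, 3), c(4, 4))) {
    manual <- plogis(0.5 - 1.2 * env$layers$a[cell[1], cell[2]] + 2)
    expect_equal(surf$values[cell[1], cell[2]], manual)
  }
  expect_error(predict_surface(list(predictor_names = "zzz",
                                    coefficients = c("(Intercept)" = 0, zzz = 1)),
                               env),
               "lacks predictor")
})

test_that("masked cells propagate as NA through prediction", {
  k <- 5
  mask <- matrix(TRUE, k, k); mask[1, 1] <- FALSE
  env <- env_grid(c(0, 0.5, 0, 0.5), 0.1,
                  layers = list(g = matrix(0, k, k)), mask = mask)
  fit <- list(species = "S", coefficients = c("(Intercept)" = 0, g = 1),
              predictor_names = "g")
  surf <- predict_surface(fit, env)
  expect_true(is.na(surf$values[1, 1]))
  expect_equal(sum(is.na(surf$values)), 1)
})
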