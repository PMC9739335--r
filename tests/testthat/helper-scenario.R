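# Small scenarios used across tests: fast to simulate, fully deterministic.

small_config <- function(n_species = 3, seed = 11, n_presences = 60, ...) {
  scenario_config(species = LETTERS[seq_len(n_species)],
                  grid_extent = c(34, 35.6, 31, 33),
                  grid_resolution = 0.1,
                  n_presences = n_presences,
                  rng_seed = seed,
                  ...)
}

# Two species with moderately overlapping niches (optima 3 breadths apart,
# true D about 0.13), the identifiable regime for overlap-recovery
# experiments: occurrence prevalence stays low enough that the logistic
# surface is not saturated inside the niche band.
recovery_config <- function(seed, n_presences = 500) {
  scenario_config(species = c("X", "Y"),
                  niche_optima = cbind(temp = c(0.35, 0.65),
                                       precip = c(0.5, 0.5)),
                  niche_breadths = cbind(temp = c(0.1, 0.1),
                                         precip = c(Inf, Inf)),
                  n_presences = n_presences,
                  rng_seed = seed)
}

# Species with strongly overlapping niches and flowering seasons, so that
# D matrices and cascade totals carry real variation between pairs.
overlap_config <- function(n_species = 3, seed = 11, n_presences = 30) {
  sp <- LETTERS[seq_len(n_species)]
  scenario_config(species = sp,
                  grid_extent = c(34, 35.6, 31, 33),
                  grid_resolution = 0.1,
                  niche_optima = cbind(temp = seq(0.35, 0.65,
                                                  length.out = n_species)),
                  niche_breadths = cbind(temp = rep(0.12, n_species)),
                  flowering_mean = stats::setNames(
                    seq(60, 90, length.out = n_species), sp),
                  n_presences = n_presences,
                  rng_seed = seed)
}

# Uniform surface over a k x k grid, optionally pre-normalized.
flat_surface <- function(k = 4, value = 1, species = "S") {
  suitability_surface(species, matrix(value, k, k),
                      extent = c(0, k * 0.1, 0, k * 0.1), resolution = 0.1)
}
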