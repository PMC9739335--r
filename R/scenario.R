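#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every parameter the generator needs to emulate a multi-species
#' study system: a rectangular study region with environmental gradients,
#' per-species Gaussian niches, truncated-normal flowering-onset
#' distributions, and binomial outcomes of within- and between-species
#' hand pollinations. The defaults describe an eight-species complex
#' distributed along a north--south gradient (the regime of the royal
#' irises of the southern Levant): well-separated niche bands, a single
#' 150-day flowering season with one early- and one late-flowering
#' species, and no intrinsic post-pollination deficit for heterospecific
#' pollen (within- and between-species success probabilities equal).
#'
#' @param species Character vector of species labels (>= 2).
#' @param grid_extent Numeric `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees.
#' @param grid_resolution Cell size in degrees (> 0).
#' @param niche_optima Numeric matrix, species x niche layers (columns named
#'   after environmental layers), giving each species' optimum in layer
#'   units. Default: optima evenly spaced along the `temp` gradient at
#'   `(i - 0.5)/n`, all species sharing the central `precip` value.
#' @param niche_breadths Matrix of the same shape: Gaussian niche standard
#'   deviations in layer units; `Inf` means the layer does not constrain the
#'   species. Default: `temp` breadth = one quarter of the inter-optimum
#'   spacing; `precip` unconstrained.
#' @param n_presences Presence points per species (scalar or named vector).
#' @param env_noise_sd Standard deviation of the smooth spatial noise added
#'   to gradient layers (layer units).
#' @param flowering_mean Mean flowering-onset day per species (named vector,
#'   day of season). The 8-species default places one species early
#'   (day 35), one late (day 118) and the rest between days 65 and 85.
#' @param flowering_sd Onset standard deviation in days (> 0).
#' @param season_length Length of the flowering season in days.
#' @param n_blocks Number of spatial blocks for garden records.
#' @param year_effect_sd SD (days) of the additive per-year shift applied to
#'   wild flowering records.
#' @param fruit_prob_within,fruit_prob_between Per-acceptor fruit-set
#'   probability for within-/between-species pollinations.
#' @param seed_viab_within,seed_viab_between Per-acceptor seed-viability
#'   probabilities.
#' @param pollen_germ_within,pollen_germ_between Per-acceptor
#'   pollen-germination probabilities.
#' @param seeds_per_fruit_mean Mean seed count per fruit (Poisson).
#' @param pollen_per_stigma Mean pollen grains deposited per pollination
#'   (Poisson), used for germination counts.
#' @param cross_acceptors Species used as pollen acceptors in cross
#'   experiments (the study design uses a subset of abundant species).
#' @param rng_seed Integer root seed; every generator derives its stream
#'   from it, so a scenario is fully reproducible.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config()
#' cfg$species
#' @export
scenario_config <- function(species = c("atrofusca", "atropurpurea",
                                        "bismarckiana", "haynei", "hermona",
                                        "lortetii", "mariae", "petrana"),
                            grid_extent = c(34, 36, 29.4, 33.3),
                            grid_resolution = 0.05,
                            niche_optima = NULL,
                            niche_breadths = NULL,
                            n_presences = 300,
                            env_noise_sd = 0.01,
                            flowering_mean = NULL,
                            flowering_sd = 8,
                            season_length = 150,
                            n_blocks = 4,
                            year_effect_sd = 3,
                            fruit_prob_within = 0.85,
                            fruit_prob_between = 0.85,
                            seed_viab_within = 0.8,
                            seed_viab_between = 0.8,
                            pollen_germ_within = 0.55,
                            pollen_germ_between = 0.55,
                            seeds_per_fruit_mean = 30,
                            pollen_per_stigma = 60,
                            cross_acceptors = NULL,
                            rng_seed = 1L) {
  species <- as.character(species)
  n <- length(species)
  if (n < 2L) stop("a scenario needs at least two species")
  if (anyDuplicated(species)) stop("species labels must be unique")

  if (length(grid_extent) != 4L ||
      grid_extent[2] <= grid_extent[1] || grid_extent[4] <= grid_extent[3]) {
    stop("grid_extent must be c(lon_min, lon_max, lat_min, lat_max) with positive spans")
  }
  if (!is.numeric(grid_resolution) || grid_resolution <= 0) {
    stop("grid_resolution must be > 0")
  }

  if (is.null(niche_optima)) {
    spacing <- 1 / n
    niche_optima <- cbind(temp = (seq_len(n) - 0.5) * spacing,
                          precip = rep(0.5, n))
    rownames(niche_optima) <- species
    if (is.null(niche_breadths)) {
      niche_breadths <- cbind(temp = rep(spacing / 4, n),
                              precip = rep(Inf, n))
      rownames(niche_breadths) <- species
    }
  }
  niche_optima <- as.matrix(niche_optima)
  niche_breadths <- as.matrix(niche_breadths)
  if (is.null(rownames(niche_optima))) rownames(niche_optima) <- species
  if (is.null(rownames(niche_breadths))) rownames(niche_breadths) <- species
  if (!identical(dim(niche_optima), dim(niche_breadths)) ||
      !identical(colnames(niche_optima), colnames(niche_breadths))) {
    stop("niche_optima and niche_breadths must have identical shape and layer names")
  }
  if (!all(species %in% rownames(niche_optima))) {
    stop("niche_optima must have one row per species")
  }
  if (any(niche_breadths <= 0)) stop("niche breadths must be > 0")

  if (is.null(flowering_mean)) {
    if (n == 8L) {
      flowering_mean <- c(70, 35, 75, 80, 72, 118, 65, 70)
    } else {
      flowering_mean <- season_length * seq(0.25, 0.75, length.out = n)
    }
    names(flowering_mean) <- species
  }
  if (is.null(names(flowering_mean))) names(flowering_mean) <- species
  if (!all(species %in% names(flowering_mean))) {
    stop("flowering_mean must name every species")
  }
  if (any(flowering_sd <= 0)) stop("flowering_sd must be > 0")
  if (season_length < 1) stop("season_length must be >= 1")

  probs <- list(fruit_prob_within = fruit_prob_within,
                fruit_prob_between = fruit_prob_between,
                seed_viab_within = seed_viab_within,
                seed_viab_between = seed_viab_between,
                pollen_germ_within = pollen_germ_within,
                pollen_germ_between = pollen_germ_between)
  for (nm in names(probs)) {
    if (any(probs[[nm]] < 0 | probs[[nm]] > 1)) {
      stop(sprintf("'%s' must lie in [0, 1]", nm))
    }
  }
  if (seeds_per_fruit_mean <= 0) stop("seeds_per_fruit_mean must be > 0")
  if (any(n_presences < 1)) stop("n_presences must be >= 1")

  if (is.null(cross_acceptors)) {
    cross_acceptors <- if (n == 8L) {
      intersect(c("atropurpurea", "mariae", "petrana"), species)
    } else {
      species
    }
  }
  if (!all(cross_acceptors %in% species)) {
    stop("cross_acceptors must be a subset of species")
  }

  structure(list(species = species,
                 grid_extent = as.numeric(grid_extent),
                 grid_resolution = grid_resolution,
                 niche_optima = niche_optima,
                 niche_breadths = niche_breadths,
                 n_presences = n_presences,
                 env_noise_sd = env_noise_sd,
                 flowering_mean = flowering_mean,
                 flowering_sd = flowering_sd,
                 season_length = as.integer(season_length),
                 n_blocks = as.integer(n_blocks),
                 year_effect_sd = year_effect_sd,
                 fruit_prob_within = fruit_prob_within,
                 fruit_prob_between = fruit_prob_between,
                 seed_viab_within = seed_viab_within,
                 seed_viab_between = seed_viab_between,
                 pollen_germ_within = pollen_germ_within,
                 pollen_germ_between = pollen_germ_between,
                 seeds_per_fruit_mean = seeds_per_fruit_mean,
                 pollen_per_stigma = pollen_per_stigma,
                 cross_acceptors = cross_acceptors,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario configuration\n")
  cat(sprintf("  species      : %s\n", paste(x$species, collapse = ", ")))
  cat(sprintf("  extent       : lon [%g, %g], lat [%g, %g] at %g deg\n",
              x$grid_extent[1], x$grid_extent[2], x$grid_extent[3],
              x$grid_extent[4], x$grid_resolution))
  cat(sprintf("  presences    : %s per species\n",
              paste(unique(x$n_presences), collapse = "/")))
  cat(sprintf("  season       : %d days, onset sd %g\n",
              x$season_length, x$flowering_sd[1]))
  cat(sprintf("  acceptors    : %s\n", paste(x$cross_acceptors, collapse = ", ")))
  cat(sprintf("  rng_seed     : %d\n", x$rng_seed))
  invisible(x)
}
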