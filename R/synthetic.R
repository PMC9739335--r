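#' Simulate presence points for one species
#'
#' Draws `n` grid cells without replacement with probability proportional to
#' the species' ground-truth suitability, then places one point in each
#' drawn cell, jittered uniformly within the cell. Cell-level sampling keeps
#' the pseudo-absence buffer rule well defined for any point pattern.
#'
#' @param config A [scenario_config()].
#' @param env The environment grid.
#' @param species Species label.
#' @param n Number of presences (default: the config's `n_presences` for
#'   this species).
#' @return A data frame with columns `species`, `lon`, `lat`, `role`
#'   (`"presence"`); deterministic given `config$rng_seed`.
#' @export
simulate_occurrences <- function(config, env, species, n = NULL) {
  suit <- true_suitability(config, env, species)
  n <- n %||% lookup_param(config$n_presences, species, "n_presences")
  pos <- which(suit$values > 0 & env$mask)
  if (n > length(pos)) {
    stop(sprintf("n_presences (%d) exceeds the %d cells with positive suitability for '%s'",
                 n, length(pos), species))
  }
  res <- env$resolution
  with_seed(derive_seed(config$rng_seed, "occurrences", species), {
    cells <- if (length(pos) == 1L) pos else {
      sample(pos, n, replace = FALSE, prob = suit$values[pos])
    }
    row <- (cells - 1L) %% env$n_rows + 1L
    col <- (cells - 1L) %/% env$n_rows + 1L
    data.frame(species = species,
               lon = env$lon[col] + stats::runif(n, -res / 2, res / 2),
               lat = env$lat[row] + stats::runif(n, -res / 2, res / 2),
               role = "presence",
               stringsAsFactors = FALSE)
  })
}

# Additive shift applied to every record of a given year (wild source);
# shared across species so that a "late year" is late for everyone.
year_shift <- function(config, year) {
  if (config$year_effect_sd <= 0) return(0)
  with_seed(derive_seed(config$rng_seed, "year", year),
            stats::rnorm(1, 0, config$year_effect_sd))
}

#' Simulate flowering-onset records
#'
#' Onset days are `round(Normal(mean, sd))` truncated to
#' `[1, season_length]`. Garden records belong to a single season and are
#' assigned spatial blocks round-robin; wild records are spread over a span
#' of years, each year carrying a shared additive shift drawn with sd
#' `year_effect_sd`.
#'
#' @param config A [scenario_config()].
#' @param species Species label.
#' @param n_records Number of plants recorded (>= 1).
#' @param source `"garden"` or `"wild"`.
#' @param years Candidate observation years (wild source only).
#' @return A data frame with columns `record_id`, `species`, `onset_day`,
#'   `source`, `year`, `block`.
#' @export
simulate_flowering <- function(config, species, n_records,
                               source = c("garden", "wild"),
                               years = 2010:2015) {
  source <- match.arg(source)
  if (!species %in% config$species) stop(sprintf("unknown species '%s'", species))
  if (n_records < 1) stop("n_records must be >= 1")
  sd <- lookup_param(config$flowering_sd, species, "flowering_sd")
  if (sd <= 0) stop("flowering_sd must be > 0")
  mu <- lookup_param(config$flowering_mean, species, "flowering_mean")
  with_seed(derive_seed(config$rng_seed, "flowering", species, source), {
    if (source == "garden") {
      yr <- rep(2017L, n_records)
      shift <- 0
      block <- paste0("B", (seq_len(n_records) - 1L) %% config$n_blocks + 1L)
    } else {
      yr <- sample(years, n_records, replace = TRUE)
      shift <- vapply(yr, function(y) year_shift(config, y), numeric(1))
      block <- NA_character_
    }
    onset <- round(stats::rnorm(n_records, mu + shift, sd))
    onset <- pmin(pmax(onset, 1), config$season_length)
    data.frame(record_id = sprintf("%s_%s_%03d", species, source,
                                   seq_len(n_records)),
               species = species,
               onset_day = as.integer(onset),
               source = source,
               year = as.integer(yr),
               block = block,
               stringsAsFactors = FALSE)
  })
}

#' Simulate one hand-pollination cross record
#'
#' Fruit set is binomial over pollinated flowers; each fruit carries a
#' Poisson seed count of which a binomial fraction is viable; pollen
#' germination is binomial over a Poisson total of deposited grains. The
#' within/between parameter set is chosen by the treatment implied by the
#' acceptor/donor pair.
#'
#' @param config A [scenario_config()].
#' @param acceptor,donor Species labels (equal labels = within-species
#'   treatment).
#' @param n_pollinations Number of pollinated flowers.
#' @param replicate Integer tag separating repeated records of the same
#'   pair (enters the derived RNG stream).
#' @return A one-row data frame with the cross-record schema
#'   (`acceptor, donor, treatment, n_pollinations, n_fruits, n_seeds_total,
#'   n_seeds_viable, n_pollen_total, n_pollen_germinated`).
#' @export
simulate_crosses <- function(config, acceptor, donor, n_pollinations,
                             replicate = 1L) {
  if (!acceptor %in% config$species || !donor %in% config$species) {
    stop(sprintf("unknown species pair '%s' x '%s'", acceptor, donor))
  }
  treatment <- if (acceptor == donor) "within" else "between"
  sfx <- if (treatment == "within") "within" else "between"
  p_fruit <- lookup_param(config[[paste0("fruit_prob_", sfx)]], acceptor,
                          paste0("fruit_prob_", sfx))
  p_viab <- lookup_param(config[[paste0("seed_viab_", sfx)]], acceptor,
                         paste0("seed_viab_", sfx))
  p_germ <- lookup_param(config[[paste0("pollen_germ_", sfx)]], acceptor,
                         paste0("pollen_germ_", sfx))
  with_seed(derive_seed(config$rng_seed, "cross", acceptor, donor, replicate), {
    n_fruits <- stats::rbinom(1, n_pollinations, p_fruit)
    n_seeds <- if (n_fruits > 0) {
      sum(stats::rpois(n_fruits, config$seeds_per_fruit_mean))
    } else 0L
    n_viable <- stats::rbinom(1, n_seeds, p_viab)
    n_pollen <- stats::rpois(1, config$pollen_per_stigma * n_pollinations)
    n_germ <- stats::rbinom(1, n_pollen, p_germ)
    data.frame(acceptor = acceptor, donor = donor, treatment = treatment,
               n_pollinations = as.integer(n_pollinations),
               n_fruits = as.integer(n_fruits),
               n_seeds_total = as.integer(n_seeds),
               n_seeds_viable = as.integer(n_viable),
               n_pollen_total = as.integer(n_pollen),
               n_pollen_germinated = as.integer(n_germ),
               stringsAsFactors = FALSE)
  })
}

#' Simulate the full cross-experiment table
#'
#' One within-species series per acceptor plus one between-species series
#' per acceptor x donor pair, each split into `n_batches` records to
#' exercise pooled summaries, following the study design in which only a
#' subset of abundant species serves as pollen acceptors.
#'
#' @param config A [scenario_config()].
#' @param acceptors Acceptor species (default `config$cross_acceptors`).
#' @param n_within,n_between Pollinations per within-series and per
#'   between-pair.
#' @param n_batches Records each series is split into.
#' @return A cross-record data frame.
#' @export
simulate_cross_table <- function(config, acceptors = config$cross_acceptors,
                                 n_within = 40, n_between = 16,
                                 n_batches = 2) {
  split_n <- function(n) {
    base <- n %/% n_batches
    out <- rep(base, n_batches)
    out[seq_len(n - base * n_batches)] <- base + 1L
    out[out > 0]
  }
  rows <- list()
  for (a in acceptors) {
    donors <- c(a, setdiff(config$species, a))
    for (d in donors) {
      n <- if (a == d) n_within else n_between
      sizes <- split_n(n)
      for (b in seq_along(sizes)) {
        rows[[length(rows) + 1L]] <-
          simulate_crosses(config, a, d, sizes[b], replicate = b)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a random phylogeny
#'
#' A random bifurcating tree with positive branch lengths over the scenario
#' species, returned as a Newick string (a stand-in for an externally
#' estimated phylogeny; no inference is performed).
#'
#' @param n_species Number of leaves (>= 2), or leave default and pass
#'   `labels`.
#' @param rng_seed Integer seed.
#' @param labels Optional leaf labels (length `n_species`).
#' @return A single Newick string with branch lengths.
#' @examples
#' simulate_tree(3, rng_seed = 1)
#' @export
simulate_tree <- function(n_species, rng_seed = 1L, labels = NULL) {
  if (!is.null(labels)) n_species <- length(labels)
  if (n_species < 2) stop("a tree needs at least two species")
  with_seed(derive_seed(rng_seed, "tree"), {
    tr <- ape::rtree(n_species, tip.label = labels)
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    ape::write.tree(tr)
  })
}
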