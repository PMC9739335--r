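#' Stage parameters for the RI pipeline
#'
#' Defaults follow the conventional settings of the analysis: a 0.05-degree
#' pseudo-absence buffer at a 4:1 absence:presence ratio, a stratified
#' 70/30 train/test split, weekly phenology bins, and exclusion of
#' cross-experiment pairs with fewer than 5 pollinations.
#'
#' @param buffer_deg Pseudo-absence exclusion buffer (degrees).
#' @param pa_ratio Pseudo-absences per presence.
#' @param train_fraction SDM training fraction.
#' @param week_length_days Phenology bin width (days).
#' @param min_n Minimum pollination count per cross treatment x pair.
#' @param pooled Pool between-species cross fractions across donors?
#' @param n_permutations Mantel permutations.
#' @param trim_quantile Symmetric quantile trim for wild flowering onsets
#'   (0 = off).
#' @param n_flowering_garden,n_flowering_wild Flowering records simulated
#'   per species and source.
#' @param n_within,n_between Pollinations per within-series / between-pair
#'   in the simulated cross table.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(buffer_deg = 0.05, pa_ratio = 4,
                            train_fraction = 0.7, week_length_days = 7,
                            min_n = 5, pooled = TRUE, n_permutations = 999,
                            trim_quantile = 0, n_flowering_garden = 50,
                            n_flowering_wild = 80, n_within = 40,
                            n_between = 16) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full reproductive-isolation pipeline
#'
#' Orchestrates simulate -> SDM -> overlap -> barriers -> cascade ->
#' association on a synthetic scenario: simulates the environment,
#' occurrences, flowering records, cross experiment and phylogeny; fits one
#' SDM per species and predicts its probability surface; computes the
#' eco-geographic and the two phenological D matrices; assembles per-barrier
#' RI and cascades it into total RI per directed pair (once per phenology
#' source); and tests total RI against patristic distance with a Mantel
#' test. A failing stage stops the run with the stage named.
#'
#' All randomness derives from `config$rng_seed`; rerunning an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [scenario_config()].
#' @param params A [pipeline_params()] list.
#' @param out_dir Optional directory; when given, every intermediate and
#'   final table is written (CSV / `.asc` / `.nwk` / JSON-free plain text)
#'   and a manifest of MD5 checksums is included in the result.
#' @param include_crosses Set `FALSE` to skip the cross-experiment stage:
#'   all asymmetric barriers become missing and totals rest on the two
#'   pre-pollination barriers alone.
#' @return A list of class `ri_pipeline_run` with the per-stage results
#'   (`env`, `occurrences`, `sdm`, `surfaces`, `d_eco`, `d_phen_garden`,
#'   `d_phen_wild`, `barriers_*`, `cascades_*`, `ri_table`, `assoc`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = scenario_config(),
                         params = pipeline_params(),
                         out_dir = NULL,
                         include_crosses = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  res <- list(config = config, params = params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  res$env <- stage("simulate", make_environment(config))
  res$occurrences <- stage("simulate", do.call(rbind, lapply(
    config$species, function(sp) simulate_occurrences(config, res$env, sp))))
  res$flowering <- stage("simulate", do.call(rbind, c(
    lapply(config$species, function(sp)
      simulate_flowering(config, sp, params$n_flowering_garden, "garden")),
    lapply(config$species, function(sp)
      simulate_flowering(config, sp, params$n_flowering_wild, "wild")))))
  res$crosses <- if (include_crosses) {
    stage("simulate", simulate_cross_table(config,
                                           n_within = params$n_within,
                                           n_between = params$n_between))
  } else NULL
  res$tree <- stage("simulate", parse_newick(
    simulate_tree(rng_seed = derive_seed(config$rng_seed, "tree-stage"),
                  labels = config$species)))

  res$sdm <- stage("sdm", lapply(stats::setNames(nm = config$species),
    function(sp) {
      pres <- res$occurrences[res$occurrences$species == sp, , drop = FALSE]
      abs <- generate_pseudo_absences(
        pres, res$env, buffer_deg = params$buffer_deg, ratio = params$pa_ratio,
        rng_seed = derive_seed(config$rng_seed, "absences", sp))
      fit_sdm(pres, abs, res$env, train_fraction = params$train_fraction,
              rng_seed = derive_seed(config$rng_seed, "split", sp))
    }))
  res$surfaces <- stage("sdm", lapply(res$sdm, predict_surface, env = res$env))

  res$d_eco <- stage("overlap", eco_overlap_matrix(res$surfaces))
  res$d_phen_garden <- stage("overlap", phenology_overlap_matrix(
    res$flowering, config$species, "garden",
    week_length_days = params$week_length_days))
  res$d_phen_wild <- stage("overlap", phenology_overlap_matrix(
    res$flowering, config$species, "wild",
    week_length_days = params$week_length_days,
    trim_quantile = params$trim_quantile))

  res$barriers_garden <- stage("barriers", assemble_barriers(
    res$d_eco, res$d_phen_garden, res$crosses, config$species, "garden",
    min_n = params$min_n, pooled = params$pooled))
  res$barriers_wild <- stage("barriers", assemble_barriers(
    res$d_eco, res$d_phen_wild, res$crosses, config$species, "wild",
    min_n = params$min_n, pooled = params$pooled))

  res$cascades_garden <- stage("cascade", ri_cascades(res$barriers_garden))
  res$cascades_wild <- stage("cascade", ri_cascades(res$barriers_wild))
  res$ri_table <- stage("cascade", build_ri_table(
    res$cascades_garden$totals, res$cascades_wild$totals, config$species))

  ri_dir <- function(totals) {
    m <- matrix(NA_real_, length(config$species), length(config$species),
                dimnames = list(config$species, config$species))
    for (i in seq_len(nrow(totals))) {
      m[totals$acceptor[i], totals$donor[i]] <- totals$total[i]
    }
    m
  }
  res$assoc <- stage("assoc", ri_distance_report(
    ri_dir(res$cascades_garden$totals), ri_dir(res$cascades_wild$totals),
    res$tree, n_permutations = params$n_permutations,
    rng_seed = derive_seed(config$rng_seed, "assoc")))

  if (!is.null(out_dir)) {
    res$manifest <- stage("write", write_pipeline_outputs(res, out_dir))
  }
  class(res) <- "ri_pipeline_run"
  res
}

# Persist every stage output and return a manifest of files + MD5 checksums.
write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths[length(paths) + 1L] <<- p

  write_env_grid(res$env, file.path(out_dir, "environment"))
  for (p in list.files(file.path(out_dir, "environment"), full.names = TRUE)) add(p)
  add(write_occurrences(res$occurrences, file.path(out_dir, "occurrences.csv")))
  add(write_flowering(res$flowering, file.path(out_dir, "flowering.csv")))
  if (!is.null(res$crosses)) {
    add(write_crosses(res$crosses, file.path(out_dir, "crosses.csv")))
  }
  add(write_newick(res$tree, file.path(out_dir, "tree.nwk")))
  add(write_d_matrix(res$d_eco, file.path(out_dir, "d_ecogeography.csv")))
  add(write_d_matrix(res$d_phen_garden, file.path(out_dir, "d_phenology_garden.csv")))
  add(write_d_matrix(res$d_phen_wild, file.path(out_dir, "d_phenology_wild.csv")))
  for (src in c("garden", "wild")) {
    b <- res[[paste0("barriers_", src)]]
    f <- file.path(out_dir, paste0("barriers_", src, ".csv"))
    utils::write.csv(b, f, row.names = FALSE); add(f)
    cc <- res[[paste0("cascades_", src)]]
    f <- file.path(out_dir, paste0("cascade_", src, ".csv"))
    utils::write.csv(cc$contributions, f, row.names = FALSE); add(f)
    f <- file.path(out_dir, paste0("totals_", src, ".csv"))
    utils::write.csv(cc$totals, f, row.names = FALSE); add(f)
  }
  add(write_d_matrix(res$ri_table, file.path(out_dir, "total_ri_matrix.csv")))
  sdm_tab <- data.frame(species = names(res$sdm),
                        auc = vapply(res$sdm, `[[`, numeric(1), "auc"),
                        tss = vapply(res$sdm, `[[`, numeric(1), "tss"),
                        tss_threshold = vapply(res$sdm, `[[`, numeric(1),
                                               "tss_threshold"))
  f <- file.path(out_dir, "sdm_metrics.csv")
  utils::write.csv(sdm_tab, f, row.names = FALSE); add(f)

  list(out_dir = out_dir,
       rng_seed = res$config$rng_seed,
       files = stats::setNames(as.vector(tools::md5sum(paths)),
                               basename(paths)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.ri_pipeline_run <- function(x, ...) {
  cat("RI pipeline run\n")
  cat(sprintf("  species: %d; presences: %d; seed: %d\n",
              length(x$config$species), nrow(x$occurrences),
              x$config$rng_seed))
  cat(sprintf("  median test AUC %.3f, median max TSS %.3f\n",
              stats::median(vapply(x$sdm, `[[`, numeric(1), "auc")),
              stats::median(vapply(x$sdm, `[[`, numeric(1), "tss"))))
  cat(sprintf("  directed pairs: %d; total RI range [%.2f, %.2f]\n",
              nrow(x$cascades_garden$totals),
              min(x$ri_table, na.rm = TRUE), max(x$ri_table, na.rm = TRUE)))
  invisible(x)
}
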