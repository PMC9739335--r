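#' Suitability surfaces
#'
#' A `suitability_surface` holds one species' per-cell occurrence
#' probability on an [env_grid()]: a numeric matrix with `NA` at invalid
#' cells, plus the grid geometry needed to compare two surfaces. Values lie
#' in \[0, 1\] when unnormalized; after [normalize_surface()] they form a
#' probability distribution over valid cells (summing to 1), the form
#' Schoener's D operates on.
#'
#' @param species Species label.
#' @param values Numeric matrix of per-cell values (`NA` = invalid).
#' @param extent,resolution Grid geometry (see [env_grid()]).
#' @param normalized Logical: do the values sum to 1 over valid cells?
#' @return An object of class `suitability_surface`.
#' @export
suitability_surface <- function(species, values, extent, resolution,
                                normalized = FALSE) {
  structure(list(species = species,
                 values = as.matrix(values),
                 extent = as.numeric(extent),
                 resolution = resolution,
                 normalized = isTRUE(normalized)),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("suitability_surface '%s': %d x %d cells, %s, range [%.3g, %.3g]\n",
              x$species, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "unnormalized",
              min(v), max(v)))
  invisible(x)
}

# Geometry check used before any cell-wise comparison of two surfaces.
same_surface_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$extent, b$extent)) &&
    isTRUE(all.equal(a$resolution, b$resolution))
}

#' Ground-truth suitability of a synthetic species
#'
#' The generating model behind the simulated occurrences: per-cell
#' suitability is the product over niche layers of a Gaussian kernel
#' `exp(-(x - optimum)^2 / (2 * breadth^2))`, rescaled so the best cell
#' scores 1. Layers with infinite breadth do not constrain the species.
#' This surface is the recovery target for the SDM-based pipeline estimate.
#'
#' @param config A [scenario_config()].
#' @param env The [make_environment()] grid (or any grid holding the niche
#'   layers).
#' @param species Species label present in the config.
#' @return An unnormalized [suitability_surface()].
#' @export
true_suitability <- function(config, env, species) {
  stopifnot(inherits(config, "scenario_config"), inherits(env, "env_grid"))
  if (!species %in% config$species) {
    stop(sprintf("unknown species '%s'", species))
  }
  s <- matrix(1, env$n_rows, env$n_cols)
  for (layer in colnames(config$niche_optima)) {
    b <- config$niche_breadths[species, layer]
    if (!is.finite(b)) next
    if (!layer %in% names(env$layers)) {
      stop(sprintf("environment grid lacks niche layer '%s'", layer))
    }
    opt <- config$niche_optima[species, layer]
    s <- s * exp(-(env$layers[[layer]] - opt)^2 / (2 * b^2))
  }
  s[!env$mask] <- NA
  mx <- max(s, na.rm = TRUE)
  if (mx > 0) s <- s / mx
  suitability_surface(species, s, env$extent, env$resolution)
}
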