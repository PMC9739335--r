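#' Environmental grid objects
#'
#' An `env_grid` is a rectangular multi-layer raster in unprojected decimal
#' degrees: a shared extent and resolution, one numeric matrix per named
#' layer (row 1 is the northernmost row, values refer to cell centers) and a
#' logical validity mask. All layers share the mask and shape.
#'
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param resolution Cell size in degrees.
#' @param layers Named list of numeric matrices, all of identical dimension.
#' @param mask Logical matrix of the same dimension (`TRUE` = valid cell);
#'   defaults to all valid.
#'
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(extent, resolution, layers, mask = NULL) {
  if (length(layers) == 0L || is.null(names(layers)) || any(names(layers) == "")) {
    stop("'layers' must be a non-empty named list of matrices")
  }
  dims <- dim(layers[[1]])
  for (nm in names(layers)) {
    layers[[nm]] <- as.matrix(layers[[nm]])
    if (!identical(dim(layers[[nm]]), dims)) {
      stop(sprintf("layer '%s' does not match the shape of the first layer", nm))
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(mask), dims)) stop("mask shape must match the layers")
  structure(list(extent = as.numeric(extent),
                 resolution = resolution,
                 n_rows = dims[1],
                 n_cols = dims[2],
                 lon = extent[1] + (seq_len(dims[2]) - 0.5) * resolution,
                 lat = extent[4] - (seq_len(dims[1]) - 0.5) * resolution,
                 layers = layers,
                 mask = mask),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d rows x %d cols at %g deg (%d layers: %s)\n",
              x$n_rows, x$n_cols, x$resolution, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; %d of %d cells valid\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Row/col indices of the cells containing lon/lat points (row 1 = north).
# Points outside the extent error with the offending index.
grid_cell_of <- function(env, lon, lat) {
  ext <- env$extent
  out <- lon < ext[1] | lon > ext[2] | lat < ext[3] | lat > ext[4]
  if (any(out)) {
    stop(sprintf("point %d (%.4f, %.4f) falls outside the grid extent",
                 which(out)[1], lon[which(out)[1]], lat[which(out)[1]]))
  }
  col <- pmin(pmax(ceiling((lon - ext[1]) / env$resolution), 1L), env$n_cols)
  row <- pmin(pmax(ceiling((ext[4] - lat) / env$resolution), 1L), env$n_rows)
  cbind(row = row, col = col)
}

# Extract a data frame of layer values at point locations.
extract_env <- function(env, lon, lat, layers = names(env$layers)) {
  rc <- grid_cell_of(env, lon, lat)
  idx <- (rc[, "col"] - 1L) * env$n_rows + rc[, "row"]
  out <- lapply(env$layers[layers], function(m) m[idx])
  as.data.frame(out, optional = TRUE)
}

# Smooth spatial noise: coarse iid normal field, bilinearly interpolated to
# the full grid, then scaled to the requested marginal sd.
smooth_noise <- function(n_rows, n_cols, sd, coarse = 6L) {
  if (sd <= 0) return(matrix(0, n_rows, n_cols))
  z <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  rp <- seq(1, coarse, length.out = n_rows)
  cp <- seq(1, coarse, length.out = n_cols)
  r0 <- pmin(floor(rp), coarse - 1L); rf <- rp - r0
  c0 <- pmin(floor(cp), coarse - 1L); cf <- cp - c0
  out <- matrix(0, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    a <- z[r0, c0[j]] * (1 - rf) + z[r0 + 1L, c0[j]] * rf
    b <- z[r0, c0[j] + 1L] * (1 - rf) + z[r0 + 1L, c0[j] + 1L] * rf
    out[, j] <- a * (1 - cf[j]) + b * cf[j]
  }
  s <- stats::sd(out)
  if (s > 0) out <- out * (sd / s)
  out
}

#' Generate the synthetic environmental grid
#'
#' Builds the scenario's environmental layers: `temp`, a gradient increasing
#' from the southern to the northern edge; `precip`, a west--east gradient;
#' and their centered squares `temp_sq` and `precip_sq`. Each gradient
#' carries smooth spatial noise of sd `env_noise_sd`. The square layers make
#' the log of any Gaussian niche kernel a linear combination of the
#' available predictors, mirroring how real bioclimatic layer sets contain
#' both monotone and curvature-carrying variables.
#'
#' @param config A [scenario_config()].
#' @return An [env_grid()] whose layers are deterministic given
#'   `config$rng_seed`.
#' @examples
#' env <- make_environment(scenario_config())
#' env$n_cols # 40 columns across 2 degrees of longitude at 0.05 deg
#' @export
make_environment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ext <- config$grid_extent
  res <- config$grid_resolution
  n_cols <- floor((ext[2] - ext[1]) / res + 1e-9)
  n_rows <- floor((ext[4] - ext[3]) / res + 1e-9)
  if (n_cols < 1L || n_rows < 1L) {
    stop("grid extent is empty at the requested resolution")
  }
  lat <- ext[4] - (seq_len(n_rows) - 0.5) * res
  lon <- ext[1] + (seq_len(n_cols) - 0.5) * res
  u <- (lat - ext[3]) / (ext[4] - ext[3])   # 0 at southern, 1 at northern edge
  v <- (lon - ext[1]) / (ext[2] - ext[1])
  with_seed(derive_seed(config$rng_seed, "environment"), {
    temp <- matrix(u, n_rows, n_cols) +
      smooth_noise(n_rows, n_cols, config$env_noise_sd)
    precip <- matrix(v, n_rows, n_cols, byrow = TRUE) +
      smooth_noise(n_rows, n_cols, config$env_noise_sd)
  })
  layers <- list(temp = temp,
                 temp_sq = (temp - 0.5)^2,
                 precip = precip,
                 precip_sq = (precip - 0.5)^2)
  env_grid(ext, res, layers)
}
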