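#' Normalize a suitability surface to a probability distribution
#'
#' Divides every valid cell by the total over valid cells so the surface
#' becomes the per-site occurrence distribution p_X that Schoener's D
#' compares. Idempotent and invariant to positive rescaling of the input.
#'
#' @param surface A [suitability_surface()].
#' @return The normalized surface (`normalized = TRUE`, values sum to 1).
#' @export
normalize_surface <- function(surface) {
  stopifnot(inherits(surface, "suitability_surface"))
  total <- sum(surface$values, na.rm = TRUE)
  if (!is.finite(total) || total <= 0) {
    stop("cannot normalize an all-zero suitability surface")
  }
  surface$values <- surface$values / total
  surface$normalized <- TRUE
  surface
}

#' Schoener's D overlap between two distributions
#'
#' `D = 1 - 0.5 * sum_i |p_X,i - p_Y,i|`, the complement of half the total
#' variation distance: 0 for disjoint distributions, 1 for identical ones,
#' symmetric in its arguments. Accepts two normalized
#' [suitability_surface()]s on the same grid, or two bare probability
#' vectors/matrices on a common index set.
#'
#' @param p_x,p_y Normalized surfaces or numeric probability vectors.
#' @return Schoener's D in \[0, 1\].
#' @examples
#' schoener_d(c(0.5, 0.5, 0), c(0, 0.5, 0.5)) # 0.5
#' @export
schoener_d <- function(p_x, p_y) {
  if (inherits(p_x, "suitability_surface") ||
      inherits(p_y, "suitability_surface")) {
    stopifnot(inherits(p_x, "suitability_surface"),
              inherits(p_y, "suitability_surface"))
    if (!same_surface_grid(p_x, p_y)) {
      stop("surfaces are not on the same grid (extent/resolution/shape differ)")
    }
    if (!p_x$normalized || !p_y$normalized) {
      stop("surfaces must be normalized before computing Schoener's D; see normalize_surface()")
    }
    vx <- p_x$values; vy <- p_y$values
    if (!identical(which(is.na(vx)), which(is.na(vy)))) {
      stop("surfaces have different validity masks")
    }
    vx <- vx[!is.na(vx)]; vy <- vy[!is.na(vy)]
  } else {
    vx <- as.numeric(p_x); vy <- as.numeric(p_y)
    if (length(vx) != length(vy)) stop("distributions differ in length")
    if (abs(sum(vx) - 1) > 1e-6 || abs(sum(vy) - 1) > 1e-6 ||
        any(vx < 0) || any(vy < 0)) {
      stop("inputs must be probability distributions (non-negative, summing to 1)")
    }
  }
  d <- 1 - 0.5 * sum(abs(vx - vy))
  min(max(d, 0), 1)
}

#' Weekly flowering-probability distribution of one species
#'
#' Bins onset days into consecutive weeks counted from season day 1 (a
#' final partial week is its own bin) and normalizes the counts. The week
#' grid spans the latest onset observed in `records` for the given source
#' across *all* species, so distributions built from the same record set
#' are directly comparable.
#'
#' @param records Flowering-record data frame (`species`, `onset_day`,
#'   `source`).
#' @param species Species to extract.
#' @param source `"garden"` or `"wild"`; garden and wild records are never
#'   pooled.
#' @param week_length_days Bin width in days.
#' @param trim_quantile Optional symmetric quantile trim in \[0, 0.5)
#'   applied to this species' onsets before binning (0 = off), for outlier
#'   removal in observational data.
#' @return An object of class `phenology_distribution` with `week_probs`
#'   summing to 1.
#' @export
phenology_distribution <- function(records, species,
                                   source = c("garden", "wild"),
                                   week_length_days = 7,
                                   trim_quantile = 0) {
  source <- match.arg(source)
  pool <- records[records$source == source, , drop = FALSE]
  own <- pool[pool$species == species, , drop = FALSE]
  if (nrow(own) == 0L) {
    stop(sprintf("no %s flowering records for species '%s'", source, species))
  }
  onset <- own$onset_day
  if (trim_quantile > 0) {
    if (trim_quantile >= 0.5) stop("trim_quantile must lie in [0, 0.5)")
    q <- stats::quantile(onset, c(trim_quantile, 1 - trim_quantile),
                         names = FALSE)
    onset <- onset[onset >= q[1] & onset <= q[2]]
  }
  n_weeks <- max((pool$onset_day - 1L) %/% week_length_days + 1L)
  wk <- (onset - 1L) %/% week_length_days + 1L
  counts <- tabulate(wk, nbins = n_weeks)
  structure(list(species = species,
                 source = source,
                 week_probs = counts / sum(counts),
                 week_length_days = week_length_days,
                 n_records = length(onset)),
            class = "phenology_distribution")
}

#' @export
print.phenology_distribution <- function(x, ...) {
  cat(sprintf("phenology_distribution '%s' (%s): %d records over %d weeks, peak week %d\n",
              x$species, x$source, x$n_records, length(x$week_probs),
              which.max(x$week_probs)))
  invisible(x)
}

#' Flowering-time overlap between two species
#'
#' Schoener's D applied to weekly flowering probabilities. Both
#' distributions must come from the same source (garden or wild) and share
#' the week grid.
#'
#' @param a,b [phenology_distribution()] objects.
#' @return D in \[0, 1\].
#' @export
phenology_overlap <- function(a, b) {
  stopifnot(inherits(a, "phenology_distribution"),
            inherits(b, "phenology_distribution"))
  if (a$source != b$source) {
    stop("garden and wild phenology are never pooled: sources differ")
  }
  if (length(a$week_probs) != length(b$week_probs) ||
      a$week_length_days != b$week_length_days) {
    stop("phenology distributions are not on the same week grid")
  }
  schoener_d(a$week_probs, b$week_probs)
}

#' Pairwise Schoener's D matrix from suitability surfaces
#'
#' Normalizes every surface over the shared valid grid and computes D for
#' every species pair; the diagonal is 1 by construction.
#'
#' @param surfaces Named list of [suitability_surface()]s on one grid.
#' @return A symmetric species x species matrix of D values.
#' @export
eco_overlap_matrix <- function(surfaces) {
  if (is.null(names(surfaces))) {
    names(surfaces) <- vapply(surfaces, `[[`, character(1), "species")
  }
  norm <- lapply(surfaces, function(s) if (s$normalized) s else normalize_surface(s))
  n <- length(norm)
  out <- matrix(1, n, n, dimnames = list(names(norm), names(norm)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        out[i, j] <- out[j, i] <- schoener_d(norm[[i]], norm[[j]])
      }
    }
  }
  out
}

#' Pairwise flowering-overlap matrix
#'
#' @param records Flowering-record data frame.
#' @param species Species to include (default: all present in the source).
#' @param source `"garden"` or `"wild"`.
#' @inheritParams phenology_distribution
#' @return A symmetric species x species matrix of D values.
#' @export
phenology_overlap_matrix <- function(records, species = NULL,
                                     source = c("garden", "wild"),
                                     week_length_days = 7,
                                     trim_quantile = 0) {
  source <- match.arg(source)
  if (is.null(species)) {
    species <- sort(unique(records$species[records$source == source]))
  }
  dists <- lapply(species, phenology_distribution, records = records,
                  source = source, week_length_days = week_length_days,
                  trim_quantile = trim_quantile)
  n <- length(species)
  out <- matrix(1, n, n, dimnames = list(species, species))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        out[i, j] <- out[j, i] <- phenology_overlap(dists[[i]], dists[[j]])
      }
    }
  }
  out
}
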