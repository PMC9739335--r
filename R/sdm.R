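#' Generate pseudo-absence points around a species' distribution
#'
#' Background points standing in for true absences: cells are eligible when
#' their center lies farther than `buffer_deg` (planar Euclidean distance in
#' degrees) from every presence point and the cell itself contains no
#' presence. `ratio` times the number of presences are sampled uniformly
#' without replacement from the eligible cells and returned at cell
#' centers. The defaults (0.05 degree buffer, 4:1 ratio) are the
#' conventional settings for presence-background distribution modelling of
#' densely surveyed floras.
#'
#' @param presences Data frame with `lon`, `lat` (and optionally `species`).
#' @param env An [env_grid()].
#' @param buffer_deg Exclusion distance in degrees (>= 0).
#' @param ratio Absences per presence.
#' @param rng_seed Integer seed.
#' @return A data frame with columns `species`, `lon`, `lat`,
#'   `role = "pseudo_absence"`.
#' @export
generate_pseudo_absences <- function(presences, env, buffer_deg = 0.05,
                                     ratio = 4, rng_seed = 1L) {
  stopifnot(inherits(env, "env_grid"))
  if (nrow(presences) < 1L) stop("at least one presence point is required")
  if (buffer_deg < 0) stop("buffer_deg must be >= 0")
  n_abs <- ratio * nrow(presences)

  centers_lon <- rep(env$lon, each = env$n_rows)
  centers_lat <- rep(env$lat, times = env$n_cols)
  d2min <- rep(Inf, env$n_rows * env$n_cols)
  for (i in seq_len(nrow(presences))) {
    d2 <- (centers_lon - presences$lon[i])^2 + (centers_lat - presences$lat[i])^2
    d2min <- pmin(d2min, d2)
  }
  occupied <- rep(FALSE, env$n_rows * env$n_cols)
  rc <- grid_cell_of(env, presences$lon, presences$lat)
  occupied[(rc[, "col"] - 1L) * env$n_rows + rc[, "row"]] <- TRUE

  eligible <- which(as.vector(env$mask) & !occupied & d2min > buffer_deg^2)
  if (length(eligible) < n_abs) {
    stop(sprintf("cannot place %d pseudo-absences: only %d cells lie beyond the %.3g degree buffer (short by %d)",
                 n_abs, length(eligible), buffer_deg, n_abs - length(eligible)))
  }
  with_seed(rng_seed, {
    cells <- if (length(eligible) == 1L) eligible else sample(eligible, n_abs)
    data.frame(species = if ("species" %in% names(presences))
                 presences$species[1] else NA_character_,
               lon = centers_lon[cells],
               lat = centers_lat[cells],
               role = "pseudo_absence",
               stringsAsFactors = FALSE)
  })
}

#' Area under the ROC curve
#'
#' Rank-based estimate: the probability that a randomly drawn presence
#' outscores a randomly drawn absence, with ties counting one half
#' (the Mann--Whitney convention). Invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores Numeric model scores.
#' @param labels Binary labels (1 = presence, 0 = absence).
#' @return AUC in \[0, 1\].
#' @examples
#' evaluate_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)) # 0.75
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both presences and absences are required to evaluate AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum true skill statistic over candidate thresholds
#'
#' TSS(t) = sensitivity(t) + specificity(t) - 1, classifying a point as a
#' presence when its score is >= t. Candidate thresholds are the midpoints
#' of consecutive sorted unique scores; the maximum (smallest maximizer on
#' ties) is returned. With a single unique score no threshold can do better
#' than chance and TSS is 0.
#'
#' @inheritParams evaluate_auc
#' @return A list with elements `tss` and `threshold`.
#' @examples
#' evaluate_tss(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1)) # tss 1 at 0.5
#' @export
evaluate_tss <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both presences and absences are required to evaluate TSS")
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    return(list(tss = 0, threshold = u[1]))
  }
  cand <- (u[-length(u)] + u[-1]) / 2
  tss <- vapply(cand, function(t) {
    sens <- sum(scores >= t & labels == 1L) / n1
    spec <- sum(scores < t & labels == 0L) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which.max(tss) # which.max returns the first (smallest) maximizer
  list(tss = tss[best], threshold = cand[best])
}

#' Fit a species distribution model
#'
#' Binomial regression with logit link on the grid's environmental layers,
#' linear terms only and no interactions, fitted to presences vs
#' pseudo-absences. The data are split into training and held-out test
#' fractions, stratified by class; AUC and maximum TSS are computed on the
#' held-out part.
#'
#' @param presences,absences Point data frames (`lon`, `lat`).
#' @param env An [env_grid()] supplying the predictor layers.
#' @param train_fraction Fraction of each class used for fitting.
#' @param rng_seed Seed for the stratified split.
#' @param predictors Layer names to use (default: all layers).
#' @return An object of class `sdm_fit`: coefficients, predictor names,
#'   test-set `auc`, `tss`, `tss_threshold`, split sizes and seed.
#' @export
fit_sdm <- function(presences, absences, env, train_fraction = 0.7,
                    rng_seed = 1L, predictors = names(env$layers)) {
  stopifnot(inherits(env, "env_grid"))
  if (nrow(presences) == 0L || nrow(absences) == 0L) {
    stop("both presences and absences are required")
  }
  dat <- rbind(cbind(extract_env(env, presences$lon, presences$lat, predictors),
                     label = 1L),
               cbind(extract_env(env, absences$lon, absences$lat, predictors),
                     label = 0L))
  with_seed(rng_seed, {
    idx1 <- which(dat$label == 1L); idx0 <- which(dat$label == 0L)
    tr <- c(sample(idx1, max(1L, round(train_fraction * length(idx1)))),
            sample(idx0, max(1L, round(train_fraction * length(idx0)))))
  })
  train <- dat[tr, , drop = FALSE]
  test <- dat[-tr, , drop = FALSE]
  if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L) {
    stop("a class is absent from the train or test split; adjust train_fraction")
  }
  novar <- vapply(train[predictors], function(x) stats::var(x) == 0, logical(1))
  if (any(novar)) {
    stop(sprintf("predictor(s) with zero variance in training data: %s",
                 paste(predictors[novar], collapse = ", ")))
  }
  # Quasi-separation only triggers a glm warning; predictions still rank.
  fit <- suppressWarnings(
    stats::glm(label ~ ., family = stats::binomial(), data = train)
  )
  if (anyNA(stats::coef(fit))) {
    stop(sprintf("singular design: coefficient(s) not estimable (%s)",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")))
  }
  scores <- suppressWarnings(
    stats::predict(fit, newdata = test, type = "response")
  )
  tss <- evaluate_tss(scores, test$label)
  structure(list(species = if ("species" %in% names(presences))
                   presences$species[1] else NA_character_,
                 coefficients = stats::coef(fit),
                 predictor_names = predictors,
                 train_fraction = train_fraction,
                 n_train = nrow(train), n_test = nrow(test),
                 auc = evaluate_auc(scores, test$label),
                 tss = tss$tss, tss_threshold = tss$threshold,
                 converged = fit$converged,
                 rng_seed = as.integer(rng_seed)),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit '%s': %d predictors, train %d / test %d\n",
              x$species, length(x$predictor_names), x$n_train, x$n_test))
  cat(sprintf("  test AUC %.3f, max TSS %.3f at threshold %.3f\n",
              x$auc, x$tss, x$tss_threshold))
  invisible(x)
}

#' Predict an occurrence-probability surface from a fitted SDM
#'
#' Applies the inverse logit of the fitted linear predictor to every valid
#' grid cell; masked cells are `NA`. The result is unnormalized (values in
#' \[0, 1\]); normalize with [normalize_surface()] before computing overlap.
#'
#' @param fit An `sdm_fit` (or any list with `coefficients` named
#'   `(Intercept)` plus predictor names, and `predictor_names`).
#' @param env An [env_grid()] holding every predictor layer.
#' @return A [suitability_surface()].
#' @export
predict_surface <- function(fit, env) {
  stopifnot(inherits(env, "env_grid"))
  missing_layers <- setdiff(fit$predictor_names, names(env$layers))
  if (length(missing_layers) > 0L) {
    stop(sprintf("environment grid lacks predictor layer(s): %s",
                 paste(missing_layers, collapse = ", ")))
  }
  lp <- matrix(fit$coefficients[["(Intercept)"]], env$n_rows, env$n_cols)
  for (nm in fit$predictor_names) {
    lp <- lp + fit$coefficients[[nm]] * env$layers[[nm]]
  }
  p <- stats::plogis(lp)
  p[!env$mask] <- NA
  suitability_surface(fit$species %||% NA_character_, p,
                      env$extent, env$resolution)
}
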