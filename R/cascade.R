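#' Absolute contributions of sequentially acting barriers
#'
#' Barriers reduce gene flow in the order they act: the first barrier
#' contributes `AC_1 = RI_1`; each later barrier acts only on the gene flow
#' remaining after the earlier ones, `AC_n = RI_n * (1 - sum_{i<n} AC_i)`.
#' A missing (untested) barrier contributes 0 and leaves the remaining
#' gene-flow term unchanged -- it is "not observed", not "no isolation".
#' Negative RI values (heterospecific advantage) are propagated unchanged
#' and can reduce the running total.
#'
#' @param ri Ordered numeric vector of per-barrier RI values, `NA` marking
#'   missing barriers; non-missing values in \[-1, 1\].
#' @return A list with `ac` (per-barrier absolute contributions, 0 at
#'   missing barriers), `total` (their sum) and `missing` (logical flags).
#' @examples
#' absolute_contributions(c(0.5, 0.5))$ac       # 0.50 0.25
#' absolute_contributions(c(0.55, 1))$total     # 1
#' absolute_contributions(c(0.8, NA, 0.5))$ac   # 0.8 0.0 0.1
#' @export
absolute_contributions <- function(ri) {
  if (length(ri) == 0L) stop("at least one barrier is required")
  ok <- !is.na(ri)
  if (any(ri[ok] < -1 - 1e-9 | ri[ok] > 1 + 1e-9)) {
    stop("RI values must lie in [-1, 1]")
  }
  ac <- numeric(length(ri))
  remaining <- 1
  for (i in seq_along(ri)) {
    if (ok[i]) {
      ac[i] <- ri[i] * remaining
      remaining <- remaining - ac[i]
    }
  }
  list(ac = ac, total = sum(ac), missing = !ok)
}

#' Total reproductive isolation
#'
#' The sum of the absolute contributions of all tested barriers. When no
#' barrier is missing this equals `1 - prod(1 - RI_n)`.
#'
#' @param ac Numeric vector of absolute contributions (or the list returned
#'   by [absolute_contributions()]).
#' @return Total RI `T`.
#' @export
total_ri <- function(ac) {
  if (is.list(ac)) ac <- ac$ac
  if (length(ac) == 0L) stop("at least one contribution is required")
  sum(ac)
}

#' Cascade every directed pair of a barrier table
#'
#' Applies [absolute_contributions()] to each acceptor--donor series of a
#' [assemble_barriers()] table.
#'
#' @param barriers A `barrier_series` data frame.
#' @return A list with `contributions` (long data frame adding `ac` and
#'   `rel_contribution = ac / total` to the barrier table) and `totals`
#'   (one row per directed pair: `acceptor`, `donor`, `total`,
#'   `n_barriers_observed`, `phenology_source`).
#' @export
ri_cascades <- function(barriers) {
  stopifnot(is.data.frame(barriers),
            all(c("acceptor", "donor", "barrier", "ri") %in% names(barriers)))
  key <- paste(barriers$acceptor, barriers$donor, sep = "\r")
  pieces <- split(seq_len(nrow(barriers)), key)
  long <- vector("list", length(pieces))
  tot <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    blk <- barriers[idx[order(match(barriers$barrier[idx], BARRIER_ORDER))], ,
                    drop = FALSE]
    cc <- absolute_contributions(blk$ri)
    blk$ac <- cc$ac
    blk$rel_contribution <- if (cc$total != 0) cc$ac / cc$total else NA_real_
    long[[i]] <- blk
    tot[[i]] <- data.frame(acceptor = blk$acceptor[1], donor = blk$donor[1],
                           total = cc$total,
                           n_barriers_observed = sum(!cc$missing),
                           phenology_source = blk$phenology_source[1],
                           stringsAsFactors = FALSE)
  }
  contributions <- do.call(rbind, long)
  totals <- do.call(rbind, tot)
  rownames(contributions) <- rownames(totals) <- NULL
  o <- order(match(totals$acceptor, unique(barriers$acceptor)),
             match(totals$donor, unique(barriers$donor)))
  list(contributions = contributions, totals = totals[o, , drop = FALSE])
}

#' Paired total-RI matrix (garden above / wild below the diagonal)
#'
#' Lays out the two parallel total-RI calculations as one square matrix:
#' rows are acceptors, columns donors; cells above the diagonal come from
#' the garden-phenology cascades, cells below from the wild-phenology
#' cascades, and the diagonal is `NA`. Full precision is retained; use
#' `digits` for display rounding (half-up).
#'
#' @param totals_garden,totals_wild Totals data frames from [ri_cascades()].
#' @param species Row/column order.
#' @param digits Optional number of decimals for half-up display rounding.
#' @return A species x species numeric matrix.
#' @export
build_ri_table <- function(totals_garden, totals_wild,
                           species = sort(unique(totals_garden$acceptor)),
                           digits = NULL) {
  n <- length(species)
  out <- matrix(NA_real_, n, n, dimnames = list(species, species))
  pick <- function(totals, a, d) {
    v <- totals$total[totals$acceptor == a & totals$donor == d]
    if (length(v) != 1L) {
      stop(sprintf("cascade totals are incomplete for pair %s -> %s", a, d))
    }
    v
  }
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      if (r == c) next
      src <- if (r < c) totals_garden else totals_wild
      out[r, c] <- pick(src, species[r], species[c])
    }
  }
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
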