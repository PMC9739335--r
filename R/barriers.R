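# Fixed order in which barriers act on gene flow, earliest first.
BARRIER_ORDER <- c("ecogeography", "phenology", "pollen_stigma",
                   "fruit_set", "seed_viability")

#' RI of a symmetric overlap-based barrier
#'
#' Eco-geographic and phenological isolation are the complement of the
#' corresponding Schoener's D overlap: `RI = 1 - D`.
#'
#' @param d Overlap value(s) in \[0, 1\].
#' @return `1 - d`, in \[0, 1\]; strictly decreasing in `d`.
#' @examples
#' ri_from_overlap(0.45) # 0.55
#' @export
ri_from_overlap <- function(d) {
  if (any(!is.na(d) & (d < -1e-9 | d > 1 + 1e-9))) {
    stop("overlap D must lie in [0, 1]")
  }
  1 - pmin(pmax(d, 0), 1)
}

#' RI of an asymmetric cross-success barrier
#'
#' For a within-species success fraction `within` (e.g. Gw, Pw) and the
#' heterospecific fraction `between` (Gb, Pb):
#' `RI = 1 - 2 * between / (within + between)`.
#' 1 = complete isolation (no heterospecific success), 0 = no isolation,
#' negative values = heterospecific advantage. When both fractions are zero
#' the barrier is unobservable and `NA` is returned with a warning.
#'
#' @param within,between Non-negative success fractions.
#' @return RI in \[-1, 1\], or `NA` when `within + between == 0`.
#' @examples
#' ri_asymmetric(0.6, 0)   # 1: complete isolation
#' ri_asymmetric(0.5, 0.5) # 0: no isolation
#' ri_asymmetric(0, 0.4)   # -1: heterospecific advantage
#' @export
ri_asymmetric <- function(within, between) {
  if (any(within < 0) || any(between < 0)) {
    stop("success fractions must be non-negative")
  }
  tot <- within + between
  out <- ifelse(tot > 0, 1 - 2 * between / tot, NA_real_)
  if (anyNA(out)) {
    warning("within + between = 0: barrier unobservable, returning NA")
  }
  out
}

#' Pooled cross-success fractions for one directed species pair
#'
#' Pools counts (not per-record ratios) over the acceptor's cross records:
#' germinated/total pollen, fruits/pollinations and viable/total seeds, for
#' the within-species treatment and for the between-species treatment.
#' Pairs whose between-treatment total pollination count falls below
#' `min_n` are flagged missing (`NA`), mirroring the exclusion of
#' small-sample crosses. With `pooled = TRUE` (default) the between
#' fractions pool every donor of the acceptor that individually meets
#' `min_n`; `pooled = FALSE` restricts them to the named donor.
#'
#' @param records Cross-record data frame (see [simulate_crosses()] for the
#'   schema).
#' @param acceptor,donor Species labels of the directed pair.
#' @param min_n Minimum pollination count per treatment x pair.
#' @param pooled Pool between-species fractions across eligible donors?
#' @return A list with `Gw`, `Gb`, `Pw_fruit`, `Pb_fruit`, `Pw_seed`,
#'   `Pb_seed` (each `NA` when unobservable) and the pollination counts
#'   `n_within`, `n_between`.
#' @export
cross_summaries <- function(records, acceptor, donor, min_n = 5,
                            pooled = TRUE) {
  frac <- function(num, den) {
    num <- sum(num, na.rm = TRUE); den <- sum(den, na.rm = TRUE)
    if (den > 0) num / den else NA_real_
  }
  pair_n <- function(df) sum(df$n_pollinations)

  wrec <- records[records$acceptor == acceptor &
                    records$treatment == "within", , drop = FALSE]
  n_w <- pair_n(wrec)
  brec_all <- records[records$acceptor == acceptor &
                        records$treatment == "between", , drop = FALSE]
  this_pair <- brec_all[brec_all$donor == donor, , drop = FALSE]
  n_b <- pair_n(this_pair)

  empty <- list(Gw = NA_real_, Gb = NA_real_, Pw_fruit = NA_real_,
                Pb_fruit = NA_real_, Pw_seed = NA_real_, Pb_seed = NA_real_,
                n_within = n_w, n_between = n_b)
  if (n_w < min_n || n_b < min_n) return(empty)

  brec <- if (pooled) {
    eligible <- vapply(split(brec_all, brec_all$donor), pair_n, numeric(1))
    brec_all[brec_all$donor %in% names(eligible)[eligible >= min_n], ,
             drop = FALSE]
  } else {
    this_pair
  }

  list(Gw = frac(wrec$n_pollen_germinated, wrec$n_pollen_total),
       Gb = frac(brec$n_pollen_germinated, brec$n_pollen_total),
       Pw_fruit = frac(wrec$n_fruits, wrec$n_pollinations),
       Pb_fruit = frac(brec$n_fruits, brec$n_pollinations),
       Pw_seed = frac(wrec$n_seeds_viable, wrec$n_seeds_total),
       Pb_seed = frac(brec$n_seeds_viable, brec$n_seeds_total),
       n_within = n_w, n_between = n_b)
}

# RI for one asymmetric barrier from a (within, between) fraction pair,
# silently NA when either fraction is unobservable.
ri_pair_or_na <- function(w, b) {
  if (is.na(w) || is.na(b)) return(NA_real_)
  suppressWarnings(ri_asymmetric(w, b))
}

#' Assemble the per-barrier RI table for every directed species pair
#'
#' Combines the eco-geographic D matrix, a phenology D matrix and the cross
#' records into one long table with a row per acceptor x donor x barrier,
#' barriers in the fixed order eco-geography, phenology, pollen--stigma,
#' fruit set, seed viability. Symmetric (overlap-based) barriers are filled
#' for every pair; asymmetric barriers only where the acceptor has adequate
#' cross data, otherwise they are flagged missing.
#'
#' @param d_eco,d_phen Square D matrices with identical species dimnames.
#' @param crosses Cross-record data frame, or `NULL` for a
#'   pre-pollination-only analysis.
#' @param species Species order (default: rownames of `d_eco`).
#' @param phenology_source Label recorded in the output (`"garden"` or
#'   `"wild"`).
#' @inheritParams cross_summaries
#' @return A data frame of class `barrier_series` with columns `acceptor`,
#'   `donor`, `barrier`, `ri`, `missing`, `phenology_source`
#'   (`n_species * (n_species - 1) * 5` rows).
#' @export
assemble_barriers <- function(d_eco, d_phen, crosses = NULL,
                              species = rownames(d_eco),
                              phenology_source = "garden",
                              min_n = 5, pooled = TRUE) {
  if (is.null(rownames(d_eco)) || is.null(rownames(d_phen))) {
    stop("D matrices must carry species dimnames")
  }
  if (!all(species %in% rownames(d_eco)) || !all(species %in% colnames(d_eco)) ||
      !all(species %in% rownames(d_phen)) || !all(species %in% colnames(d_phen))) {
    stop("species labels are not covered by both D matrices")
  }
  if (!is.null(crosses)) {
    unknown <- setdiff(unique(c(crosses$acceptor, crosses$donor)), species)
    if (length(unknown) > 0L) {
      stop(sprintf("cross records name species absent from the D matrices: %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  rows <- vector("list", length(species) * (length(species) - 1L))
  k <- 0L
  for (a in species) {
    for (d in setdiff(species, a)) {
      cs <- if (is.null(crosses)) NULL else
        cross_summaries(crosses, a, d, min_n = min_n, pooled = pooled)
      ri <- c(ecogeography = ri_from_overlap(d_eco[a, d]),
              phenology = ri_from_overlap(d_phen[a, d]),
              pollen_stigma = if (is.null(cs)) NA_real_ else
                ri_pair_or_na(cs$Gw, cs$Gb),
              fruit_set = if (is.null(cs)) NA_real_ else
                ri_pair_or_na(cs$Pw_fruit, cs$Pb_fruit),
              seed_viability = if (is.null(cs)) NA_real_ else
                ri_pair_or_na(cs$Pw_seed, cs$Pb_seed))
      k <- k + 1L
      rows[[k]] <- data.frame(acceptor = a, donor = d,
                              barrier = BARRIER_ORDER,
                              ri = unname(ri),
                              missing = is.na(unname(ri)),
                              phenology_source = phenology_source,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("barrier_series", "data.frame")
  out
}
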