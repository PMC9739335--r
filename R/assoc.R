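#' Parse a Newick tree with branch lengths
#'
#' Thin validated wrapper around [ape::read.tree()]: the tree must parse,
#' carry a branch length on every edge (all non-negative) and have unique
#' leaf labels.
#'
#' @param text Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo")) {
    stop("malformed Newick string (check parentheses and the trailing ';')")
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("every edge must carry a branch length")
  }
  if (any(tr$edge.length < 0)) stop("branch lengths must be non-negative")
  if (anyDuplicated(tr$tip.label)) {
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  tr
}

#' Patristic distance matrix of a tree
#'
#' Entry (a, b) is the total branch length along the unique path between
#' leaves a and b.
#'
#' @param tree A `phylo` object (see [parse_newick()]).
#' @return A symmetric, zero-diagonal species x species matrix.
#' @examples
#' patristic_distances(parse_newick("(A:1,B:2);"))["A", "B"] # 3
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  as.matrix(ape::cophenetic.phylo(tree))
}

#' Symmetrize an asymmetric (directed) RI matrix
#'
#' Total RI is directional (acceptor vs donor); a Mantel test needs one
#' value per unordered pair. The default takes the arithmetic mean of the
#' two directions; `"min"`/`"max"` are available as sensitivity variants.
#'
#' @param m Square matrix (diagonal ignored).
#' @param method `"mean"`, `"min"` or `"max"`.
#' @return A symmetric matrix with a zero diagonal.
#' @export
symmetrize_ri <- function(m, method = c("mean", "min", "max")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  out <- switch(method,
                mean = (m + t(m)) / 2,
                min = pmin(m, t(m)),
                max = pmax(m, t(m)))
  diag(out) <- 0
  out
}

#' Permutation Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries. The null distribution is built by jointly permuting the rows
#' and columns of the second matrix; the p-value is
#' `(1 + #permutations at least as extreme) / (1 + n_permutations)`.
#'
#' @param m1,m2 Symmetric square matrices with identical dimnames (order
#'   included).
#' @param n_permutations Number of label permutations.
#' @param rng_seed Integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return An object of class `mantel_test`: `statistic`, `p_value`,
#'   `alternative`, `n_permutations`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 9999, rng_seed = 1L,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(m1), is.matrix(m2))
  n <- nrow(m1)
  if (n < 3L) stop("a Mantel test needs at least three labels")
  if (!identical(dim(m1), dim(m2)) ||
      !identical(dimnames(m1)[[1]], dimnames(m2)[[1]])) {
    stop("matrices must share shape and label order")
  }
  lt <- lower.tri(m1)
  v1 <- m1[lt]; v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("a matrix is constant off-diagonal: the correlation is undefined")
  }
  r_obs <- stats::cor(v1, v2)
  perm <- with_seed(rng_seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n)
      stats::cor(v1, m2[idx, idx][lt])
    }, numeric(1))
  })
  p <- switch(alternative,
              greater = (1 + sum(perm >= r_obs - 1e-12)) / (1 + n_permutations),
              less = (1 + sum(perm <= r_obs + 1e-12)) / (1 + n_permutations),
              two.sided = (1 + sum(abs(perm) >= abs(r_obs) - 1e-12)) /
                (1 + n_permutations))
  structure(list(statistic = r_obs, p_value = p,
                 alternative = alternative,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed)),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_value, x$alternative, x$n_permutations))
  invisible(x)
}

#' Association between total RI and phylogenetic distance
#'
#' Symmetrizes the two directed total-RI matrices (garden- and
#' wild-phenology calculations), aligns them with the tree's patristic
#' distances and runs a Mantel test for each.
#'
#' @param ri_garden,ri_wild Directed total-RI matrices (acceptor rows,
#'   donor columns) with species dimnames.
#' @param tree A `phylo` object covering every species.
#' @param n_permutations,rng_seed,alternative Passed to [mantel_test()]
#'   (per-source seeds are derived from `rng_seed`).
#' @param symmetrize Directed-pair reduction, see [symmetrize_ri()].
#' @return A list of class `ri_assoc_report` with one `mantel_test` per
#'   phenology source plus the settings used.
#' @export
ri_distance_report <- function(ri_garden, ri_wild, tree,
                               n_permutations = 9999, rng_seed = 1L,
                               alternative = "greater",
                               symmetrize = "mean") {
  species <- rownames(ri_garden)
  if (is.null(species) || !identical(species, rownames(ri_wild))) {
    stop("RI matrices must share species rownames")
  }
  absent <- setdiff(species, tree$tip.label)
  if (length(absent) > 0L) {
    stop(sprintf("species absent from the tree: %s",
                 paste(absent, collapse = ", ")))
  }
  pd <- patristic_distances(tree)[species, species]
  run <- function(m, tag) {
    mantel_test(symmetrize_ri(m, symmetrize), pd,
                n_permutations = n_permutations,
                rng_seed = derive_seed(rng_seed, "mantel", tag),
                alternative = alternative)
  }
  structure(list(garden = run(ri_garden, "garden"),
                 wild = run(ri_wild, "wild"),
                 symmetrize = symmetrize,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed)),
            class = "ri_assoc_report")
}

#' @export
print.ri_assoc_report <- function(x, ...) {
  cat("Total RI vs patristic distance (symmetrized by", x$symmetrize, ")\n")
  cat(sprintf("  garden phenology: r = %.4f, p = %.4g\n",
              x$garden$statistic, x$garden$p_value))
  cat(sprintf("  wild phenology  : r = %.4f, p = %.4g\n",
              x$wild$statistic, x$wild$p_value))
  invisible(x)
}
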