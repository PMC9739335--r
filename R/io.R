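# File formats: occurrences / flowering / crosses CSV, ESRI ASCII grids,
# D-matrix CSV, Newick. All readers validate schemas and address errors by
# row and column.

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write occurrence tables
#'
#' CSV schema: `species, lon, lat, role` with `role` in
#' `presence`/`pseudo_absence`.
#'
#' @param occ Occurrence data frame.
#' @param path File path.
#' @return `read_occurrences()` returns the validated data frame;
#'   `write_occurrences()` returns `path` invisibly.
#' @export
write_occurrences <- function(occ, path) {
  check_columns(occ, c("species", "lon", "lat", "role"), "occurrences")
  utils::write.csv(occ[, c("species", "lon", "lat", "role")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(occ, c("species", "lon", "lat", "role"), basename(path))
  bad <- which(!occ$role %in% c("presence", "pseudo_absence"))
  if (length(bad) > 0L) {
    stop(sprintf("%s row %d: invalid role '%s'", basename(path), bad[1],
                 occ$role[bad[1]]))
  }
  if (anyNA(occ$lon) || anyNA(occ$lat)) {
    stop(sprintf("%s: non-numeric coordinates (first bad row %d)",
                 basename(path), which(is.na(occ$lon) | is.na(occ$lat))[1]))
  }
  occ
}

#' Read and write flowering-record tables
#'
#' CSV schema: `record_id, species, onset_day, source, year, block`.
#'
#' @param records Flowering data frame.
#' @param path File path.
#' @param season_length Optional bound for validating onset days.
#' @return The validated data frame (readers) or `path` (writers).
#' @export
write_flowering <- function(records, path) {
  check_columns(records, c("record_id", "species", "onset_day", "source",
                           "year", "block"), "flowering records")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flowering
#' @export
read_flowering <- function(path, season_length = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(rec, c("record_id", "species", "onset_day", "source",
                       "year", "block"), basename(path))
  bad <- which(!rec$source %in% c("garden", "wild"))
  if (length(bad) > 0L) {
    stop(sprintf("%s row %d: source must be garden or wild, got '%s'",
                 basename(path), bad[1], rec$source[bad[1]]))
  }
  lo <- which(rec$onset_day < 1 |
                (!is.null(season_length) & rec$onset_day > season_length))
  if (length(lo) > 0L) {
    stop(sprintf("%s row %d: onset_day %s outside the season", basename(path),
                 lo[1], rec$onset_day[lo[1]]))
  }
  rec
}

#' Read and write cross-experiment tables
#'
#' CSV schema: `acceptor, donor, treatment, n_pollinations, n_fruits,
#' n_seeds_total, n_seeds_viable, n_pollen_total, n_pollen_germinated`
#' (pollen columns may be `NA` for fruit-only experiments). Count ordering
#' invariants are enforced on read.
#'
#' @param crosses Cross-record data frame.
#' @param path File path.
#' @return The validated data frame (reader) or `path` (writer).
#' @export
write_crosses <- function(crosses, path) {
  cols <- c("acceptor", "donor", "treatment", "n_pollinations", "n_fruits",
            "n_seeds_total", "n_seeds_viable", "n_pollen_total",
            "n_pollen_germinated")
  check_columns(crosses, cols, "cross records")
  utils::write.csv(crosses[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosses
#' @export
read_crosses <- function(path) {
  cr <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("acceptor", "donor", "treatment", "n_pollinations", "n_fruits",
            "n_seeds_total", "n_seeds_viable", "n_pollen_total",
            "n_pollen_germinated")
  check_columns(cr, cols, basename(path))
  fail <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0L) stop(sprintf("%s row %d: %s", basename(path), i[1], msg))
  }
  fail(!cr$treatment %in% c("within", "between"),
       "treatment must be within or between")
  fail(cr$treatment == "within" & cr$acceptor != cr$donor,
       "within-treatment rows must have acceptor == donor")
  fail(cr$treatment == "between" & cr$acceptor == cr$donor,
       "between-treatment rows must have acceptor != donor")
  fail(cr$n_fruits < 0 | cr$n_fruits > cr$n_pollinations,
       "n_fruits must lie in [0, n_pollinations]")
  fail(cr$n_seeds_viable < 0 | cr$n_seeds_viable > cr$n_seeds_total,
       "n_seeds_viable must lie in [0, n_seeds_total]")
  fail(!is.na(cr$n_pollen_total) &
         (cr$n_pollen_germinated < 0 | cr$n_pollen_germinated > cr$n_pollen_total),
       "n_pollen_germinated must lie in [0, n_pollen_total]")
  cr
}

#' Write a layer as an ESRI ASCII grid
#'
#' Standard `.asc` format: six header lines (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows from north to
#' south. `NA` cells are written as the NODATA value.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param path Output path.
#' @param extent,resolution Grid geometry.
#' @param nodata NODATA sentinel.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, path, extent, resolution, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(values)),
               sprintf("nrows %d", nrow(values)),
               sprintf("xllcorner %.10g", extent[1]),
               sprintf("yllcorner %.10g", extent[3]),
               sprintf("cellsize %.10g", resolution),
               sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return A list with `values` (matrix, NODATA as `NA`), `extent`,
#'   `resolution`, `nodata`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys) || anyNA(vals[need])) {
    stop(sprintf("%s: malformed ESRI ASCII header", basename(path)))
  }
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  m <- matrix(scan(path, skip = 6L, quiet = TRUE), nrow = nr, ncol = nc,
              byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  ext <- c(vals[["xllcorner"]], vals[["xllcorner"]] + nc * vals[["cellsize"]],
           vals[["yllcorner"]], vals[["yllcorner"]] + nr * vals[["cellsize"]])
  list(values = m, extent = ext, resolution = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Write / read a full environment grid as one `.asc` file per layer
#'
#' @param env An [env_grid()].
#' @param dir Directory for the `.asc` files (created if absent).
#' @param paths Named character vector of `.asc` files (names become layer
#'   names).
#' @return `write_env_grid()` returns the written paths; `read_env_grid()`
#'   an [env_grid()] whose mask marks cells valid in every layer.
#' @export
write_env_grid <- function(env, dir) {
  stopifnot(inherits(env, "env_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vapply(names(env$layers), function(nm) {
    v <- env$layers[[nm]]
    v[!env$mask] <- NA
    write_asc(v, file.path(dir, paste0(nm, ".asc")), env$extent,
              env$resolution)
  }, character(1))
  invisible(out)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.asc$", "", basename(paths))
  }
  grids <- lapply(paths, read_asc)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(g$extent, ref$extent))) {
      stop("environment layers disagree on extent or shape")
    }
  }
  layers <- lapply(grids, `[[`, "values")
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  env_grid(ref$extent, ref$resolution, layers, mask)
}

#' Write / read a species-by-species D (or RI) matrix CSV
#'
#' Square matrix with species labels in the first column and the header,
#' the layout of a pairwise-overlap table with a unit diagonal.
#'
#' @param m Square numeric matrix with dimnames.
#' @param path File path.
#' @return The matrix (reader) or `path` (writer).
#' @export
write_d_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_d_matrix
#' @export
read_d_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "species") {
    stop(sprintf("%s: first column must be 'species'", basename(path)))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  if (!identical(rownames(m), colnames(m))) {
    stop(sprintf("%s: row and column species labels differ", basename(path)))
  }
  storage.mode(m) <- "double"
  m
}

#' Read / write Newick tree files
#'
#' @param tree A `phylo` object (writer) or file path (reader).
#' @param path File path.
#' @return The parsed tree (reader) or `path` (writer).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path), collapse = ""))
}
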