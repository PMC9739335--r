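# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-stream seed from a root seed and a stage/label path.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    utf8ToInt(paste(as.character(x), collapse = ","))
  }), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (p in parts) h <- (h * 31 + p) %% 2147483647
  as.integer(h)
}

# Per-acceptor parameter lookup: scalars recycle, named vectors index by label.
lookup_param <- function(par, label, what) {
  if (length(par) == 1L && is.null(names(par))) return(unname(par))
  if (is.null(names(par))) {
    stop(sprintf("'%s' must be a scalar or a named per-species vector", what))
  }
  if (!label %in% names(par)) {
    stop(sprintf("no '%s' entry for species '%s'", what, label))
  }
  unname(par[[label]])
}

# Half-up rounding to `digits` decimals, as used for table display.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
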