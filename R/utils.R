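# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, then restores the caller's RNG
#' state so seeded package internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Derive a stream of distinct 32-bit-safe seeds from one base seed.
derive_seeds <- function(seed, n, stream = 0L) {
  (as.integer(seed) + stream * 10000L + seq_len(n) * 7919L) %% .Machine$integer.max
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_scalar_num <- function(x, min = -Inf, max = Inf) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x <= max
}

#' Names of metadata columns in a feature table
#'
#' Feature tables use the CellProfiler convention: every column whose name
#' starts with `Metadata_` is metadata; all remaining columns are features.
#'
#' @param x A data frame.
#' @return Character vector of metadata column names.
#' @export
metadata_cols <- function(x) {
  grep("^Metadata_", names(x), value = TRUE)
}

#' Names of feature columns in a feature table
#'
#' @param x A data frame.
#' @return Character vector of feature (non-`Metadata_`) column names.
#' @export
feature_cols <- function(x) {
  setdiff(names(x), metadata_cols(x))
}
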