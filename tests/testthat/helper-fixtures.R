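# Shared fixtures: small configurations and brute-force oracles.

# A deliberately small simulation: 5 channels + brightfield, few features,
# one or two sites, tens of cells per site. Signal and noise structure are
# the package defaults unless overridden.
small_config <- function(..., seed = 0L) {
  defaults <- list(n_features_per_channel = 4L, n_channel_free_features = 4L,
                   sites_per_well = 1L, cells_per_site = c("20X" = 30),
                   magnification = "20X", seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

small_schema <- function(cfg = small_config()) {
  build_feature_schema(channel_registry(), cfg$n_features_per_channel,
                       cfg$n_channel_free_features)
}

# Full pipeline from a plate map + config to selected well profiles.
simulate_profiles <- function(pm, cfg) {
  cells <- simulate_plate(pm, config = cfg)
  feature_select(mad_robustize(aggregate_profiles(cells)))
}

# Hand-built well-level profile table (no simulation) from a matrix whose
# rows are wells of `pm`, in plate-map order.
profiles_from_matrix <- function(M, pm) {
  stopifnot(nrow(M) == nrow(pm))
  colnames(M) <- colnames(M) %||% paste0("Feat_", seq_len(ncol(M)))
  out <- cbind(data.frame(Metadata_Plate = "P1",
                          Metadata_Well = pm$well_position,
                          stringsAsFactors = FALSE),
               as.data.frame(M))
  structure(out, normalized = TRUE, selected = TRUE,
            class = c("profile", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain data.frame stripped of provenance attributes, for content equality.
strip_df <- function(x) {
  x <- as.data.frame(x)
  out <- data.frame(x, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

# Brute-force median pairwise Pearson correlation among rows of a matrix.
oracle_median_pairwise <- function(M) {
  n <- nrow(M)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, stats::cor(M[i, ], M[j, ]))
    }
  }
  stats::median(vals)
}

# Brute-force median correlation across two sets of rows.
oracle_median_cross <- function(A, B) {
  vals <- c()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      vals <- c(vals, stats::cor(A[i, ], B[j, ]))
    }
  }
  stats::median(vals)
}
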