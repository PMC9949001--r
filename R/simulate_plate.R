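# Single-cell feature-table simulation.

#' Simulate a single-cell morphological feature table for one plate
#'
#' Emulates the output of image segmentation + feature extraction for a
#' whole plate under one acquisition-setting combination, with the
#' statistical structure downstream profiling assumes:
#'
#' * every well gets `sites_per_well` acquisition sites; cells per site are
#'   Poisson with mean `cells_per_site[magnification]`, so cell count is
#'   coupled to magnification and site count as in real acquisitions;
#' * a cell's feature vector is
#'   `beta_compound + row_effect + column_effect + site_effect + noise`,
#'   where the plate row/column gradients (SD `sigma_plate`) are drawn once
#'   per plate per feature, site effects (SD `sigma_site`) once per site per
#'   feature, and cell noise (SD `sigma_cell`) is correlated within a
#'   channel through one latent factor per channel per cell with loading
#'   `sqrt(channel_correlation)` (colocalization features load equally on
#'   both their channels' factors);
#' * negative-control wells have zero effect vector.
#'
#' Identical `config` + `seed` give byte-identical tables. Wells whose every
#' site draws zero cells are reported with a warning and recorded in the
#' `empty_wells` attribute (they produce no rows).
#'
#' @param platemap A [generate_jumpmoa_layout()] plate map.
#' @param library An [build_effect_library()] effect library (or NULL to
#'   build one from `config`).
#' @param schema A [build_feature_schema()] (or NULL to build the default
#'   schema implied by `config` with the standard registry).
#' @param config A [sim_config()].
#' @param setting_label Free-text acquisition-setting label stored in
#'   `Metadata_Setting`.
#' @param seed Seed for the plate draw; defaults to `config$seed`. Use
#'   distinct seeds for replicate plates of the same configuration.
#' @return A single-cell feature table: data frame with metadata columns
#'   `Metadata_Plate`, `Metadata_Well`, `Metadata_Site`,
#'   `Metadata_Compound`, `Metadata_MOA`, `Metadata_Setting` followed by one
#'   column per schema feature; one row per cell.
#' @examples
#' pm <- generate_jumpmoa_layout(n_compounds = 4, n_moa = 2, seed = 1)
#' cfg <- sim_config(n_features_per_channel = 2, n_channel_free_features = 2,
#'                   sites_per_well = 2, cells_per_site = c("20X" = 5))
#' cells <- simulate_plate(pm, config = cfg)
#' @export
simulate_plate <- function(platemap, library = NULL, schema = NULL,
                           config = sim_config(),
                           setting_label = config$magnification,
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(schema)) {
    schema <- build_feature_schema(channel_registry(),
                                   config$n_features_per_channel,
                                   config$n_channel_free_features)
  }
  if (is.null(library)) {
    library <- build_effect_library(platemap, schema, config)
  }
  if (!nrow(platemap)) stop("empty plate map", call. = FALSE)

  feats <- schema$feature
  F <- length(feats)
  registry <- attr(schema, "registry")
  chans <- as.character(registry)
  lambda <- config$cells_per_site[[config$magnification]]
  S <- config$sites_per_well
  n_wells <- nrow(platemap)
  plate_id <- attr(platemap, "plate_id") %||% "PLATE1"

  # channel-factor loading matrix (n_channels x F)
  r <- config$channel_correlation
  L <- matrix(0, nrow = length(chans), ncol = F,
              dimnames = list(chans, feats))
  for (j in seq_len(F)) {
    c1 <- schema$channel1[j]; c2 <- schema$channel2[j]
    if (!is.na(c1) && is.na(c2)) L[c1, j] <- sqrt(r)
    if (!is.na(c2)) L[c(c1, c2), j] <- sqrt(r / 2)
  }
  resid_sd <- sqrt(pmax(0, 1 - colSums(L^2)))

  rows <- sort(unique(platemap$row))
  cols <- sort(unique(platemap$column))

  out <- with_seed(seed, {
    row_eff <- matrix(stats::rnorm(length(rows) * F, sd = config$sigma_plate),
                      nrow = length(rows), dimnames = list(rows, NULL))
    col_eff <- matrix(stats::rnorm(length(cols) * F, sd = config$sigma_plate),
                      nrow = length(cols),
                      dimnames = list(as.character(cols), NULL))
    n_cells_site <- matrix(stats::rpois(n_wells * S, lambda),
                           nrow = n_wells)           # wells x sites
    site_eff <- matrix(stats::rnorm(n_wells * S * F, sd = config$sigma_site),
                       nrow = n_wells * S)           # (well,site) x features

    cells_per_well <- rowSums(n_cells_site)
    N <- sum(cells_per_well)
    # expansion indices: one entry per cell
    site_flat <- as.vector(t(n_cells_site))          # well-major, site-minor
    cell_ws <- rep(seq_len(n_wells * S), site_flat)  # (well,site) index/cell
    cell_well <- (cell_ws - 1L) %/% S + 1L
    cell_site <- (cell_ws - 1L) %% S + 1L

    X <- matrix(0, nrow = N, ncol = F, dimnames = list(NULL, feats))
    # compound effects
    beta_w <- matrix(0, nrow = n_wells, ncol = F)
    treat <- platemap$role == "treatment"
    beta_w[treat, ] <- library$beta[platemap$compound_id[treat], ,
                                    drop = FALSE]
    X <- X + beta_w[cell_well, , drop = FALSE]
    # plate gradients and site effects
    X <- X + row_eff[match(platemap$row, rows)[cell_well], , drop = FALSE]
    X <- X + col_eff[match(platemap$column, cols)[cell_well], , drop = FALSE]
    X <- X + site_eff[cell_ws, , drop = FALSE]
    # correlated cell noise
    G <- matrix(stats::rnorm(N * length(chans)), nrow = N)
    E <- matrix(stats::rnorm(N * F), nrow = N)
    X <- X + config$sigma_cell * (G %*% L + sweep(E, 2L, resid_sd, `*`))

    list(X = X, cell_well = cell_well, cell_site = cell_site,
         cells_per_well = cells_per_well)
  })

  empty <- platemap$well_position[out$cells_per_well == 0L]
  if (length(empty)) {
    warning("well(s) with zero simulated cells: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }

  tab <- data.frame(
    Metadata_Plate = plate_id,
    Metadata_Well = platemap$well_position[out$cell_well],
    Metadata_Site = out$cell_site,
    Metadata_Compound = platemap$compound_id[out$cell_well],
    Metadata_MOA = platemap$moa[out$cell_well],
    Metadata_Setting = setting_label,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(out$X))
  structure(tab, empty_wells = empty, setting = setting_label,
            class = c("feature_table", "data.frame"))
}
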