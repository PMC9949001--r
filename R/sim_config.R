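# Simulator configuration.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic plate generator. Defaults
#' describe a plausible Cell Painting acquisition: a 20X objective with nine
#' sites per well and ~150 cells per site (~1,350 cells/well, in the range
#' where profile strength saturates at roughly 2,500 cells/well), Gaussian
#' cell-level noise with moderate within-channel correlation, mild additive
#' plate row/column gradients, and compound effects that are partly shared
#' within a mechanism-of-action (MOA) class.
#'
#' @param n_features_per_channel Single-channel features per channel.
#' @param n_channel_free_features Channel-free (shape/neighbor) features.
#' @param active_fraction Fraction `f` of compounds with a non-zero
#'   morphological effect (the rest behave like vehicle), in `[0, 1]`.
#' @param effect_size Effect magnitude `a` (length of the compound effect
#'   vector in robust-SD units); 0 gives a pure-noise null plate.
#' @param moa_sharing MOA-sharing weight `rho` in `[0, 1]`: the expected
#'   squared cosine overlap between effect vectors of two active compounds
#'   sharing an MOA. 0 = compound-specific effects only; 1 = effects fully
#'   determined by the MOA class.
#' @param sigma_cell Cell-level noise SD.
#' @param sigma_site Site-level (field-of-view) effect SD, shared by all
#'   cells of a site.
#' @param sigma_plate Plate row/column gradient SD (additive per-row and
#'   per-column effects, drawn once per plate per feature), emulating
#'   well-edge and center related effects.
#' @param channel_correlation Within-channel feature correlation
#'   `r_chan` in `[0, 1)`, induced by one latent factor per channel per cell.
#' @param rna_er_redundancy Weight in `[0, 1]` mixing RNA-channel effect
#'   loadings with the corresponding ER-channel loadings, emulating the
#'   spectral/biological redundancy of the RNA dye being visible in the ER
#'   channel. 0 = independent channels.
#' @param brightfield_loading Multiplier on effect loadings of
#'   Brightfield-referencing features (default 0.25: brightfield carries
#'   attenuated, not absent, phenotypic signal).
#' @param cells_per_site Named numeric vector of Poisson means for cells per
#'   site by magnification. Defaults (10X = 600, 20X = 150, 40X = 40) follow
#'   field-of-view area ratios and put the default 20X / 9-site plate near
#'   2,500 cells per well... see Details.
#' @param magnification One of `names(cells_per_site)`.
#' @param sites_per_well Acquisition sites (fields of view) per well.
#' @param seed Integer seed for every stochastic component.
#'
#' @details The cells-per-site means encode the inverse relationship between
#' magnification and cell count: a lower-power objective covers a larger
#' field of view and so images more cells per site. They are configuration,
#' not measurements.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_features_per_channel = 20L,
                       n_channel_free_features = 10L,
                       active_fraction = 0.9,
                       effect_size = 1,
                       moa_sharing = 0.5,
                       sigma_cell = 1,
                       sigma_site = 0.1,
                       sigma_plate = 0.1,
                       channel_correlation = 0.3,
                       rna_er_redundancy = 0.8,
                       brightfield_loading = 0.25,
                       cells_per_site = c("10X" = 600, "20X" = 150,
                                          "40X" = 40),
                       magnification = "20X",
                       sites_per_well = 9L,
                       seed = 0L) {
  # YAML/JSON configs deliver named lists
  if (is.list(cells_per_site)) cells_per_site <- unlist(cells_per_site)
  stopifnot(is_count(n_features_per_channel),
            is_count(n_channel_free_features, min = 0L),
            is_scalar_num(active_fraction, 0, 1),
            is_scalar_num(effect_size, 0),
            is_scalar_num(moa_sharing, 0, 1),
            is_scalar_num(sigma_cell, 0), is_scalar_num(sigma_site, 0),
            is_scalar_num(sigma_plate, 0),
            is_scalar_num(channel_correlation, 0, 1 - 1e-12),
            is_scalar_num(rna_er_redundancy, 0, 1),
            is_scalar_num(brightfield_loading, 0),
            is.numeric(cells_per_site), all(cells_per_site > 0),
            !is.null(names(cells_per_site)),
            is_count(sites_per_well),
            is_scalar_num(seed))
  if (!magnification %in% names(cells_per_site)) {
    stop("magnification '", magnification, "' has no cells_per_site entry",
         call. = FALSE)
  }
  structure(list(
    n_features_per_channel = as.integer(n_features_per_channel),
    n_channel_free_features = as.integer(n_channel_free_features),
    active_fraction = active_fraction,
    effect_size = effect_size,
    moa_sharing = moa_sharing,
    sigma_cell = sigma_cell,
    sigma_site = sigma_site,
    sigma_plate = sigma_plate,
    channel_correlation = channel_correlation,
    rna_er_redundancy = rna_er_redundancy,
    brightfield_loading = brightfield_loading,
    cells_per_site = cells_per_site,
    magnification = magnification,
    sites_per_well = as.integer(sites_per_well),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$magnification, "objective,",
      x$sites_per_well, "sites/well,",
      "lambda =", x$cells_per_site[[x$magnification]], "cells/site\n")
  cat("  effect a =", x$effect_size,
      "| active fraction f =", x$active_fraction,
      "| MOA sharing rho =", x$moa_sharing, "\n")
  cat("  noise: cell", x$sigma_cell, "site", x$sigma_site,
      "plate", x$sigma_plate,
      "| within-channel r =", x$channel_correlation, "\n")
  invisible(x)
}
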