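# Compound- and MOA-level effect vectors for the simulator.

#' Build the per-compound effect library
#'
#' Draws, deterministically for a given seed, the morphological effect
#' vector of every treatment compound on a plate. Each MOA class `m` gets a
#' unit direction `u_m` over the feature space and each compound `c` a unit
#' compound-specific direction `v_c`; the effect of an *active* compound is
#'
#'   `beta_c = a * (sqrt(rho) * u_m(c) + sqrt(1 - rho) * v_c)`
#'
#' with effect size `a` and MOA-sharing weight `rho`, so that two active
#' compounds sharing an MOA have expected effect-vector cosine similarity
#' `rho` (exactly parallel at `rho = 1`). A seeded subset of
#' `round(f * n_compounds)` compounds is active; the rest (and all
#' negative-control wells) get `beta = 0`.
#'
#' Two structural modifiers act on the directions before use:
#' * RNA/ER redundancy: the loading of the j-th single-channel RNA feature
#'   is mixed with the j-th ER feature's loading with weight
#'   `rna_er_redundancy`, mimicking the RNA dye's visibility in the ER
#'   channel — this is what makes dropping RNA features nearly neutral.
#' * Brightfield attenuation: loadings of Brightfield-referencing features
#'   are multiplied by `brightfield_loading`.
#'
#' @param platemap A [generate_jumpmoa_layout()] plate map (treatment
#'   compounds must carry MOA labels).
#' @param schema A [build_feature_schema()].
#' @param config A [sim_config()].
#' @return An `effect_library`: list with `beta` (compounds x features
#'   matrix), `active` (named logical), `u` (MOA directions matrix), `v`
#'   (compound directions matrix).
#' @export
build_effect_library <- function(platemap, schema, config) {
  stopifnot(inherits(schema, "feature_schema"), inherits(config, "sim_config"))
  treat <- platemap[platemap$role == "treatment", , drop = FALSE]
  if (!nrow(treat)) stop("plate map has no treatment wells", call. = FALSE)
  if (anyNA(treat$moa)) {
    stop("treatment compounds must have MOA labels", call. = FALSE)
  }
  cmpd_moa <- vapply(split(treat$moa, treat$compound_id), `[`, "", 1L)
  compounds <- names(cmpd_moa)
  moas <- sort(unique(cmpd_moa))
  feats <- schema$feature
  F <- length(feats)

  registry <- attr(schema, "registry")
  # aligned single-channel feature indices for RNA <- ER loading mixture
  single <- !is.na(schema$channel1) & is.na(schema$channel2)
  rna_idx <- which(single & schema$channel1 == "RNA")
  er_idx <- which(single & schema$channel1 == "ER")
  mix_rna <- config$rna_er_redundancy > 0 &&
    length(rna_idx) == length(er_idx) && length(rna_idx) > 0
  bf_idx <- which(vapply(channels_of_feature(feats, registry),
                         function(ch) "Brightfield" %in% ch, NA))

  shape_direction <- function(x) {
    if (mix_rna) {
      k <- config$rna_er_redundancy
      x[rna_idx] <- sqrt(k) * x[er_idx] + sqrt(1 - k) * x[rna_idx]
    }
    x / sqrt(sum(x^2))
  }

  lib <- with_seed(config$seed, {
    u <- t(vapply(moas, function(m) shape_direction(stats::rnorm(F)),
                  numeric(F)))
    v <- t(vapply(compounds, function(cc) shape_direction(stats::rnorm(F)),
                  numeric(F)))
    n_active <- round(config$active_fraction * length(compounds))
    active_set <- sample(compounds, n_active)
    list(u = u, v = v, active = stats::setNames(compounds %in% active_set,
                                                compounds))
  })
  colnames(lib$u) <- feats
  colnames(lib$v) <- feats

  rho <- config$moa_sharing
  beta <- config$effect_size *
    (sqrt(rho) * lib$u[cmpd_moa, , drop = FALSE] +
     sqrt(1 - rho) * lib$v)
  rownames(beta) <- compounds
  beta[!lib$active, ] <- 0
  if (length(bf_idx)) {
    beta[, bf_idx] <- beta[, bf_idx] * config$brightfield_loading
  }

  structure(list(beta = beta, active = lib$active, u = lib$u, v = lib$v,
                 compound_moa = cmpd_moa),
            class = "effect_library")
}

#' @export
print.effect_library <- function(x, ...) {
  cat("effect library: ", nrow(x$beta), " compounds x ", ncol(x$beta),
      " features; ", sum(x$active), " active\n", sep = "")
  invisible(x)
}
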