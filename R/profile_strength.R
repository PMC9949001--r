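# The profile-strength estimator: both metrics plus their nulls, as one
# classed result object.

#' Estimate profile strength for one plate of well profiles
#'
#' Computes percent replicating, percent matching, and their mean (percent
#' score) for a set of normalized, feature-selected well profiles against a
#' plate map, together with the resampled null distributions and
#' per-compound statistics that define them. This is the quantity the
#' setting leaderboards rank.
#'
#' @param profiles Well-level `profile` (normalized and feature-selected).
#' @param platemap The plate map the wells were treated under.
#' @param config A [metric_config()].
#' @return An object of class `profile_strength` with components
#'   `replicating`, `matching` (each: `percent`, `threshold`, `null`,
#'   `per_compound`, `n_evaluated`, `excluded`), `percent_score`, `config`,
#'   `setting`, `n_wells`, `n_features`, and `call`. Supports `print()`,
#'   `summary()`, and `plot()`.
#' @examples
#' \donttest{
#' pm <- generate_jumpmoa_layout(seed = 1)
#' cfg <- sim_config(n_features_per_channel = 3, n_channel_free_features = 3,
#'                   sites_per_well = 1, cells_per_site = c("20X" = 25),
#'                   effect_size = 2, seed = 1)
#' cells <- simulate_plate(pm, config = cfg)
#' prof <- feature_select(mad_robustize(aggregate_profiles(cells)))
#' ps <- profile_strength(prof, pm, metric_config(null_size = 1000))
#' ps
#' }
#' @export
profile_strength <- function(profiles, platemap, config = metric_config()) {
  stopifnot(inherits(config, "metric_config"))
  rep_frag <- percent_replicating(profiles, platemap, config)
  match_frag <- percent_matching(profiles, platemap, config)
  structure(list(
    replicating = rep_frag,
    matching = match_frag,
    percent_score = percent_score(rep_frag$percent, match_frag$percent),
    config = config,
    setting = attr(profiles, "setting"),
    n_wells = nrow(profiles),
    n_features = length(feature_cols(profiles)),
    call = match.call()
  ), class = "profile_strength")
}

#' @export
print.profile_strength <- function(x, digits = 1, ...) {
  cat("Profile strength",
      if (!is.null(x$setting)) paste0("(setting: ", x$setting, ")"), "\n")
  cat(sprintf("  percent replicating: %.*f%%  (%d compounds, threshold %.3f)\n",
              digits, x$replicating$percent, x$replicating$n_evaluated,
              x$replicating$threshold))
  cat(sprintf("  percent matching:    %.*f%%  (%d compounds, threshold %.3f)\n",
              digits, x$matching$percent, x$matching$n_evaluated,
              x$matching$threshold))
  cat(sprintf("  percent score:       %.*f%%\n", digits, x$percent_score))
  cat(sprintf("  null: %d draws, %gth percentile, unit '%s'\n",
              x$config$null_size, x$config$threshold_percentile,
              x$config$null_unit))
  invisible(x)
}

#' @describeIn profile_strength Per-compound table: median replicate and
#'   MOA-matching correlations and whether each passed its threshold.
#' @param object,x A `profile_strength` object.
#' @param ... Unused.
#' @export
summary.profile_strength <- function(object, ...) {
  r <- object$replicating$per_compound
  m <- object$matching$per_compound
  cmpds <- sort(union(names(r), names(m)))
  out <- data.frame(
    compound = cmpds,
    replicate_correlation = unname(r[cmpds]),
    replicating_pass = unname(r[cmpds] > object$replicating$threshold),
    matching_correlation = unname(m[cmpds]),
    matching_pass = unname(m[cmpds] > object$matching$threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, percent_replicating = object$replicating$percent,
            percent_matching = object$matching$percent,
            percent_score = object$percent_score,
            class = c("summary.profile_strength", "data.frame"))
}

#' @export
print.summary.profile_strength <- function(x, ...) {
  cat(sprintf("percent replicating %.1f%% | percent matching %.1f%% | percent score %.1f%%\n",
              attr(x, "percent_replicating"), attr(x, "percent_matching"),
              attr(x, "percent_score")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more compounds)\n", sep = "")
  invisible(x)
}

#' @describeIn profile_strength Null-distribution histograms with the
#'   percentile threshold (dashed) and the per-compound foreground
#'   statistics (rug).
#' @export
plot.profile_strength <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  panel <- function(frag, label) {
    rng <- range(frag$null, frag$per_compound, frag$threshold)
    graphics::hist(frag$null, breaks = 40, xlim = rng, col = "grey85",
                   border = "grey60", main = label,
                   xlab = "median Pearson correlation")
    graphics::abline(v = frag$threshold, lty = 2, col = "red3")
    graphics::rug(frag$per_compound, col = "blue3", lwd = 1.5)
    graphics::mtext(sprintf("%.1f%% pass", frag$percent), side = 3,
                    line = -1.5, adj = 0.98, cex = 0.8)
  }
  panel(x$replicating, "Percent replicating")
  panel(x$matching, "Percent matching")
  invisible(x)
}
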