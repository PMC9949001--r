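# Percent replicating / percent matching and their resampling nulls.

#' Metric configuration
#'
#' Parameters of the profile-strength statistics. The defaults follow the
#' published procedure: a null distribution of 10,000 resampled
#' non-matching well groups and a 95th-percentile significance threshold,
#' with Pearson correlation across post-selection feature columns.
#'
#' @param null_size Number of null resampling draws K (default 10,000).
#' @param threshold_percentile Null percentile q defining the threshold
#'   (default 95; strict `>` at the threshold).
#' @param correlation Correlation kind; only `"pearson"` is implemented.
#' @param null_unit `"group"` (default): each null draw mirrors the
#'   foreground statistic — a group of wells/compounds summarized by its
#'   median pairwise correlation, making null and foreground exchangeable.
#'   `"pair"`: each draw is a single non-matching well pair's correlation.
#' @param include_negcon_null Allow negative-control wells into the null
#'   draws (they are always excluded from the foreground)?
#' @param seed Integer seed for the null resampling.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(null_size = 10000L, threshold_percentile = 95,
                          correlation = c("pearson"),
                          null_unit = c("group", "pair"),
                          include_negcon_null = FALSE, seed = 0L) {
  stopifnot(is_count(null_size),
            is_scalar_num(threshold_percentile, 1e-9, 100 - 1e-9),
            is_scalar_num(seed))
  structure(list(null_size = as.integer(null_size),
                 threshold_percentile = threshold_percentile,
                 correlation = match.arg(correlation),
                 null_unit = match.arg(null_unit),
                 include_negcon_null = include_negcon_null,
                 seed = as.integer(seed)),
            class = "metric_config")
}

# Assemble the well x feature matrix and per-well annotation used by every
# metric: treatment wells only (negcon optionally kept for the null),
# empty-profile and zero-variance rows excluded with a warning.
.metric_frame <- function(profiles, platemap) {
  fcols <- feature_cols(profiles)
  M <- as.matrix(as.data.frame(profiles)[, fcols, drop = FALSE])
  well <- profiles$Metadata_Well
  if (is.null(well)) stop("profiles lack Metadata_Well", call. = FALSE)
  pm_idx <- match(well, platemap$well_position)
  if (anyNA(pm_idx)) {
    stop("profiled well(s) absent from plate map: ",
         paste(well[is.na(pm_idx)], collapse = ", "), call. = FALSE)
  }
  compound <- platemap$compound_id[pm_idx]
  moa <- platemap$moa[pm_idx]
  role <- platemap$role[pm_idx]

  incomplete <- !stats::complete.cases(M)
  if (any(incomplete)) {
    warning("excluding ", sum(incomplete),
            " profile(s) with missing feature values", call. = FALSE)
  }
  novar <- !incomplete & apply(M, 1L, function(x) stats::sd(x) == 0)
  if (any(novar)) {
    warning("excluding ", sum(novar),
            " zero-variance profile(s); correlation undefined",
            call. = FALSE)
  }
  keep <- !incomplete & !novar
  list(M = M[keep, , drop = FALSE], well = well[keep],
       compound = compound[keep], moa = moa[keep], role = role[keep])
}

# Well x well Pearson correlation matrix over feature columns.
.well_cor <- function(M) stats::cor(t(M))

.upper_vals <- function(cm, idx) {
  sub <- cm[idx, idx, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Median replicate correlation per compound
#'
#' For each treatment compound with at least two profiled wells, the median
#' of all pairwise Pearson correlations (across feature columns) among its
#' replicate wells.
#'
#' @param profiles Well-level `profile` (normalized and feature-selected).
#' @param platemap The plate map.
#' @return Named numeric vector `r_c`; compounds with fewer than two
#'   profiled wells are excluded and listed in the `excluded` attribute.
#' @export
median_replicate_correlation <- function(profiles, platemap) {
  fr <- .metric_frame(profiles, platemap)
  treat <- fr$role == "treatment"
  cm <- .well_cor(fr$M)
  groups <- split(which(treat), fr$compound[treat])
  sizes <- lengths(groups)
  eval_g <- groups[sizes >= 2L]
  r <- vapply(eval_g, function(idx) stats::median(.upper_vals(cm, idx)),
              numeric(1))
  structure(r, excluded = names(groups)[sizes < 2L])
}

#' Median MOA-matching correlation per compound
#'
#' For each compound whose MOA class contains at least one *other* profiled
#' compound, the median Pearson correlation over all well pairs (well of
#' the compound) x (well of a same-MOA different compound).
#'
#' @inheritParams median_replicate_correlation
#' @return Named numeric vector `m_c`; compounds in singleton MOA classes
#'   are excluded and listed in the `excluded` attribute.
#' @export
median_moa_correlation <- function(profiles, platemap) {
  fr <- .metric_frame(profiles, platemap)
  treat <- which(fr$role == "treatment")
  cm <- .well_cor(fr$M)
  compounds <- unique(fr$compound[treat])
  cmpd_moa <- vapply(compounds,
                     function(cc) fr$moa[treat][fr$compound[treat] == cc][1L],
                     "")
  res <- numeric(0); excluded <- character(0)
  for (cc in compounds) {
    own <- treat[fr$compound[treat] == cc]
    partners <- treat[fr$moa[treat] == cmpd_moa[[cc]] &
                      fr$compound[treat] != cc]
    if (!length(partners)) {
      excluded <- c(excluded, cc)
      next
    }
    res[cc] <- stats::median(cm[own, partners])
  }
  structure(res, excluded = excluded)
}

#' Resample a null distribution of non-matching correlations
#'
#' Draws `K` seeded resamples from the profiled treatment wells and returns
#' one summary correlation per draw.
#'
#' With `null_unit = "group"` (default) each draw mirrors the foreground
#' statistic: for `mode = "non-replicate"`, `group_size` wells with
#' pairwise-distinct compounds, summarized by the median of all pairwise
#' correlations; for `mode = "non-matching-moa"`, `group_size` *compounds*
#' with pairwise-distinct MOA classes, summarized by the median correlation
#' over all cross-compound well pairs. With `null_unit = "pair"` each draw
#' is a single well pair (distinct compounds, or distinct MOAs) and its
#' correlation. Draws violating the distinctness rule are rejected and
#' redrawn; sampling is without replacement within a draw and with
#' replacement across draws.
#'
#' @inheritParams median_replicate_correlation
#' @param group_size Wells (or compounds, for the MOA mode) per draw.
#' @param K Number of draws.
#' @param mode `"non-replicate"` or `"non-matching-moa"`.
#' @param seed Integer seed.
#' @param null_unit See [metric_config()].
#' @param include_negcon Include negative-control wells in the draws?
#' @return Numeric vector of length `K`.
#' @export
sample_null <- function(profiles, platemap, group_size = 4L, K = 10000L,
                        mode = c("non-replicate", "non-matching-moa"),
                        seed = 0L, null_unit = c("group", "pair"),
                        include_negcon = FALSE) {
  mode <- match.arg(mode)
  null_unit <- match.arg(null_unit)
  stopifnot(is_count(group_size, min = 2L), is_count(K))
  fr <- .metric_frame(profiles, platemap)
  pool <- if (include_negcon) seq_along(fr$well) else which(fr$role == "treatment")
  cm <- .well_cor(fr$M)
  compound <- fr$compound
  moa <- fr$moa
  # negcon wells have no MOA; treat each as its own pseudo-class for
  # distinctness when included in the null
  moa[is.na(moa)] <- paste0(".negcon_", fr$well[is.na(moa)])

  if (mode == "non-replicate") {
    if (length(unique(compound[pool])) < group_size) {
      stop("cannot draw ", group_size, " wells with distinct compounds",
           call. = FALSE)
    }
  } else {
    if (length(unique(moa[pool])) < group_size) {
      stop("cannot draw ", group_size, " groups with distinct MOA classes",
           call. = FALSE)
    }
  }

  with_seed(seed, {
    out <- numeric(K)
    if (null_unit == "pair") {
      for (k in seq_len(K)) {
        repeat {
          idx <- sample(pool, 2L)
          ok <- if (mode == "non-replicate")
            compound[idx[1L]] != compound[idx[2L]]
          else moa[idx[1L]] != moa[idx[2L]]
          if (ok) break
        }
        out[k] <- cm[idx[1L], idx[2L]]
      }
    } else if (mode == "non-replicate") {
      for (k in seq_len(K)) {
        repeat {
          idx <- sample(pool, group_size)
          if (length(unique(compound[idx])) == group_size) break
        }
        out[k] <- stats::median(.upper_vals(cm, idx))
      }
    } else {
      cmpds <- unique(compound[pool])
      cmpd_wells <- split(pool, compound[pool])[cmpds]
      cmpd_moa <- vapply(cmpds, function(cc) moa[cmpd_wells[[cc]][1L]], "")
      for (k in seq_len(K)) {
        repeat {
          pick <- sample(cmpds, group_size)
          if (length(unique(cmpd_moa[pick])) == group_size) break
        }
        wells <- cmpd_wells[pick]
        vals <- unlist(lapply(seq_len(group_size - 1L), function(i) {
          lapply((i + 1L):group_size, function(j) {
            cm[wells[[i]], wells[[j]]]
          })
        }), use.names = FALSE)
        out[k] <- stats::median(vals)
      }
    }
    out
  })
}

#' Linear-interpolation percentile
#'
#' The inclusive-endpoint linear-interpolation convention (R's default
#' quantile type 7): `percentile(0:99, 95)` is 94.05 and
#' `percentile(x, 100)` is `max(x)`.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in (0, 100].
#' @return A single number.
#' @export
percentile <- function(values, q) {
  if (!length(values)) stop("empty value list", call. = FALSE)
  stats::quantile(values, q / 100, type = 7, names = FALSE)
}

# Shared scaffolding for the two metric fragments.
.percent_metric <- function(stat, null, q) {
  threshold <- percentile(null, q)
  list(per_compound = stat,
       threshold = threshold,
       null = null,
       percent = 100 * mean(stat > threshold),  # strict: ties fail
       n_evaluated = length(stat),
       excluded = attr(stat, "excluded"))
}

#' Percent replicating
#'
#' The fraction (as a percentage) of evaluated compounds whose median
#' replicate correlation exceeds the `q`-th percentile of the non-replicate
#' null distribution.
#'
#' @inheritParams median_replicate_correlation
#' @param config A [metric_config()].
#' @param group_size Wells per null draw; defaults to the plate's replicate
#'   count.
#' @return List with `percent`, `threshold`, `null`, `per_compound`,
#'   `n_evaluated`, `excluded`.
#' @export
percent_replicating <- function(profiles, platemap, config = metric_config(),
                                group_size = attr(platemap, "replicates") %||% 4L) {
  r_c <- median_replicate_correlation(profiles, platemap)
  if (!length(r_c)) stop("no compounds with >= 2 profiled wells", call. = FALSE)
  null <- sample_null(profiles, platemap, group_size = group_size,
                      K = config$null_size, mode = "non-replicate",
                      seed = config$seed, null_unit = config$null_unit,
                      include_negcon = config$include_negcon_null)
  .percent_metric(r_c, null, config$threshold_percentile)
}

#' Percent matching
#'
#' The fraction (as a percentage) of evaluated compounds whose median
#' MOA-matching correlation exceeds the `q`-th percentile of the
#' non-matching-MOA null distribution. Compounds in singleton MOA classes
#' cannot be evaluated; they are excluded and reported.
#'
#' @inheritParams percent_replicating
#' @return As [percent_replicating()].
#' @export
percent_matching <- function(profiles, platemap, config = metric_config()) {
  m_c <- median_moa_correlation(profiles, platemap)
  if (!length(m_c)) stop("no MOA class with >= 2 profiled compounds",
                         call. = FALSE)
  null <- sample_null(profiles, platemap, group_size = 2L,
                      K = config$null_size, mode = "non-matching-moa",
                      seed = config$seed + 1L, null_unit = config$null_unit,
                      include_negcon = config$include_negcon_null)
  .percent_metric(m_c, null, config$threshold_percentile)
}

#' Percent score
#'
#' The arithmetic mean of percent replicating and percent matching for one
#' profile/setting.
#'
#' @param pr,pm Percentages in `[0, 100]` (vectorized).
#' @return `(pr + pm) / 2`.
#' @export
percent_score <- function(pr, pm) {
  stopifnot(all(pr >= 0 & pr <= 100), all(pm >= 0 & pm <= 100))
  (pr + pm) / 2
}

#' Mean-aggregate duplicate setting labels
#'
#' Leaderboards carry one row per setting combination; plates acquired
#' under a duplicated setting label are mean aggregated first.
#'
#' @param scores Data frame with a `setting` column and numeric score
#'   column(s).
#' @param score_cols Which columns to average (default: every numeric one).
#' @return One row per distinct setting, scores averaged.
#' @export
mean_aggregate_duplicates <- function(scores,
                                      score_cols = names(scores)[vapply(scores, is.numeric, NA)]) {
  stopifnot("setting" %in% names(scores))
  agg <- stats::aggregate(scores[score_cols],
                          by = list(setting = scores$setting), FUN = mean)
  agg[order(agg$setting), , drop = FALSE]
}

#' Normalize a leaderboard to its best setting
#'
#' Each percent score is rescaled to `100 * score / max(score)` so the
#' best-performing setting reads 100; rows are ordered by descending
#' normalized score, ties ordered by setting label.
#'
#' @param scores Data frame with `setting` and `percent_score` columns
#'   (duplicates already aggregated, see [mean_aggregate_duplicates()]).
#' @return The leaderboard with `normalized_score` and `place` columns.
#' @export
normalize_leaderboard <- function(scores) {
  stopifnot(all(c("setting", "percent_score") %in% names(scores)))
  best <- max(scores$percent_score)
  if (best <= 0) stop("all scores are zero; cannot normalize", call. = FALSE)
  scores$normalized_score <- 100 * scores$percent_score / best
  ord <- order(-scores$normalized_score, scores$setting)
  scores <- scores[ord, , drop = FALSE]
  scores$place <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}
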