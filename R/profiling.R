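# Well-profile construction: aggregation, normalization, channel dropout.

.profile_attrs <- c("level", "empty_wells", "setting", "normalized",
                    "selected", "provenance", "selection_trace",
                    "dropped_channels")

# `[.data.frame` drops custom attributes; keep profile provenance intact
# across row/column subsetting.
#' @export
`[.profile` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in .profile_attrs) attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}

#' @export
`[.feature_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("empty_wells", "setting")) attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}

#' Aggregate a single-cell table into site- or well-level profiles
#'
#' Computes the per-group arithmetic mean of every feature over all cells in
#' the group — for `level = "well"` the mean is over *cells*, not over site
#' means, so sites with more cells weigh proportionally more. Cell counts
#' are recorded in `Metadata_CellCount` (and `Metadata_Sites`, the number of
#' sites contributing cells, at well level). Wells listed in the input's
#' `empty_wells` attribute (zero cells) yield a row of missing feature
#' values, flagged in the `empty_wells` attribute of the result.
#'
#' @param cells Feature table with `Metadata_Plate`, `Metadata_Well` (and
#'   `Metadata_Site` for site-level) columns.
#' @param level `"well"` (default) or `"site"`.
#' @return A `profile` data frame, one row per group, metadata columns
#'   first.
#' @examples
#' tab <- data.frame(Metadata_Plate = "P", Metadata_Well = "A01",
#'                   f1 = c(1, 5), f2 = c(3, 7))
#' aggregate_profiles(tab)[, c("f1", "f2")]  # 3, 5
#' @export
aggregate_profiles <- function(cells, level = c("well", "site")) {
  level <- match.arg(level)
  need <- c("Metadata_Plate", "Metadata_Well",
            if (level == "site") "Metadata_Site")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("missing grouping metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fcols <- feature_cols(cells)
  key <- do.call(paste, c(unname(cells[need]), list(sep = "\r")))
  ord <- !duplicated(key)
  counts <- as.vector(table(key)[key[ord]])
  sums <- rowsum(as.matrix(cells[, fcols, drop = FALSE]), key,
                 reorder = FALSE)
  means <- sums / counts

  meta_keep <- intersect(c("Metadata_Plate", "Metadata_Well", "Metadata_Site",
                           "Metadata_Compound", "Metadata_MOA",
                           "Metadata_Setting"), names(cells))
  if (level == "well") meta_keep <- setdiff(meta_keep, "Metadata_Site")
  plain <- cells
  class(plain) <- "data.frame"
  prof <- plain[ord, meta_keep, drop = FALSE]
  prof$Metadata_CellCount <- counts
  if (level == "well" && "Metadata_Site" %in% names(cells)) {
    nsites <- tapply(cells$Metadata_Site, key, function(s) length(unique(s)))
    prof$Metadata_Sites <- as.integer(nsites[key[ord]])
  }
  prof <- cbind(prof, as.data.frame(means, row.names = NULL))

  empty <- attr(cells, "empty_wells")
  if (level == "well" && length(empty)) {
    pad <- prof[rep(NA_integer_, length(empty)), , drop = FALSE]
    pad$Metadata_Plate <- unique(cells$Metadata_Plate)[1L]
    pad$Metadata_Well <- empty
    pad$Metadata_CellCount <- 0L
    prof <- rbind(prof, pad)
  }
  rownames(prof) <- NULL
  structure(prof,
            level = level,
            empty_wells = empty %||% character(),
            setting = attr(cells, "setting"),
            normalized = FALSE, selected = FALSE,
            provenance = list(),
            class = c("profile", "data.frame"))
}

#' Per-plate MAD robustization
#'
#' Robust per-feature standardization within each plate:
#' `x <- (x - median(x)) / (1.4826 * MAD(x) + epsilon)`, where MAD is the
#' raw median absolute deviation from the median and 1.4826 is the
#' consistency constant that makes the robust scale comparable to a
#' standard deviation for Gaussian data. Features whose MAD is 0 on a plate
#' (near-constant) become all-missing on that plate and are left for
#' feature selection to remove.
#'
#' @param profiles A `profile` (well-level recommended) with >= 2 rows per
#'   plate.
#' @param epsilon Small stabilizer added to the scale (default 1e-18).
#' @return The robustized `profile`; attribute `normalized` set.
#' @export
mad_robustize <- function(profiles, epsilon = 1e-18) {
  fcols <- feature_cols(profiles)
  plates <- unique(profiles$Metadata_Plate)
  for (p in plates) {
    idx <- which(profiles$Metadata_Plate == p)
    if (length(idx) < 2L) {
      stop("plate ", p, " has a single profile; cannot robustize",
           call. = FALSE)
    }
    M <- as.matrix(profiles[idx, fcols, drop = FALSE])
    med <- apply(M, 2L, stats::median, na.rm = TRUE)
    madv <- apply(sweep(M, 2L, med), 2L,
                  function(z) stats::median(abs(z), na.rm = TRUE))
    scaled <- sweep(sweep(M, 2L, med), 2L, 1.4826 * madv + epsilon, `/`)
    scaled[, madv == 0 | is.na(madv)] <- NA_real_
    profiles[idx, fcols] <- scaled
  }
  attr(profiles, "normalized") <- TRUE
  profiles
}

#' Feature selection for well profiles
#'
#' Applies, in order, the requested selection operations:
#' \describe{
#'   \item{`drop_na`}{remove features whose missing fraction exceeds
#'     `na_cutoff`.}
#'   \item{`variance_threshold`}{remove near-zero-variance features: ratio
#'     of the most common to the second most common value > `freq_cut`
#'     *and* unique-value fraction < `unique_cut`.}
#'   \item{`correlation_threshold`}{while any feature pair has
#'     `|Pearson r| > corr_cutoff`, remove the involved feature with the
#'     largest mean absolute correlation to all remaining features (ties
#'     broken lexicographically by feature name), then recompute.}
#' }
#' The removed features and the rule that removed each are recorded in the
#' result's `selection_trace` attribute.
#'
#' @param profiles A normalized `profile`.
#' @param ops Character vector of operations, applied in the given order.
#' @param corr_cutoff Absolute-correlation cutoff (default 0.9).
#' @param na_cutoff Maximum tolerated missing fraction (default 0.05).
#' @param freq_cut,unique_cut Near-zero-variance parameters (defaults 19
#'   and 0.01, i.e. 95/5 frequency ratio and < 1% unique values).
#' @return The selected `profile`; attributes `selected` and
#'   `selection_trace` set.
#' @export
feature_select <- function(profiles,
                           ops = c("drop_na", "variance_threshold",
                                   "correlation_threshold"),
                           corr_cutoff = 0.9, na_cutoff = 0.05,
                           freq_cut = 19, unique_cut = 0.01) {
  stopifnot(all(ops %in% c("drop_na", "variance_threshold",
                           "correlation_threshold")))
  trace <- list()
  for (op in ops) {
    fcols <- feature_cols(profiles)
    if (!length(fcols)) break
    M <- as.matrix(as.data.frame(profiles)[, fcols, drop = FALSE])
    drop <- character()
    if (op == "drop_na") {
      na_frac <- colMeans(is.na(M))
      drop <- fcols[na_frac > na_cutoff]
    } else if (op == "variance_threshold") {
      nzv <- vapply(fcols, function(f) {
        x <- M[, f]; x <- x[!is.na(x)]
        if (!length(x)) return(TRUE)
        tab <- sort(table(x), decreasing = TRUE)
        ratio <- if (length(tab) < 2L) Inf else tab[[1L]] / tab[[2L]]
        ratio > freq_cut && (length(tab) / length(x)) < unique_cut
      }, NA)
      drop <- fcols[nzv]
    } else {  # correlation_threshold
      sds <- apply(M, 2L, function(x) stats::sd(x, na.rm = TRUE))
      keep <- fcols[!is.na(sds) & sds > 0]
      if (length(keep) < 2L) next
      cm <- abs(stats::cor(M[, keep, drop = FALSE],
                           use = "pairwise.complete.obs"))
      diag(cm) <- 0
      while (length(keep) > 1L && max(cm, na.rm = TRUE) > corr_cutoff) {
        involved <- colnames(cm)[apply(cm > corr_cutoff, 2L, any, na.rm = TRUE)]
        mean_abs <- rowMeans(cm[involved, , drop = FALSE], na.rm = TRUE)
        worst <- involved[order(-mean_abs, involved)][1L]
        drop <- c(drop, worst)
        keep <- setdiff(keep, worst)
        cm <- cm[keep, keep, drop = FALSE]
      }
    }
    if (length(drop)) {
      trace[[op]] <- c(trace[[op]], drop)
      profiles <- profiles[, setdiff(names(profiles), drop), drop = FALSE]
    }
  }
  if (!length(feature_cols(profiles))) {
    stop("feature selection removed every feature", call. = FALSE)
  }
  attr(profiles, "selected") <- TRUE
  attr(profiles, "selection_trace") <- trace
  profiles
}

#' Drop all features of one channel
#'
#' Removes every feature whose channel set (by name parsing, see
#' [channels_of_feature()]) contains `channel` — including two-channel
#' colocalization features naming it. Emulates re-profiling an acquisition
#' without that channel; intended to run *before* feature selection, as in
#' the RNA- and brightfield-dropout analyses.
#'
#' @param profiles A `profile` (or any feature table).
#' @param channel Channel token to drop.
#' @param registry The [channel_registry()] the feature names follow.
#' @return The table without that channel's features; the drop is recorded
#'   in the `dropped_channels` attribute.
#' @export
drop_channel_features <- function(profiles, channel,
                                  registry = channel_registry()) {
  if (!channel %in% as.character(registry)) {
    stop("channel '", channel, "' is not in the registry", call. = FALSE)
  }
  if (isTRUE(attr(profiles, "selected"))) {
    warning("dropping channel features after feature selection; ",
            "the published procedure drops before selection", call. = FALSE)
  }
  fcols <- feature_cols(profiles)
  hit <- vapply(channels_of_feature(fcols, registry),
                function(ch) channel %in% ch, NA)
  out <- profiles[, setdiff(names(profiles), fcols[hit]), drop = FALSE]
  attr(out, "dropped_channels") <- c(attr(profiles, "dropped_channels"),
                                     channel)
  out
}
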