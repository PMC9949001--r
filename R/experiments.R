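# Setting-perturbation experiments: site subsampling, cell-count curves,
# channel dropout, channel-correlation summaries, end-to-end runs.

# default-builder alias: inside experiment_spec() the argument named
# `metric_config` shadows the constructor
.default_metric_config <- function() metric_config()

#' Experiment specification
#'
#' Bundles a base simulation configuration with the perturbations to sweep:
#' site-subsampling targets, channels to drop, magnifications, and effect
#' sizes. Used by [cellcount_curve()], [channel_dropout_experiment()] and
#' [run_experiment()].
#'
#' @param base_config A [sim_config()] (its `sites_per_well` is the number
#'   of sites actually simulated; subsampling targets must not exceed it).
#' @param metric_config A [metric_config()].
#' @param site_targets Integer vector of site counts to subsample to.
#' @param drop_channels Character vector of channel tokens to drop (each
#'   produces a with/without comparison).
#' @param magnifications Magnifications to sweep (must have
#'   `cells_per_site` entries in `base_config`).
#' @param effect_sizes Effect magnitudes to sweep.
#' @param seed Integer master seed for the experiment.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(base_config = sim_config(),
                            metric_config = NULL,
                            site_targets = seq_len(base_config$sites_per_well),
                            drop_channels = character(),
                            magnifications = base_config$magnification,
                            effect_sizes = base_config$effect_size,
                            seed = base_config$seed) {
  if (is.null(metric_config)) metric_config <- .default_metric_config()
  stopifnot(inherits(base_config, "sim_config"),
            inherits(metric_config, "metric_config"))
  site_targets <- as.integer(site_targets)
  if (any(site_targets < 1L) ||
      any(site_targets > base_config$sites_per_well)) {
    stop("site targets must lie in 1..sites_per_well", call. = FALSE)
  }
  if (!all(magnifications %in% names(base_config$cells_per_site))) {
    stop("magnification(s) without a cells_per_site entry", call. = FALSE)
  }
  structure(list(base_config = base_config, metric_config = metric_config,
                 site_targets = site_targets, drop_channels = drop_channels,
                 magnifications = magnifications,
                 effect_sizes = effect_sizes, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Read an experiment specification from YAML
#'
#' The YAML file may contain `sim`, `metric`, and `experiment` mappings
#' whose keys are the arguments of [sim_config()], [metric_config()], and
#' [experiment_spec()] respectively; omitted keys take the defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_spec`.
#' @export
read_experiment_spec <- function(path) {
  y <- yaml::read_yaml(path)
  base <- do.call(sim_config, y$sim %||% list())
  met <- do.call(metric_config, y$metric %||% list())
  args <- y$experiment %||% list()
  args$base_config <- base
  args$metric_config <- met
  do.call(experiment_spec, args)
}

#' Subsample acquisition sites and re-aggregate
#'
#' Emulates having acquired fewer sites: for every well, `target_sites`
#' site labels are chosen uniformly without replacement (an independent
#' seeded draw per well), only cells from those sites are kept, and the
#' well profile is recomputed as the cell-level mean. Provenance records
#' the retained sites and new cell counts.
#'
#' @param cells Single-cell feature table with `Metadata_Site`.
#' @param target_sites Number of sites to keep per well.
#' @param seed Integer seed for the per-well site draws.
#' @return A well-level `profile`; attribute `sites_used` maps wells to the
#'   retained site labels.
#' @export
subsample_sites <- function(cells, target_sites, seed = 0L) {
  stopifnot(is_count(target_sites))
  if (!"Metadata_Site" %in% names(cells)) {
    stop("missing Metadata_Site column", call. = FALSE)
  }
  wkey <- paste(cells$Metadata_Plate, cells$Metadata_Well, sep = "\r")
  avail <- lapply(split(cells$Metadata_Site, wkey), unique)
  short <- lengths(avail) < target_sites
  if (any(short)) {
    stop("well(s) with fewer than ", target_sites, " sites: ",
         paste(sub(".*\r", "", names(avail)[short]), collapse = ", "),
         call. = FALSE)
  }
  chosen <- with_seed(seed, lapply(avail, function(s) {
    sort(s[sample.int(length(s), target_sites)])
  }))
  allowed <- unlist(lapply(names(chosen), function(key) {
    paste(key, chosen[[key]], sep = "\r")
  }), use.names = FALSE)
  keep <- paste(wkey, cells$Metadata_Site, sep = "\r") %in% allowed
  prof <- aggregate_profiles(cells[keep, , drop = FALSE], level = "well")
  attr(prof, "sites_used") <- chosen
  prof
}

# One full pipeline pass: cells -> well profiles -> robustize -> select.
.pipeline <- function(cells, drop_channel = NULL,
                      registry = channel_registry(), ...) {
  prof <- aggregate_profiles(cells, level = "well")
  if (!is.null(drop_channel)) {
    prof <- drop_channel_features(prof, drop_channel, registry)
  }
  feature_select(mad_robustize(prof), ...)
}

#' Cell-count / site-count profile-strength curve
#'
#' For every magnification in the spec, simulates a plate at the full site
#' count, then subsamples each well to every target site count, runs the
#' profiling pipeline and both metrics, and reports one row per condition —
#' the desk-scale analogue of sweeping acquisition settings to relate plate
#' cell count to profile strength.
#'
#' @param spec An [experiment_spec()].
#' @param platemap Plate map (default: the standard JUMP-MOA layout under
#'   the spec seed).
#' @return Data frame with columns `magnification`, `sites`,
#'   `plate_cell_count`, `percent_replicating`, `percent_matching`,
#'   `percent_score`.
#' @export
cellcount_curve <- function(spec,
                            platemap = generate_jumpmoa_layout(seed = spec$seed)) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  seeds <- derive_seeds(spec$seed, length(spec$magnifications), stream = 1L)
  for (i in seq_along(spec$magnifications)) {
    mag <- spec$magnifications[i]
    cfg <- spec$base_config
    cfg$magnification <- mag
    cells <- simulate_plate(platemap, config = cfg,
                            setting_label = mag, seed = seeds[i])
    sub_seeds <- derive_seeds(seeds[i], length(spec$site_targets),
                              stream = 2L)
    for (j in seq_along(spec$site_targets)) {
      s <- spec$site_targets[j]
      prof <- subsample_sites(cells, s, seed = sub_seeds[j])
      sel <- feature_select(mad_robustize(prof))
      ps <- profile_strength(sel, platemap, spec$metric_config)
      rows[[length(rows) + 1L]] <- data.frame(
        magnification = mag, sites = s,
        plate_cell_count = sum(prof$Metadata_CellCount),
        percent_replicating = ps$replicating$percent,
        percent_matching = ps$matching$percent,
        percent_score = ps$percent_score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Channel-dropout experiment
#'
#' Runs the profiling pipeline twice from the *same* simulated cells — once
#' intact, once with the channel's features dropped before feature
#' selection — and reports both profile-strength results and their
#' difference. This is the procedure used to test whether RNA or
#' brightfield features carry non-redundant signal.
#'
#' @param spec An [experiment_spec()].
#' @param channel Channel token to drop.
#' @param platemap Plate map (default: standard layout under the spec seed).
#' @param registry Channel registry of the simulated schema.
#' @return List with `with` and `without` (`profile_strength` objects) and
#'   `delta` (named numeric: without minus with, for both metrics and the
#'   percent score).
#' @export
channel_dropout_experiment <- function(spec, channel,
                                       platemap = generate_jumpmoa_layout(seed = spec$seed),
                                       registry = channel_registry()) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (!channel %in% as.character(registry)) {
    stop("channel '", channel, "' is not in the registry", call. = FALSE)
  }
  cells <- simulate_plate(platemap, config = spec$base_config,
                          setting_label = spec$base_config$magnification,
                          seed = spec$seed)
  with_ps <- profile_strength(.pipeline(cells, registry = registry),
                              platemap, spec$metric_config)
  without_ps <- profile_strength(
    .pipeline(cells, drop_channel = channel, registry = registry),
    platemap, spec$metric_config)
  list(with = with_ps, without = without_ps,
       delta = c(
         percent_replicating = without_ps$replicating$percent -
           with_ps$replicating$percent,
         percent_matching = without_ps$matching$percent -
           with_ps$matching$percent,
         percent_score = without_ps$percent_score - with_ps$percent_score))
}

#' Channel-by-channel feature-correlation summary
#'
#' For every channel pair, the mean absolute Pearson correlation (computed
#' across wells) between the features attributed to one channel and those
#' attributed to the other; the diagonal holds the within-channel mean
#' excluding self-pairs. Channels without features give missing rows and
#' columns.
#'
#' @param profiles Well-level `profile`.
#' @param registry A [channel_registry()].
#' @return Symmetric numeric matrix, channels x channels.
#' @export
channel_correlation_summary <- function(profiles,
                                        registry = channel_registry()) {
  chans <- as.character(registry)
  if (length(chans) < 2L) stop("need >= 2 channels", call. = FALSE)
  fcols <- feature_cols(profiles)
  membership <- channels_of_feature(fcols, registry)
  by_chan <- lapply(chans, function(ch) {
    fcols[vapply(membership, function(x) ch %in% x, NA)]
  })
  names(by_chan) <- chans
  M <- as.matrix(as.data.frame(profiles)[, fcols, drop = FALSE])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  cm <- abs(stats::cor(M))
  out <- matrix(NA_real_, length(chans), length(chans),
                dimnames = list(chans, chans))
  for (i in seq_along(chans)) {
    fi <- by_chan[[i]]
    if (!length(fi)) next
    for (j in i:length(chans)) {
      fj <- by_chan[[j]]
      if (!length(fj)) next
      block <- cm[fi, fj, drop = FALSE]
      if (i == j) {
        vals <- block[upper.tri(block)]
        # shared-feature pairs (a colocalization feature vs itself) excluded
        out[i, j] <- if (length(vals)) mean(vals) else NA_real_
      } else {
        shared <- intersect(fi, fj)
        for (f in shared) block[f, f] <- NA
        out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
      }
    }
  }
  out
}

#' Run a full setting-comparison experiment
#'
#' Simulates one plate per (magnification x site-target) setting
#' combination, runs the profiling pipeline and metrics for each, writes
#' all artifacts (profiles, metric JSONs, leaderboard CSV, log), and
#' finishes with a manifest JSON recording the seed, configuration hash,
#' package version, per-stage status and every artifact path. A failed
#' setting is marked `failed` in the manifest and the run continues.
#'
#' @param spec An [experiment_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @param platemap Plate map shared by every setting.
#' @return Invisibly, the manifest list. The leaderboard is written to
#'   `leaderboard.csv` in `out_dir`.
#' @export
run_experiment <- function(spec, out_dir,
                           platemap = generate_jumpmoa_layout(seed = spec$seed)) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(sim = unclass(spec$base_config),
                            metric = unclass(spec$metric_config),
                            site_targets = spec$site_targets,
                            magnifications = spec$magnifications,
                            seed = spec$seed),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  write_platemap(platemap, file.path(out_dir, "platemap.csv"))

  settings <- expand.grid(magnification = spec$magnifications,
                          sites = spec$site_targets,
                          stringsAsFactors = FALSE)
  stages <- list(); scores <- list()
  seeds <- derive_seeds(spec$seed, nrow(settings), stream = 3L)
  for (k in seq_len(nrow(settings))) {
    mag <- settings$magnification[k]; s <- settings$sites[k]
    label <- sprintf("%s_%dsite", mag, s)
    logf("setting ", label, ": simulate + profile + metrics")
    res <- tryCatch({
      cfg <- spec$base_config
      cfg$magnification <- mag
      cells <- simulate_plate(platemap, config = cfg, setting_label = label,
                              seed = seeds[k])
      prof <- subsample_sites(cells, s, seed = seeds[k] + 1L)
      sel <- feature_select(mad_robustize(prof))
      ps <- profile_strength(sel, platemap, spec$metric_config)
      prof_path <- file.path(out_dir, paste0("profiles_", label, ".csv"))
      write_profiles(sel, prof_path)
      met_path <- file.path(out_dir, paste0("metrics_", label, ".json"))
      jsonlite::write_json(list(
        setting = label,
        percent_replicating = ps$replicating$percent,
        percent_matching = ps$matching$percent,
        percent_score = ps$percent_score,
        threshold_replicating = ps$replicating$threshold,
        threshold_matching = ps$matching$threshold,
        n_evaluated_replicating = ps$replicating$n_evaluated,
        n_evaluated_matching = ps$matching$n_evaluated,
        plate_cell_count = sum(prof$Metadata_CellCount)),
        met_path, auto_unbox = TRUE, digits = NA)
      scores[[label]] <- data.frame(
        setting = label, magnification = mag, sites = s,
        percent_replicating = ps$replicating$percent,
        percent_matching = ps$matching$percent,
        percent_score = ps$percent_score, stringsAsFactors = FALSE)
      list(status = "complete",
           artifacts = c(profiles = basename(prof_path),
                         metrics = basename(met_path)))
    }, error = function(e) {
      logf("setting ", label, " FAILED: ", conditionMessage(e))
      list(status = "failed", error = conditionMessage(e))
    })
    stages[[label]] <- res
  }

  lb <- NULL
  if (length(scores)) {
    lb <- normalize_leaderboard(
      mean_aggregate_duplicates(do.call(rbind, scores)))
    utils::write.csv(lb, file.path(out_dir, "leaderboard.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = spec$seed,
    config = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("cpscope")),
    r_version = R.version.string,
    stages = stages,
    complete = all(vapply(stages, function(s) s$status == "complete", NA)),
    leaderboard = if (!is.null(lb)) "leaderboard.csv" else NULL,
    log = basename(log_path)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  logf("run ", if (manifest$complete) "complete" else "INCOMPLETE")
  invisible(manifest)
}
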