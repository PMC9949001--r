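# Site subsampling, dropout experiments, correlation summaries, runs.

test_that("subsampling all available sites is the identity", {
  pm <- generate_jumpmoa_layout(n_compounds = 6, n_moa = 3, seed = 1)
  cfg <- small_config(sites_per_well = 3, cells_per_site = c("20X" = 15),
                      seed = 2)
  cells <- simulate_plate(pm, config = cfg)
  direct <- aggregate_profiles(cells)
  sub <- subsample_sites(cells, 3, seed = 99)
  ord <- order(direct$Metadata_Well)
  ord2 <- order(sub$Metadata_Well)
  fc <- feature_cols(direct)
  expect_equal(as.matrix(sub[ord2, fc]), as.matrix(direct[ord, fc]))
})

test_that("subsampling to one site equals that site's independently
          recomputed mean", {
  pm <- generate_jumpmoa_layout(n_compounds = 4, n_moa = 2, seed = 3)
  cfg <- small_config(sites_per_well = 4, cells_per_site = c("20X" = 10),
                      seed = 3)
  cells <- simulate_plate(pm, config = cfg)
  sub <- subsample_sites(cells, 1, seed = 7)
  chosen <- attr(sub, "sites_used")
  for (w in sample(unique(cells$Metadata_Well), 5)) {
    key <- paste(unique(cells$Metadata_Plate), w, sep = "\r")
    site <- chosen[[key]]
    expect_length(site, 1)
    manual <- colMeans(as.matrix(
      cells[cells$Metadata_Well == w & cells$Metadata_Site == site,
            feature_cols(cells)]))
    got <- unlist(sub[sub$Metadata_Well == w, feature_cols(sub)])
    expect_equal(unname(got), unname(manual))
  }
})

test_that("subsampling more sites than acquired is an error", {
  pm <- generate_jumpmoa_layout(n_compounds = 2, n_moa = 1, seed = 1)
  cells <- simulate_plate(pm, config = small_config(sites_per_well = 4,
                                                    seed = 1))
  expect_error(subsample_sites(cells, 5), "fewer than 5 sites")
})

test_that("composed subsampling matches direct subsampling in
          distribution", {
  pm <- generate_jumpmoa_layout(n_compounds = 8, n_moa = 4, seed = 2)
  cfg <- small_config(sites_per_well = 4, cells_per_site = c("20X" = 25),
                      seed = 2)
  cells <- simulate_plate(pm, config = cfg)
  fc <- feature_cols(cells)
  # direct: 4 -> 1 site; composed: 4 -> 2 sites (keep cells) -> 1 site
  direct <- vapply(1:15, function(s) {
    mean(as.matrix(subsample_sites(cells, 1, seed = s)[, fc[1]]))
  }, numeric(1))
  composed <- vapply(1:15, function(s) {
    step <- subsample_sites(cells, 2, seed = 1000 + s)
    kept <- attr(step, "sites_used")
    wkey <- paste(cells$Metadata_Plate, cells$Metadata_Well, sep = "\r")
    allowed <- unlist(lapply(names(kept), function(k) paste(k, kept[[k]])))
    inner <- cells[paste(wkey, cells$Metadata_Site) %in% allowed, ]
    mean(as.matrix(subsample_sites(inner, 1, seed = 2000 + s)[, fc[1]]))
  }, numeric(1))
  expect_lt(abs(mean(direct) - mean(composed)),
            4 * sd(c(direct, composed)) / sqrt(15) + 0.05)
})

test_that("channel-correlation summary recovers planted structure", {
  # two channels simulated with identical effect directions correlate most
  reg <- channel_registry(channels = c("DNA", "ER", "RNA"))
  n_wells <- 60
  set.seed(12)
  latent <- matrix(rnorm(n_wells * 3), ncol = 3)
  feats <- list(
    Cells_Intensity_MeanIntensity_DNA = latent[, 1] + rnorm(n_wells, sd = .2),
    Cells_Texture_Contrast_DNA = latent[, 1] + rnorm(n_wells, sd = .2),
    Cells_Intensity_MeanIntensity_ER = latent[, 1] + rnorm(n_wells, sd = .2),
    Cells_Texture_Contrast_ER = latent[, 1] + rnorm(n_wells, sd = .2),
    Cells_Intensity_MeanIntensity_RNA = latent[, 3] + rnorm(n_wells, sd = .2),
    Cells_Texture_Contrast_RNA = latent[, 3] + rnorm(n_wells, sd = .2))
  prof <- structure(
    cbind(data.frame(Metadata_Plate = "P",
                     Metadata_Well = sprintf("W%02d", 1:n_wells)),
          as.data.frame(feats)),
    class = c("profile", "data.frame"))
  cc <- channel_correlation_summary(prof, reg)
  expect_true(isSymmetric(cc))
  off <- cc[upper.tri(cc)]
  expect_equal(max(off), cc["DNA", "ER"])  # the planted twin pair

  # brute force the DNA-ER block mean
  M <- as.matrix(prof[, feature_cols(prof)])
  cm <- abs(cor(M))
  expect_equal(cc["DNA", "ER"], mean(cm[1:2, 3:4]))
  # diagonal: within-channel mean excluding self-pairs
  expect_equal(cc["DNA", "DNA"], cm[1, 2])
})

test_that("single feature per channel reduces the summary to |r|", {
  reg <- channel_registry(channels = c("DNA", "ER"))
  set.seed(3)
  prof <- structure(
    data.frame(Metadata_Plate = "P", Metadata_Well = sprintf("W%02d", 1:30),
               Cells_Intensity_MeanIntensity_DNA = rnorm(30),
               Cells_Intensity_MeanIntensity_ER = rnorm(30)),
    class = c("profile", "data.frame"))
  cc <- channel_correlation_summary(prof, reg)
  r <- abs(cor(prof$Cells_Intensity_MeanIntensity_DNA,
               prof$Cells_Intensity_MeanIntensity_ER))
  expect_equal(cc["DNA", "ER"], r)
  expect_true(is.na(cc["DNA", "DNA"]))  # no within-channel pairs
})

test_that("independent noise channels have near-zero summary off-diagonals", {
  pm <- generate_jumpmoa_layout(seed = 5)
  cfg <- small_config(effect_size = 0, sigma_plate = 0, sigma_site = 0,
                      channel_correlation = 0, seed = 5)
  prof <- mad_robustize(aggregate_profiles(simulate_plate(pm, config = cfg)))
  reg <- channel_registry()
  cc <- channel_correlation_summary(prof, reg)
  # pair features overlap two channels, inflating their block means; compare
  # single-channel blocks only via a registry without shared features
  expect_lt(cc["DNA", "Mito"], 0.2)
})

test_that("channel dropout experiment pairs runs from the same cells", {
  cfg <- small_config(effect_size = 2, seed = 21)
  spec <- experiment_spec(base_config = cfg,
                          metric_config = metric_config(null_size = 400,
                                                        seed = 2),
                          site_targets = 1L)
  res <- channel_dropout_experiment(spec, "RNA")
  expect_s3_class(res$with, "profile_strength")
  expect_s3_class(res$without, "profile_strength")
  expect_equal(unname(res$delta["percent_score"]),
               res$without$percent_score - res$with$percent_score)
  expect_lt(res$without$n_features, res$with$n_features)
  expect_error(channel_dropout_experiment(spec, "XYZ"), "registry")
})

test_that("cell-count curve reports per-condition bookkeeping", {
  cfg <- small_config(sites_per_well = 2, cells_per_site = c("20X" = 15),
                      effect_size = 2, seed = 31)
  spec <- experiment_spec(base_config = cfg,
                          metric_config = metric_config(null_size = 300,
                                                        seed = 3),
                          site_targets = c(1L, 2L))
  curve <- cellcount_curve(spec)
  expect_equal(nrow(curve), 2)
  expect_equal(curve$sites, c(1, 2))
  expect_true(all(curve$plate_cell_count > 0))
  expect_lt(curve$plate_cell_count[1], curve$plate_cell_count[2])
  expect_equal(curve$percent_score,
               (curve$percent_replicating + curve$percent_matching) / 2)
})

test_that("experiment specs round-trip through YAML with defaults filled", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "sim:",
    "  n_features_per_channel: 3",
    "  sites_per_well: 2",
    "  effect_size: 1.5",
    "metric:",
    "  null_size: 250",
    "experiment:",
    "  site_targets: [1, 2]",
    "  drop_channels: [RNA]"), path)
  spec <- read_experiment_spec(path)
  expect_s3_class(spec, "experiment_spec")
  expect_equal(spec$base_config$n_features_per_channel, 3L)
  expect_equal(spec$base_config$effect_size, 1.5)
  expect_equal(spec$base_config$moa_sharing, sim_config()$moa_sharing)
  expect_equal(spec$metric_config$null_size, 250L)
  expect_equal(spec$metric_config$threshold_percentile, 95)
  expect_equal(spec$site_targets, c(1L, 2L))
  expect_equal(spec$drop_channels, "RNA")
  expect_error(experiment_spec(site_targets = 99), "sites_per_well")
})

test_that("run_experiment writes a reproducible, complete artifact set", {
  cfg <- small_config(sites_per_well = 2, cells_per_site = c("20X" = 12),
                      effect_size = 2, seed = 41)
  spec <- experiment_spec(base_config = cfg,
                          metric_config = metric_config(null_size = 200,
                                                        seed = 4),
                          site_targets = c(1L, 2L))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  man1 <- run_experiment(spec, out1)
  man2 <- run_experiment(spec, out2)
  expect_true(man1$complete)
  lb1 <- read.csv(file.path(out1, "leaderboard.csv"))
  lb2 <- read.csv(file.path(out2, "leaderboard.csv"))
  expect_identical(lb1, lb2)  # same spec twice -> identical leaderboards
  expect_equal(nrow(lb1), 2)
  expect_equal(max(lb1$normalized_score), 100)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "platemap.csv")))
  # every leaderboard score equals the mean of its stored metrics
  for (k in seq_len(nrow(lb1))) {
    met <- jsonlite::read_json(
      file.path(out1, paste0("metrics_", lb1$setting[k], ".json")),
      simplifyVector = TRUE)
    expect_equal(lb1$percent_score[k],
                 (met$percent_replicating + met$percent_matching) / 2)
  }
})
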