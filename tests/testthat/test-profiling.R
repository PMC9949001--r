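# Aggregation, MAD robustization, feature selection, channel dropout.

test_that("well aggregation is the arithmetic mean over cells", {
  tab <- data.frame(Metadata_Plate = "P", Metadata_Well = "A01",
                    f1 = c(1, 5), f2 = c(3, 7))
  prof <- aggregate_profiles(tab)
  expect_equal(unlist(prof[, c("f1", "f2")], use.names = FALSE), c(3, 5))
  expect_equal(prof$Metadata_CellCount, 2L)

  single <- aggregate_profiles(tab[1, ])
  expect_equal(unlist(single[, c("f1", "f2")], use.names = FALSE), c(1, 3))
})

test_that("well mean is cell-weighted, not the mean of site means", {
  # site A = {0, 0}, site B = {3}: cell-weighted mean 1.0, site-mean mean 1.5
  tab <- data.frame(Metadata_Plate = "P", Metadata_Well = "A01",
                    Metadata_Site = c(1, 1, 2), f = c(0, 0, 3))
  well <- aggregate_profiles(tab, level = "well")
  expect_equal(well$f, 1.0)
  site <- aggregate_profiles(tab, level = "site")
  expect_equal(sort(site$f), c(0, 3))
  expect_equal(mean(site$f), 1.5)  # the path the pipeline must NOT take
  expect_equal(well$Metadata_Sites, 2L)
})

test_that("aggregation requires grouping metadata and pads empty wells", {
  expect_error(aggregate_profiles(data.frame(f = 1)), "Metadata")
  tab <- structure(data.frame(Metadata_Plate = "P", Metadata_Well = "A01",
                              f = c(1, 2)),
                   empty_wells = "B02",
                   class = c("feature_table", "data.frame"))
  prof <- aggregate_profiles(tab)
  expect_equal(nrow(prof), 2)
  pad <- prof[prof$Metadata_Well == "B02", ]
  expect_true(is.na(pad$f))
  expect_equal(pad$Metadata_CellCount, 0L)
  expect_equal(attr(prof, "empty_wells"), "B02")
})

test_that("mad_robustize matches the hand-computed oracle", {
  prof <- structure(data.frame(Metadata_Plate = "P",
                               Metadata_Well = sprintf("A%02d", 1:5),
                               f = c(1, 2, 3, 4, 5),
                               const = rep(7, 5)),
                    class = c("profile", "data.frame"))
  out <- mad_robustize(prof)
  # median 3, raw MAD 1, scale 1.4826
  expect_equal(round(out$f, 4), c(-1.3490, -0.6745, 0, 0.6745, 1.3490))
  expect_equal(median(out$f), 0)
  expect_true(all(is.na(out$const)))  # MAD = 0 becomes all-missing
  expect_true(attr(out, "normalized"))

  # idempotence on already-robustized data (up to epsilon)
  again <- mad_robustize(out[, c("Metadata_Plate", "Metadata_Well", "f")])
  expect_equal(again$f, out$f, tolerance = 1e-9)

  expect_error(mad_robustize(prof[1, ]), "single")
})

test_that("robustization is per plate", {
  prof <- structure(data.frame(Metadata_Plate = rep(c("P1", "P2"), each = 3),
                               Metadata_Well = rep(c("A01", "A02", "A03"), 2),
                               f = c(1, 2, 3, 101, 102, 103)),
                    class = c("profile", "data.frame"))
  out <- mad_robustize(prof)
  expect_equal(out$f[1:3], out$f[4:6])  # each plate centered on its own median
})

test_that("feature selection removes missing, constant, and redundant
          features", {
  set.seed(42)
  x <- rnorm(20)
  prof <- structure(data.frame(Metadata_Plate = "P",
                               Metadata_Well = sprintf("W%02d", 1:20),
                               a = x, dup_a = x,       # |r| = 1 pair
                               allna = NA_real_,
                               indep = rnorm(20)),
                    normalized = TRUE,
                    class = c("profile", "data.frame"))
  out <- feature_select(prof, corr_cutoff = 0.9)
  kept <- feature_cols(out)
  expect_false("allna" %in% kept)
  expect_equal(sum(c("a", "dup_a") %in% kept), 1)  # exactly one survives
  expect_true("indep" %in% kept)
  trace <- attr(out, "selection_trace")
  expect_true("allna" %in% trace$drop_na)
  expect_equal(length(trace$correlation_threshold), 1)
})

test_that("correlation threshold removes the hub and keeps the spokes", {
  # hub correlates ~0.9 with each spoke; spokes correlate ~0.81 with each
  # other (the geometric floor: two features both at |r| = 0.9 to a third
  # cannot correlate below 2 * 0.9^2 - 1), so with cutoff 0.85 only the two
  # hub-spoke pairs exceed it. Greedy mean-|r| removal drops the hub first
  # and both spokes survive.
  set.seed(7)
  n <- 4000
  h <- rnorm(n)
  s1 <- 0.9 * h + sqrt(1 - 0.81) * rnorm(n)
  s2 <- 0.9 * h + sqrt(1 - 0.81) * rnorm(n)
  prof <- structure(data.frame(Metadata_Plate = "P",
                               Metadata_Well = sprintf("W%04d", 1:n),
                               hub = h, spoke1 = s1, spoke2 = s2),
                    normalized = TRUE,
                    class = c("profile", "data.frame"))
  cm <- abs(cor(cbind(h, s1, s2)))
  expect_gt(cm["h", "s1"], 0.85)
  expect_gt(cm["h", "s2"], 0.85)
  expect_lt(cm["s1", "s2"], 0.85)
  out <- feature_select(prof, ops = "correlation_threshold",
                        corr_cutoff = 0.85)
  expect_setequal(feature_cols(out), c("spoke1", "spoke2"))
  expect_equal(attr(out, "selection_trace")$correlation_threshold, "hub")
})

test_that("near-zero-variance filter uses the frequency-ratio rule", {
  n <- 1000
  nzv <- c(rep(0, 995), rep(1, 5))          # ratio 199 > 19, unique 0.2% < 1%
  ok <- rep_len(c(0, 0, 1), n)              # ratio 2, not near-zero-variance
  prof <- structure(data.frame(Metadata_Plate = "P",
                               Metadata_Well = sprintf("W%04d", 1:n),
                               nzv = nzv, ok = ok, cont = rnorm(n)),
                    normalized = TRUE,
                    class = c("profile", "data.frame"))
  out <- feature_select(prof, ops = "variance_threshold")
  expect_setequal(feature_cols(out), c("ok", "cont"))
})

test_that("robustize followed by selection leaves no missing values", {
  pm <- generate_jumpmoa_layout(seed = 3)
  cells <- simulate_plate(pm, config = small_config(seed = 3))
  sel <- feature_select(mad_robustize(aggregate_profiles(cells)))
  expect_false(anyNA(as.matrix(sel[, feature_cols(sel)])))
  expect_error(feature_select(
    structure(data.frame(Metadata_Plate = "P", Metadata_Well = c("A01", "A02"),
                         f = NA_real_),
              class = c("profile", "data.frame"))), "every feature")
})

test_that("channel dropout removes exactly the channel's features", {
  reg <- channel_registry()
  pm <- generate_jumpmoa_layout(n_compounds = 4, n_moa = 2, seed = 1)
  cells <- simulate_plate(pm, config = small_config(seed = 1))
  prof <- aggregate_profiles(cells)

  dropped <- drop_channel_features(prof, "RNA", reg)
  leftover <- channels_of_feature(feature_cols(dropped), reg)
  expect_false(any(vapply(leftover, function(x) "RNA" %in% x, NA)))
  # pair features naming RNA are gone too
  expect_false(any(grepl("Pearson_.*RNA", feature_cols(dropped))))
  # channel-free shape features survive a Brightfield drop
  bf <- drop_channel_features(prof, "Brightfield", reg)
  expect_true(any(grepl("AreaShape", feature_cols(bf))))

  expect_error(drop_channel_features(prof, "XYZ", reg), "not in the registry")

  # dropping a registered channel with no features present is the identity
  no_bf <- bf
  again <- drop_channel_features(no_bf, "Brightfield", reg)
  expect_identical(feature_cols(again), feature_cols(no_bf))

  # dropout commutes with row subsetting
  sub_then_drop <- drop_channel_features(prof[1:5, ], "RNA", reg)
  drop_then_sub <- dropped[1:5, ]
  expect_equal(strip_df(sub_then_drop), strip_df(drop_then_sub))
})

test_that("profiles round-trip through CSV with provenance", {
  pm <- generate_jumpmoa_layout(n_compounds = 4, n_moa = 2, seed = 1)
  cells <- simulate_plate(pm, config = small_config(seed = 1))
  sel <- feature_select(mad_robustize(aggregate_profiles(cells)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(sel, path)
  back <- read_profiles(path)
  expect_equal(strip_df(back), strip_df(sel), tolerance = 1e-6)
  expect_true(attr(back, "normalized"))
  expect_true(attr(back, "selected"))
})
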