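# Channel registry and CellProfiler-style feature naming.

#' Channel registry for Cell Painting simulations
#'
#' The standard Cell Painting acquisition yields five effective fluorescent
#' channels — DNA, endoplasmic reticulum (ER), nucleoli + cytoplasmic RNA
#' (RNA), actin + Golgi + plasma membrane (AGP), and mitochondria (Mito) —
#' optionally plus a transmitted-light Brightfield channel. Some filter
#' setups split AGP into separate Actin and Golgi channels for six-channel
#' imaging; `split_agp = TRUE` builds that variant.
#'
#' @param channels Character vector of channel tokens. Tokens must be
#'   unique, non-empty, and contain no underscore (they are embedded as
#'   underscore-delimited feature-name components).
#' @param brightfield Include the Brightfield channel?
#' @param split_agp Replace AGP with separate Actin and Golgi channels?
#' @return Character vector of channel tokens with class `channel_registry`.
#' @examples
#' channel_registry()                     # DNA ER RNA AGP Mito Brightfield
#' channel_registry(split_agp = TRUE)     # six fluorescent channels
#' channel_registry(brightfield = FALSE)  # five fluorescent channels
#' @export
channel_registry <- function(channels = NULL, brightfield = TRUE,
                             split_agp = FALSE) {
  if (is.null(channels)) {
    fluor <- if (split_agp) c("DNA", "ER", "RNA", "Actin", "Golgi", "Mito")
             else c("DNA", "ER", "RNA", "AGP", "Mito")
    channels <- if (brightfield) c(fluor, "Brightfield") else fluor
  }
  stopifnot(is.character(channels), length(channels) >= 1L)
  if (anyDuplicated(channels) || any(!nzchar(channels)) ||
      any(grepl("_", channels, fixed = TRUE))) {
    stop("channel tokens must be unique, non-empty, and underscore-free",
         call. = FALSE)
  }
  structure(channels, class = "channel_registry")
}

#' Channels referenced by a feature name
#'
#' Feature names follow the `Compartment_Group_Measure[_Channel[_Channel2]]`
#' convention, so the channel attribution of every feature is recoverable
#' from its name alone: every registry token appearing as an
#' underscore-delimited component is returned. Channel-free features (e.g.
#' `Nuclei_AreaShape_Area`) yield an empty set; colocalization features name
#' two channels. Unknown tokens are ignored.
#'
#' @param name Character vector of feature names.
#' @param registry A [channel_registry()].
#' @return A list (one element per name) of character vectors of tokens.
#' @examples
#' reg <- channel_registry()
#' channels_of_feature("Cells_Intensity_MeanIntensity_RNA", reg)
#' channels_of_feature("Cytoplasm_Correlation_Pearson_DNA_RNA", reg)
#' channels_of_feature("Nuclei_AreaShape_Area", reg)
#' @export
channels_of_feature <- function(name, registry) {
  stopifnot(inherits(registry, "channel_registry") || is.character(registry))
  lapply(strsplit(name, "_", fixed = TRUE),
         function(parts) intersect(parts, as.character(registry)))
}

# Compartment / measurement vocabulary used to synthesize realistic
# CellProfiler-style names. Cycled as needed to reach the requested count.
.compartments <- c("Cells", "Cytoplasm", "Nuclei")
.channel_measures <- c("Intensity_MeanIntensity", "Intensity_IntegratedIntensity",
                       "Intensity_StdIntensity", "Intensity_UpperQuartileIntensity",
                       "Texture_Contrast", "Texture_Entropy",
                       "Texture_Correlation", "Granularity_1", "Granularity_2",
                       "Granularity_3", "RadialDistribution_MeanFrac",
                       "RadialDistribution_FracAtD")
.free_measures <- c("AreaShape_Area", "AreaShape_Perimeter",
                    "AreaShape_Eccentricity", "AreaShape_FormFactor",
                    "AreaShape_Solidity", "AreaShape_Extent",
                    "AreaShape_Compactness", "Neighbors_NumberOfNeighbors",
                    "Neighbors_PercentTouching")

#' Build a synthetic CellProfiler-style feature schema
#'
#' Constructs the feature-name universe for a simulation: per channel,
#' `n_per_channel` single-channel features (intensity, texture, granularity,
#' radial-distribution measures over the Cells/Cytoplasm/Nuclei
#' compartments); one colocalization (Pearson correlation) feature per
#' unordered channel pair; and `n_channel_free` channel-free shape/neighbor
#' features. Channel membership of every feature is recoverable from its
#' name via [channels_of_feature()].
#'
#' @param registry A [channel_registry()].
#' @param n_per_channel Single-channel features per channel.
#' @param n_channel_free Channel-free features.
#' @return A `feature_schema`: data frame with columns `feature` (name),
#'   `channel1`, `channel2` (NA when absent), plus the registry as an
#'   attribute.
#' @examples
#' sch <- build_feature_schema(channel_registry(brightfield = FALSE), 10, 5)
#' nrow(sch)  # 5*10 single-channel + choose(5,2) pair + 5 free = 65
#' @export
build_feature_schema <- function(registry, n_per_channel = 20L,
                                 n_channel_free = 10L) {
  stopifnot(inherits(registry, "channel_registry"))
  if (!is_count(n_per_channel) || !is_count(n_channel_free, min = 0L)) {
    stop("feature counts must be positive (n_channel_free may be 0)",
         call. = FALSE)
  }
  chans <- as.character(registry)

  name_k <- function(k, pool) {
    # k-th name from compartment x measure grid, suffixing a cycle index
    # when the vocabulary is exhausted so names stay unique
    grid <- as.vector(outer(.compartments, pool, paste, sep = "_"))
    idx <- ((k - 1L) %% length(grid)) + 1L
    cyc <- (k - 1L) %/% length(grid)
    ifelse(cyc > 0L, paste0(grid[idx], "_", cyc + 1L), grid[idx])
  }

  single <- do.call(rbind, lapply(chans, function(ch) {
    base <- name_k(seq_len(n_per_channel), .channel_measures)
    data.frame(feature = paste(base, ch, sep = "_"),
               channel1 = ch, channel2 = NA_character_,
               stringsAsFactors = FALSE)
  }))

  pair <- NULL
  if (length(chans) >= 2L) {
    cmb <- utils::combn(chans, 2L)
    pair <- data.frame(
      feature = paste("Cytoplasm_Correlation_Pearson", cmb[1L, ], cmb[2L, ],
                      sep = "_"),
      channel1 = cmb[1L, ], channel2 = cmb[2L, ],
      stringsAsFactors = FALSE)
  }

  free <- NULL
  if (n_channel_free > 0L) {
    free <- data.frame(feature = name_k(seq_len(n_channel_free),
                                        .free_measures),
                       channel1 = NA_character_, channel2 = NA_character_,
                       stringsAsFactors = FALSE)
  }

  schema <- rbind(single, pair, free)
  rownames(schema) <- NULL
  stopifnot(!anyDuplicated(schema$feature))
  structure(schema, registry = registry,
            n_per_channel = as.integer(n_per_channel),
            class = c("feature_schema", "data.frame"))
}

#' @export
print.feature_schema <- function(x, ...) {
  reg <- attr(x, "registry")
  cat("feature schema: ", nrow(x), " features over ", length(reg),
      " channels (", paste(reg, collapse = ", "), ")\n", sep = "")
  cat("  ", sum(!is.na(x$channel1) & is.na(x$channel2)), " single-channel, ",
      sum(!is.na(x$channel2)), " channel-pair, ",
      sum(is.na(x$channel1)), " channel-free\n", sep = "")
  invisible(x)
}
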