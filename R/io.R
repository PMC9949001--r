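# Profile / feature-table CSV I/O with a JSON provenance sidecar.

#' Write profiles (or any feature table) to CSV
#'
#' Writes the table with its `Metadata_` column convention intact, plus a
#' JSON sidecar (`<path>.provenance.json`) recording profiling provenance:
#' normalization and selection state, selection trace, dropped channels,
#' empty wells, and setting label.
#'
#' @param profiles A `profile` or feature table.
#' @param path Output CSV path.
#' @param sidecar Write the provenance sidecar?
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  if (sidecar) {
    prov <- list(
      setting = attr(profiles, "setting"),
      level = attr(profiles, "level"),
      normalized = isTRUE(attr(profiles, "normalized")),
      selected = isTRUE(attr(profiles, "selected")),
      selection_trace = attr(profiles, "selection_trace"),
      dropped_channels = attr(profiles, "dropped_channels"),
      empty_wells = attr(profiles, "empty_wells"),
      n_features = length(feature_cols(profiles))
    )
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read profiles from CSV
#'
#' Restores a table written by [write_profiles()], re-attaching the
#' provenance sidecar when present.
#'
#' @param path CSV path.
#' @return A `profile` data frame.
#' @export
read_profiles <- function(path) {
  prof <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  structure(prof,
            setting = prov$setting,
            level = prov$level %||% "well",
            normalized = isTRUE(prov$normalized),
            selected = isTRUE(prov$selected),
            selection_trace = prov$selection_trace,
            dropped_channels = prov$dropped_channels,
            empty_wells = prov$empty_wells %||% character(),
            class = c("profile", "data.frame"))
}
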