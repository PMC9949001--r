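# JUMP-MOA style plate maps: generation, validation, CSV I/O.

PLATE_ROWS <- 16L
PLATE_COLS <- 24L
CONTROL_ID <- "DMSO"

#' Format well addresses
#'
#' Builds canonical zero-padded well labels ("A01" ... "P24") from row
#' letters and 1-based column numbers.
#'
#' @param row Character vector of row letters (A-P on a 384-well plate).
#' @param column Integer vector of 1-based column numbers.
#' @return Character vector of well labels.
#' @examples
#' format_well("A", 1)   # "A01"
#' format_well("P", 24)  # "P24"
#' @export
format_well <- function(row, column) {
  stopifnot(is.character(row), all(row %in% LETTERS))
  stopifnot(all(column >= 1), all(column == as.integer(column)))
  sprintf("%s%02d", row, as.integer(column))
}

#' Parse well labels
#'
#' Inverse of [format_well()]: splits labels such as "A01" or "P24" into row
#' letter and column number. Unpadded labels ("A1") are accepted on input;
#' the canonical form is always zero-padded.
#'
#' @param label Character vector of well labels.
#' @param rows,cols Plate dimensions used for validation.
#' @return Data frame with columns `row`, `column`, `label` (canonical).
#' @export
parse_well <- function(label, rows = PLATE_ROWS, cols = PLATE_COLS) {
  stopifnot(is.character(label))
  ok <- grepl("^[A-Z][0-9]{1,2}$", label)
  row <- substr(label, 1L, 1L)
  column <- suppressWarnings(as.integer(substr(label, 2L, nchar(label))))
  valid <- ok & row %in% LETTERS[seq_len(rows)] &
    !is.na(column) & column >= 1L & column <= cols
  if (!all(valid)) {
    bad <- unique(label[!valid])
    stop("invalid well address(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(row = row, column = column,
             label = format_well(row, column),
             stringsAsFactors = FALSE)
}

#' All well labels of a plate
#'
#' @param rows,cols Plate dimensions (16 x 24 for a 384-well plate).
#' @return Character vector of labels in row-major order.
#' @export
well_labels <- function(rows = PLATE_ROWS, cols = PLATE_COLS) {
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), format_well)))
}

#' Generate a JUMP-MOA style plate layout
#'
#' Creates a 384-well positive-control plate map in the style of the
#' JUMP-MOA plate: `n_compounds` treatment compounds drawn from `n_moa`
#' mechanism-of-action (MOA) classes, each compound occupying `replicates`
#' wells, the remainder of the plate filled with negative-control (DMSO)
#' wells. Treatment wells are placed by a seeded random permutation of the
#' plate; the leftover (last) positions of that permutation become the
#' controls, so for a fixed seed the layout is fully deterministic.
#'
#' The compounds-per-MOA distribution defaults to as many two-compound
#' classes as possible plus singletons (90 compounds over 47 classes gives
#' 43 pairs + 4 singletons), matching the plate's design purpose of
#' MOA-matched compound pairs; pass `moa_sizes` to override.
#'
#' @param n_compounds Number of distinct treatment compounds (default 90).
#' @param n_moa Number of distinct MOA classes (default 47).
#' @param replicates Replicate wells per compound (default 4).
#' @param moa_sizes Integer vector of length `n_moa`: compounds per MOA
#'   class. Must sum to `n_compounds`. Default: pairs then singletons.
#' @param seed Integer seed controlling well placement.
#' @param rows,cols Plate dimensions.
#' @param plate_id Plate identifier stored with the map.
#' @param concentration_uM Treatment concentration in micromolar (default 3,
#'   the JUMP-MOA treatment concentration).
#' @return A `platemap`: a data frame with one row per well and columns
#'   `well_position`, `row`, `column`, `compound_id`, `moa`,
#'   `concentration_uM`, `role`.
#' @examples
#' pm <- generate_jumpmoa_layout(seed = 1)
#' table(pm$role)                       # 360 treatment, 24 negative_control
#' length(unique(pm$compound_id[pm$role == "treatment"]))  # 90
#' @export
generate_jumpmoa_layout <- function(n_compounds = 90L, n_moa = 47L,
                                    replicates = 4L, moa_sizes = NULL,
                                    seed = 0L, rows = PLATE_ROWS,
                                    cols = PLATE_COLS,
                                    plate_id = "SIMPLATE1",
                                    concentration_uM = 3) {
  stopifnot(is_count(n_compounds), is_count(n_moa), is_count(replicates),
            is_count(rows), is_count(cols))
  n_wells <- rows * cols
  n_treat <- n_compounds * replicates
  if (n_treat > n_wells) {
    stop("layout infeasible: ", n_compounds, " compounds x ", replicates,
         " replicates = ", n_treat, " wells > plate size ", n_wells,
         call. = FALSE)
  }
  if (n_moa > n_compounds) {
    stop("more MOA classes than compounds", call. = FALSE)
  }
  if (is.null(moa_sizes)) {
    n_pairs <- n_compounds - n_moa  # pairs use one extra compound each
    if (n_pairs > n_moa) {
      stop("no default MOA-size distribution with at most 2 compounds per ",
           "class exists for this n_compounds/n_moa; supply `moa_sizes`",
           call. = FALSE)
    }
    moa_sizes <- c(rep(2L, n_pairs), rep(1L, n_moa - n_pairs))
  }
  moa_sizes <- as.integer(moa_sizes)
  if (length(moa_sizes) != n_moa || sum(moa_sizes) != n_compounds ||
      any(moa_sizes < 1L)) {
    stop("`moa_sizes` must have length n_moa, positive entries, and sum to ",
         "n_compounds", call. = FALSE)
  }

  compounds <- sprintf("Cmpd%03d", seq_len(n_compounds))
  moas <- sprintf("MOA%03d", seq_len(n_moa))
  compound_moa <- rep(moas, times = moa_sizes)

  placement <- with_seed(seed, sample(well_labels(rows, cols)))
  treat_wells <- placement[seq_len(n_treat)]
  ctrl_wells <- placement[setdiff(seq_len(n_wells), seq_len(n_treat))]

  pm <- data.frame(
    well_position = c(treat_wells, ctrl_wells),
    compound_id = c(rep(compounds, each = replicates),
                    rep(CONTROL_ID, length(ctrl_wells))),
    moa = c(rep(compound_moa, each = replicates),
            rep(NA_character_, length(ctrl_wells))),
    concentration_uM = c(rep(concentration_uM, n_treat),
                         rep(0, length(ctrl_wells))),
    role = c(rep("treatment", n_treat),
             rep("negative_control", length(ctrl_wells))),
    stringsAsFactors = FALSE
  )
  addr <- parse_well(pm$well_position, rows, cols)
  pm$row <- addr$row
  pm$column <- addr$column
  pm <- pm[order(match(pm$well_position, well_labels(rows, cols))),
           c("well_position", "row", "column", "compound_id", "moa",
             "concentration_uM", "role")]
  rownames(pm) <- NULL
  structure(pm,
            plate_id = plate_id, rows = rows, cols = cols,
            replicates = replicates,
            class = c("platemap", "data.frame"))
}

#' Validate a plate map
#'
#' Checks the structural invariants of a JUMP-MOA style plate map and
#' returns every violation found (not just the first).
#'
#' @param pm A `platemap` or plain data frame with the platemap columns.
#' @param replicates If non-NULL, require every treatment compound to occupy
#'   exactly this many wells.
#' @param rows,cols Plate dimensions.
#' @return Invisibly, a character vector of violations (empty when valid).
#'   If `stop_on_error` is TRUE (default) violations raise one error.
#' @param stop_on_error Raise an error listing all violations?
#' @export
validate_platemap <- function(pm, replicates = attr(pm, "replicates"),
                              rows = PLATE_ROWS, cols = PLATE_COLS,
                              stop_on_error = TRUE) {
  problems <- character()
  need <- c("well_position", "compound_id", "moa", "concentration_uM", "role")
  miss <- setdiff(need, names(pm))
  if (length(miss)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(miss, collapse = ", ")))
  } else {
    addr <- tryCatch(parse_well(pm$well_position, rows, cols),
                     error = function(e) conditionMessage(e))
    if (is.character(addr)) {
      bad_rows <- which(!pm$well_position %in% well_labels(rows, cols))
      problems <- c(problems, paste0(addr, " (row ",
                                     paste(bad_rows, collapse = ", "), ")"))
    }
    dup <- unique(pm$well_position[duplicated(pm$well_position)])
    if (length(dup)) {
      problems <- c(problems,
                    paste0("duplicate well(s): ", paste(dup, collapse = ", ")))
    }
    if (!all(pm$role %in% c("treatment", "negative_control"))) {
      problems <- c(problems, "role must be 'treatment' or 'negative_control'")
    }
    treat <- pm[pm$role == "treatment", , drop = FALSE]
    if (anyNA(treat$moa)) {
      problems <- c(problems, "treatment wells with missing MOA")
    }
    if (!is.null(replicates) && nrow(treat)) {
      counts <- table(treat$compound_id)
      off <- names(counts)[counts != replicates]
      if (length(off)) {
        problems <- c(problems,
                      paste0("compound(s) not at ", replicates,
                             " replicate wells: ", paste(off, collapse = ", ")))
      }
    }
    negcon <- pm[pm$role == "negative_control", , drop = FALSE]
    if (nrow(negcon) && any(!is.na(negcon$moa))) {
      problems <- c(problems, "negative-control wells must have no MOA")
    }
  }
  if (length(problems) && stop_on_error) {
    stop("invalid plate map:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(problems)
}

#' @export
print.platemap <- function(x, ...) {
  treat <- x[x$role == "treatment", , drop = FALSE]
  cat("JUMP-MOA style plate map '", attr(x, "plate_id") %||% "?", "'\n",
      sep = "")
  cat("  wells: ", nrow(x), " (", nrow(treat), " treatment, ",
      sum(x$role == "negative_control"), " negative control)\n", sep = "")
  cat("  compounds: ", length(unique(treat$compound_id)),
      ", MOA classes: ", length(unique(treat$moa[!is.na(treat$moa)])), "\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plate map to CSV
#'
#' @param pm A `platemap`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_platemap()]
#' @export
write_platemap <- function(pm, path) {
  validate_platemap(pm)
  out <- pm[, c("well_position", "compound_id", "moa", "concentration_uM",
                "role")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a plate map from CSV
#'
#' Expects the header columns `well_position`, `compound_id`, `moa`,
#' `concentration_uM`, `role`. The map is validated on read; every
#' violation (duplicate wells, unparseable addresses, missing columns)
#' is reported in a single error.
#'
#' @param path CSV file path.
#' @param replicates If non-NULL, validate the replicate count per compound.
#' @param rows,cols Plate dimensions.
#' @return A `platemap`.
#' @export
read_platemap <- function(path, replicates = NULL,
                          rows = PLATE_ROWS, cols = PLATE_COLS) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(well_position = "character"))
  need <- c("well_position", "compound_id", "moa", "concentration_uM", "role")
  miss <- setdiff(need, names(pm))
  if (length(miss)) {
    stop("plate-map file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pm$moa <- as.character(pm$moa)
  pm$moa[!is.na(pm$moa) & pm$moa == ""] <- NA_character_
  validate_platemap(pm, replicates = replicates, rows = rows, cols = cols)
  addr <- parse_well(pm$well_position, rows, cols)
  pm$well_position <- addr$label
  pm$row <- addr$row
  pm$column <- addr$column
  pm <- pm[, c("well_position", "row", "column", "compound_id", "moa",
               "concentration_uM", "role")]
  structure(pm,
            plate_id = sub("\\.csv$", "", basename(path)),
            rows = rows, cols = cols, replicates = replicates,
            class = c("platemap", "data.frame"))
}
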