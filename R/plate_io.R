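# Well metadata parsing, CellProfiler CSV ingest and plate-layout export.

#' Default filename metadata pattern
#'
#' Perl-style regular expression with named groups `cell_line`, `compound`,
#' `conc`, `unit` and `rep`, matching names such as
#' `"HCT116_5FU_100nM_r2.tif"`. Override it to match site-specific naming.
#'
#' @return A single regular-expression string.
#' @export
default_filename_pattern <- function() {
  "^(?<cell_line>[^_]+)_(?<compound>[^_]+)_(?<conc>[0-9.]+)(?<unit>nM|uM|µM)_r(?<rep>[0-9]+)\\.[A-Za-z]+$"
}

#' Parse well metadata from an image file name
#'
#' Extracts cell line, compound, concentration and replicate from a file
#' name via a regular expression with named capture groups; concentrations
#' are normalised to nM (`uM`/`µM` multiplied by 1000).
#'
#' @param name File name (base name is enough).
#' @param pattern Perl regular expression with named groups `cell_line`,
#'   `compound`, `conc`, `unit`, `rep`.
#' @return Named list: `cell_line`, `compound`, `concentration` (nM),
#'   `replicate` (integer).
#' @export
parse_filename <- function(name, pattern = default_filename_pattern()) {
  need <- c("cell_line", "compound", "conc", "unit", "rep")
  m <- regexpr(pattern, name, perl = TRUE)
  gnames <- attr(m, "capture.names")
  if (is.null(gnames) || !all(need %in% gnames)) {
    abort(paste0("pattern must define named groups: ", paste(need, collapse = ", ")))
  }
  if (m == -1) abort(paste0("file name does not match metadata pattern: ", name))
  starts <- attr(m, "capture.start")[1, ]
  lens <- attr(m, "capture.length")[1, ]
  grab <- function(g) substr(name, starts[g], starts[g] + lens[g] - 1)
  conc <- as.numeric(grab("conc"))
  unit <- grab("unit")
  if (unit %in% c("uM", "µM")) conc <- conc * 1000
  list(cell_line = grab("cell_line"), compound = grab("compound"),
       concentration = conc, replicate = as.integer(grab("rep")))
}

#' Default feature whitelist for CellProfiler ingest
#' @return Character vector of the six shape-feature column names.
#' @export
default_feature_whitelist <- function() {
  c("AreaShape_Area", "AreaShape_Perimeter", "AreaShape_FormFactor",
    "AreaShape_Compactness", "AreaShape_Solidity", "AreaShape_MedianRadius")
}

#' Read a CellProfiler export CSV into a well-level feature table
#'
#' Keeps the whitelisted feature columns (plus any `Granularity_*` columns
#' when `keep_granularity = TRUE`), reduces multiple objects per image to
#' the largest-area object (one spheroid per well is the assay design), and
#' drops rows with missing or non-positive feature values, reporting the
#' number dropped.
#'
#' Metadata may be present as columns (`cell_line`, `compound`,
#' `concentration`, `replicate`) or derived from a `FileName`-type column
#' through `pattern`.
#'
#' @param path CSV file path.
#' @param feature_whitelist Feature columns to retain.
#' @param keep_granularity Also retain `Granularity_*` columns.
#' @param pattern Filename pattern used when metadata must be parsed from a
#'   `FileName*` column.
#' @return Feature table tibble with attribute `provenance =
#'   "cellprofiler"` and attribute `n_dropped`.
#' @export
read_cellprofiler_csv <- function(path,
                                  feature_whitelist = default_feature_whitelist(),
                                  keep_granularity = TRUE,
                                  pattern = default_filename_pattern()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort("empty CellProfiler table")

  meta_cols <- c("cell_line", "compound", "concentration", "replicate")
  if (!all(meta_cols %in% names(raw))) {
    fn_col <- grep("^FileName", names(raw), value = TRUE)
    if (length(fn_col) == 0) {
      abort("no metadata columns and no FileName column to parse them from")
    }
    meta <- list_rbind(map(raw[[fn_col[1]]], function(nm)
      as_tibble(parse_filename(nm, pattern))))
    raw <- dplyr::bind_cols(meta, raw[setdiff(names(raw), meta_cols)])
  }

  feats <- intersect(feature_whitelist, names(raw))
  if (length(feats) == 0) abort("none of the whitelisted feature columns are present")
  if (keep_granularity) {
    feats <- c(feats, grep("^Granularity_", names(raw), value = TRUE))
  }
  missing_area <- !"AreaShape_Area" %in% names(raw)

  tbl <- raw[, c(meta_cols, feats)]
  # largest object per well when CellProfiler exported several objects/image
  if (!missing_area) {
    tbl <- tbl |>
      group_by(across(dplyr::all_of(meta_cols))) |>
      arrange(dplyr::desc(.data$AreaShape_Area), .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  } else {
    tbl <- distinct(tbl, across(dplyr::all_of(meta_cols)), .keep_all = TRUE)
  }

  ok <- stats::complete.cases(tbl[feats]) &
    rowSums(as.matrix(tbl[feats]) <= 0, na.rm = TRUE) == 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d row(s) with missing or non-positive feature values",
                 n_dropped))
  }
  tbl <- tbl[ok, ]
  if (nrow(tbl) == 0) abort("no usable rows after ingest filtering")

  out <- as_tibble(tbl)
  attr(out, "provenance") <- "cellprofiler"
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assign 96-well plate coordinates to a feature table
#'
#' Deterministic column-major assignment (A01, B01, ... H01, A02, ...) in
#' (compound, concentration, replicate) order, used when file names carry
#' no explicit well id.
#'
#' @param tbl Feature table.
#' @return The table with a `well_id` column.
#' @export
assign_well_ids <- function(tbl) {
  check_well_keys(tbl)
  tbl <- arrange(tbl, .data$compound, .data$concentration, .data$replicate)
  if (nrow(tbl) > 96) abort("more than 96 wells; 96-well geometry only")
  rows <- LETTERS[1:8]
  idx <- seq_len(nrow(tbl)) - 1
  tbl$well_id <- paste0(rows[idx %% 8 + 1], sprintf("%02d", idx %/% 8 + 1))
  tbl
}

#' Arrange a feature table as 8 x 12 plate-layout grids
#'
#' One grid per feature, empty wells `NA`.
#'
#' @param tbl Feature table with (or able to derive) `well_id`.
#' @return Named list of 8 x 12 matrices (rows A-H, columns 1-12).
#' @export
plate_layout <- function(tbl) {
  if (!"well_id" %in% names(tbl)) tbl <- assign_well_ids(tbl)
  if (anyDuplicated(tbl$well_id)) abort("duplicate well assignment")
  feats <- feature_columns(tbl)
  rows <- LETTERS[1:8]
  ri <- match(substr(tbl$well_id, 1, 1), rows)
  ci <- as.integer(substr(tbl$well_id, 2, 3))
  if (anyNA(ri) || anyNA(ci) || any(ci > 12)) abort("well_id outside 96-well geometry")
  lapply(setNames(feats, feats), function(f) {
    m <- matrix(NA_real_, 8, 12, dimnames = list(rows, 1:12))
    m[cbind(ri, ci)] <- tbl[[f]]
    m
  })
}

#' Write plate-layout grids to disk
#'
#' One CSV per feature ("sheet") in `dir`, each an 8 x 12 grid with row
#' letters in the first column; [read_plate_layout()] reads them back
#' losslessly.
#'
#' @param tbl Feature table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_plate_layout <- function(tbl, dir) {
  grids <- plate_layout(tbl)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(grids), function(f) {
    p <- file.path(dir, paste0(f, ".csv"))
    df <- data.frame(row = rownames(grids[[f]]), grids[[f]], check.names = FALSE)
    readr::write_csv(df, p, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Read plate-layout grids written by [write_plate_layout()]
#' @param dir Directory of per-feature layout CSVs.
#' @return Named list of 8 x 12 matrices.
#' @export
read_plate_layout <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) abort("no layout CSVs found")
  out <- lapply(files, function(p) {
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1])
    dimnames(m) <- list(df[[1]], 1:12)
    storage.mode(m) <- "double"
    m
  })
  setNames(out, sub("\\.csv$", "", basename(files)))
}
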