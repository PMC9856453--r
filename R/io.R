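#' Read a CellProfiler-style per-cell feature table
#'
#' Ingests a CSV export with `Metadata_*` columns plus one numeric column
#' per feature, producing a cell-level [profile_frame()]. Feature columns
#' are auto-detected as every non-metadata column; all of them must be
#' numeric.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the required metadata
#'   fields (`plate`, `well`, `field`, `concentration`, and optionally
#'   `cell`) to column names in the file. When no `cell` column exists,
#'   cells are numbered within each image in file order.
#' @param concentrations Optional declared treatment set (µg/mL); defaults
#'   to the concentrations present.
#' @return A `profile_frame` at level `"cell"`.
#' @export
read_cell_table <- function(path,
                            schema = c(plate = "Metadata_Plate",
                                       well = "Metadata_Well",
                                       field = "Metadata_Field",
                                       concentration = "Metadata_Concentration",
                                       cell = "Metadata_Cell"),
                            concentrations = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("no rows in '", path, "'"))

  required <- c("plate", "well", "field", "concentration")
  for (fld in required) {
    col <- schema[[fld]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(paste0("schema error: metadata column '",
                   if (is.null(col)) fld else col, "' not found in '", path, "'"))
    }
  }
  meta <- tibble(
    plate_id = as.character(raw[[schema[["plate"]]]]),
    well_id = as.character(raw[[schema[["well"]]]]),
    field_id = as.integer(raw[[schema[["field"]]]]),
    concentration = as.numeric(raw[[schema[["concentration"]]]])
  )
  cell_col <- schema[["cell"]]
  if (!is.null(cell_col) && !is.na(cell_col) && cell_col %in% names(raw)) {
    meta$cell_id <- as.integer(raw[[cell_col]])
    meta_cols <- unname(schema[c(required, "cell")])
  } else {
    meta$cell_id <- stats::ave(seq_len(nrow(raw)),
                               paste(meta$plate_id, meta$well_id, meta$field_id),
                               FUN = seq_along)
    meta_cols <- unname(schema[required])
  }
  meta <- meta[c("plate_id", "well_id", "field_id", "cell_id", "concentration")]

  feat_cols <- setdiff(names(raw), meta_cols)
  feat_cols <- feat_cols[!grepl("^Metadata_", feat_cols)]
  if (!length(feat_cols)) abort("no feature columns detected")
  for (fc in feat_cols) {
    v <- raw[[fc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(paste0("non-numeric feature value in column '", fc, "' at row ",
                   if (length(bad)) bad[1] else "?", " of '", path, "'"))
    }
  }
  m <- as.matrix(raw[feat_cols])
  storage.mode(m) <- "double"
  profile_frame(meta, m, level = "cell", concentrations = concentrations)
}

#' Write a profile frame to CSV
#'
#' Emits the metadata key columns followed by one column per feature, UTF-8
#' with `.` as decimal separator; values round-trip through
#' [read_profiles()] within floating tolerance.
#'
#' @param x A `profile_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  validate_profile_frame(x)
  readr::write_csv(profile_wide(x), path, progress = FALSE)
  invisible(path)
}

#' Read back a profile frame written by [write_profiles()]
#'
#' @param path CSV path.
#' @param level Profile level of the stored frame.
#' @return A `profile_frame`.
#' @export
read_profiles <- function(path, level = c("cell", "image", "well", "treatment")) {
  level <- match.arg(level)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("no rows in '", path, "'"))
  keys <- profile_keys(level)
  if (level == "treatment" && "plate_id" %in% names(raw)) keys <- c("plate_id", keys)
  meta_cols <- intersect(c(keys, "concentration"), names(raw))
  missing <- setdiff(keys, names(raw))
  if (length(missing)) {
    abort(paste0("missing key column(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(raw[setdiff(names(raw), meta_cols)])
  storage.mode(m) <- "double"
  profile_frame(raw[meta_cols], m, level = level)
}

#' Read a feature block-list
#'
#' Plain text, one feature name per line; blank lines and `#` comments are
#' ignored (the published Cell Painting block-list format).
#'
#' @param path Path to the block-list file.
#' @return Character vector of feature names.
#' @export
read_blocklist <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
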