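#' Quality-control filtering of a single-cell table
#'
#' Removes under-populated wells first (fewer than `min_cells_per_well`
#' cells across all fields), then under-populated images (fewer than
#' `min_cells_per_image` cells), recording both in a QC report. Sparse
#' wells and images typically indicate dispensing or focus failures and
#' would otherwise contribute unstable medians downstream.
#'
#' @param cells A cell-level [profile_frame()].
#' @param min_cells_per_well Minimum cells per well (default 500).
#' @param min_cells_per_image Minimum cells per image (default 30).
#' @return The filtered `profile_frame`, with the report attached as the
#'   `"qc_report"` attribute (see [qc_report()]).
#' @export
qc_filter <- function(cells, min_cells_per_well = 500, min_cells_per_image = 30) {
  stopifnot(inherits(cells, "profile_frame"), profile_level(cells) == "cell")
  n0 <- nrow(cells)

  # per-row well/image cell counts via one radix grouping pass
  dt <- data.table::data.table(p = cells$plate_id, w = cells$well_id,
                               f = cells$field_id)
  dt[, n_well := .N, by = c("p", "w")]
  dt[, n_img := .N, by = c("p", "w", "f")]
  keep_well <- dt$n_well >= min_cells_per_well
  # a well removal drops whole images, so image counts are unaffected by it
  bad_img <- keep_well & dt$n_img < min_cells_per_image
  keep <- keep_well & !bad_img

  wells_removed <- data.table::uniqueN(dt[!keep_well, c("p", "w")])
  images_removed <- data.table::uniqueN(dt[bad_img, c("p", "w", "f")])
  out <- if (all(keep)) cells else pf_slice(cells, keep)

  if (nrow(out) == 0) abort("empty after QC: all cells removed")

  attr(out, "qc_report") <- new_qc_report(
    wells_removed = wells_removed,
    images_removed = images_removed,
    cells_removed = n0 - nrow(out),
    cells_retained = nrow(out),
    features_removed = character(),
    thresholds = list(min_cells_per_well = min_cells_per_well,
                      min_cells_per_image = min_cells_per_image)
  )
  out
}

#' Drop block-listed features and cells with missing values
#'
#' Applies a feature block-list (features known to be unreliable, e.g.
#' saturated or execution-dependent measurements), then removes any cell
#' whose retained profile still contains missing values — in that order,
#' so a missing value confined to a block-listed feature does not cost the
#' cell.
#'
#' @param cells A cell-level [profile_frame()].
#' @param blocklist Character vector of feature names to drop (see
#'   [read_blocklist()]). Names absent from the table are ignored.
#' @return The filtered `profile_frame`, with a `qc_report` attribute
#'   recording removed features and cells.
#' @export
drop_cells_and_features <- function(cells, blocklist = character()) {
  stopifnot(inherits(cells, "profile_frame"))
  m <- feature_matrix(cells)
  drop <- intersect(colnames(m), blocklist)
  keep_feats <- setdiff(colnames(m), drop)
  if (!length(keep_feats)) abort("block-list removes all features")
  m <- m[, keep_feats, drop = FALSE]
  complete <- stats::complete.cases(m)
  out <- pf_slice(cells, complete)
  out <- set_feature_matrix(out, m[complete, , drop = FALSE])
  attr(out, "qc_report") <- new_qc_report(
    wells_removed = 0L, images_removed = 0L,
    cells_removed = sum(!complete), cells_retained = nrow(out),
    features_removed = drop,
    thresholds = list(blocklist_size = length(blocklist))
  )
  out
}

#' Retrieve the QC report attached by a filtering stage
#'
#' @param x A `profile_frame` returned by [qc_filter()] or
#'   [drop_cells_and_features()].
#' @return A `qc_report` object, or `NULL` if none is attached.
#' @export
qc_report <- function(x) attr(x, "qc_report")

new_qc_report <- function(wells_removed, images_removed, cells_removed,
                          cells_retained, features_removed, thresholds) {
  structure(list(
    wells_removed = as.integer(wells_removed),
    images_removed = as.integer(images_removed),
    cells_removed = as.integer(cells_removed),
    cells_retained = as.integer(cells_retained),
    features_removed = features_removed,
    thresholds = thresholds
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  wells removed:    %d\n", x$wells_removed))
  cat(sprintf("  images removed:   %d\n", x$images_removed))
  cat(sprintf("  cells removed:    %d (retained %d)\n",
              x$cells_removed, x$cells_retained))
  if (length(x$features_removed)) {
    cat(sprintf("  features removed: %d\n", length(x$features_removed)))
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    wells_removed = x$wells_removed,
    images_removed = x$images_removed,
    cells_removed = x$cells_removed,
    cells_retained = x$cells_retained,
    n_features_removed = length(x$features_removed)
  )
}
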