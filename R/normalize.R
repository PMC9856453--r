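#' Normalize single-cell profiles against unexposed controls
#'
#' Robust control-based normalization: per feature (and per plate by
#' default), each value is centered by the median of the unexposed-control
#' cells and scaled by the median absolute deviation (MAD) of the same
#' control cells,
#'
#'   x' = (x - median_ctrl) / MAD_ctrl .
#'
#' The MAD is *unscaled* by default — the plain median of absolute
#' deviations from the median, with no 1.4826 normal-consistency factor —
#' so control cells sit exactly at median 0 / MAD 1 afterwards. Features
#' whose control MAD is zero in any stratum carry no usable scale and are
#' dropped (recorded in the attached report).
#'
#' @param cells A cell-level [profile_frame()].
#' @param control_concentration Concentration (µg/mL) defining the
#'   unexposed control; default 0.
#' @param per_plate Normalize within each plate separately (default) or
#'   pool controls across plates.
#' @param mad_scale Multiply the MAD by 1.4826 (normal-consistency)?
#'   Default `FALSE`.
#' @return The normalized `profile_frame` (level `"cell"`), with dropped
#'   zero-MAD features listed in `attr(, "normalization")$features_dropped`.
#' @export
normalize_to_control <- function(cells, control_concentration = 0,
                                 per_plate = TRUE, mad_scale = FALSE) {
  stopifnot(inherits(cells, "profile_frame"))
  m <- feature_matrix(cells)
  is_ctrl <- cells$concentration == control_concentration
  strata <- if (per_plate) cells$plate_id else rep("all", nrow(cells))
  plate_levels <- unique(strata)
  scale_const <- if (mad_scale) 1.4826 else 1

  ctrl_rows <- which(is_ctrl)
  ctrl_n <- table(factor(strata[ctrl_rows], levels = plate_levels))
  if (any(ctrl_n < 2)) {
    abort(paste0("normalization stratum '",
                 plate_levels[which(ctrl_n < 2)[1]],
                 "' has fewer than 2 control cells (",
                 control_concentration, " µg/mL)"))
  }
  ctrl <- m[ctrl_rows, , drop = FALSE]
  ctrl_idx <- match(strata[ctrl_rows], plate_levels)
  meds <- grouped_col_medians_cpp(ctrl, ctrl_idx, length(plate_levels))
  mads <- grouped_col_mads_cpp(ctrl, ctrl_idx, length(plate_levels), meds) *
    scale_const
  dimnames(meds) <- dimnames(mads) <- list(plate_levels, colnames(m))

  zero_mad <- colnames(m)[apply(!is.finite(mads) | mads == 0, 2, any)]
  keep <- setdiff(colnames(m), zero_mad)
  if (!length(keep)) abort("all features have zero control MAD")
  if (length(zero_mad)) {
    m <- m[, keep, drop = FALSE]
    meds <- meds[, keep, drop = FALSE]
    mads <- mads[, keep, drop = FALSE]
  }

  stratum_idx <- match(strata, plate_levels)
  m <- scale_by_group_cpp(m, stratum_idx, meds, mads)
  colnames(m) <- keep

  out <- set_feature_matrix(cells, m)
  attr(out, "normalization") <- list(
    control_concentration = control_concentration,
    per_plate = per_plate,
    mad_scale = mad_scale,
    features_dropped = zero_mad,
    medians = meds, mads = mads
  )
  out
}
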