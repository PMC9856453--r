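#' Morphological profile frames
#'
#' A `profile_frame` is a tibble holding one morphological profile per row:
#' metadata key columns (a subset of `plate_id`, `well_id`, `field_id`,
#' `cell_id`, plus `concentration` in µg/mL) and a single matrix column
#' `features` whose columns are the measured features. The matrix backing
#' keeps per-cell tables with hundreds of thousands of rows fast to
#' normalize and aggregate, while the object still behaves as a tibble
#' (filter/arrange/ggplot all work on the metadata columns).
#'
#' The `level` attribute records the profile granularity and fixes the key
#' arity: `"cell"` is keyed by (plate, well, field, cell), `"image"` by
#' (plate, well, field), `"well"` by (plate, well) and `"treatment"` by
#' concentration (optionally within plate).
#'
#' @param meta A data frame of metadata key columns.
#' @param features A numeric matrix with one row per row of `meta` and named
#'   columns (the feature list).
#' @param level One of `"cell"`, `"image"`, `"well"`, `"treatment"`.
#' @param concentrations Optional numeric vector declaring the treatment
#'   set; defaults to the sorted unique concentrations present.
#' @param validate Check invariants (unique keys, declared concentrations)?
#' @return A `profile_frame` tibble.
#' @export
profile_frame <- function(meta, features, level = c("cell", "image", "well", "treatment"),
                          concentrations = NULL, validate = TRUE) {
  level <- match.arg(level)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("feature_%03d", seq_len(ncol(features)))
  }
  meta <- as_tibble(meta)
  if (nrow(meta) != nrow(features)) {
    abort("`meta` and `features` must have the same number of rows.")
  }
  out <- meta
  out$features <- features
  out <- tibble::new_tibble(out, class = "profile_frame",
                            level = level,
                            concentrations = concentrations %||%
                              sort(unique(meta$concentration)))
  if (validate) validate_profile_frame(out)
  out
}

profile_keys <- function(level) {
  switch(level,
    cell = c("plate_id", "well_id", "field_id", "cell_id"),
    image = c("plate_id", "well_id", "field_id"),
    well = c("plate_id", "well_id"),
    treatment = "concentration"
  )
}

#' @rdname profile_frame
#' @param x A `profile_frame`.
#' @export
profile_level <- function(x) attr(x, "level")

#' @rdname profile_frame
#' @export
feature_matrix <- function(x) {
  stopifnot(inherits(x, "profile_frame"))
  m <- x[["features"]]
  # subsetting a tibble row-wise keeps the matrix column intact
  m
}

#' @rdname profile_frame
#' @export
feature_names <- function(x) colnames(feature_matrix(x))

#' @rdname profile_frame
#' @export
n_features <- function(x) ncol(feature_matrix(x))

#' Replace the feature matrix of a profile frame
#'
#' @param x A `profile_frame`.
#' @param value A numeric matrix with `nrow(x)` rows.
#' @return `x` with its `features` column replaced.
#' @keywords internal
set_feature_matrix <- function(x, value) {
  stopifnot(nrow(value) == nrow(x))
  x[["features"]] <- value
  x
}

#' Validate profile-frame invariants
#'
#' Checks key uniqueness for the declared level, presence of the metadata
#' columns, and membership of every concentration in the declared treatment
#' set.
#'
#' @param x A `profile_frame`.
#' @return `x`, invisibly; aborts on violation.
#' @export
validate_profile_frame <- function(x) {
  level <- profile_level(x)
  keys <- profile_keys(level)
  if (level == "treatment" && "plate_id" %in% names(x)) {
    keys <- c("plate_id", keys)
  }
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    abort(paste0("profile_frame at level '", level, "' is missing key column(s): ",
                 paste(missing, collapse = ", ")))
  }
  key_df <- as.data.frame(x)[keys]
  if (anyDuplicated(key_df)) {
    abort(paste0("duplicate (", paste(keys, collapse = ", "), ") keys in profile_frame"))
  }
  conc_set <- attr(x, "concentrations")
  if (!is.null(conc_set) && "concentration" %in% names(x)) {
    bad <- setdiff(unique(x$concentration), conc_set)
    if (length(bad)) {
      abort(paste0("concentrations outside the declared treatment set: ",
                   paste(signif(bad, 4), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
print.profile_frame <- function(x, ...) {
  cat(sprintf("# A profile_frame: level '%s', %d rows x %d features\n",
              profile_level(x), nrow(x), n_features(x)))
  NextMethod()
}

#' Widen a profile frame to one column per feature
#'
#' @param x A `profile_frame`.
#' @return A plain tibble with metadata columns followed by one numeric
#'   column per feature.
#' @export
profile_wide <- function(x) {
  m <- feature_matrix(x)
  meta <- as_tibble(as.data.frame(x)[setdiff(names(x), "features")])
  dplyr::bind_cols(meta, as_tibble(as.data.frame(m)))
}

#' Lengthen a profile frame to (key, feature, value) form
#'
#' Convenient for ggplot2 and dplyr summaries; one row per profile/feature
#' pair.
#'
#' @param x A `profile_frame`.
#' @return A long tibble with the metadata columns plus `feature` and `value`.
#' @export
profile_long <- function(x) {
  m <- feature_matrix(x)
  meta <- as_tibble(as.data.frame(x)[setdiff(names(x), "features")])
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(meta, as_tibble(as.data.frame(m))),
    cols = dplyr::all_of(colnames(m)), names_to = "feature", values_to = "value"
  )
  long
}

# column medians without apply()'s aperm copy; NA-aware fast path
col_medians <- function(m, rows = NULL) {
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    out[j] <- if (anyNA(v)) median(v, na.rm = TRUE) else median(v)
  }
  names(out) <- colnames(m)
  out
}

# grouped column medians (NA-dropping, R median convention); returns a
# groups x features matrix in `levels` order
grouped_col_medians <- function(m, groups, levels) {
  idx <- match(groups, levels)
  res <- grouped_col_medians_cpp(m, idx, length(levels))
  dimnames(res) <- list(levels, colnames(m))
  res
}

# if each group occupies one contiguous run of rows, return per-group
# (first, last) ranges; otherwise NULL
contiguous_blocks <- function(idx, n_groups) {
  r <- rle(idx)
  if (length(r$values) != length(unique(r$values))) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  blocks <- vector("list", n_groups)
  blocks[r$values] <- lapply(seq_along(r$values), function(k) c(starts[k], ends[k]))
  blocks
}

# row-subset helper that preserves class/attributes
pf_slice <- function(x, i) {
  out <- x[i, , drop = FALSE]
  attrs <- attributes(x)
  attr(out, "level") <- attrs$level
  attr(out, "concentrations") <- attrs$concentrations
  class(out) <- class(x)
  out
}
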