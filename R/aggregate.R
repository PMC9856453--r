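#' Aggregate profiles to coarser levels
#'
#' `aggregate_images()` takes cell-level profiles to image level
#' (per-field median over cells), `aggregate_wells()` takes cell- or
#' image-level profiles to well level (median over contributing rows), and
#' `aggregate_treatment()` averages well-level profiles per concentration
#' within each plate and then, by default, across plates. Medians at the
#' lower levels make the profiles robust to segmentation outliers; means
#' at the treatment level follow the replicate-averaging convention of the
#' study design.
#'
#' @param x A [profile_frame()] at the appropriate level.
#' @return A `profile_frame` at the coarser level.
#' @name aggregation
NULL

# grouped column medians over (possibly multi-column) keys; run-length ids
# suffice because profile tables keep each group in one contiguous block —
# if not, rows are radix-sorted first
agg_median <- function(keys, m) {
  rid <- data.table::rleidv(keys)
  first <- !duplicated(rid)
  meta <- keys[first, , drop = FALSE]
  if (anyDuplicated(meta)) {
    ord <- do.call(order, unname(as.list(keys)))
    return(agg_median(keys[ord, , drop = FALSE], m[ord, , drop = FALSE]))
  }
  res <- grouped_col_medians_cpp(m, rid, max(rid))
  colnames(res) <- colnames(m)
  list(meta = as_tibble(meta), m = res)
}

#' @rdname aggregation
#' @export
aggregate_images <- function(x) {
  stopifnot(inherits(x, "profile_frame"), profile_level(x) == "cell")
  keys <- as.data.frame(x)[c("plate_id", "well_id", "field_id", "concentration")]
  res <- agg_median(keys, feature_matrix(x))
  profile_frame(res$meta, res$m, level = "image",
                concentrations = attr(x, "concentrations"), validate = FALSE)
}

#' @rdname aggregation
#' @export
aggregate_wells <- function(x) {
  stopifnot(inherits(x, "profile_frame"),
            profile_level(x) %in% c("cell", "image"))
  keys <- as.data.frame(x)[c("plate_id", "well_id", "concentration")]
  res <- agg_median(keys, feature_matrix(x))
  profile_frame(res$meta, res$m, level = "well",
                concentrations = attr(x, "concentrations"), validate = FALSE)
}

#' @rdname aggregation
#' @param across_plates Average the per-plate treatment means across
#'   plates (default `TRUE`)? If `FALSE`, the result keeps one row per
#'   (plate, concentration).
#' @export
aggregate_treatment <- function(x, across_plates = TRUE) {
  stopifnot(inherits(x, "profile_frame"), profile_level(x) == "well")
  m <- feature_matrix(x)
  key <- paste(x$plate_id, x$concentration, sep = "\r")
  # rowsum orders by sorted key; rebuild metadata from the key afterwards
  cnt <- rowsum(rep(1, nrow(m)), key)
  per_plate <- rowsum(m, key) / as.vector(cnt)
  parts <- do.call(rbind, strsplit(rownames(per_plate), "\r", fixed = TRUE))
  rownames(per_plate) <- NULL
  meta <- tibble(plate_id = parts[, 1],
                 concentration = as.numeric(parts[, 2]))

  conc_set <- attr(x, "concentrations") %||% sort(unique(meta$concentration))
  plates <- unique(x$plate_id)
  for (cc in conc_set) {
    have <- meta$plate_id[meta$concentration == cc]
    lack <- setdiff(plates, have)
    if (length(lack)) {
      warn(paste0("concentration ", cc, " µg/mL absent from plate(s) ",
                  paste(lack, collapse = ", "), "; averaging over the rest"))
    }
  }

  if (!across_plates) {
    return(profile_frame(meta, per_plate, level = "treatment",
                         concentrations = conc_set, validate = FALSE))
  }
  key2 <- as.character(meta$concentration)
  cnt2 <- rowsum(rep(1, nrow(per_plate)), key2)
  avg <- rowsum(per_plate, key2) / as.vector(cnt2)
  conc <- as.numeric(rownames(avg))
  rownames(avg) <- NULL
  ord <- order(conc)
  profile_frame(tibble(concentration = conc[ord]),
                avg[ord, , drop = FALSE],
                level = "treatment", concentrations = conc_set,
                validate = FALSE)
}
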