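#' Build an ordered treatment-by-feature heatmap matrix
#'
#' Arranges control-normalized treatment-level profiles for display the
#' way dose-response Cell Painting summaries are drawn: one row per
#' nonzero exposure concentration in *descending* order (highest dose on
#' top), one column per feature of the requested compartment, ordered by
#' feature group (Correlation, Intensity, RadialDistribution, Texture),
#' then by fluorescent channel (DNA, AGP, ER, RNA, Mito), then by name.
#' Granularity and Location features are excluded by default. Values are
#' the normalized deviations from the unexposed control (the reference is
#' implicit: profiles are already control-normalized).
#'
#' @param x A treatment-level [profile_frame()] including the control
#'   concentration.
#' @param compartment `"Cells"`, `"Cytoplasm"` or `"Nuclei"`.
#' @param groups Feature groups to keep, in display order.
#' @param include_all_groups Keep every feature group (overrides
#'   `groups`)?
#' @param control_concentration Concentration identifying the control row
#'   to drop from the display (default 0).
#' @return A numeric matrix (concentrations x features) of class
#'   `heatmap_matrix`, with `attr(, "features")` holding the ordered
#'   feature descriptors.
#' @export
heatmap_matrix <- function(x, compartment,
                           groups = c("Correlation", "Intensity",
                                      "RadialDistribution", "Texture"),
                           include_all_groups = FALSE,
                           control_concentration = 0) {
  stopifnot(inherits(x, "profile_frame"), profile_level(x) == "treatment")
  if (!compartment %in% c("Cells", "Cytoplasm", "Nuclei")) {
    abort(paste0("unknown compartment '", compartment,
                 "' (expected Cells, Cytoplasm or Nuclei)"))
  }
  desc <- feature_descriptors(x)
  desc <- desc[desc$compartment == compartment, ]
  if (!include_all_groups) desc <- desc[desc$group %in% groups, ]
  if (nrow(desc) == 0) {
    abort(paste0("no features for compartment '", compartment, "'"))
  }

  grp_rank <- match(desc$group, unique(c(groups, sort(unique(desc$group)))))
  chan_rank <- vapply(desc$channels, function(ch) {
    if (!length(ch)) length(.channel_order) + 1L
    else min(match(ch, .channel_order))
  }, numeric(1))
  ord <- order(grp_rank, chan_rank, desc$raw_name)
  desc <- desc[ord, ]

  rows <- x$concentration != control_concentration
  conc <- x$concentration[rows]
  row_ord <- order(conc, decreasing = TRUE)
  m <- feature_matrix(x)[rows, desc$raw_name, drop = FALSE]
  m <- m[row_ord, , drop = FALSE]
  rownames(m) <- as.character(conc[row_ord])

  structure(m, class = c("heatmap_matrix", "matrix", "array"),
            features = desc, compartment = compartment,
            concentrations = conc[row_ord])
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("heatmap_matrix: compartment %s, %d concentrations x %d features\n",
              attr(x, "compartment"), nrow(x), ncol(x)))
  invisible(x)
}

#' Long-format view of a heatmap matrix (for ggplot2)
#'
#' @param x A `heatmap_matrix`.
#' @param ... Unused.
#' @return A tibble with `concentration`, `feature`, `group`, `channel`,
#'   `value`; feature order is preserved as a factor.
#' @export
tidy.heatmap_matrix <- function(x, ...) {
  desc <- attr(x, "features")
  conc <- attr(x, "concentrations")
  first_chan <- vapply(desc$channels, function(ch) {
    if (length(ch)) ch[1] else NA_character_
  }, character(1))
  tidyr::expand_grid(
    concentration = conc,
    feature = factor(desc$raw_name, levels = desc$raw_name)
  ) %>%
    mutate(
      group = desc$group[match(feature, desc$raw_name)],
      channel = first_chan[match(feature, desc$raw_name)],
      value = as.vector(t(unclass(x)))
    )
}

#' Plot a heatmap matrix
#'
#' @param object A `heatmap_matrix`.
#' @param ... Unused.
#' @param limits Symmetric color limits; default the data range clipped at
#'   the 99th percentile of `|value|`.
#' @return A ggplot object.
#' @export
autoplot.heatmap_matrix <- function(object, ..., limits = NULL) {
  long <- tidy(object)
  if (is.null(limits)) {
    lim <- stats::quantile(abs(long$value), 0.99, na.rm = TRUE)
    limits <- c(-lim, lim)
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = feature, y = factor(concentration, levels = rev(sort(unique(concentration)))),
    fill = pmin(pmax(value, limits[1]), limits[2])
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "normalized\nchange") +
    ggplot2::labs(x = NULL, y = "concentration (µg/mL)",
                  title = paste0(attr(object, "compartment"), " features")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
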