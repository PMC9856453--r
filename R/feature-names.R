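#' Parse CellProfiler-style feature names
#'
#' CellProfiler exports feature names as underscore-separated tokens, e.g.
#' `Cells_Correlation_Overlap_AGP_ER` or `Cytoplasm_Granularity_13_Mito`.
#' This parser assigns each token, in order, to a compartment
#' (Cells/Cytoplasm/Nuclei), a feature group (Correlation, Intensity,
#' RadialDistribution, Texture, Granularity, Location, Neighbors,
#' AreaShape), the fluorescent channels involved (DNA, AGP, ER, RNA, Mito),
#' the measurement token(s), and numeric scale suffixes. Parsing is total:
#' names that carry no compartment or group map to `"unknown"`/`"other"`
#' rather than failing, and the raw name always round-trips unchanged in
#' `raw_name`. A space between the compartment and the rest of the name
#' (a common display spelling, e.g. `Cells Correlation_Overlap_AGP_ER`)
#' is accepted.
#'
#' @param raw_name Character vector of feature names.
#' @return A tibble with one row per name: `raw_name`, `compartment`,
#'   `group`, `channels` (list of character vectors), `measurement`,
#'   `scale_tokens` (list of character vectors, zero-padding preserved).
#' @examples
#' parse_feature_name("Cells_Correlation_Overlap_AGP_ER")
#' parse_feature_name("Texture_Entropy_AGP_5_02_256")
#' @export
parse_feature_name <- function(raw_name) {
  stopifnot(is.character(raw_name), all(nzchar(raw_name)))
  compartments <- c("Cells", "Cytoplasm", "Nuclei")
  groups <- c("Correlation", "Intensity", "RadialDistribution", "Texture",
              "Granularity", "Location", "Neighbors", "AreaShape")
  channels <- c("DNA", "AGP", "ER", "RNA", "Mito")

  parse_one <- function(nm) {
    # accept "Cells Correlation_..." display spelling
    norm <- sub(paste0("^(", paste(compartments, collapse = "|"), ")[ ]"),
                "\\1_", nm)
    tokens <- strsplit(norm, "_", fixed = TRUE)[[1]]
    comp <- "unknown"
    if (length(tokens) && tokens[1] %in% compartments) {
      comp <- tokens[1]
      tokens <- tokens[-1]
    }
    grp <- "other"
    if (length(tokens) && tokens[1] %in% groups) {
      grp <- tokens[1]
      tokens <- tokens[-1]
    }
    is_chan <- tokens %in% channels
    is_num <- grepl("^[0-9]+$", tokens)
    chans <- unique(tokens[is_chan])
    scales <- tokens[is_num & !is_chan]
    meas <- tokens[!is_chan & !is_num]
    list(compartment = comp, group = grp, channels = chans,
         measurement = if (length(meas)) paste(meas, collapse = "_") else NA_character_,
         scale_tokens = scales)
  }

  parsed <- lapply(raw_name, parse_one)
  tibble(
    raw_name = raw_name,
    compartment = vapply(parsed, `[[`, character(1), "compartment"),
    group = vapply(parsed, `[[`, character(1), "group"),
    channels = lapply(parsed, `[[`, "channels"),
    measurement = vapply(parsed, `[[`, character(1), "measurement"),
    scale_tokens = lapply(parsed, `[[`, "scale_tokens")
  )
}

#' Describe the feature list of a profile frame
#'
#' @param x A `profile_frame`.
#' @return `parse_feature_name()` applied to `feature_names(x)`.
#' @export
feature_descriptors <- function(x) parse_feature_name(feature_names(x))

# canonical display orderings used by heatmap construction
.group_order <- c("Correlation", "Intensity", "RadialDistribution", "Texture")
.channel_order <- c("DNA", "AGP", "ER", "RNA", "Mito")
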