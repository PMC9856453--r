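#' Per-analyte one-way ANOVA with Tukey HSD post hoc test
#'
#' Tests each analyte of a lipidomics/metabolomics table for differences
#' among exposure groups. Technical replicates are averaged into their
#' biological replicate first (so the experimental unit is the biological
#' replicate), abundances are log2-transformed, and a one-way ANOVA is
#' followed by Tukey's honest-significant-difference test for all group
#' pairs.
#'
#' @param table An `analyte_table` (see [generate_analyte_table()]) or any
#'   tibble with columns `analyte`, `group`, `bio_rep`, `tech_rep`,
#'   `abundance`.
#' @param average_technical Average technical replicates within biological
#'   replicates before testing (default `TRUE`)?
#' @param log2_transform Run the tests on log2 abundances (default
#'   `TRUE`)?
#' @return An `anova_tukey` tibble, one row per analyte: `analyte`,
#'   `statistic` (ANOVA F), `df1`, `df2`, `p_value`, `degenerate` (zero
#'   variance everywhere), and `tukey` (list column of tibbles with
#'   `comparison`, `diff`, `p_adjusted`).
#' @export
anova_tukey <- function(table, average_technical = TRUE, log2_transform = TRUE) {
  check_analyte_table(table)
  dat <- prepare_omics(table, average_technical, log2_transform)
  groups <- unique(dat$group)
  if (length(groups) < 2) abort("need >= 2 groups")
  n_per <- dat %>% distinct(group, bio_rep) %>% count(group)
  if (any(n_per$n < 2)) abort("each group needs >= 2 observations")

  out <- dat %>%
    tidyr::nest(data = -analyte) %>%
    mutate(res = purrr::map(data, function(d) {
      degenerate <- all(tapply(d$value, d$group, function(v) var(v) == 0))
      if (degenerate || var(d$value) == 0) {
        return(tibble(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p_value = NA_real_, degenerate = TRUE,
                      tukey = list(tibble(comparison = character(),
                                          diff = numeric(),
                                          p_adjusted = numeric()))))
      }
      fit <- aov(value ~ group, data = transform(d, group = factor(group)))
      an <- summary(fit)[[1]]
      tk <- TukeyHSD(fit)$group
      tibble(statistic = an[["F value"]][1],
             df1 = an[["Df"]][1], df2 = an[["Df"]][2],
             p_value = an[["Pr(>F)"]][1], degenerate = FALSE,
             tukey = list(tibble(comparison = rownames(tk),
                                 diff = tk[, "diff"],
                                 p_adjusted = tk[, "p adj"])))
    })) %>%
    select(-data) %>%
    tidyr::unnest(res)
  structure(out, class = c("anova_tukey", class(out)),
            log2_transform = log2_transform,
            average_technical = average_technical)
}

check_analyte_table <- function(table) {
  need <- c("analyte", "group", "abundance")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    abort(paste0("analyte table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(table$abundance <= 0, na.rm = TRUE)) {
    abort("abundances must be positive (log-transformable)")
  }
  invisible(table)
}

prepare_omics <- function(table, average_technical, log2_transform) {
  dat <- as_tibble(table)
  if (!"bio_rep" %in% names(dat)) dat$bio_rep <- seq_len(nrow(dat))
  dat$value <- if (log2_transform) log2(dat$abundance) else dat$abundance
  if (average_technical && "tech_rep" %in% names(dat)) {
    dat <- dat %>%
      group_by(analyte, group, bio_rep) %>%
      summarise(value = mean(value), .groups = "drop")
  }
  dat
}

#' Volcano classification of analytes against a reference group
#'
#' Computes, per analyte, the fold change of `group` over `reference` as
#' the ratio of geometric means (i.e. `2^(mean log2 difference)`), takes
#' the p-value for that pair from the Tukey HSD test by default (a plain
#' Welch t-test is available), and classifies each analyte as
#' up-regulated (`p < p_thresh` and `FC > fc_thresh`), down-regulated
#' (`p < p_thresh` and `FC < 1/fc_thresh`) or not significant.
#'
#' @inheritParams anova_tukey
#' @param group Exposure group to compare.
#' @param reference Reference group (default `"control"`).
#' @param p_thresh,fc_thresh Significance gates (defaults 0.05 and 2).
#' @param p_from `"tukey"` (default) or `"ttest"`.
#' @return A `volcano_result` tibble: `analyte`, `fold_change`, `log2_fc`,
#'   `p_value`, `neg_log10_p`, `class` (`"up"`, `"down"`, `"ns"`).
#' @export
volcano_classify <- function(table, group, reference = "control",
                             p_thresh = 0.05, fc_thresh = 2,
                             p_from = c("tukey", "ttest"),
                             average_technical = TRUE) {
  check_analyte_table(table)
  p_from <- match.arg(p_from)
  groups_present <- unique(table$group)
  if (!reference %in% groups_present) {
    abort(paste0("reference group '", reference, "' not present"))
  }
  if (!group %in% groups_present) {
    abort(paste0("group '", group, "' not present"))
  }
  dat <- prepare_omics(table, average_technical, log2_transform = TRUE)

  fc <- dat %>%
    filter(group %in% c(!!group, !!reference)) %>%
    group_by(analyte) %>%
    summarise(
      log2_fc = mean(value[group == !!group]) - mean(value[group == !!reference]),
      .groups = "drop"
    )

  if (p_from == "tukey") {
    at <- anova_tukey(table, average_technical = average_technical)
    pair <- c(paste0(group, "-", reference), paste0(reference, "-", group))
    pvals <- purrr::map_dbl(at$tukey, function(tk) {
      hit <- tk$p_adjusted[tk$comparison %in% pair]
      if (length(hit)) hit[1] else NA_real_
    })
    pv <- tibble(analyte = at$analyte, p_value = pvals)
  } else {
    pv <- dat %>%
      filter(group %in% c(!!group, !!reference)) %>%
      group_by(analyte) %>%
      summarise(p_value = tryCatch(
        stats::t.test(value[group == !!group], value[group == !!reference])$p.value,
        error = function(e) NA_real_), .groups = "drop")
  }

  out <- fc %>%
    left_join(pv, by = "analyte") %>%
    mutate(
      fold_change = 2^log2_fc,
      neg_log10_p = -log10(p_value),
      class = dplyr::case_when(
        is.na(p_value) ~ "ns",
        p_value < p_thresh & fold_change > fc_thresh ~ "up",
        p_value < p_thresh & fold_change < 1 / fc_thresh ~ "down",
        TRUE ~ "ns"
      )
    ) %>%
    select(analyte, fold_change, log2_fc, p_value, neg_log10_p, class)
  structure(out, class = c("volcano_result", class(out)),
            group = group, reference = reference,
            p_thresh = p_thresh, fc_thresh = fc_thresh)
}

#' @export
autoplot.volcano_result <- function(object, ...) {
  pt <- attr(object, "p_thresh"); ft <- attr(object, "fc_thresh")
  ggplot2::ggplot(object, ggplot2::aes(x = log2_fc, y = neg_log10_p,
                                       color = class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(pt), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-log2(ft), log2(ft)),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(up = "#B2182B", down = "#2166AC",
                                           ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_classic()
}

#' Top-N clustered heatmap of differential analytes
#'
#' Selects the `top_n` analytes by ascending ANOVA p-value (ties broken
#' alphabetically), standardizes each analyte's log2 abundances across
#' samples (z-score), and clusters the analytes hierarchically. Columns
#' are the individual samples (biological x technical replicates per
#' group).
#'
#' @inheritParams anova_tukey
#' @param results An `anova_tukey` result for the same table.
#' @param top_n Number of analytes to keep (default 25); clamped with a
#'   warning if fewer are available.
#' @param distance Distance measure for clustering (passed to
#'   [stats::dist()]).
#' @param linkage Agglomeration method (passed to [stats::hclust()];
#'   default `"ward.D2"`).
#' @return A `clustered_heatmap`: list with `matrix` (analytes x samples,
#'   rows in dendrogram order), `row_order`, `sample_info`, `hclust`.
#' @export
cluster_heatmap <- function(table, results, top_n = 25,
                            distance = "euclidean", linkage = "ward.D2") {
  check_analyte_table(table)
  stopifnot(inherits(results, "anova_tukey"))
  n_analytes <- length(unique(results$analyte))
  if (top_n > n_analytes) {
    warn(paste0("top_n = ", top_n, " exceeds the ", n_analytes,
                " available analytes; using all"))
    top_n <- n_analytes
  }
  ranked <- results %>% arrange(p_value, analyte)
  top <- head(ranked$analyte, top_n)

  dat <- as_tibble(table) %>%
    filter(analyte %in% top) %>%
    mutate(sample = paste(group, bio_rep, tech_rep, sep = "_"),
           value = log2(abundance))
  wide <- dat %>%
    select(analyte, sample, value) %>%
    tidyr::pivot_wider(names_from = sample, values_from = value)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$analyte
  m <- m[top, , drop = FALSE]
  # per-analyte z-score across samples
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0] <- 1
  mz <- (m - mu) / s

  hc <- if (nrow(mz) > 2) {
    hclust(dist(mz, method = distance), method = linkage)
  } else NULL
  ord <- if (is.null(hc)) seq_len(nrow(mz)) else hc$order
  sample_info <- dat %>% distinct(sample, group, bio_rep, tech_rep)

  structure(list(
    matrix = mz[ord, , drop = FALSE],
    row_order = rownames(mz)[ord],
    sample_info = sample_info,
    hclust = hc, top_n = top_n,
    distance = distance, linkage = linkage
  ), class = "clustered_heatmap")
}

#' @export
print.clustered_heatmap <- function(x, ...) {
  cat(sprintf("clustered_heatmap: %d analytes x %d samples (%s/%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$distance, x$linkage))
  invisible(x)
}

#' @export
autoplot.clustered_heatmap <- function(object, ...) {
  long <- as_tibble(as.data.frame(object$matrix), rownames = "analyte") %>%
    tidyr::pivot_longer(-analyte, names_to = "sample", values_to = "value") %>%
    mutate(analyte = factor(analyte, levels = rev(object$row_order)))
  ggplot2::ggplot(long, ggplot2::aes(x = sample, y = analyte, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "z(log2)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
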