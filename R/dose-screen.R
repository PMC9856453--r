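#' Per-feature ANCOVA concentration screen
#'
#' Fits, for every feature of an image-level profile matrix, the ordinary
#' least-squares model
#'
#'   value ~ intercept + beta1 * g(concentration) + plate
#'
#' with the plate as a factor absorbing residual batch differences, and
#' tests `beta1 = 0` with a two-sided t test. Raw p-values are corrected
#' with the Bonferroni rule over the family of all tested features
#' (`p_adjusted = min(1, m * p)`).
#'
#' @param x An image-level [profile_frame()] (well level also accepted).
#' @param dose_scale `"log"` (default, log10 with half-minimum offset; see
#'   [dose_transform()]) or `"identity"`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return An `ancova_screen` tibble with one row per feature: `feature`,
#'   `estimate` (slope on the dose scale), `std_error`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`, `direction` (`"+"`/`"-"`,
#'   `NA` for zero or undefined slopes).
#' @export
ancova_screen <- function(x, dose_scale = c("log", "identity"), alpha = 0.05) {
  stopifnot(inherits(x, "profile_frame"))
  dose_scale <- match.arg(dose_scale)
  conc <- x$concentration
  if (length(unique(conc)) < 2) abort("need >= 2 distinct concentrations")
  g <- dose_transform(conc, dose_scale, attr(x, "concentrations"))

  plates <- unique(x$plate_id)
  if (length(plates) >= 2) {
    design <- stats::model.matrix(~ g + factor(x$plate_id))
  } else {
    warn("single plate: plate factor dropped from the ANCOVA")
    design <- stats::model.matrix(~ g)
  }
  y <- feature_matrix(x)
  n <- nrow(y)
  p <- ncol(design)
  df <- n - p
  if (df < 1) abort("not enough rows for the ANCOVA design")

  qr_d <- qr(design)
  coefs <- qr.coef(qr_d, y)
  fitted <- design %*% coefs
  rss <- colSums((y - fitted)^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta1 <- coefs[2, ]
  tstat <- beta1 / se
  pval <- 2 * pt(-abs(tstat), df)
  m <- ncol(y)
  padj <- pmin(1, m * pval)
  # constant features: zero residual and zero slope -> undefined t
  undef <- !is.finite(tstat)
  padj[undef] <- NA_real_

  out <- tibble(
    feature = colnames(y),
    estimate = unname(beta1),
    std_error = unname(se),
    statistic = unname(tstat),
    p_value = unname(pval),
    p_adjusted = unname(padj),
    significant = !undef & !is.na(padj) & padj < alpha,
    direction = dplyr::case_when(
      undef | beta1 == 0 ~ NA_character_,
      beta1 > 0 ~ "+",
      TRUE ~ "-"
    )
  )
  structure(out, class = c("ancova_screen", class(out)),
            alpha = alpha, m = m, dose_scale = dose_scale, df = df)
}

#' Summarize an ANCOVA screen family-wise
#'
#' @param results An `ancova_screen` tibble.
#' @return A one-row `screen_summary` tibble: family size `m`,
#'   `n_significant`, `fraction_significant`, and among significant
#'   features the `fraction_positive` / `fraction_negative` split (`NA`
#'   when nothing is significant).
#' @export
summarize_screen <- function(results) {
  stopifnot(inherits(results, "ancova_screen"), nrow(results) > 0)
  m <- attr(results, "m") %||% nrow(results)
  sig <- results[results$significant, ]
  n_sig <- nrow(sig)
  out <- tibble(
    m = m,
    n_significant = n_sig,
    fraction_significant = n_sig / m,
    fraction_positive = if (n_sig) mean(sig$direction == "+") else NA_real_,
    fraction_negative = if (n_sig) mean(sig$direction == "-") else NA_real_,
    alpha = attr(results, "alpha") %||% 0.05
  )
  structure(out, class = c("screen_summary", class(out)))
}

#' @export
glance.ancova_screen <- function(x, ...) summarize_screen(x)

#' Empirical family-wise error rate of the screen under the global null
#'
#' Monte-Carlo verification of the Bonferroni guarantee: repeatedly
#' simulates a null experiment (no concentration effect, plate batch
#' effects retained), runs the full processing chain (QC, control
#' median/MAD normalization, image-level aggregation, batch correction)
#' and the ANCOVA screen, and reports the fraction of replicates with at
#' least one Bonferroni-significant feature.
#'
#' @param config A [sim_config()] whose effects are forced to zero.
#' @param n_sims Number of simulated experiments.
#' @param alpha Family-wise level (default 0.05).
#' @param seed Root seed; replicate r uses `seed + r`.
#' @param min_cells_per_well,min_cells_per_image QC thresholds passed to
#'   [qc_filter()] (defaults 500 and 30; lower them for reduced designs).
#' @return An `fwer_result` list: `fwer` (fraction of replicates with >= 1
#'   rejection), `n_sims`, `rejected` (logical per replicate),
#'   `n_significant` (count per replicate), `alpha`, `mc_se` (binomial
#'   Monte-Carlo standard error at the nominal level).
#' @export
fwer_simulation <- function(config = sim_config(), n_sims = 200,
                            alpha = 0.05, seed = config$seed,
                            min_cells_per_well = 500,
                            min_cells_per_image = 30) {
  rejected <- logical(n_sims)
  n_sig <- integer(n_sims)
  for (r in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- generate_null_experiment(cfg)
    screen <- sim$cells %>%
      qc_filter(min_cells_per_well, min_cells_per_image) %>%
      normalize_to_control() %>%
      aggregate_images() %>%
      combat_correct() %>%
      ancova_screen(alpha = alpha)
    n_sig[r] <- sum(screen$significant, na.rm = TRUE)
    rejected[r] <- n_sig[r] > 0
  }
  structure(list(
    fwer = mean(rejected), n_sims = n_sims,
    rejected = rejected, n_significant = n_sig,
    alpha = alpha, mc_se = sqrt(alpha * (1 - alpha) / n_sims)
  ), class = "fwer_result")
}

#' @export
print.fwer_result <- function(x, ...) {
  cat(sprintf("Empirical FWER: %.1f%% over %d null replicates (nominal %.0f%%, MC SE %.1f%%)\n",
              100 * x$fwer, x$n_sims, 100 * x$alpha, 100 * x$mc_se))
  invisible(x)
}

#' Per-concentration value groups for a single feature
#'
#' Extracts one feature of an image-level profile matrix grouped by
#' concentration (ascending), with quartile summaries — the data behind a
#' dose-response boxplot. Concentrations of the declared treatment set
#' with no surviving images are kept as empty groups.
#'
#' @param x An image-level [profile_frame()].
#' @param feature Feature name.
#' @return A tibble with one row per concentration: `concentration`, `n`,
#'   `values` (list column), `q1`, `median`, `q3`, `empty`.
#' @export
feature_boxplot_data <- function(x, feature) {
  stopifnot(inherits(x, "profile_frame"))
  m <- feature_matrix(x)
  if (!feature %in% colnames(m)) {
    abort(paste0("unknown feature '", feature, "'"))
  }
  v <- m[, feature]
  conc_set <- attr(x, "concentrations") %||% sort(unique(x$concentration))
  purrr::map_dfr(sort(conc_set), function(cc) {
    vals <- v[x$concentration == cc]
    qs <- if (length(vals)) quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
          else rep(NA_real_, 3)
    tibble(concentration = cc, n = length(vals),
           values = list(vals),
           q1 = qs[1], median = qs[2], q3 = qs[3],
           empty = length(vals) == 0)
  })
}

#' Boxplot of one feature across concentrations
#'
#' @param x An image-level [profile_frame()].
#' @param feature Feature name.
#' @return A ggplot object.
#' @export
plot_feature_boxplot <- function(x, feature) {
  dat <- feature_boxplot_data(x, feature)
  long <- tidyr::unnest(dat[!dat$empty, c("concentration", "values")],
                        cols = "values")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(concentration), y = values)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "concentration (µg/mL)", y = feature) +
    ggplot2::theme_classic()
}
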