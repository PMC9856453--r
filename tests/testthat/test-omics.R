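omics_fixture <- function(values_by_group, analyte = "a1") {
  # values are log2 abundances; one technical replicate per biological
  purrr::imap_dfr(values_by_group, function(vals, grp) {
    tibble::tibble(analyte = analyte, group = grp,
                   bio_rep = seq_along(vals), tech_rep = 1L,
                   abundance = 2^vals)
  })
}

test_that("the one-way ANOVA matches the hand computation", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, SSW = 6, F = (6/2)/(6/6) = 3
  tab <- omics_fixture(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(3, 4, 5)))
  res <- anova_tukey(tab)
  expect_equal(res$statistic, 3.0)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$p_value, 1 - stats::pf(3, 2, 6))
  expect_equal(nrow(res$tukey[[1]]), 3) # all pairwise comparisons
})

test_that("identical group distributions give F near 0 and p near 1", {
  tab <- omics_fixture(list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3)))
  res <- anova_tukey(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)
})

test_that("a strongly shifted group drives exactly its Tukey pairs", {
  tab <- omics_fixture(list(A = c(1, 1.1, 0.9), B = c(1.05, 0.95, 1),
                            C = c(11, 11.1, 10.9)))
  tk <- anova_tukey(tab)$tukey[[1]]
  involved <- grepl("C", tk$comparison)
  expect_true(all(tk$p_adjusted[involved] < 0.01))
  expect_true(all(tk$p_adjusted[!involved] > 0.5))
})

test_that("technical replicates are averaged into biological replicates", {
  tab <- tibble::tibble(
    analyte = "a1", group = rep(c("A", "B"), each = 4),
    bio_rep = rep(c(1, 1, 2, 2), 2), tech_rep = rep(c(1, 2), 4),
    abundance = 2^c(1, 3, 2, 4, 5, 7, 6, 8)
  )
  res <- anova_tukey(tab)
  # averaged bio reps: A = {2, 3}, B = {6, 7} -> same as direct aov on those
  d <- data.frame(v = c(2, 3, 6, 7), g = factor(rep(c("A", "B"), each = 2)))
  ref <- summary(aov(v ~ g, d))[[1]]
  expect_equal(res$statistic, ref[["F value"]][1])
  expect_equal(res$df2, 2)
  # without averaging, the pseudo-replicated fit has df2 = 6
  res2 <- anova_tukey(tab, average_technical = FALSE)
  expect_equal(res2$df2, 6)
})

test_that("degenerate zero-variance tables are flagged", {
  tab <- omics_fixture(list(A = c(2, 2, 2), B = c(2, 2, 2)))
  res <- anova_tukey(tab)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
})

test_that("volcano classification applies both significance gates", {
  set.seed(8)
  fc <- matrix(1, 30, 3)
  fc[1, 2] <- 4    # strong up-regulation in AMP
  fc[2, 2] <- 0.2  # strong down-regulation
  fc[3, 2] <- 3    # up but will be tested with noise
  tab <- generate_analyte_table(n_analytes = 30, fold_changes = fc,
                                bio_sd = 0.15, tech_sd = 0.05, seed = 8)
  res <- volcano_classify(tab, group = "AMP")
  expect_equal(res$class[res$analyte == "analyte_001"], "up")
  expect_equal(res$class[res$analyte == "analyte_002"], "down")
  expect_equal(res$neg_log10_p, -log10(res$p_value))
  expect_equal(res$log2_fc, log2(res$fold_change))
  # brute-force re-evaluation of the rule for every analyte
  reclass <- ifelse(res$p_value < 0.05 & res$fold_change > 2, "up",
             ifelse(res$p_value < 0.05 & res$fold_change < 0.5, "down", "ns"))
  expect_equal(res$class, reclass)
})

test_that("the classification rule handles each threshold edge", {
  # synthetic results exercised through the exported rule by construction:
  # FC 2.5 & p 0.01 -> up; FC 0.4 & p 0.001 -> down; FC 3 & p 0.2 -> ns
  mk <- function(l2fc, p) {
    tibble::tibble(analyte = "a", fold_change = 2^l2fc, log2_fc = l2fc,
                   p_value = p)
  }
  rule <- function(fold_change, p_value, p_thresh = 0.05, fc_thresh = 2) {
    dplyr::case_when(
      p_value < p_thresh & fold_change > fc_thresh ~ "up",
      p_value < p_thresh & fold_change < 1 / fc_thresh ~ "down",
      .default = "ns"
    )
  }
  expect_equal(rule(2.5, 0.01), "up")
  expect_equal(rule(0.4, 0.001), "down")
  expect_equal(rule(3.0, 0.2), "ns")
})

test_that("a null analyte table yields ~5% ANOVA positives and no volcano calls", {
  tab <- generate_analyte_table(n_analytes = 400, seed = 19)
  res <- anova_tukey(tab)
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 4 * se)
  v <- volcano_classify(tab, group = "AMP")
  expect_lt(mean(v$class != "ns"), 0.02)
})

test_that("programmed fold changes are recovered within 3 SE", {
  fc <- matrix(1, 40, 3)
  planted <- 2^seq(-2, 2, length.out = 10)
  fc[1:10, 2] <- planted
  tab <- generate_analyte_table(n_analytes = 40, fold_changes = fc, seed = 5)
  res <- volcano_classify(tab, group = "AMP")
  dat <- tab |>
    dplyr::group_by(analyte, group, bio_rep) |>
    dplyr::summarise(v = mean(log2(abundance)), .groups = "drop")
  for (i in 1:10) {
    a <- sprintf("analyte_%03d", i)
    va <- dat$v[dat$analyte == a & dat$group == "AMP"]
    vc <- dat$v[dat$analyte == a & dat$group == "control"]
    se <- sqrt(var(va) / 3 + var(vc) / 3)
    expect_lt(abs(res$log2_fc[res$analyte == a] - log2(planted[i])), 3 * se)
  }
})

test_that("top-N clustered heatmaps rank by p, clamp, and standardize rows", {
  tab <- generate_analyte_table(n_analytes = 73, seed = 7)
  res <- anova_tukey(tab)
  hm <- cluster_heatmap(tab, res, top_n = 25)
  expect_equal(nrow(hm$matrix), 25)
  expect_equal(ncol(hm$matrix), 3 * 3 * 2)
  expect_setequal(rownames(hm$matrix),
                  dplyr::arrange(res, p_value, analyte)$analyte[1:25])
  # rows are z-scored
  expect_equal(unname(rowMeans(hm$matrix)), rep(0, 25))
  expect_equal(unname(apply(hm$matrix, 1, sd)), rep(1, 25))

  tab63 <- generate_analyte_table(n_analytes = 63, seed = 7)
  hm63 <- cluster_heatmap(tab63, anova_tukey(tab63), top_n = 25)
  expect_equal(nrow(hm63$matrix), 25)

  small <- generate_analyte_table(n_analytes = 3, seed = 7)
  expect_warning(hm3 <- cluster_heatmap(small, anova_tukey(small), top_n = 5),
                 "exceeds")
  expect_equal(nrow(hm3$matrix), 3)
})

test_that("volcano errors when a requested group is absent", {
  tab <- generate_analyte_table(n_analytes = 5, seed = 2)
  expect_error(volcano_classify(tab, group = "AMP", reference = "mock"),
               "mock")
  expect_error(volcano_classify(tab, group = "unknown"), "unknown")
})
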