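screen_fixture <- function(slope = 0.1, noise = 1e-6, n_features = 3,
                           plate_offsets = c(0, 1, -2), seed = 5) {
  set.seed(seed)
  conc <- c(0, 0.156, 0.313, 0.625, 1.25, 2.5, 5, 25, 50, 100)
  meta <- tidyr::expand_grid(plate_id = c("P1", "P2", "P3"),
                             concentration = conc,
                             well = 1:6)
  meta$well_id <- sprintf("w%03d", seq_len(nrow(meta)))
  meta$field_id <- 1L
  g <- dose_transform(meta$concentration, "log", conc)
  m <- sapply(seq_len(n_features), function(j) {
    slope * g + plate_offsets[match(meta$plate_id, c("P1", "P2", "P3"))] +
      rnorm(nrow(meta), 0, noise)
  })
  colnames(m) <- sprintf("f%d", seq_len(n_features))
  profile_frame(meta[c("plate_id", "well_id", "field_id", "concentration")],
                m, level = "image", validate = FALSE, concentrations = conc)
}

test_that("the ANCOVA recovers a known slope with plate offsets absorbed", {
  x <- screen_fixture(slope = 0.1)
  res <- ancova_screen(x)
  expect_equal(res$estimate, rep(0.1, 3), tolerance = 1e-3)
  expect_true(all(res$significant))
  expect_true(all(res$direction == "+"))
  # closed-form OLS oracle, feature by feature, via lm()
  g <- dose_transform(x$concentration, "log", attr(x, "concentrations"))
  for (j in 1:3) {
    fit <- lm(feature_matrix(x)[, j] ~ g + factor(x$plate_id))
    sm <- summary(fit)$coefficients
    expect_equal(res$estimate[j], unname(sm["g", "Estimate"]), tolerance = 1e-10)
    expect_equal(res$std_error[j], unname(sm["g", "Std. Error"]), tolerance = 1e-8)
    expect_equal(res$p_value[j], unname(sm["g", "Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("the slope is invariant to adding per-plate constants", {
  x <- screen_fixture(slope = 0.05, noise = 0.3, seed = 8)
  res1 <- ancova_screen(x)
  m <- feature_matrix(x)
  shift <- c(P1 = 17, P2 = -4, P3 = 100)[x$plate_id]
  res2 <- ancova_screen(set_feature_matrix(x, m + shift))
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-10)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-8)
})

test_that("Bonferroni adjustment is min(1, m * p)", {
  x <- screen_fixture(noise = 0.5, n_features = 3, seed = 2)
  res <- ancova_screen(x)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_value))
  expect_true(all(res$p_adjusted >= res$p_value))
  # the worked adjustment at the published family size
  expect_equal(min(1, 977 * 3.0e-5), 0.02931)
  expect_lt(min(1, 977 * 3.0e-5), 0.05)
})

test_that("constant features are flagged, not significant", {
  x <- screen_fixture(n_features = 2)
  m <- feature_matrix(x)
  m[, 2] <- 42
  res <- ancova_screen(set_feature_matrix(x, m))
  expect_false(res$significant[2])
  expect_true(is.na(res$direction[2]))
})

test_that("single-plate input drops the plate factor with a warning", {
  x <- screen_fixture()
  one <- x[x$plate_id == "P1", ]
  one <- profile_frame(as.data.frame(one)[c("plate_id", "well_id", "field_id",
                                            "concentration")],
                       one$features, level = "image", validate = FALSE)
  expect_warning(res <- ancova_screen(one), "plate factor")
  expect_equal(res$estimate, rep(0.1, 3), tolerance = 1e-3)
})

test_that("uncorrected per-feature rejections run at the nominal rate", {
  # pure-noise features; two-sided t at alpha = 0.05 without correction
  set.seed(41)
  rejections <- replicate(40, {
    x <- screen_fixture(slope = 0, noise = 1, n_features = 10,
                        seed = sample.int(1e6, 1))
    res <- ancova_screen(x)
    mean(res$p_value < 0.05)
  })
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / (40 * 10))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("screen summaries count directions among significant features", {
  x <- screen_fixture(noise = 1e-6, n_features = 10, seed = 3)
  m <- feature_matrix(x)
  g <- dose_transform(x$concentration, "log", attr(x, "concentrations"))
  m[, 5:8] <- m[, 5:8] - 0.2 * g   # net slope -0.1 for features 5-8
  m[, 9:10] <- matrix(rnorm(2 * nrow(m), 0, 1e-6), ncol = 2) # two nulls
  res <- ancova_screen(set_feature_matrix(x, m))
  s <- summarize_screen(res)
  expect_equal(s$m, 10)
  expect_equal(s$n_significant, 8)
  expect_equal(s$fraction_significant, 0.8)
  expect_equal(s$fraction_positive, 0.5)
  expect_equal(s$fraction_negative, 0.5)

  none <- res
  none$significant <- FALSE
  s0 <- summarize_screen(none)
  expect_equal(s0$n_significant, 0)
  expect_true(is.na(s0$fraction_positive))
})

test_that("the screen recovers the planted affected fraction at large effect", {
  sim <- generate_experiment(small_config(
    n_features = 40, seed = 63, effect_fraction = 0.3, effect_size = 2,
    wells_per_treatment = 3, cells_per_field = c(40L, 50L)
  ))
  screen <- sim$cells |> normalize_to_control() |> aggregate_images() |>
    combat_correct() |> ancova_screen()
  s <- summarize_screen(screen)
  expect_equal(s$fraction_significant, 0.3, tolerance = 0.15)
  expect_setequal(screen$feature[screen$significant], sim$truth$affected)
})

test_that("the FWER harness rejects always at alpha = 1", {
  cfg <- small_config(n_features = 3, seed = 2,
                      cells_per_field = c(25L, 30L))
  res <- fwer_simulation(cfg, n_sims = 2, alpha = 1, seed = 5,
                         min_cells_per_well = 0, min_cells_per_image = 0)
  expect_equal(res$fwer, 1)
})

test_that("per-feature boxplot groups cover the declared treatment set", {
  x <- screen_fixture(noise = 0.2)
  bd <- feature_boxplot_data(x, "f1")
  expect_equal(nrow(bd), 10)
  expect_equal(bd$concentration, sort(attr(x, "concentrations")))
  expect_true(all(bd$n == 18))
  expect_error(feature_boxplot_data(x, "nope"), "unknown feature")

  # quartile convention on {1,2,3,4,5}
  tiny <- profile_frame(
    tibble::tibble(plate_id = "P1", well_id = sprintf("w%d", 1:5),
                   field_id = 1L, concentration = 0),
    matrix(1:5, ncol = 1, dimnames = list(NULL, "f")),
    level = "image", validate = FALSE
  )
  bd2 <- feature_boxplot_data(tiny, "f")
  expect_equal(c(bd2$q1, bd2$median, bd2$q3), c(2, 3, 4))

  # a concentration with no surviving images stays as an empty group
  part <- x[x$concentration != 25, ]
  part <- profile_frame(as.data.frame(part)[c("plate_id", "well_id",
                                              "field_id", "concentration")],
                        part$features, level = "image", validate = FALSE,
                        concentrations = attr(x, "concentrations"))
  bd3 <- feature_boxplot_data(part, "f1")
  expect_true(bd3$empty[bd3$concentration == 25])
  expect_equal(nrow(bd3), 10)
})

test_that("rejection probability grows with the planted slope", {
  set.seed(77)
  conc <- c(0, 0.156, 0.313, 0.625, 1.25, 2.5, 5, 25, 50, 100)
  power_at <- function(slope) {
    hits <- replicate(12, {
      x <- screen_fixture(slope = slope, noise = 1, n_features = 1,
                          seed = sample.int(1e6, 1))
      ancova_screen(x)$significant[1]
    })
    mean(hits)
  }
  p <- vapply(c(0, 0.3, 1), power_at, numeric(1))
  expect_true(p[3] >= p[1])
  expect_equal(p[3], 1) # slope 1 at noise 1 over 180 images is certain
})
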