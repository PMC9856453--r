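test_that("the default layout produces the full plate design", {
  cfg <- sim_config(n_features = 2, cells_per_field = c(3L, 5L))
  sim <- generate_experiment(cfg)
  imgs <- dplyr::distinct(as.data.frame(sim$cells)[c("plate_id", "well_id", "field_id")])
  expect_equal(nrow(imgs), 3 * 10 * 6 * 9)
  expect_equal(sort(unique(sim$cells$concentration)),
               c(0, 0.156, 0.313, 0.625, 1.25, 2.5, 5, 25, 50, 100))
  # every well hosts exactly one concentration, 6 wells per treatment per plate
  wc <- dplyr::distinct(as.data.frame(sim$cells)[c("plate_id", "well_id", "concentration")])
  expect_equal(nrow(wc), 3 * 60)
  expect_true(all(table(wc$plate_id, wc$concentration) == 6))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_config(seed = 99)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(feature_matrix(a$cells), feature_matrix(b$cells))
  expect_identical(a$truth$slopes, b$truth$slopes)
})

test_that("a zero-effect, zero-batch config matches its nominal moments", {
  cfg <- sim_config(n_plates = 1, wells_per_treatment = 3, fields_per_well = 3,
                    cells_per_field = c(150L, 150L), n_features = 6,
                    effect_fraction = 0, batch_sd = 0, batch_scale_sd = 0,
                    noise_sd = 1, seed = 21)
  sim <- generate_experiment(cfg)
  m <- feature_matrix(sim$cells)
  conc <- sim$cells$concentration
  base <- sim$truth$baseline
  for (cc in c(0, 1.25, 100)) {
    grp <- m[conc == cc, , drop = FALSE]
    se <- 1 / sqrt(nrow(grp))
    expect_true(all(abs(colMeans(grp) - base) < 4 * se))
  }
})

test_that("null experiments have empty affected sets but keep batch offsets", {
  cfg <- small_config(seed = 4, batch_sd = 1, batch_scale_sd = 0,
                      cells_per_field = c(100L, 100L))
  sim <- generate_null_experiment(cfg)
  expect_length(sim$truth$affected, 0)
  expect_true(all(sim$truth$slopes == 0))
  # per-plate means separate by the drawn gamma offsets before correction
  m <- feature_matrix(sim$cells)
  for (j in c(1, 5)) {
    means <- tapply(m[, j], sim$cells$plate_id, mean)
    gaps <- means - sim$truth$baseline[j] - sim$truth$gamma[, j]
    expect_true(all(abs(gaps) < 4 / sqrt(1200)))
  }
})

test_that("QC-defect injection is exact by construction", {
  cfg <- small_config(seed = 8, low_cell_wells = 2, low_cell_well_cells = 10,
                      low_cell_images = 3, low_cell_image_cells = 4)
  sim <- generate_experiment(cfg)
  counts <- dplyr::count(as.data.frame(sim$cells), plate_id, well_id)
  low_wells <- counts[counts$n == 10, ] # exactly the injected well total
  expect_equal(nrow(low_wells), 2)
  expect_equal(sort(paste(low_wells$plate_id, low_wells$well_id)),
               sort(paste(sim$truth$defects$low_cell_wells$plate_id,
                          sim$truth$defects$low_cell_wells$well_id)))
  expect_true(all(low_wells$n == 10))
  img_counts <- dplyr::count(as.data.frame(sim$cells), plate_id, well_id, field_id)
  inj <- sim$truth$defects$low_cell_images
  got <- dplyr::inner_join(img_counts, inj, by = c("plate_id", "well_id", "field_id"))
  expect_equal(nrow(got), 3)
  expect_true(all(got$n == 4))
})

test_that("empirical slopes converge to the configured slopes", {
  cfg <- sim_config(n_plates = 2, wells_per_treatment = 3, fields_per_well = 3,
                    cells_per_field = c(60L, 60L), n_features = 8,
                    effect_fraction = 0.5, effect_size = 0.4,
                    batch_sd = 0, batch_scale_sd = 0, seed = 12)
  sim <- generate_experiment(cfg)
  m <- feature_matrix(sim$cells)
  g <- dose_transform(sim$cells$concentration, "log", cfg$concentrations)
  gc <- g - mean(g)
  for (j in seq_len(ncol(m))) {
    fit <- stats::lm.fit(cbind(1, gc), m[, j])
    slope <- fit$coefficients[2]
    se <- sqrt(sum(fit$residuals^2) / (nrow(m) - 2) / sum(gc^2))
    expect_lt(abs(slope - sim$truth$slopes[j]), 3.5 * se)
  }
})

test_that("analyte tables have the declared replicate structure", {
  tab <- generate_analyte_table(n_analytes = 73, seed = 2)
  expect_equal(length(unique(tab$analyte)), 73)
  expect_equal(nrow(tab), 73 * 3 * 3 * 2)
  expect_true(all(tab$abundance > 0))
  expect_equal(sort(unique(tab$group)), sort(c("control", "AMP", "SiO2")))
  counts <- dplyr::count(tab, group, bio_rep, tech_rep)
  expect_true(all(counts$n == 73))
})

test_that("programmed fold changes are recovered as noise vanishes", {
  fc <- matrix(1, 5, 3); fc[1, 2] <- 4
  tab <- generate_analyte_table(n_analytes = 5, fold_changes = fc,
                                bio_sd = 1e-6, tech_sd = 1e-6, seed = 3)
  wide <- tapply(log2(tab$abundance), list(tab$analyte, tab$group), mean)
  est_fc <- 2^(wide["analyte_001", "AMP"] - wide["analyte_001", "control"])
  expect_equal(est_fc, 4, tolerance = 1e-4)
  est_null <- 2^(wide["analyte_002", "AMP"] - wide["analyte_002", "control"])
  expect_equal(est_null, 1, tolerance = 1e-4)
})
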