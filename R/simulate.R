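#' Simulation configuration for plate-structured Cell Painting experiments
#'
#' Defines the layout and generative model of a synthetic high-content
#' experiment: three 96-well microplates, ten exposure concentrations
#' (0 to 100 µg/mL), six replicate wells per concentration, nine imaged
#' fields per well and 200-250 segmented cells per field, mirroring a
#' typical Cell Painting dose-response design. Each feature j of cell i on
#' plate p is drawn as
#'
#'   x_ij = baseline_j + s_j * g(conc_i) + gamma_pj + delta_pj * eps_ij
#'
#' with `g` the dose transform (log10 of concentration offset by half the
#' smallest nonzero dose, or identity), `s_j` the per-feature slope (zero
#' for unaffected features), `gamma_pj`/`delta_pj` additive and
#' multiplicative plate batch effects drawn once per (plate, feature), and
#' `eps_ij` unit Gaussian (optionally t with 5 df) noise.
#'
#' @param n_plates Number of microplates (biological replicates).
#' @param concentrations Treatment set in µg/mL; must contain 0 (the
#'   unexposed control).
#' @param wells_per_treatment Replicate wells per concentration per plate.
#' @param fields_per_well Imaged fields of view per well.
#' @param cells_per_field Integer range (length 2) of cells per image;
#'   counts are uniform on this range.
#' @param n_features Number of morphological features.
#' @param effect_fraction Fraction of features with a nonzero dose slope.
#' @param effect_size Absolute slope of affected features on the `g` scale,
#'   in noise-SD units; signs are random.
#' @param dose_scale `"log"` (default) or `"identity"` dose transform.
#' @param batch_sd SD of the per-(plate, feature) additive offsets
#'   `gamma_pj` (0 disables location batch effects).
#' @param batch_scale_sd SD of `log(delta_pj)` (0 disables scale batch
#'   effects).
#' @param noise_sd SD of the cell-level noise.
#' @param noise One of `"gaussian"`, `"t5"` (heavy-tailed, 5 df, rescaled
#'   to unit variance) to exercise median/MAD robustness.
#' @param missing_rate Fraction of feature values set to `NA`.
#' @param low_cell_wells,low_cell_well_cells Number of wells to downsample
#'   to `low_cell_well_cells` total cells (QC-defect injection).
#' @param low_cell_images,low_cell_image_cells Number of additional images
#'   to downsample to `low_cell_image_cells` cells.
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plates = 3,
                       concentrations = c(0, 0.156, 0.313, 0.625, 1.25,
                                          2.5, 5, 25, 50, 100),
                       wells_per_treatment = 6,
                       fields_per_well = 9,
                       cells_per_field = c(200L, 250L),
                       n_features = 100,
                       effect_fraction = 0.3,
                       effect_size = 0.5,
                       dose_scale = c("log", "identity"),
                       batch_sd = 0.5,
                       batch_scale_sd = 0.2,
                       noise_sd = 1,
                       noise = c("gaussian", "t5"),
                       missing_rate = 0,
                       low_cell_wells = 0, low_cell_well_cells = 100,
                       low_cell_images = 0, low_cell_image_cells = 10,
                       seed = 1L) {
  cfg <- list(
    n_plates = as.integer(n_plates),
    concentrations = sort(unique(as.numeric(concentrations))),
    wells_per_treatment = as.integer(wells_per_treatment),
    fields_per_well = as.integer(fields_per_well),
    cells_per_field = as.integer(cells_per_field),
    n_features = as.integer(n_features),
    effect_fraction = effect_fraction,
    effect_size = effect_size,
    dose_scale = match.arg(dose_scale),
    batch_sd = batch_sd,
    batch_scale_sd = batch_scale_sd,
    noise_sd = noise_sd,
    noise = match.arg(noise),
    missing_rate = missing_rate,
    low_cell_wells = as.integer(low_cell_wells),
    low_cell_well_cells = as.integer(low_cell_well_cells),
    low_cell_images = as.integer(low_cell_images),
    low_cell_image_cells = as.integer(low_cell_image_cells),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_plates >= 1, wells_per_treatment >= 1, fields_per_well >= 1,
              n_features >= 1, length(cells_per_field) == 2,
              all(cells_per_field >= 1), cells_per_field[1] <= cells_per_field[2],
              effect_fraction >= 0, effect_fraction <= 1,
              noise_sd > 0, missing_rate >= 0, missing_rate < 1)
    if (!0 %in% concentrations) {
      abort("the concentration set must contain 0 (unexposed control)")
    }
  })
  invisible(cfg)
}

#' Dose transform used by the simulator and the ANCOVA screen
#'
#' Concentrations in these experiments span three orders of magnitude, so
#' the default covariate scale is log10 after offsetting by half the
#' smallest nonzero concentration (which maps the 0 µg/mL control to a
#' finite value). The identity scale is available for comparison.
#'
#' @param conc Numeric concentrations (µg/mL).
#' @param scale `"log"` or `"identity"`.
#' @param concentrations Treatment set used to find the smallest nonzero
#'   dose; defaults to the values in `conc`.
#' @return Transformed doses.
#' @export
dose_transform <- function(conc, scale = c("log", "identity"),
                           concentrations = NULL) {
  scale <- match.arg(scale)
  if (scale == "identity") return(conc)
  cset <- concentrations %||% unique(conc)
  c0 <- min(cset[cset > 0])
  log10(conc + c0 / 2)
}

sim_layout <- function(cfg) {
  plates <- sprintf("P%d", seq_len(cfg$n_plates))
  n_wells <- length(cfg$concentrations) * cfg$wells_per_treatment
  wells <- sprintf("w%02d", seq_len(n_wells))
  # concentrations assigned to wells in a fixed round-robin order
  well_conc <- rep(cfg$concentrations, each = cfg$wells_per_treatment)
  images <- tidyr::expand_grid(
    plate_id = plates,
    well_idx = seq_len(n_wells),
    field_id = seq_len(cfg$fields_per_well)
  )
  images$well_id <- wells[images$well_idx]
  images$concentration <- well_conc[images$well_idx]
  images[c("plate_id", "well_id", "field_id", "concentration")]
}

#' Generate a synthetic Cell Painting experiment with known ground truth
#'
#' Draws a full plate-structured single-cell feature table under the model
#' described in [sim_config()], together with the ground truth (true
#' slopes, affected-feature set, batch parameters, injected QC defects)
#' needed to verify every downstream stage.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cells` (a cell-level [profile_frame()])
#'   and `truth` (a `ground_truth` list).
#' @export
generate_experiment <- function(config = sim_config()) {
  cfg <- config
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_features
  feat_names <- simulate_feature_names(m)

  # per-feature model parameters
  baseline <- rnorm(m, 0, 1)
  n_affected <- round(cfg$effect_fraction * m)
  affected <- sort(sample.int(m, n_affected))
  slopes <- numeric(m)
  if (n_affected > 0) {
    slopes[affected] <- cfg$effect_size * cfg$noise_sd *
      sample(c(-1, 1), n_affected, replace = TRUE)
  }
  gamma <- matrix(rnorm(cfg$n_plates * m, 0, cfg$batch_sd), cfg$n_plates, m)
  delta <- matrix(exp(rnorm(cfg$n_plates * m, 0, cfg$batch_scale_sd)),
                  cfg$n_plates, m)
  if (cfg$batch_sd == 0) gamma[] <- 0
  if (cfg$batch_scale_sd == 0) delta[] <- 1

  images <- sim_layout(cfg)
  n_img <- nrow(images)
  count_range <- seq.int(cfg$cells_per_field[1], cfg$cells_per_field[2])
  cells_per_img <- count_range[sample.int(length(count_range), n_img,
                                          replace = TRUE)]

  # QC-defect injection: reduce selected wells / images to fixed cell counts
  defects <- inject_defects(cfg, images, cells_per_img)
  cells_per_img <- defects$cells_per_img

  n_cells <- sum(cells_per_img)
  img_idx <- rep.int(seq_len(n_img), cells_per_img)
  meta <- tibble(
    plate_id = images$plate_id[img_idx],
    well_id = images$well_id[img_idx],
    field_id = images$field_id[img_idx],
    cell_id = sequence(cells_per_img),
    concentration = images$concentration[img_idx]
  )

  g <- dose_transform(meta$concentration, cfg$dose_scale, cfg$concentrations)
  plate_idx <- match(meta$plate_id, sprintf("P%d", seq_len(cfg$n_plates)))

  # draw each (plate, feature) block with its own location/scale; plates
  # are contiguous row blocks, so this needs no second pass over the data
  offset <- gamma + rep(baseline, each = cfg$n_plates)
  blocks <- contiguous_blocks(plate_idx, cfg$n_plates)
  stopifnot(!is.null(blocks)) # layout keeps each plate in one row block
  x <- matrix(NA_real_, n_cells, m)
  gaussian <- cfg$noise == "gaussian"
  for (j in seq_len(m)) {
    for (p in seq_len(cfg$n_plates)) {
      r <- blocks[[p]]
      if (is.null(r)) next
      nr <- r[2] - r[1] + 1
      x[r[1]:r[2], j] <- if (gaussian) {
        rnorm(nr, mean = offset[p, j], sd = cfg$noise_sd * delta[p, j])
      } else {
        draw_noise(nr, cfg$noise) * (cfg$noise_sd * delta[p, j]) + offset[p, j]
      }
    }
    if (slopes[j] != 0) x[, j] <- x[, j] + g * slopes[j]
  }
  if (cfg$missing_rate > 0) {
    n_na <- rbinom(1, length(x), cfg$missing_rate)
    if (n_na > 0) x[sample.int(length(x), n_na)] <- NA_real_
  }
  colnames(x) <- feat_names

  cells <- profile_frame(meta, x, level = "cell",
                         concentrations = cfg$concentrations, validate = FALSE)
  truth <- structure(list(
    slopes = setNames(slopes, feat_names),
    affected = feat_names[affected],
    baseline = setNames(baseline, feat_names),
    gamma = gamma, delta = delta,
    defects = defects$record,
    config = cfg
  ), class = "ground_truth")
  list(cells = cells, truth = truth)
}

#' Generate a global-null experiment (no concentration effect)
#'
#' Identical to [generate_experiment()] but with every dose slope forced to
#' zero; plate batch effects are retained. Used by the family-wise
#' error-rate harness for the ANCOVA screen.
#'
#' @inheritParams generate_experiment
#' @return As [generate_experiment()]; `truth$affected` is empty.
#' @export
generate_null_experiment <- function(config = sim_config()) {
  config$effect_fraction <- 0
  generate_experiment(config)
}

draw_noise <- function(n, kind) {
  if (kind == "gaussian") rnorm(n) else rt(n, df = 5) / sqrt(5 / 3)
}

simulate_feature_names <- function(m) {
  comps <- c("Cells", "Cytoplasm", "Nuclei")
  grps <- c("Correlation", "Intensity", "RadialDistribution", "Texture",
            "Granularity", "Location", "Neighbors", "AreaShape")
  chans <- c("DNA", "AGP", "ER", "RNA", "Mito")
  meas <- c("Mean", "Median", "Max", "Entropy", "Contrast", "Overlap",
            "FracAtD", "Gini")
  comp <- sample(comps, m, replace = TRUE)
  grp <- sample(grps, m, replace = TRUE)
  chan <- sample(chans, m, replace = TRUE)
  ms <- sample(meas, m, replace = TRUE)
  nm <- paste(comp, grp, ms, chan, sep = "_")
  # disambiguate collisions with a numeric scale suffix
  nm <- make.unique(nm, sep = "_")
  nm
}

inject_defects <- function(cfg, images, cells_per_img) {
  record <- list(low_cell_wells = tibble(plate_id = character(),
                                         well_id = character()),
                 low_cell_images = tibble(plate_id = character(),
                                          well_id = character(),
                                          field_id = integer()))
  wells <- dplyr::distinct(images, plate_id, well_id)
  if (cfg$low_cell_wells > 0) {
    pick <- wells[sample.int(nrow(wells), cfg$low_cell_wells), ]
    for (i in seq_len(nrow(pick))) {
      sel <- which(images$plate_id == pick$plate_id[i] &
                     images$well_id == pick$well_id[i])
      # spread the reduced total over the well's fields
      per <- diff(round(seq(0, cfg$low_cell_well_cells, length.out = length(sel) + 1)))
      cells_per_img[sel] <- per
    }
    record$low_cell_wells <- pick
  }
  if (cfg$low_cell_images > 0) {
    taken <- paste(record$low_cell_wells$plate_id, record$low_cell_wells$well_id)
    free <- which(!paste(images$plate_id, images$well_id) %in% taken)
    pick <- sample(free, cfg$low_cell_images)
    cells_per_img[pick] <- cfg$low_cell_image_cells
    record$low_cell_images <- images[pick, c("plate_id", "well_id", "field_id")]
  }
  list(cells_per_img = cells_per_img, record = record)
}

#' Generate a synthetic analyte (lipid/metabolite) abundance table
#'
#' Emulates a targeted omics design: `n_analytes` analytes measured in a
#' small number of exposure groups, each with biological replicates and
#' nested technical replicates. Abundances are log-normal: on the log2
#' scale each value is a per-analyte baseline plus `log2(fold_change)` for
#' its group, a biological-replicate effect (SD `bio_sd`) and a smaller
#' technical error (SD `tech_sd`).
#'
#' @param n_analytes Number of analytes (73 for a lipid arm, 63 for a
#'   polar-metabolite arm).
#' @param groups Character vector of group labels; first is the reference.
#' @param n_bio,n_tech Biological replicates per group and technical
#'   replicates per biological replicate.
#' @param fold_changes Matrix (`n_analytes` x `length(groups)`) or named
#'   list of per-analyte fold changes vs baseline; defaults to all 1.
#' @param bio_sd,tech_sd Log2-scale SDs of the biological and technical
#'   variance components.
#' @param seed Integer seed.
#' @return An `analyte_table` tibble: `analyte`, `group`, `bio_rep`,
#'   `tech_rep`, `abundance` (positive), with the programmed fold changes
#'   in `attr(, "fold_changes")`.
#' @export
generate_analyte_table <- function(n_analytes = 73,
                                   groups = c("control", "AMP", "SiO2"),
                                   n_bio = 3, n_tech = 2,
                                   fold_changes = NULL,
                                   bio_sd = 0.35, tech_sd = 0.15,
                                   seed = 1L) {
  stopifnot(n_analytes >= 1, n_bio >= 2, n_tech >= 1, length(groups) >= 2)
  set.seed(as.integer(seed))
  analytes <- sprintf("analyte_%03d", seq_len(n_analytes))
  if (is.null(fold_changes)) {
    fold_changes <- matrix(1, n_analytes, length(groups))
  }
  fold_changes <- as.matrix(fold_changes)
  stopifnot(nrow(fold_changes) == n_analytes,
            ncol(fold_changes) == length(groups),
            all(fold_changes > 0))
  dimnames(fold_changes) <- list(analytes, groups)

  base <- rnorm(n_analytes, mean = 10, sd = 2) # log2 baseline abundances
  grid <- tidyr::expand_grid(group = groups,
                             bio_rep = seq_len(n_bio),
                             tech_rep = seq_len(n_tech))
  bio_eff <- array(rnorm(n_analytes * length(groups) * n_bio, 0, bio_sd),
                   dim = c(n_analytes, length(groups), n_bio))
  out <- purrr::pmap_dfr(grid, function(group, bio_rep, tech_rep) {
    gi <- match(group, groups)
    log2_ab <- base + log2(fold_changes[, gi]) + bio_eff[, gi, bio_rep] +
      rnorm(n_analytes, 0, tech_sd)
    tibble(analyte = analytes, group = group,
           bio_rep = bio_rep, tech_rep = tech_rep,
           abundance = 2^log2_ab)
  })
  structure(out, class = c("analyte_table", class(out)),
            fold_changes = fold_changes, groups = groups)
}
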