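# small fixtures shared across tests; everything is generated in code

# a tiny hand-built cell-level frame: `n` cells per (plate, well, field)
tiny_cells <- function(values, plate = "P1", well = "w01", field = 1L,
                       concentration = 0, feature = "Cells_Intensity_Mean_DNA") {
  n <- length(values)
  m <- matrix(values, ncol = 1, dimnames = list(NULL, feature))
  profile_frame(
    tibble::tibble(plate_id = plate, well_id = well, field_id = field,
                   cell_id = seq_len(n), concentration = concentration),
    m, level = "cell", validate = FALSE
  )
}

# cell frame from explicit metadata + matrix
cells_from <- function(meta, m, ...) {
  profile_frame(meta, m, level = "cell", ...)
}

# a small but complete simulated experiment (fast: 2 wells, 2 fields,
# 20-30 cells/field)
small_config <- function(...) {
  args <- list(n_plates = 3, wells_per_treatment = 2, fields_per_well = 2,
               cells_per_field = c(20L, 30L), n_features = 12)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# deterministic multi-plate image-level frame with separable dose structure
separable_images <- function(n_per_class = 30, n_features = 10, gap = 3,
                             seed = 1) {
  set.seed(seed)
  conc <- rep(c(0, 100), each = n_per_class)
  m <- matrix(rnorm(2 * n_per_class * n_features), ncol = n_features)
  m[conc == 100, 1:3] <- m[conc == 100, 1:3] + gap
  colnames(m) <- sprintf("f%02d", seq_len(n_features))
  profile_frame(
    tibble::tibble(
      plate_id = rep(rep(c("P1", "P2", "P3"), length.out = n_per_class), 2),
      well_id = sprintf("w%02d", seq_len(2 * n_per_class)),
      field_id = 1L,
      concentration = conc
    ),
    m, level = "image", validate = FALSE
  )
}
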