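#' Released-metal mass fraction from dissolution measurements
#'
#' Converts blank-corrected released-metal concentrations measured by
#' atomic absorption spectroscopy into the mass fraction of the particle
#' loading that dissolved:
#'
#'   fraction = (released - blank) [µg/L] * volume [L] / mass [µg]
#'
#' @param released Released-metal concentration in the exposure medium
#'   (µg/L).
#' @param blank Blank (medium-only) concentration (µg/L); default 0.
#' @param volume_l Solution volume in liters.
#' @param mass_ug Particle sample mass in µg.
#' @return A tibble with `fraction` (dimensionless), `percent`
#'   (100 x fraction) and `percent_display` (one significant digit, the
#'   conventional reporting style for trace release). All inputs are
#'   vectorized.
#' @examples
#' # 21 µg/L released from 1 mg powder in 10 mL medium -> ~0.02%
#' released_fraction(21, 0, volume_l = 0.01, mass_ug = 1000)
#' @export
released_fraction <- function(released, blank = 0, volume_l, mass_ug) {
  stopifnot(all(volume_l > 0), all(mass_ug > 0),
            all(released >= 0), all(blank >= 0))
  if (any(blank > released)) {
    abort("blank concentration exceeds released concentration (negative release)")
  }
  fraction <- (released - blank) * volume_l / mass_ug
  tibble(
    released = released, blank = blank,
    volume_l = volume_l, mass_ug = mass_ug,
    fraction = fraction,
    percent = 100 * fraction,
    percent_display = signif(100 * fraction, 1)
  )
}

#' Summarize a particle-size sample
#'
#' Arithmetic mean, sample SD (n-1 convention), range and an equal-width
#' histogram of measured particle diameters.
#'
#' @param diameters Positive diameters in nm.
#' @param n_bins Number of equal-width histogram bins (default 10).
#' @return A `size_summary` list: `n`, `mean`, `sd` (`NA` with
#'   `sd_defined = FALSE` for a single measurement), `min`, `max`, and
#'   `histogram` (tibble of `bin_low`, `bin_high`, `mid`, `count`).
#' @export
size_summary <- function(diameters, n_bins = 10) {
  if (!length(diameters)) abort("empty size sample")
  stopifnot(all(diameters > 0))
  n <- length(diameters)
  mn <- mean(diameters)
  s <- if (n > 1) sd(diameters) else NA_real_
  lo <- min(diameters); hi <- max(diameters)
  if (hi == lo) {
    breaks <- c(lo - 0.5, lo + 0.5)
    counts <- n
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1)
    bin <- findInterval(diameters, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
  }
  nb <- length(breaks) - 1
  histogram <- tibble(
    bin_low = breaks[seq_len(nb)],
    bin_high = breaks[seq_len(nb) + 1],
    mid = (breaks[seq_len(nb)] + breaks[seq_len(nb) + 1]) / 2,
    count = counts
  )
  structure(list(n = n, mean = mn, sd = s, sd_defined = n > 1,
                 min = lo, max = hi, histogram = histogram,
                 n_bins = nb), class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("size_summary: n = %d, mean = %.3g nm, SD = %s, range %.3g-%.3g nm\n",
              x$n, x$mean,
              if (x$sd_defined) sprintf("%.3g", x$sd) else "undefined (n = 1)",
              x$min, x$max))
  invisible(x)
}

#' @export
tidy.size_summary <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sd = x$sd, sd_defined = x$sd_defined,
         min = x$min, max = x$max)
}
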