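#' Empirical-Bayes location-scale batch correction (ComBat)
#'
#' Removes per-plate ("batch") location and scale shifts from a profile
#' matrix using the parametric empirical-Bayes location-scale model: per
#' feature, values are standardized against the pooled mean and variance,
#' per-batch location (`gamma_hat`) and scale (`delta2_hat`) estimates are
#' shrunk toward feature-wise priors (normal prior for locations,
#' inverse-gamma for scales, hyperparameters by method of moments), and
#' the data are adjusted as `(z - gamma_star) / sqrt(delta2_star)` before
#' rescaling to the pooled moments. With `shrink = FALSE` the raw
#' per-batch estimates are used, which equalizes per-batch means and
#' variances per feature exactly.
#'
#' The operation is level-agnostic: it corrects whatever profile level it
#' is given (cell-level profiles after control normalization, or
#' image-level profiles ahead of regression and embedding analyses).
#'
#' @param x A [profile_frame()] at any level.
#' @param batch Name of the column holding batch labels (default
#'   `"plate_id"`), or a vector of labels with one element per row.
#' @param shrink Apply empirical-Bayes shrinkage of the batch estimates
#'   (default `TRUE`)? `FALSE` gives the direct location-scale adjustment.
#' @param eb_tol,eb_maxit Convergence tolerance and iteration cap of the
#'   EB fixed-point iteration.
#' @return The corrected `profile_frame`; the fitted `combat_model` (batch
#'   estimates, hyperparameters, shrunken parameters, pooled moments) is
#'   attached as the `"combat_model"` attribute, retrievable with
#'   [combat_model()]. With a single batch the input is returned
#'   unchanged. Features with zero pooled variance are passed through and
#'   listed in the model's `skipped` element.
#' @export
combat_correct <- function(x, batch = "plate_id", shrink = TRUE,
                           eb_tol = 1e-6, eb_maxit = 200) {
  stopifnot(inherits(x, "profile_frame"))
  labels <- if (is.character(batch) && length(batch) == 1) {
    if (!batch %in% names(x)) abort(paste0("batch column '", batch, "' not found"))
    as.character(x[[batch]])
  } else {
    as.character(batch)
  }
  stopifnot(length(labels) == nrow(x))
  batches <- unique(labels)
  n_batches <- length(batches)
  tab <- table(labels)
  if (any(tab < 2)) {
    abort(paste0("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", ")))
  }
  m <- feature_matrix(x)
  if (n_batches == 1) {
    model <- structure(list(batches = batches, skipped = character(),
                            identity = TRUE), class = "combat_model")
    attr(x, "combat_model") <- model
    return(x)
  }

  n_i <- as.numeric(tab[batches])
  N <- nrow(m)
  idx <- split(seq_len(N), factor(labels, levels = batches))

  # pooled (batch-weighted) feature means and residual variances
  batch_means <- t(vapply(idx, function(r) colMeans(m[r, , drop = FALSE]),
                          numeric(ncol(m))))
  alpha_hat <- colSums(batch_means * n_i) / N
  resid <- m
  for (b in seq_along(batches)) {
    r <- idx[[b]]
    resid[r, ] <- m[r, , drop = FALSE] - rep(batch_means[b, ], each = length(r))
  }
  sigma2_hat <- colSums(resid^2) / N

  skipped <- colnames(m)[sigma2_hat <= 0 | !is.finite(sigma2_hat)]
  act <- setdiff(colnames(m), skipped)
  if (!length(act)) {
    abort("no feature has positive pooled variance; nothing to correct")
  }
  ai <- match(act, colnames(m))
  sd_j <- sqrt(sigma2_hat[ai])

  # standardize
  z <- m[, ai, drop = FALSE]
  z <- (z - rep(alpha_hat[ai], each = N)) / rep(sd_j, each = N)

  gamma_hat <- matrix(NA_real_, n_batches, length(ai),
                      dimnames = list(batches, act))
  delta2_hat <- gamma_hat
  for (b in seq_along(batches)) {
    r <- idx[[b]]
    zb <- z[r, , drop = FALSE]
    g <- colMeans(zb)
    gamma_hat[b, ] <- g
    delta2_hat[b, ] <- colSums((zb - rep(g, each = length(r)))^2) / (length(r) - 1)
  }

  if (shrink) {
    # per-batch hyperparameters across features (method of moments)
    gamma_bar <- rowMeans(gamma_hat)
    tau2 <- apply(gamma_hat, 1, var)
    d_mean <- rowMeans(delta2_hat)
    d_var <- apply(delta2_hat, 1, var)
    lambda <- (2 * d_var + d_mean^2) / d_var       # inverse-gamma shape
    theta <- (d_mean * d_var + d_mean^3) / d_var   # inverse-gamma scale

    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (b in seq_along(batches)) {
      r <- idx[[b]]
      zb <- z[r, , drop = FALSE]
      n_b <- length(r)
      g_new <- gamma_hat[b, ]
      d_new <- delta2_hat[b, ]
      if (!is.finite(tau2[b]) || tau2[b] <= 0 ||
          !is.finite(d_var[b]) || d_var[b] <= 0) {
        # degenerate hyperpriors (e.g. a single feature): keep raw estimates
        gamma_star[b, ] <- g_new
        delta2_star[b, ] <- d_new
        next
      }
      sum2_base <- colSums(zb^2)
      sum_z <- colSums(zb)
      for (it in seq_len(eb_maxit)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (n_b * tau2[b] * gamma_hat[b, ] + d_new * gamma_bar[b]) /
          (n_b * tau2[b] + d_new)
        ss <- sum2_base - 2 * g_new * sum_z + n_b * g_new^2
        d_new <- (theta[b] + 0.5 * ss) / (n_b / 2 + lambda[b] - 1)
        change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                      abs(d_new - d_old) / (abs(d_old) + 1e-12))
        if (change < eb_tol) break
      }
      gamma_star[b, ] <- g_new
      delta2_star[b, ] <- d_new
    }
    hyper <- list(gamma_bar = gamma_bar, tau2 = tau2,
                  lambda = lambda, theta = theta)
  } else {
    gamma_star <- gamma_hat
    # ML variance so the direct adjustment equalizes batch moments exactly
    delta2_star <- delta2_hat * rep((n_i - 1) / n_i, ncol(delta2_hat))
    hyper <- NULL
  }

  for (b in seq_along(batches)) {
    r <- idx[[b]]
    nr <- length(r)
    z[r, ] <- (z[r, , drop = FALSE] - rep(gamma_star[b, ], each = nr)) /
      rep(sqrt(delta2_star[b, ]), each = nr)
  }
  corrected <- z * rep(sd_j, each = N) + rep(alpha_hat[ai], each = N)

  out_m <- m
  out_m[, ai] <- corrected
  out <- set_feature_matrix(x, out_m)
  model <- structure(list(
    batches = batches, n_per_batch = setNames(n_i, batches),
    alpha_hat = alpha_hat, sigma2_hat = sigma2_hat,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    hyperparameters = hyper, shrink = shrink,
    skipped = skipped, identity = FALSE
  ), class = "combat_model")
  attr(out, "combat_model") <- model
  out
}

#' Retrieve the fitted batch-correction model
#'
#' @param x A `profile_frame` returned by [combat_correct()].
#' @return A `combat_model`, or `NULL`.
#' @export
combat_model <- function(x) attr(x, "combat_model")

#' @export
print.combat_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("combat_model: single batch, identity correction\n")
    return(invisible(x))
  }
  cat(sprintf("combat_model: %d batches (%s), shrink = %s\n",
              length(x$batches), paste(x$batches, collapse = ", "),
              x$shrink))
  if (length(x$skipped)) {
    cat(sprintf("  %d zero-variance feature(s) passed through\n",
                length(x$skipped)))
  }
  invisible(x)
}

#' @export
tidy.combat_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    return(tibble(batch = character(), feature = character(),
                  gamma_hat = numeric(), delta2_hat = numeric(),
                  gamma_star = numeric(), delta2_star = numeric()))
  }
  purrr::map_dfr(seq_along(x$batches), function(b) {
    tibble(
      batch = x$batches[b],
      feature = colnames(x$gamma_hat),
      gamma_hat = x$gamma_hat[b, ],
      delta2_hat = x$delta2_hat[b, ],
      gamma_star = x$gamma_star[b, ],
      delta2_star = x$delta2_star[b, ]
    )
  })
}
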