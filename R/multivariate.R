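#' Sparse PLS-DA with soft-thresholded direction vectors
#'
#' Fits a sparse partial least squares discriminant analysis in the
#' soft-thresholding (L1-style) formulation: classes are one-hot encoded
#' and centered, and for each of `K` components the leading left singular
#' vector of the feature-class cross-product `t(X) %*% Y` is
#' soft-thresholded at `eta * max(|w|)`, renormalized, and used to score
#' and deflate `X`. A nearest-centroid discriminant rule on the latent
#' scores assigns classes; the selected-feature set is the union of
#' features with a nonzero weight on any component. `eta = 0` gives the
#' dense PLS-DA limit (all features selected).
#'
#' @param x A [profile_frame()], data frame or numeric matrix of
#'   predictors (rows = samples, named columns = features).
#' @param classes Class label per row; numeric concentrations are ordered
#'   numerically (ties in prediction break toward the lower class).
#' @param K Number of latent components.
#' @param eta Sparsity penalty in `[0, 1)`; the fraction of the largest
#'   absolute cross-product coefficient below which weights are zeroed.
#' @return An `splsda_model`.
#' @export
fit_splsda <- function(x, classes, K = 2, eta = 0.5) {
  X <- splsda_predictors(x)
  stopifnot(K >= 1)
  if (eta < 0 || eta >= 1) abort("`eta` must be in [0, 1)")
  cls <- classes
  lev <- class_levels(cls)
  cls <- factor(as.character(cls), levels = lev)
  if (nlevels(cls) < 2) abort("need >= 2 classes")
  if (length(cls) != nrow(X)) abort("`classes` must have one label per row")

  x_center <- colMeans(X)
  Xc <- X - rep(x_center, each = nrow(X))
  Y <- stats::model.matrix(~ cls - 1)
  Yc <- Y - rep(colMeans(Y), each = nrow(Y))

  p <- ncol(Xc)
  K <- min(K, p, nrow(Xc) - 1)
  W <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  Xd <- Xc
  for (k in seq_len(K)) {
    M <- crossprod(Xd, Yc)
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    if (max(abs(w)) == 0) { K <- k - 1L; break }
    thr <- eta * max(abs(w))
    w <- sign(w) * pmax(abs(w) - thr, 0)
    w <- w / sqrt(sum(w^2))
    t_k <- as.vector(Xd %*% w)
    tt <- sum(t_k^2)
    if (tt < .Machine$double.eps) { K <- k - 1L; break }
    p_k <- as.vector(crossprod(Xd, t_k)) / tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    W[, k] <- w
    P[, k] <- p_k
  }
  if (K < 1) abort("no informative component could be extracted")
  W <- W[, seq_len(K), drop = FALSE]
  P <- P[, seq_len(K), drop = FALSE]
  # weights giving scores directly from centered X
  Wstar <- W %*% solve(crossprod(P, W))
  scores <- Xc %*% Wstar

  centroids <- do.call(rbind, lapply(levels(cls), function(l) {
    colMeans(scores[cls == l, , drop = FALSE])
  }))
  rownames(centroids) <- levels(cls)
  selected <- rownames(W)[rowSums(W != 0) > 0]

  structure(list(
    W = W, P = P, Wstar = Wstar, x_center = x_center,
    feature_names = colnames(X), K = K, eta = eta,
    class_levels = lev, centroids = centroids,
    scores = scores, classes = cls, selected = selected
  ), class = "splsda_model")
}

splsda_predictors <- function(x) {
  if (inherits(x, "profile_frame")) return(feature_matrix(x))
  if (is.data.frame(x)) return(as.matrix(x[vapply(x, is.numeric, logical(1))]))
  as.matrix(x)
}

# numeric-looking labels are ordered numerically so "lower class" is the
# lower concentration; otherwise alphabetically
class_levels <- function(cls) {
  u <- unique(as.character(cls))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("splsda_model: %d classes, K = %d, eta = %.2f, %d/%d features selected\n",
              length(x$class_levels), x$K, x$eta,
              length(x$selected), length(x$feature_names)))
  invisible(x)
}

#' @export
tidy.splsda_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    tibble(component = k, feature = rownames(x$W), weight = x$W[, k])
  }) %>% filter(weight != 0)
}

#' @export
glance.splsda_model <- function(x, ...) {
  tibble(K = x$K, eta = x$eta,
         n_features = length(x$feature_names),
         n_selected = length(x$selected),
         n_classes = length(x$class_levels))
}

#' Predict classes from a fitted sparse PLS-DA model
#'
#' Projects new profiles onto the model's latent directions and assigns
#' the nearest class centroid in score space; ties break toward the lower
#' concentration class. Columns are aligned by feature name, so column
#' order does not matter.
#'
#' @param model An `splsda_model`.
#' @param x_new New data ([profile_frame()], data frame or matrix) with
#'   the model's features.
#' @return A factor of predicted class labels (levels in ascending
#'   concentration order).
#' @export
predict_splsda <- function(model, x_new) {
  X <- splsda_predictors(x_new)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names)) {
      abort("feature mismatch: unnamed input with wrong column count")
    }
    colnames(X) <- model$feature_names
  }
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    abort(paste0("feature mismatch: missing ", length(missing),
                 " feature(s), e.g. ", missing[1]))
  }
  X <- X[, model$feature_names, drop = FALSE]
  scores <- (X - rep(model$x_center, each = nrow(X))) %*% model$Wstar
  d2 <- outer(rowSums(scores^2), rep(1, nrow(model$centroids))) -
    2 * scores %*% t(model$centroids) +
    outer(rep(1, nrow(scores)), rowSums(model$centroids^2))
  # centroids rows follow levels(cls) order = ascending concentration;
  # which.min takes the first minimum, i.e. the lower class on ties
  pick <- apply(round(d2, 12), 1, which.min)
  factor(rownames(model$centroids)[pick], levels = model$class_levels)
}

#' Binarize concentration classes at a threshold
#'
#' @param concentration Numeric concentrations (µg/mL); must be
#'   non-negative.
#' @param threshold Concentrations `<= threshold` are `"small"`, the rest
#'   `"large"` (default 1.25 µg/mL).
#' @return A factor with levels `c("small", "large")`.
#' @export
binarize_classes <- function(concentration, threshold = 1.25) {
  concentration <- as.numeric(as.character(concentration))
  if (any(concentration < 0, na.rm = TRUE)) {
    abort("negative concentration")
  }
  factor(ifelse(concentration <= threshold, "small", "large"),
         levels = c("small", "large"))
}

#' Binary confusion metrics with "large" as the positive class
#'
#' Sensitivity is computed over the large-concentration class,
#' specificity over the small class, and balanced accuracy is their mean.
#'
#' @param truth,predicted Factors (or vectors coercible to factors) with
#'   levels `small`/`large`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `defined` (FALSE when the truth
#'   contains a single class, in which case the undefined metrics are
#'   `NA`).
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- factor(as.character(truth), levels = c("small", "large"))
  predicted <- factor(as.character(predicted), levels = c("small", "large"))
  stopifnot(length(truth) == length(predicted), !anyNA(truth), !anyNA(predicted))
  tp <- sum(truth == "large" & predicted == "large")
  fn <- sum(truth == "large" & predicted == "small")
  tn <- sum(truth == "small" & predicted == "small")
  fp <- sum(truth == "small" & predicted == "large")
  defined <- (tp + fn) > 0 && (tn + fp) > 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         balanced_accuracy = mean(c(sens, spec)),
         defined = defined)
}

#' Leave-one-plate-out cross-validation of the sparse PLS-DA classifier
#'
#' For each plate: fit the model on the remaining plates, predict the
#' left-out plate's concentration classes, binarize truth and prediction
#' at `threshold`, and compute confusion metrics. The summary reports each
#' metric as mean ± SD over runs, the mean selected-feature count, and the
#' size of the across-run selection intersection.
#'
#' @param x A [profile_frame()] (typically image level) with `plate_id`
#'   and `concentration` columns.
#' @param K,eta Passed to [fit_splsda()].
#' @param threshold Binarization threshold in µg/mL (default 1.25).
#' @return An `splsda_cv` object; `tidy()` returns the per-run table,
#'   `glance()` the summary, [cv_prediction_table()] the pooled
#'   true-by-predicted class counts, and `$pooled` a single confusion
#'   computed over the predictions of all runs together (the second
#'   reporting convention for such cross-validations).
#' @export
crossvalidate_leave_one_plate <- function(x, K = 2, eta = 0.5, threshold = 1.25) {
  stopifnot(inherits(x, "profile_frame"))
  plates <- unique(x$plate_id)
  if (length(plates) < 2) abort("need >= 2 plates for leave-one-plate-out CV")

  runs <- purrr::map_dfr(plates, function(p) {
    test <- x$plate_id == p
    fit <- fit_splsda(pf_slice(x, !test),
                      classes = x$concentration[!test], K = K, eta = eta)
    pred <- predict_splsda(fit, pf_slice(x, test))
    true_bin <- binarize_classes(x$concentration[test], threshold)
    pred_bin <- binarize_classes(as.numeric(as.character(pred)), threshold)
    cm <- confusion_metrics(true_bin, pred_bin)
    tibble(
      plate_left_out = p,
      predictions = list(tibble(
        true_class = x$concentration[test],
        predicted_class = as.numeric(as.character(pred))
      )),
      n_selected = length(fit$selected),
      selected = list(fit$selected)
    ) %>% dplyr::bind_cols(cm)
  })

  inter <- Reduce(intersect, runs$selected)
  metrics <- c("sensitivity", "specificity", "balanced_accuracy")
  summary <- tibble(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(runs[[mm]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(mm) sd(runs[[mm]], na.rm = TRUE), numeric(1))
  )
  # second reporting mode: one confusion over the predictions pooled
  # across runs (as read off a single prediction-scatter figure)
  all_pred <- dplyr::bind_rows(runs$predictions)
  pooled <- confusion_metrics(binarize_classes(all_pred$true_class, threshold),
                              binarize_classes(all_pred$predicted_class, threshold))
  structure(list(
    runs = runs, summary = summary, pooled = pooled,
    mean_selected = mean(runs$n_selected),
    intersection = inter, n_intersection = length(inter),
    K = K, eta = eta, threshold = threshold
  ), class = "splsda_cv")
}

#' @export
print.splsda_cv <- function(x, ...) {
  cat(sprintf("splsda_cv: %d leave-one-plate-out runs (K = %d, eta = %.2f)\n",
              nrow(x$runs), x$K, x$eta))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-18s %.0f%% ± %.0f\n", x$summary$metric[i],
                100 * x$summary$mean[i], 100 * x$summary$sd[i]))
  }
  cat(sprintf("  pooled over runs:  sensitivity %.0f%%, specificity %.0f%%\n",
              100 * x$pooled$sensitivity, 100 * x$pooled$specificity))
  cat(sprintf("  selected features: %.0f on average, %d in all runs\n",
              x$mean_selected, x$n_intersection))
  invisible(x)
}

#' @export
tidy.splsda_cv <- function(x, ...) {
  dplyr::select(x$runs, -dplyr::any_of(c("selected", "predictions")))
}

#' @export
glance.splsda_cv <- function(x, ...) {
  s <- x$summary
  tibble(
    n_runs = nrow(x$runs),
    sensitivity_mean = s$mean[s$metric == "sensitivity"],
    sensitivity_sd = s$sd[s$metric == "sensitivity"],
    specificity_mean = s$mean[s$metric == "specificity"],
    specificity_sd = s$sd[s$metric == "specificity"],
    balanced_accuracy_mean = s$mean[s$metric == "balanced_accuracy"],
    balanced_accuracy_sd = s$sd[s$metric == "balanced_accuracy"],
    mean_selected = x$mean_selected,
    n_intersection = x$n_intersection
  )
}

#' Pooled true-by-predicted class counts across CV runs
#'
#' The data behind a prediction scatter: one row per (true class,
#' predicted class) pair with the pooled count over all
#' leave-one-plate-out runs.
#'
#' @param cv An `splsda_cv`.
#' @return A tibble `true_class`, `predicted_class`, `n`.
#' @export
cv_prediction_table <- function(cv) {
  stopifnot(inherits(cv, "splsda_cv"))
  tidyr::unnest(cv$runs["predictions"], cols = "predictions") %>%
    count(true_class, predicted_class, name = "n")
}

#' @export
autoplot.splsda_cv <- function(object, ...) {
  tab <- cv_prediction_table(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(true_class),
                                    y = factor(predicted_class), size = n)) +
    ggplot2::geom_point(alpha = 0.7, color = "#2166AC") +
    ggplot2::geom_text(data = dplyr::filter(tab, n > 20),
                       ggplot2::aes(label = n), size = 3, vjust = -1.2) +
    ggplot2::labs(x = "true concentration class (µg/mL)",
                  y = "predicted concentration class (µg/mL)") +
    ggplot2::theme_classic()
}

#' UMAP embedding of image-level profiles
#'
#' Interface to the uwot implementation of uniform manifold approximation
#' and projection, configured for profile exploration (200 neighbors by
#' default, matching the broad-neighborhood setting appropriate for
#' plate-structured dose-response data). The embedding is exploratory:
#' concentration metadata is carried along for coloring.
#'
#' @param x A [profile_frame()].
#' @param n_neighbors Neighborhood size; must not exceed the row count.
#' @param n_dims Embedding dimensionality (default 2).
#' @param seed Integer seed; fixed seed gives identical coordinates across
#'   calls.
#' @return A `umap_embedding` tibble: metadata columns plus `umap1`,
#'   `umap2`, ...
#' @export
umap_embed <- function(x, n_neighbors = 200, n_dims = 2, seed = 1L) {
  stopifnot(inherits(x, "profile_frame"))
  m <- feature_matrix(x)
  if (nrow(m) < n_neighbors) {
    abort(paste0("only ", nrow(m), " rows but n_neighbors = ", n_neighbors,
                 "; use a smaller neighborhood"))
  }
  set.seed(as.integer(seed))
  coords <- uwot::umap(m, n_neighbors = n_neighbors, n_components = n_dims,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  colnames(coords) <- paste0("umap", seq_len(n_dims))
  meta <- as_tibble(as.data.frame(x)[setdiff(names(x), "features")])
  out <- dplyr::bind_cols(meta, as_tibble(as.data.frame(coords)))
  structure(out, class = c("umap_embedding", class(out)),
            n_neighbors = n_neighbors, seed = seed)
}

#' @export
autoplot.umap_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = umap1, y = umap2,
                                       color = factor(concentration))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_color_viridis_d(name = "µg/mL") +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_classic()
}
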