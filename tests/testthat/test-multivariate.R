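test_that("eta = 0 reproduces the dense PLS-DA oracle", {
  x <- separable_images(n_per_class = 20, gap = 1.5, seed = 3)
  fit <- fit_splsda(x, x$concentration, K = 2, eta = 0)
  expect_setequal(fit$selected, feature_names(x))
  oracle <- dense_plsda_oracle(feature_matrix(x), x$concentration, K = 2)
  expect_equal(unname(fit$scores), unname(oracle$scores), tolerance = 1e-8)
  pred <- predict_splsda(fit, x)
  expect_equal(as.character(pred), oracle$pred)
})

test_that("informative features are recovered under sparsity", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 160; p <- 100
    conc <- rep(c(0.156, 50), each = n / 2)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", 1:p)))
    m[conc == 50, 1:5] <- m[conc == 50, 1:5] + 2 # 2 MAD-unit separation
    fit <- fit_splsda(m, conc, K = 1, eta = 0.8)
    sum(sprintf("f%03d", 1:5) %in% fit$selected)
  }, numeric(1))
  expect_true(all(hits >= 4))
})

test_that("selection is monotone non-increasing in eta", {
  x <- separable_images(n_per_class = 25, gap = 2, seed = 6)
  sizes <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95), function(e) {
    length(fit_splsda(x, x$concentration, K = 2, eta = e)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], n_features(x))
  expect_error(fit_splsda(x, x$concentration, eta = 1), "eta")
})

test_that("separable two-class data is fit perfectly and ties go low", {
  x <- separable_images(n_per_class = 20, gap = 4, seed = 9)
  fit <- fit_splsda(x, x$concentration, K = 1, eta = 0)
  pred <- predict_splsda(fit, x)
  expect_equal(as.numeric(as.character(pred)), x$concentration)

  # symmetric two-class toy: a zero row is equidistant -> lower class wins
  m <- matrix(c(-1, -1, 1, 1), 4, 1, dimnames = list(NULL, "f1"))
  classes <- c(0, 0, 5, 5)
  fit2 <- fit_splsda(m, classes, K = 1, eta = 0)
  tie <- predict_splsda(fit2, matrix(0, 1, 1, dimnames = list(NULL, "f1")))
  expect_equal(as.character(tie), "0")
})

test_that("predictions align columns by feature name", {
  x <- separable_images(n_per_class = 15, gap = 3, seed = 12)
  fit <- fit_splsda(x, x$concentration, K = 2, eta = 0.3)
  m <- feature_matrix(x)
  perm <- m[, sample(ncol(m)), drop = FALSE]
  expect_equal(predict_splsda(fit, perm), predict_splsda(fit, m))
  expect_error(predict_splsda(fit, m[, 1:3]), "feature mismatch")
})

test_that("binarization respects the 1.25 µg/mL boundary", {
  expect_equal(as.character(binarize_classes(c(0, 1.25, 2.5, 100))),
               c("small", "small", "large", "large"))
  expect_error(binarize_classes(-1), "negative")
})

test_that("confusion metrics match brute-force counting", {
  truth <- rep(c("large", "small"), c(11, 32))
  pred <- c(rep("large", 9), rep("small", 2), rep("small", 30), rep("large", 2))
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm$tp, 9); expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 30); expect_equal(cm$fp, 2)
  expect_equal(cm$sensitivity, 9 / 11)           # 81.82%
  expect_equal(cm$specificity, 30 / 32)          # 93.75%
  expect_equal(round(100 * cm$sensitivity, 2), 81.82)
  expect_equal(round(100 * cm$specificity, 2), 93.75)
  expect_equal(cm$balanced_accuracy, mean(c(9 / 11, 30 / 32)))

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  allsmall <- confusion_metrics(truth, rep("small", 43))
  expect_equal(allsmall$sensitivity, 0)
  expect_equal(allsmall$specificity, 1)
  expect_equal(allsmall$balanced_accuracy, 0.5)

  onesided <- confusion_metrics(rep("small", 4), rep("small", 4))
  expect_false(onesided$defined)
  expect_true(is.na(onesided$sensitivity))

  # brute force over random label pairs
  set.seed(3)
  for (r in 1:5) {
    t_ <- sample(c("small", "large"), 50, TRUE)
    p_ <- sample(c("small", "large"), 50, TRUE)
    cm <- confusion_metrics(t_, p_)
    expect_equal(cm$sensitivity, sum(t_ == "large" & p_ == "large") / sum(t_ == "large"))
    expect_equal(cm$specificity, sum(t_ == "small" & p_ == "small") / sum(t_ == "small"))
  }
})

test_that("leave-one-plate-out CV reports runs, summary and selection overlap", {
  sim <- generate_experiment(small_config(n_features = 30, seed = 14,
                                          effect_fraction = 0.5,
                                          effect_size = 2,
                                          cells_per_field = c(40L, 50L)))
  images <- sim$cells |> normalize_to_control() |> aggregate_images()
  cv <- crossvalidate_leave_one_plate(images, K = 2, eta = 0.5)
  expect_equal(nrow(cv$runs), 3)
  expect_setequal(cv$runs$plate_left_out, c("P1", "P2", "P3"))
  expect_true(all(c("sensitivity", "specificity", "balanced_accuracy") %in%
                    cv$summary$metric))
  expect_lte(cv$n_intersection, min(cv$runs$n_selected))
  g <- glance(cv)
  expect_equal(g$n_runs, 3)
  expect_true(g$balanced_accuracy_mean > 0.5) # strong planted effects
  tab <- cv_prediction_table(cv)
  expect_equal(sum(tab$n), nrow(images))
  # pooled reporting mode: one confusion over all runs' predictions
  pooled <- cv$pooled
  expect_equal(pooled$tp + pooled$fp + pooled$tn + pooled$fn, nrow(images))
  all_pred <- tidyr::unnest(cv$runs["predictions"], cols = "predictions")
  oracle <- confusion_metrics(binarize_classes(all_pred$true_class),
                              binarize_classes(all_pred$predicted_class))
  expect_equal(pooled$sensitivity, oracle$sensitivity)
  expect_equal(pooled$specificity, oracle$specificity)
})

test_that("cross-validated accuracy grows with the planted effect size", {
  acc_at <- function(es) {
    sim <- generate_experiment(small_config(n_features = 20, seed = 31,
                                            effect_fraction = 0.5,
                                            effect_size = es,
                                            cells_per_field = c(30L, 40L)))
    images <- sim$cells |> normalize_to_control() |> aggregate_images()
    cv <- crossvalidate_leave_one_plate(images, K = 2, eta = 0.3)
    glance(cv)$balanced_accuracy_mean
  }
  accs <- vapply(c(0, 4), acc_at, numeric(1))
  expect_gt(accs[2], accs[1])
  expect_gt(accs[2], 0.9) # near-perfect at large separation
})

test_that("UMAP embeddings are deterministic and shaped correctly", {
  x <- separable_images(n_per_class = 60, gap = 5, seed = 21)
  e1 <- umap_embed(x, n_neighbors = 15, seed = 4)
  e2 <- umap_embed(x, n_neighbors = 15, seed = 4)
  expect_equal(dim(e1[c("umap1", "umap2")]), c(120, 2))
  expect_identical(e1$umap1, e2$umap1)
  expect_error(umap_embed(x, n_neighbors = 500), "smaller")
  # well-separated classes stay separated in the embedding
  d <- as.matrix(dist(cbind(e1$umap1, e1$umap2)))
  same <- outer(x$concentration, x$concentration, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same], na.rm = TRUE), mean(d[same], na.rm = TRUE))
})
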