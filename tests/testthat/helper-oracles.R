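# independent dense PLS-DA oracle: NIPALS-style SVD directions with no
# thresholding, nearest-centroid rule, written without the package's code
dense_plsda_oracle <- function(X, classes, K) {
  cls <- factor(as.character(classes),
                levels = as.character(sort(unique(as.numeric(as.character(classes))))))
  Y <- stats::model.matrix(~ cls - 1)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  Xd <- Xc
  W <- P <- NULL
  for (k in seq_len(K)) {
    w <- svd(crossprod(Xd, Yc), nu = 1, nv = 0)$u[, 1]
    w <- w / sqrt(sum(w^2))
    t_k <- Xd %*% w
    p_k <- crossprod(Xd, t_k) / sum(t_k^2)
    Xd <- Xd - t_k %*% t(p_k)
    W <- cbind(W, w); P <- cbind(P, p_k)
  }
  Wstar <- W %*% solve(crossprod(P, W))
  scores <- Xc %*% Wstar
  cent <- do.call(rbind, lapply(levels(cls), function(l) {
    colMeans(scores[cls == l, , drop = FALSE])
  }))
  pred <- apply(as.matrix(dist(rbind(scores, cent)))[seq_len(nrow(scores)),
                nrow(scores) + seq_len(nrow(cent)), drop = FALSE], 1, which.min)
  list(scores = scores, pred = levels(cls)[pred])
}
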