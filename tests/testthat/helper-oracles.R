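# Independent oracles used against the package's own computations.

# Least-squares residual by QR (lm.fit), independent of the SVD
# pseudo-inverse path.
ls_residual_oracle <- function(A, Y) {
  fit <- stats::lm.fit(A, Y)
  sqrt(sum(fit$residuals^2))
}

# AUC as the pairwise concordance probability (ties count 1/2).
concordance_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force re-evaluation of the voting rule for one triple.
vote_oracle <- function(e, v, s) {
  if (e == v || e == s) return(e)
  if (v == s) return(v)
  e
}

# Nearest-centroid classifier on per-image mean RGB; returns held-out
# accuracy with odd indices (per class) as train, even as test.
mean_color_centroid_accuracy <- function(imgs) {
  feat <- t(vapply(imgs$images, function(im) apply(im, 3, mean),
                   numeric(3)))
  tr <- unlist(lapply(seq_along(imgs$class_names), function(k) {
    idx <- which(imgs$labels == k)
    idx[seq(1, length(idx), by = 2)]
  }))
  cen <- rowsum(feat[tr, , drop = FALSE], imgs$labels[tr])
  cen <- cen / as.vector(table(imgs$labels[tr]))
  te <- setdiff(seq_along(imgs$labels), tr)
  pred <- apply(feat[te, , drop = FALSE], 1,
                function(v) which.min(colSums((t(cen) - v)^2)))
  mean(pred == imgs$labels[te])
}

# Least-squares one-hot linear classifier (with intercept), used as the
# oracle for feature-cloud separability.
linear_ls_accuracy <- function(train, test) {
  Xtr <- cbind(1, as.matrix(train[grep("^f", names(train))]))
  Xte <- cbind(1, as.matrix(test[grep("^f", names(test))]))
  B <- stats::lm.fit(Xtr, label_matrix(train$label))$coefficients
  B[is.na(B)] <- 0
  mean(max.col(Xte %*% B, ties.method = "first") == test$label)
}

# Tiny constant-image set builder for count arithmetic at scale.
constant_image_set <- function(n_per_class, class_names,
                               provenance = "original", size = 16) {
  im <- array(128, c(size, size, 3))
  n <- sum(n_per_class)
  image_set(rep(list(im), n),
            rep(seq_along(class_names), n_per_class),
            class_names, provenance)
}
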