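# Randomized neural networks trained in closed form.
#
# All three variants share the same single random hidden layer: weights W
# (d x Z) and biases b (Z) are drawn once, uniform on [-1, 1], and never
# updated. The hidden activation for sample x_i is
#     H[i, j] = g(w_j . x_i + b_j),
# and the output weights are the minimum-norm least-squares solution of a
# linear system against the one-hot label matrix Y:
#
#   ELM : P = H+ Y                      (outputs O = H P)
#   RVFL: P = M+ Y with M = [X | H]     (direct input-output links)
#   SNN : [P; e] = [H | 1]+ Y           (trainable output bias e)
#
# where A+ is the Moore-Penrose pseudo-inverse. No gradient descent, no
# iterations: one SVD per fit.

rnn_activations <- c("sigmoid", "tanh", "relu")

apply_activation <- function(a, activation) {
  switch(activation,
    sigmoid = 1 / (1 + exp(-a)),
    tanh = tanh(a),
    relu = pmax(a, 0),
    abort(paste("unknown activation:", activation)))
}

#' Draw the fixed random hidden layer
#'
#' Input-to-hidden weights and biases are i.i.d. uniform on \[-1, 1\] and
#' remain frozen for the life of the model; only the output weights are
#' ever solved for.
#'
#' @param d Input dimension.
#' @param Z Number of hidden nodes.
#' @param seed Integer seed.
#' @return `list(W = d x Z matrix, b = length-Z vector)`.
#' @export
init_random_layer <- function(d, Z, seed = 1) {
  d <- assert_scalar_int(d, "d")
  Z <- assert_scalar_int(Z, "Z")
  with_seed(seed, {
    list(W = matrix(runif(d * Z, -1, 1), d, Z), b = runif(Z, -1, 1))
  })
}

#' Hidden-layer output matrix
#'
#' @param x N x d input matrix (or data frame of features).
#' @param W d x Z hidden weight matrix.
#' @param b Length-Z bias vector.
#' @param activation One of `"sigmoid"` (default), `"tanh"`, `"relu"`.
#' @return The N x Z matrix `H` with `H[i, j] = g(w_j . x_i + b_j)`.
#' @export
hidden_output <- function(x, W, b, activation = "sigmoid") {
  x <- as.matrix(x)
  if (anyNA(x)) abort("`x` contains NA")
  if (ncol(x) != nrow(W)) abort("ncol(x) must equal nrow(W)")
  apply_activation(sweep(x %*% W, 2L, b, `+`), activation)
}

new_rnn_model <- function(variant, W, b, activation, P, e, seed,
                          n_classes, class_names, residual,
                          use_direct_links = NA) {
  structure(list(variant = variant, W = W, b = b, activation = activation,
                 P = P, e = e, Z = ncol(W), d = nrow(W),
                 n_classes = n_classes, class_names = class_names,
                 seed = seed, residual = residual,
                 use_direct_links = use_direct_links),
            class = "rnn_model")
}

# Shared front half of every fit: resolve inputs, draw the hidden layer,
# compute H. `y` may come as a column of `data`, a vector, or one-hot.
rnn_prepare <- function(data, y, Z, activation, seed, n_classes,
                        class_names) {
  fm <- as_feature_matrix(data, y)
  if (is.null(fm$y)) abort("class labels are required (a `label` column or `y`)")
  n_classes <- n_classes %||% max(fm$y)
  if (n_classes < 2L) abort("need at least 2 classes")
  Y <- label_matrix(fm$y, n_classes)
  hidden <- init_random_layer(ncol(fm$x), Z, seed)
  H <- hidden_output(fm$x, hidden$W, hidden$b, activation)
  list(x = fm$x, y = fm$y, Y = Y, W = hidden$W, b = hidden$b, H = H,
       n_classes = n_classes,
       class_names = class_names %||% paste0("class", seq_len(n_classes)))
}

# Minimum-norm least-squares solve of A P = Y, with the degenerate all-zero
# design handled explicitly.
solve_output_weights <- function(A, Y, rcond = NULL, lambda = 0) {
  if (all(A == 0)) {
    warn("degenerate (all-zero) design matrix; output weights set to 0")
    return(matrix(0, ncol(A), ncol(Y)))
  }
  if (lambda > 0) {
    return(solve(crossprod(A) + diag(lambda, ncol(A)), crossprod(A, Y)))
  }
  pinv(A, rcond) %*% Y
}

#' Train an extreme learning machine (ELM)
#'
#' Draws a fixed random hidden layer and solves the output weights in one
#' step as `P = H+ Y`, the minimum-norm minimizer of the Frobenius residual
#' `||H P - Y||_F` against the one-hot label matrix.
#'
#' @param data N x d feature matrix, or a data frame with a `label` column.
#' @param y Integer class labels in `1:n_classes` (unneeded if `data` has a
#'   `label` column).
#' @param Z Hidden-node count (default 400).
#' @param activation Hidden activation `g()`; `"sigmoid"` by default.
#' @param seed Seed for the random hidden layer.
#' @param n_classes,class_names Optional explicit class table.
#' @param rcond Singular-value cutoff passed to [pinv()].
#' @param lambda Optional ridge penalty (0 = pure pseudo-inverse, the
#'   default).
#' @return An object of class `rnn_model`.
#' @examples
#' fx <- make_gaussian_features(30, 3, dim = 5, separation = 6, seed = 1)
#' m <- train_elm(fx, Z = 20, seed = 2)
#' mean(predict(m, fx) == fx$label)
#' @export
train_elm <- function(data, y = NULL, Z = 400, activation = "sigmoid",
                      seed = 1, n_classes = NULL, class_names = NULL,
                      rcond = NULL, lambda = 0) {
  Z <- assert_scalar_int(Z, "Z")
  pr <- rnn_prepare(data, y, Z, activation, seed, n_classes, class_names)
  P <- solve_output_weights(pr$H, pr$Y, rcond, lambda)
  res <- norm(pr$H %*% P - pr$Y, "F")
  new_rnn_model("ELM", pr$W, pr$b, activation, P, NULL, seed,
                pr$n_classes, pr$class_names, res)
}

#' Train a random vector functional link network (RVFL)
#'
#' Identical hidden layer to the ELM, plus direct links from the input to
#' the output: the design matrix is the concatenation `M = [X | H]`
#' (N x (d + Z)) and `P = M+ Y`. Setting `use_direct_links = FALSE` solves
#' on `H` alone, which collapses the fit to the ELM normal equations.
#'
#' @inheritParams train_elm
#' @param use_direct_links Include the input block in the design (default
#'   `TRUE`, the standard RVFL).
#' @return An object of class `rnn_model`.
#' @export
train_rvfl <- function(data, y = NULL, Z = 400, activation = "sigmoid",
                       seed = 1, n_classes = NULL, class_names = NULL,
                       rcond = NULL, lambda = 0, use_direct_links = TRUE) {
  Z <- assert_scalar_int(Z, "Z")
  pr <- rnn_prepare(data, y, Z, activation, seed, n_classes, class_names)
  M <- if (use_direct_links) cbind(pr$x, pr$H) else pr$H
  P <- solve_output_weights(M, pr$Y, rcond, lambda)
  res <- norm(M %*% P - pr$Y, "F")
  new_rnn_model("RVFL", pr$W, pr$b, activation, P, NULL, seed,
                pr$n_classes, pr$class_names, res,
                use_direct_links = use_direct_links)
}

#' Train a Schmidt neural network (SNN)
#'
#' Identical hidden layer to the ELM, plus a trainable output bias `e`:
#' weights and bias are solved jointly as `[P; e] = [H | 1]+ Y`, and
#' predictions use `H P + 1 e'`.
#'
#' @inheritParams train_elm
#' @return An object of class `rnn_model`.
#' @export
train_snn <- function(data, y = NULL, Z = 400, activation = "sigmoid",
                      seed = 1, n_classes = NULL, class_names = NULL,
                      rcond = NULL, lambda = 0) {
  Z <- assert_scalar_int(Z, "Z")
  pr <- rnn_prepare(data, y, Z, activation, seed, n_classes, class_names)
  A <- cbind(pr$H, 1)
  Pe <- solve_output_weights(A, pr$Y, rcond, lambda)
  P <- Pe[seq_len(Z), , drop = FALSE]
  e <- Pe[Z + 1L, ]
  res <- norm(A %*% Pe - pr$Y, "F")
  new_rnn_model("SNN", pr$W, pr$b, activation, P, e, seed,
                pr$n_classes, pr$class_names, res)
}

# Raw (pre-argmax) network outputs, one column per class.
rnn_scores <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object$d) {
    abort(sprintf("newdata has %d columns; model expects %d", ncol(x),
                  object$d))
  }
  H <- hidden_output(x, object$W, object$b, object$activation)
  switch(object$variant,
    ELM = H %*% object$P,
    RVFL = if (isTRUE(object$use_direct_links)) {
      cbind(x, H) %*% object$P
    } else {
      H %*% object$P
    },
    SNN = sweep(H %*% object$P, 2L, object$e, `+`))
}

#' Predict classes or scores from a randomized network
#'
#' @param object An `rnn_model`.
#' @param newdata Feature matrix or data frame (a `label` column, if
#'   present, is ignored).
#' @param type `"class"` for integer labels (argmax over the m output
#'   columns, ties broken toward the lowest class index) or `"raw"` for the
#'   N x m score matrix.
#' @param ... Unused.
#' @return Integer labels in `1:n_classes`, or a score matrix.
#' @export
predict.rnn_model <- function(object, newdata, type = c("class", "raw"),
                              ...) {
  type <- match.arg(type)
  fm <- as_feature_matrix(newdata)
  O <- rnn_scores(object, fm$x)
  if (type == "raw") return(O)
  max.col(O, ties.method = "first")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("<rnn_model> %s: d=%d, Z=%d, %d classes, activation=%s\n",
              x$variant, x$d, x$Z, x$n_classes, x$activation))
  cat(sprintf("  training residual ||A P - Y||_F = %.6g\n", x$residual))
  invisible(x)
}
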