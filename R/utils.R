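#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif predict
#' @importFrom utils head tail
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic package internals funnel through
# this so that a single integer seed makes a whole stage reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1)", name))
  }
  as.numeric(x)
}

#' One-hot ground-truth label matrix
#'
#' Expands integer class labels (1-based) into the N x m indicator matrix
#' used as the regression target of the pseudo-inverse classifiers: row i
#' has a single 1 in the column of the true class of sample i.
#'
#' @param y Integer vector of class labels in `1:n_classes` (a factor is
#'   converted by its level index).
#' @param n_classes Number of classes m; defaults to `max(y)`.
#' @return An N x m numeric 0/1 matrix with unit row sums.
#' @examples
#' label_matrix(c(1, 3, 2), 3)
#' @export
label_matrix <- function(y, n_classes = NULL) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  n_classes <- if (is.null(n_classes)) max(y) else
    assert_scalar_int(n_classes, "n_classes", min = 2L)
  if (any(y < 1L | y > n_classes)) {
    abort("labels must lie in 1:n_classes")
  }
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# Accepts either a data frame with a `label` column (all remaining numeric
# columns are features) or a plain numeric matrix plus `y`. Returns
# list(x = N x d matrix, y = integer labels or NULL).
as_feature_matrix <- function(data, y = NULL) {
  if (is.data.frame(data)) {
    if ("label" %in% names(data)) {
      if (is.null(y)) y <- data[["label"]]
      data <- data[setdiff(names(data), "label")]
    }
    keep <- vapply(data, is.numeric, logical(1))
    x <- as.matrix(data[keep])
  } else {
    x <- as.matrix(data)
  }
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    abort("feature matrix contains NA or non-finite values")
  }
  if (!is.null(y)) {
    if (is.factor(y)) y <- as.integer(y)
    y <- as.integer(y)
    if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  }
  list(x = x, y = y)
}

#' Moore-Penrose pseudo-inverse
#'
#' SVD-based generalized inverse. Singular values below
#' `rcond * max(singular value)` are treated as zero, so the induced
#' least-squares solution is the minimum-Frobenius-norm minimizer.
#'
#' @param a Numeric matrix.
#' @param rcond Relative cutoff for small singular values; defaults to
#'   `.Machine$double.eps * max(dim(a))`.
#' @return The pseudo-inverse of `a` (`ncol(a)` x `nrow(a)`).
#' @export
pinv <- function(a, rcond = NULL) {
  a <- as.matrix(a)
  if (is.null(rcond)) rcond <- .Machine$double.eps * max(dim(a))
  s <- svd(a)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(a), nrow(a)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
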