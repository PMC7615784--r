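# ETRN: ensemble of the three randomized networks by majority voting.
#
# For an input c with member predictions R_e (ELM), R_v (RVFL), R_s (SNN),
# the ensemble label is
#     L(c) = R_a  if any two members agree (R_a == R_b),
#     L(c) = R_e  otherwise (three-way disagreement falls back to the ELM).
# Pure label voting: no probability averaging, no weights.

#' Majority vote with ELM fallback
#'
#' Vectorized over samples: returns the label any two members agree on, or
#' the ELM member's label when all three differ.
#'
#' @param r_e,r_v,r_s Integer label vectors from the ELM, RVFL, and SNN
#'   members (equal length, each in `1:n_classes`).
#' @param n_classes Optional upper bound used for validation.
#' @return Integer vector of ensemble labels.
#' @examples
#' majority_vote(c(3, 2, 1), c(3, 4, 2), c(1, 4, 3))  # 3, 4, 1
#' @export
majority_vote <- function(r_e, r_v, r_s, n_classes = NULL) {
  if (length(r_v) != length(r_e) || length(r_s) != length(r_e)) {
    abort("member prediction vectors must have equal length")
  }
  r_e <- as.integer(r_e); r_v <- as.integer(r_v); r_s <- as.integer(r_s)
  all_lab <- c(r_e, r_v, r_s)
  if (any(all_lab < 1L) ||
      (!is.null(n_classes) && any(all_lab > n_classes))) {
    abort("labels out of range")
  }
  out <- r_e                       # three-way disagreement -> ELM
  out[r_v == r_s] <- r_v[r_v == r_s]
  out[r_e == r_v | r_e == r_s] <- r_e[r_e == r_v | r_e == r_s]
  out
}

#' Train the ETRN ensemble
#'
#' Fits one ELM, one RVFL, and one SNN independently on the same features
#' and labels, each with its own seed for the random hidden layer, and
#' combines them under [majority_vote()].
#'
#' @inheritParams train_elm
#' @param seeds Integer vector of three member seeds; a single value `s`
#'   expands to `c(s, s + 1, s + 2)`.
#' @return An object of class `etrn_model` with members `$elm`, `$rvfl`,
#'   `$snn`.
#' @examples
#' fx <- make_gaussian_features(30, 3, dim = 5, separation = 6, seed = 1)
#' em <- train_etrn(fx, Z = 30, seeds = 1)
#' mean(predict(em, fx) == fx$label)
#' @export
train_etrn <- function(data, y = NULL, Z = 400, activation = "sigmoid",
                       seeds = 1, n_classes = NULL, class_names = NULL,
                       rcond = NULL, lambda = 0) {
  if (length(seeds) == 1L) seeds <- seeds + 0:2
  if (length(seeds) != 3L) abort("`seeds` must have length 1 or 3")
  elm <- train_elm(data, y, Z, activation, seeds[1], n_classes, class_names,
                   rcond, lambda)
  rvfl <- train_rvfl(data, y, Z, activation, seeds[2], n_classes,
                     class_names, rcond, lambda)
  snn <- train_snn(data, y, Z, activation, seeds[3], n_classes, class_names,
                   rcond, lambda)
  stopifnot(elm$d == rvfl$d, elm$d == snn$d,
            elm$n_classes == rvfl$n_classes, elm$n_classes == snn$n_classes)
  structure(list(elm = elm, rvfl = rvfl, snn = snn,
                 n_classes = elm$n_classes, class_names = elm$class_names,
                 seeds = as.integer(seeds)),
            class = "etrn_model")
}

#' Predict with the ETRN ensemble
#'
#' @param object An `etrn_model`.
#' @param newdata Feature matrix or data frame.
#' @param type `"class"` for voted labels, `"members"` for a tibble of
#'   per-member and voted labels, or `"raw"` for the score matrix of the
#'   member named in `score_member`.
#' @param score_member Member whose continuous outputs serve as scores when
#'   `type = "raw"` (default `"elm"`, the fallback member).
#' @param ... Unused.
#' @return Integer labels, a tibble, or a score matrix.
#' @export
predict.etrn_model <- function(object, newdata,
                               type = c("class", "members", "raw"),
                               score_member = c("elm", "rvfl", "snn"), ...) {
  type <- match.arg(type)
  score_member <- match.arg(score_member)
  if (type == "raw") {
    return(predict(object[[score_member]], newdata, type = "raw"))
  }
  r_e <- predict(object$elm, newdata)
  r_v <- predict(object$rvfl, newdata)
  r_s <- predict(object$snn, newdata)
  voted <- majority_vote(r_e, r_v, r_s, object$n_classes)
  if (type == "class") return(voted)
  tibble(elm = r_e, rvfl = r_v, snn = r_s, vote = voted)
}

#' @export
print.etrn_model <- function(x, ...) {
  cat(sprintf("<etrn_model> ELM + RVFL + SNN, d=%d, Z=%d, %d classes\n",
              x$elm$d, x$elm$Z, x$n_classes))
  cat(sprintf("  member seeds: %s\n", paste(x$seeds, collapse = ", ")))
  invisible(x)
}
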