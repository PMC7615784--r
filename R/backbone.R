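# Transfer-learning feature extractor: a frozen convolutional trunk ending
# at a global pooling layer, plus a trainable six-layer head
#   FC128 -> ReLU -> BN -> FC4 -> Softmax -> Classification
# The buffer layers (FC128/ReLU/BN) smooth the reduction from the trunk's
# pooled width down to the 4-way classifier. Only the head is fine-tuned;
# trunk parameters are bit-identical before and after. Features for the
# downstream randomized networks are tapped at the FC128 output (pre-ReLU),
# i.e. the layer that remains once the last five head layers are removed.

head_layer_names <- c("FC128", "ReLU", "BN", "FC4", "Softmax",
                      "Classification")

#' Build a small random convolutional trunk
#'
#' A frozen stand-in for a large pre-trained trunk: two stride-1
#' convolution blocks with ReLU and 2x2 max pooling, ending in global
#' average pooling over a configurable channel width. Random weights are
#' fixed at construction; the trunk is never trained. Suitable for
#' desk-scale runs and for exercising the full pipeline without any
#' pre-trained weight archive.
#'
#' @param out_width Width of the pooled output vector (2048 matches the
#'   customary large-backbone pooling width).
#' @param seed Integer seed for the random weights.
#' @param normalize Optional `list(mean, sd)` of per-channel constants
#'   applied after \[0, 1\] scaling (used when mimicking a trunk with
#'   published preprocessing); `NULL` means plain \[0, 1\] scaling.
#' @return An object of class `cnn_trunk`.
#' @export
random_trunk <- function(out_width = 32, seed = 1, normalize = NULL) {
  out_width <- assert_scalar_int(out_width, "out_width")
  net <- with_seed(seed, list(layers = list(
    nn_conv(3L, 8L, 3L),
    nn_act("relu"),
    nn_maxpool(),
    nn_conv(8L, out_width, 3L),
    nn_act("relu"),
    nn_maxpool(),
    nn_gap())))
  structure(list(net = net, out_width = out_width, normalize = normalize,
                 seed = seed),
            class = "cnn_trunk")
}

#' Build the modified backbone (frozen trunk + trainable head)
#'
#' Attaches the six-layer classification head to a trunk that exposes a
#' pooled feature vector. All trunk parameters are frozen; the FC128, BN,
#' and FC4 parameters are the only trainable ones (for a 2048-wide trunk
#' and 4 classes: 263,044 parameters).
#'
#' @param base A `cnn_trunk` (see [random_trunk()]); any object with a
#'   `$net` ending in a pooled vector and an `$out_width` works.
#' @param num_classes Number of classes (default 4).
#' @param seed Seed for head initialization.
#' @return An object of class `backbone_model` with fields `trunk`, `head`,
#'   `head_layer_names`, `trainable` (per-head-layer flags), and
#'   `num_classes`.
#' @export
build_modified_backbone <- function(base, num_classes = 4, seed = 1) {
  num_classes <- assert_scalar_int(num_classes, "num_classes", min = 2L)
  if (!inherits(base, "cnn_trunk") &&
      !(is.list(base) && !is.null(base$net) && !is.null(base$out_width))) {
    abort("`base` must provide a pooled-vector endpoint ($net, $out_width)")
  }
  w <- base$out_width
  head <- with_seed(seed, list(layers = list(
    nn_dense(w, 128L),                 # FC128
    nn_act("relu"),                    # ReLU
    nn_bn(128L, "dense"),              # BN
    nn_dense(128L, num_classes))))     # FC4
  structure(list(trunk = base, head = head,
                 head_layer_names = head_layer_names,
                 trainable = c(trunk = FALSE, head = TRUE),
                 num_classes = num_classes),
            class = "backbone_model")
}

#' Fine-tuning configuration
#'
#' Defaults follow the reference hyper-parameters: mini-batch 10, a single
#' epoch (guarding against overfitting on modest datasets), initial
#' learning rate 1e-4, Adam.
#'
#' @param mini_batch Mini-batch size.
#' @param max_epoch Number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed for shuffling and BN/dropout randomness.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(mini_batch = 10, max_epoch = 1,
                            learning_rate = 1e-4, optimizer = "adam",
                            seed = 1) {
  stopifnot(mini_batch >= 1, max_epoch >= 1, learning_rate > 0,
            optimizer == "adam")
  structure(list(mini_batch = as.integer(mini_batch),
                 max_epoch = as.integer(max_epoch),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# Stack an image_set (all images sharing one size) into an [H, W, 3, N]
# array scaled to [0, 1], with optional channel standardization.
images_to_batch <- function(data, normalize = NULL) {
  stopifnot(inherits(data, "image_set"), length(data) > 0)
  d1 <- dim(data$images[[1]])
  x <- array(0, c(d1[1], d1[2], 3, length(data)))
  for (i in seq_along(data$images)) {
    if (!identical(dim(data$images[[i]]), d1)) {
      abort("all images must share the same size; resize at load time")
    }
    x[, , , i] <- data$images[[i]] / 255
  }
  if (!is.null(normalize)) {
    for (ch in 1:3) {
      x[, , ch, ] <- (x[, , ch, ] - normalize$mean[ch]) / normalize$sd[ch]
    }
  }
  x
}

# Frozen trunk forward pass in chunks; returns the N x width pooled
# feature matrix. Pure function of (trunk weights, images).
trunk_features <- function(model, data, chunk = 32L) {
  x <- images_to_batch(data, model$trunk$normalize)
  n <- dim(x)[4]
  out <- matrix(0, n, model$trunk$out_width)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- nn_forward(model$trunk$net,
                             x[, , , s:e, drop = FALSE],
                             training = FALSE)$out
  }
  out
}

#' Count trainable (head) parameters
#'
#' @param model A `backbone_model`.
#' @return Integer count over FC128, BN, and FC4.
#' @export
backbone_trainable_params <- function(model) {
  stopifnot(inherits(model, "backbone_model"))
  sum(vapply(model$head$layers,
             function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

#' Class probabilities from the full modified backbone
#'
#' Runs trunk + head in inference mode (BN uses running statistics) and
#' applies the softmax, so each row is a probability simplex over classes.
#'
#' @param model A `backbone_model`.
#' @param data An [image_set].
#' @return An N x num_classes probability matrix.
#' @export
backbone_probs <- function(model, data) {
  f <- trunk_features(model, data)
  logits <- nn_forward(model$head, f, training = FALSE)$out
  softmax_rows(logits)
}

#' Fine-tune the backbone head
#'
#' Minimizes categorical cross-entropy on the softmax output over the head
#' parameters only, with Adam, for `max_epoch` passes in seeded shuffled
#' mini-batches. Trunk parameters are untouched (the features are computed
#' once and reused), so the freeze contract holds exactly.
#'
#' @param model A `backbone_model`.
#' @param train Training [image_set]; labels must cover all classes.
#' @param cfg A [finetune_config()].
#' @return The model with updated head parameters and a `loss_history`
#'   tibble (`epoch`, `batch`, `loss`).
#' @export
finetune_backbone <- function(model, train, cfg = finetune_config()) {
  stopifnot(inherits(model, "backbone_model"))
  if (length(train) == 0L) abort("empty training set")
  if (length(unique(train$labels)) < model$num_classes) {
    abort("training labels must cover every class")
  }
  f <- trunk_features(model, train)
  Y <- label_matrix(train$labels, model$num_classes)
  head <- model$head
  st <- adam_init(head)
  hist <- list()
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$max_epoch)) {
      ord <- sample.int(nrow(f))
      starts <- seq(1L, nrow(f), by = cfg$mini_batch)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$mini_batch - 1L,
                                  nrow(f))]
        fwd <- nn_forward(head, f[idx, , drop = FALSE], training = TRUE)
        head <- fwd$net
        ce <- softmax_xent(fwd$out, Y[idx, , drop = FALSE])
        bwd <- nn_backward(head, fwd$caches, ce$dlogits)
        upd <- adam_step(head, bwd$grads, st, cfg$learning_rate)
        head <- upd$net
        st <- upd$st
        hist[[length(hist) + 1L]] <- tibble(epoch = ep, batch = bi,
                                            loss = ce$loss)
      }
    }
  })
  model$head <- head
  model$loss_history <- dplyr::bind_rows(hist)
  model
}

#' Extract 128-dimensional features
#'
#' Taps the FC128 output (pre-ReLU) — the layer remaining once the last
#' five head layers (ReLU, BN, FC4, Softmax, Classification) are removed —
#' in inference mode. This is the feature matrix consumed by the
#' randomized-network classifiers.
#'
#' @param model A `backbone_model` (fine-tuned or not).
#' @param data An [image_set].
#' @return A tibble with columns `f1..f128` and `label`.
#' @export
extract_features <- function(model, data) {
  stopifnot(inherits(model, "backbone_model"))
  if (length(data) == 0L) abort("empty image set")
  f <- trunk_features(model, data)
  fc128 <- dense_forward(model$head$layers[[1]], f)$out
  out <- as_tibble(as.data.frame(fc128), .name_repair = "minimal")
  names(out) <- paste0("f", seq_len(ncol(fc128)))
  out$label <- data$labels
  out
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf(
    "<backbone_model> trunk width %d (frozen) + head [%s], %d classes\n",
    x$trunk$out_width, paste(x$head_layer_names, collapse = ", "),
    x$num_classes))
  cat(sprintf("  trainable parameters: %d\n",
              backbone_trainable_params(x)))
  invisible(x)
}
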