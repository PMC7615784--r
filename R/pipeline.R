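# End-to-end orchestration: augmentation -> backbone fine-tune -> feature
# extraction -> randomized-network ensemble -> evaluation. The test split
# is produced before any training, never augmented, and read exactly once
# at evaluation time.

#' Pipeline configuration
#'
#' Collects every stage's settings under one seed. Classifier
#' hyper-parameter defaults mirror the reference setting (mini-batch 10,
#' max-epoch 1, learning rate 1e-4, Z = 400 hidden nodes); fixture modes
#' shrink the image counts and synthetic-image budget to desk scale.
#'
#' @param mode `"fixtures"` (synthetic cell images), `"features"` (Gaussian
#'   feature clouds, skipping the image stages), or `"disk"` (a
#'   class-per-subdirectory image tree at `data_root`).
#' @param data_root Image tree root (mode `"disk"`).
#' @param class_names Optional class names (default: 4 fixture classes, or
#'   the subdirectory names on disk).
#' @param n_per_class Fixture images (or feature rows) per class before the
#'   split.
#' @param image_size Classifier input size `c(H, W)` (also the GAN
#'   resolution in fixture mode).
#' @param train_fraction Stratified split fraction (default 0.7).
#' @param per_class_counts Optional explicit per-class `c(train, test)`
#'   counts, as [split_dataset()].
#' @param n_synthetic_per_class GAN images added per class (reference 3000;
#'   fixture default 50).
#' @param feature_dim,separation Gaussian-cloud geometry (mode
#'   `"features"`).
#' @param trunk_width Pooled width of the random trunk.
#' @param Z Hidden nodes per randomized network (default 400).
#' @param gan A [gan_config()]; defaults to a small one matching
#'   `image_size`.
#' @param finetune A [finetune_config()].
#' @param skip_gan Skip augmentation (the "original dataset" condition).
#' @param skip_finetune Skip head fine-tuning (features from the randomly
#'   initialized head).
#' @param out_dir Artifact directory; `NULL` for a fresh temporary
#'   directory.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `dlbcnet_config` list.
#' @export
dlbcnet_config <- function(mode = c("fixtures", "features", "disk"),
                           data_root = NULL, class_names = NULL,
                           n_per_class = 120, image_size = c(32, 32),
                           train_fraction = 0.7, per_class_counts = NULL,
                           n_synthetic_per_class = NULL,
                           feature_dim = 128, separation = 10,
                           trunk_width = 32, Z = 400,
                           gan = NULL, finetune = NULL,
                           skip_gan = FALSE, skip_finetune = FALSE,
                           out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "disk" && (is.null(data_root) || !dir.exists(data_root))) {
    abort("mode 'disk' requires an existing `data_root`")
  }
  if (is.null(class_names) && mode != "disk") {
    class_names <- c("neutrophil", "eosinophil", "monocyte", "lymphocyte")
  }
  n_synthetic_per_class <- n_synthetic_per_class %||%
    (if (mode == "disk") 3000L else 50L)
  gan <- gan %||% gan_config(image_size = image_size, gen_blocks = 2,
                             disc_blocks = 2, base_filters = 8,
                             iterations = 60, mini_batch = 8, seed = seed)
  finetune <- finetune %||% finetune_config(seed = seed)
  structure(list(mode = mode, data_root = data_root,
                 class_names = class_names,
                 n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 train_fraction = train_fraction,
                 per_class_counts = per_class_counts,
                 n_synthetic_per_class = as.integer(n_synthetic_per_class),
                 feature_dim = as.integer(feature_dim),
                 separation = separation,
                 trunk_width = as.integer(trunk_width),
                 Z = as.integer(Z), gan = gan, finetune = finetune,
                 skip_gan = skip_gan, skip_finetune = skip_finetune,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "dlbcnet_config")
}

# Stage 1-5 of the pipeline: produce train/test feature tibbles (f1..fd +
# label) plus side artifacts. Shared by single runs and repeated-run
# aggregation so re-randomizing the classifiers reuses fixed features.
pipeline_features <- function(cfg) {
  side <- list()
  if (cfg$mode == "features") {
    cloud <- make_gaussian_features(2L * cfg$n_per_class,
                                    length(cfg$class_names),
                                    dim = cfg$feature_dim,
                                    separation = cfg$separation,
                                    seed = cfg$seed)
    tr_idx <- integer(0)
    with_seed(cfg$seed + 1L, {
      for (k in seq_len(length(cfg$class_names))) {
        idx <- which(cloud$label == k)
        tr_idx <- c(tr_idx, sample(idx, round(cfg$train_fraction *
                                                length(idx))))
      }
    })
    return(list(train = cloud[sort(tr_idx), ],
                test = cloud[-sort(tr_idx), ], side = side,
                class_names = cfg$class_names))
  }
  data <- if (cfg$mode == "disk") {
    load_image_dataset(cfg$data_root, cfg$class_names, cfg$image_size)
  } else {
    make_synthetic_cell_images(cfg$n_per_class, length(cfg$class_names),
                               cfg$image_size, seed = cfg$seed,
                               class_names = cfg$class_names)
  }
  cfg$class_names <- data$class_names
  sp <- split_dataset(data, cfg$train_fraction, cfg$per_class_counts,
                      seed = cfg$seed + 1L)
  train <- sp$train
  if (!cfg$skip_gan) {
    synth <- NULL
    histories <- list()
    for (k in seq_along(cfg$class_names)) {
      gcfg <- cfg$gan
      gcfg$seed <- cfg$gan$seed + k
      cls <- subset_image_set(train, which(train$labels == k))
      pair <- train_bcgan(cls, gcfg)
      histories[[k]] <- dplyr::mutate(pair$loss_history,
                                      class = cfg$class_names[k],
                                      .before = 1)
      smp <- sample_images(pair, cfg$n_synthetic_per_class, k,
                           seed = cfg$seed + 10L + k,
                           class_names = cfg$class_names,
                           image_size = cfg$image_size)
      synth <- if (is.null(synth)) smp else
        assemble_mixed_dataset(synth, smp)
    }
    side$gan_history <- dplyr::bind_rows(histories)
    train <- assemble_mixed_dataset(train, synth)
  }
  trunk <- random_trunk(cfg$trunk_width, seed = cfg$seed + 2L)
  model <- build_modified_backbone(trunk, length(cfg$class_names),
                                   seed = cfg$seed + 3L)
  if (!cfg$skip_finetune) {
    model <- finetune_backbone(model, train, cfg$finetune)
    side$finetune_history <- model$loss_history
  }
  side$backbone <- model
  side$train_set <- train
  side$test_set <- sp$test
  list(train = extract_features(model, train),
       test = extract_features(model, sp$test), side = side,
       class_names = cfg$class_names)
}

#' Run the full classification pipeline
#'
#' Executes every stage in order — dataset assembly, optional per-class GAN
#' augmentation of the training split, backbone head fine-tuning, 128-d
#' feature extraction, ensemble training, evaluation — and persists the
#' intermediate artifacts (feature CSVs, model archives, metric tables,
#' run manifest) under `cfg$out_dir`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [dlbcnet_config()].
#' @return An object of class `dlbcnet_run`: `report` (per-class + macro
#'   metric tibble, proportions in \[0, 1\]), `auc` (per-class one-vs-rest
#'   AUC from the ELM member's continuous scores), `etrn`, `predictions`,
#'   `config`, `out_dir`, and stage side artifacts.
#' @examples
#' \donttest{
#' cfg <- dlbcnet_config(mode = "features", n_per_class = 60, Z = 50)
#' run <- run_dlbcnet(cfg)
#' run$report
#' }
#' @export
run_dlbcnet <- function(cfg = dlbcnet_config()) {
  stopifnot(inherits(cfg, "dlbcnet_config"))
  out_dir <- cfg$out_dir %||% tempfile("dlbcnet_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- pipeline_features(cfg)
  cn <- feats$class_names
  m <- length(cn)
  etrn <- train_etrn(feats$train, Z = cfg$Z, seeds = cfg$seed + 100L,
                     n_classes = m, class_names = cn)
  members <- predict(etrn, feats$test, type = "members")
  report <- metrics_report(feats$test$label, members$vote, m, cn)
  scores <- predict(etrn, feats$test, type = "raw")
  auc <- roc_auc_ovr(scores, feats$test$label, cn)
  readr::write_csv(feats$train, file.path(out_dir, "features_train.csv"))
  readr::write_csv(feats$test, file.path(out_dir, "features_test.csv"))
  readr::write_csv(report, file.path(out_dir, "metrics.csv"))
  readr::write_csv(auc, file.path(out_dir, "auc.csv"))
  if (!is.null(feats$side$gan_history)) {
    readr::write_csv(feats$side$gan_history,
                     file.path(out_dir, "gan_loss_history.csv"))
  }
  save_etrn_model(etrn, file.path(out_dir, "etrn"))
  jsonlite::write_json(
    list(mode = cfg$mode, seed = cfg$seed, Z = cfg$Z,
         n_classes = m, class_names = cn,
         skip_gan = cfg$skip_gan, skip_finetune = cfg$skip_finetune,
         n_train = nrow(feats$train), n_test = nrow(feats$test),
         package_version = as.character(utils::packageVersion("dlbcnet"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  structure(list(report = report, auc = auc, etrn = etrn,
                 predictions = dplyr::mutate(members,
                                             truth = feats$test$label),
                 features = feats[c("train", "test")],
                 side = feats$side, config = cfg, out_dir = out_dir),
            class = "dlbcnet_run")
}

#' Repeat classifier training over several runs and aggregate
#'
#' Keeps the feature pipeline fixed (one dataset, one backbone, one feature
#' extraction) and re-trains the randomized ensemble `n_runs` times with
#' run-indexed seeds — the repeated-runs protocol that averages out the
#' variance of the random hidden layers. Per-run per-class metrics are
#' retained and their element-wise mean (then macro average) reported.
#'
#' @param cfg A [dlbcnet_config()].
#' @param n_runs Number of repetitions (default 5).
#' @return A `dlbcnet_five` object: `per_run` (long tibble with `run`),
#'   `aggregate` (run-averaged per-class metrics), `macro` (their macro
#'   averages), and the individual `runs`.
#' @export
run_five_runs <- function(cfg = dlbcnet_config(), n_runs = 5) {
  stopifnot(inherits(cfg, "dlbcnet_config"))
  n_runs <- assert_scalar_int(n_runs, "n_runs")
  feats <- pipeline_features(cfg)
  cn <- feats$class_names
  m <- length(cn)
  runs <- vector("list", n_runs)
  per_run <- list()
  for (r in seq_len(n_runs)) {
    etrn <- train_etrn(feats$train, Z = cfg$Z,
                       seeds = cfg$seed + 100L + 1000L * (r - 1L),
                       n_classes = m, class_names = cn)
    pred <- predict(etrn, feats$test)
    pc <- per_class_metrics(confusion_counts(feats$test$label, pred, m,
                                             cn))
    runs[[r]] <- list(etrn = etrn, metrics = pc)
    per_run[[r]] <- dplyr::mutate(pc, run = r, .before = 1)
  }
  per_run <- dplyr::bind_rows(per_run)
  agg <- aggregate_runs(per_run)
  structure(list(per_run = per_run, aggregate = agg,
                 macro = macro_average(agg), runs = runs, config = cfg),
            class = "dlbcnet_five")
}

#' @export
print.dlbcnet_run <- function(x, ...) {
  cat("<dlbcnet_run>\n")
  print(format_metrics_percent(x$report))
  invisible(x)
}

#' @export
print.dlbcnet_five <- function(x, ...) {
  cat(sprintf("<dlbcnet_five> %d runs\n", max(x$per_run$run)))
  print(format_metrics_percent(x$aggregate))
  cat("macro averages:\n")
  print(format_metrics_percent(x$macro))
  invisible(x)
}

#' Format a metric tibble on the percentage scale
#'
#' Multiplies metric columns by 100 and rounds to 2 decimals — the printed
#' convention of reported tables. Rounding happens only here, never inside
#' the aggregation arithmetic.
#'
#' @param metrics A metric tibble (proportions in \[0, 1\]).
#' @param digits Decimal places (default 2).
#' @return The tibble with metric columns as rounded percentages.
#' @export
format_metrics_percent <- function(metrics, digits = 2) {
  dplyr::mutate(metrics,
                dplyr::across(dplyr::any_of(metric_cols),
                              ~ round(100 * .x, digits)))
}
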