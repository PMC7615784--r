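# Text-based model archives: JSON metadata + numeric arrays (matrices are
# serialized with their dimensions so loads are exact to double precision).

mat_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  list(dim = dim(m) %||% length(m), values = as.vector(m))
}

list_to_mat <- function(l) {
  if (is.null(l)) return(NULL)
  v <- as.numeric(l$values)
  d <- as.integer(unlist(l$dim))
  if (length(d) > 1L) dim(v) <- d
  v
}

#' Save / load a randomized-network model
#'
#' Writes the variant tag, frozen random layer (W, b), activation, solved
#' output weights (and SNN bias), seed, and class table as a single JSON
#' archive; numbers round-trip at full double precision.
#'
#' @param model An `rnn_model`.
#' @param path Output file path (`.json`).
#' @return `save_rnn_model` returns `path` invisibly; `load_rnn_model`
#'   returns the restored `rnn_model`.
#' @export
save_rnn_model <- function(model, path) {
  stopifnot(inherits(model, "rnn_model"))
  obj <- list(variant = model$variant, activation = model$activation,
              seed = model$seed, n_classes = model$n_classes,
              class_names = model$class_names,
              use_direct_links = model$use_direct_links,
              residual = model$residual,
              W = mat_to_list(model$W), b = mat_to_list(model$b),
              P = mat_to_list(model$P), e = mat_to_list(model$e))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_rnn_model
#' @param path Archive path written by `save_rnn_model`.
#' @export
load_rnn_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_rnn_model(o$variant, list_to_mat(o$W), as.numeric(o$b$values),
                o$activation, list_to_mat(o$P),
                if (is.null(o$e)) NULL else as.numeric(o$e$values),
                o$seed, o$n_classes, o$class_names, o$residual,
                use_direct_links = o$use_direct_links %||% NA)
}

#' Save / load an ETRN ensemble
#'
#' Three member archives plus a manifest JSON under one directory.
#'
#' @param model An `etrn_model`.
#' @param dir Archive directory.
#' @return `save_etrn_model` returns `dir` invisibly; `load_etrn_model`
#'   the restored `etrn_model`.
#' @export
save_etrn_model <- function(model, dir) {
  stopifnot(inherits(model, "etrn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_rnn_model(model$elm, file.path(dir, "elm.json"))
  save_rnn_model(model$rvfl, file.path(dir, "rvfl.json"))
  save_rnn_model(model$snn, file.path(dir, "snn.json"))
  jsonlite::write_json(list(members = c("elm.json", "rvfl.json",
                                        "snn.json"),
                            seeds = model$seeds,
                            n_classes = model$n_classes,
                            class_names = model$class_names),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_etrn_model
#' @export
load_etrn_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(list(elm = load_rnn_model(file.path(dir, "elm.json")),
                 rvfl = load_rnn_model(file.path(dir, "rvfl.json")),
                 snn = load_rnn_model(file.path(dir, "snn.json")),
                 n_classes = man$n_classes,
                 class_names = man$class_names,
                 seeds = as.integer(man$seeds)),
            class = "etrn_model")
}
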