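# Single-file JSON model container, including the preprocessing state a
# deployed model needs (wavelength subset, SNV flag, centering constants).

.matrix_to_list <- function(m) list(data = as.vector(m), dim = dim(m))
.list_to_matrix <- function(l) {
  if (is.null(l)) return(NULL)
  array(unlist(l$data), dim = unlist(l$dim))
}

#' Serialise a fitted model to a JSON container
#'
#' Stores every field of a `plsr_model` or `lssvm_model` at full numeric
#' precision, plus optional preprocessing metadata (the wavelength subset
#' the model expects, whether SNV was applied, ...), in one portable JSON
#' file.
#'
#' @param model A `plsr_model` or `lssvm_model`.
#' @param path Output path.
#' @param meta Optional named list of preprocessing state to store
#'   alongside the model (e.g. `list(snv = TRUE, feature_indices = ...)`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, meta = list()) {
  payload <- if (inherits(model, "plsr_model")) {
    list(type = "plsr", n_lv = model$n_lv,
         w = .matrix_to_list(model$w), p = .matrix_to_list(model$p),
         q = model$q, coef = model$coef,
         x_mean = model$x_mean, y_mean = model$y_mean,
         wavelengths = model$wavelengths)
  } else if (inherits(model, "lssvm_model")) {
    list(type = "lssvm", alpha = model$alpha, bias = model$bias,
         gamma = model$gamma, sigma = model$sigma,
         x = .matrix_to_list(model$x),
         y_center = model$y_center, y_scale = model$y_scale)
  } else {
    rlang::abort("Unsupported model class.", class = "ovaspec_io_error")
  }
  payload$meta <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model back from its JSON container
#'
#' @param path Path written by [write_model()].
#' @return The restored `plsr_model` or `lssvm_model`; preprocessing
#'   metadata, if present, is attached as attribute `"meta"`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (identical(obj$type, "plsr")) {
    structure(
      list(n_lv = as.integer(obj$n_lv),
           w = .list_to_matrix(obj$w), p = .list_to_matrix(obj$p),
           q = obj$q, scores = NULL, coef = obj$coef,
           coef_path = NULL,
           x_mean = obj$x_mean, y_mean = obj$y_mean,
           wavelengths = obj$wavelengths),
      class = "plsr_model")
  } else if (identical(obj$type, "lssvm")) {
    structure(
      list(alpha = obj$alpha, bias = obj$bias, gamma = obj$gamma,
           sigma = obj$sigma, x = .list_to_matrix(obj$x),
           y_center = obj$y_center, y_scale = obj$y_scale,
           kkt_residual = NA_real_),
      class = "lssvm_model")
  } else {
    rlang::abort("Unrecognised model container.", class = "ovaspec_io_error")
  }
  if (length(obj$meta)) attr(model, "meta") <- obj$meta
  model
}
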