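#' Write a bias model as a YAML key-value file
#'
#' Flat serialization mirroring the [bias_model()] fields, so simulator
#' configurations can be versioned and shared outside R.
#'
#' @param model A `bias_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_model_yaml <- function(model, path) {
  x <- unclass(model)
  # named numeric vectors must become YAML maps, not bare sequences
  for (nm in c("lig5_weights", "lig3_weights", "base_count_coeffs",
               "artifact_rates"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a bias model from a YAML key-value file
#'
#' @param path YAML path written by [write_bias_model_yaml()] or edited by
#'   hand; unknown keys are rejected, missing keys take defaults.
#' @return A `bias_model`.
#' @export
read_bias_model_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(bias_model))
  raw <- raw[!names(raw) %in% "umi_len"]
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown bias model keys: ", paste(unknown, collapse = ", "))
  for (nm in c("lig5_weights", "lig3_weights", "base_count_coeffs",
               "artifact_rates"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(bias_model, raw)
}
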