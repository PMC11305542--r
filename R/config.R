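#' Read pipeline parameters from a YAML config file
#'
#' The file mirrors [vmseg_params()] field for field (`kernel_sizes` as a
#' list); missing fields fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [vmseg_params].
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(vmseg_params))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$kernel_sizes)) y$kernel_sizes <- unlist(y$kernel_sizes)
  do.call(vmseg_params, y)
}

#' Write pipeline parameters to a YAML config file
#'
#' @param params A [vmseg_params].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "vmseg_params"))
  x <- unclass(params)
  x$kernel_sizes <- as.list(x$kernel_sizes)
  yaml::write_yaml(x, path)
  invisible(path)
}
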