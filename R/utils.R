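`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
stop_config <- function(...) stop("config error: ", ..., call. = FALSE)

stop_validation <- function(...) stop("validation error: ", ..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Merge user overrides into a nested default list, one level deep per call.
merge_config <- function(defaults, overrides) {
  if (length(overrides) == 0) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop_config("unknown option(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, overrides)
}
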