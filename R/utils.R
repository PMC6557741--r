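#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange filter mutate select bind_rows group_by summarise
#'   desc n
#' @importFrom stats kmeans rnorm runif sd
#' @importFrom utils head read.delim write.table
NULL

abort_config <- function(message, ...) {
  abort(message, class = "scgonet_config_error", ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = "scgonet_parse_error", ...)
}

abort_integrity <- function(message, ...) {
  abort(message, class = "scgonet_integrity_error", ...)
}

abort_domain <- function(message, ...) {
  abort(message, class = "scgonet_domain_error", ...)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_config(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_config(sprintf("`%s` must be a single number.", name))
  }
  if (x < min) {
    abort_config(sprintf("`%s` must be >= %g.", name, min))
  }
  as.numeric(x)
}
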