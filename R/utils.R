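#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   left_join n bind_rows across all_of
#' @importFrom stats var sd qt pf predict lm aov coef residuals rnorm runif
#' @importFrom grDevices rgb2hsv convertColor col2rgb hsv rgb
NULL

# validation errors carry a dedicated class so batch drivers (and the CLI)
# can map them to exit code 2
stop_validation <- function(msg, ...) {
  abort(msg, class = "bollcount_validation_error", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "bollcount_format_error", ...)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Re-exported generics
#'
#' See [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#'
#' @name reexports
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname reexports
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname reexports
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
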