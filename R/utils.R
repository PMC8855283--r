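#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

# Round half away from zero, as in the published tables (base round() rounds
# half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
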