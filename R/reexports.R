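# broom-style generics and ggplot2 autoplot, re-exported so users get the
# methods without attaching the generics packages themselves

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' @importFrom rlang :=
#' @importFrom tibble tibble
NULL
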