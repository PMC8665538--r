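# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
an_log <- function(...) {
  message("[aneunet] ", ...)
}

# All randomness in the package flows through explicit seeds; RNG state of the
# caller is never touched.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @keywords internal
#' @noRd
stop_an <- function(...) {
  stop(..., call. = FALSE)
}
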