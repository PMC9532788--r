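#' Percent loss of a compound between two states
#'
#' Relative decrease from an initial to a final content, in percent —
#' the arithmetic behind "total anthocyanin content fell by X%" statements.
#'
#' @param initial Initial content; positive.
#' @param final Final content; nonnegative.
#' @return Percent loss, `(initial - final) / initial * 100`.
#' @examples
#' percent_loss(1546.18, 351.81)  # ~77
#' @export
percent_loss <- function(initial, final) {
  stopifnot(initial > 0, final >= 0)
  (initial - final) / initial * 100
}
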