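#' @noRd
.assert <- function(ok, msg) if (!isTRUE(ok)) abort(msg)

# Draw a derived seed stream: one master seed -> reproducible child seeds,
# kept inside 32-bit integer range.
#' @noRd
.child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
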