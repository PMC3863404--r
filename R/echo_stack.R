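#' Multiecho image stack
#'
#' Container for a spatially registered series of 2D gradient-echo images of
#' the same slice acquired at ascending echo times. Every pixel `(i, j)`
#' carries a decay curve `V_ij = (V_ij1, ..., V_ijn)` sampled at the echo
#' times `te_ms`, the raw material for all mapping operations.
#'
#' @param intensities Numeric array of dimension `rows x cols x n_echoes`
#'   with finite, nonnegative values (arbitrary scanner units).
#' @param te_ms Numeric vector of echo times in milliseconds, strictly
#'   ascending, all positive, of length `dim(intensities)[3]` (at least 2).
#'
#' @return An object of class `echo_stack`: a list with elements
#'   `intensities` and `te_ms`.
#' @examples
#' te <- te_schedule()
#' arr <- array(rexp(4 * 4 * length(te), 1 / 50), dim = c(4, 4, length(te)))
#' stk <- echo_stack(arr, te)
#' n_echoes(stk)
#' @export
echo_stack <- function(intensities, te_ms) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (rows x cols x echoes)", call. = FALSE)
  storage.mode(intensities) <- "double"
  te_ms <- as.double(te_ms)
  if (length(te_ms) < 2L)
    stop("at least 2 echoes are required", call. = FALSE)
  if (anyNA(te_ms) || any(te_ms <= 0))
    stop("`te_ms` must be positive and finite", call. = FALSE)
  if (any(diff(te_ms) <= 0))
    stop("`te_ms` must be strictly ascending", call. = FALSE)
  if (dim(intensities)[3] != length(te_ms))
    stop("third dimension of `intensities` (", dim(intensities)[3],
         ") does not match length of `te_ms` (", length(te_ms), ")",
         call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("`intensities` must be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("`intensities` must be nonnegative", call. = FALSE)
  structure(list(intensities = intensities, te_ms = te_ms),
            class = "echo_stack")
}

#' @export
print.echo_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<echo_stack> %d x %d pixels, %d echoes\n", d[1], d[2], d[3]))
  cat(sprintf("  TE: %.2f .. %.2f ms\n", x$te_ms[1], x$te_ms[length(x$te_ms)]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Number of echoes in a stack
#' @param stack An [echo_stack()].
#' @return Integer echo count.
#' @export
n_echoes <- function(stack) {
  stopifnot(inherits(stack, "echo_stack"))
  length(stack$te_ms)
}

#' Default 12-echo TE schedule
#'
#' The echo-time schedule of the target acquisition: 12 echoes from
#' 2.61 ms to 38.91 ms in equal steps of 3.3 ms.
#'
#' @param n_echoes Number of echoes (default 12).
#' @param first_ms First echo time in ms (default 2.61).
#' @param step_ms Echo spacing in ms (default 3.3).
#' @return Numeric vector of echo times in ms.
#' @export
te_schedule <- function(n_echoes = 12L, first_ms = 2.61, step_ms = 3.3) {
  stopifnot(n_echoes >= 2, first_ms > 0, step_ms > 0)
  first_ms + step_ms * (seq_len(n_echoes) - 1)
}

# flatten rows x cols x n to (rows*cols) x n for vectorised per-pixel fits
.pixel_matrix <- function(stack) {
  d <- dim(stack$intensities)
  matrix(stack$intensities, nrow = d[1] * d[2], ncol = d[3])
}
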