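#' Reference decay signal
#'
#' A length-n reference curve against which every pixel's decay is fit.
#' Usually model-generated by [generate_reference()]; alternatively the mean
#' curve of a manually chosen ROI via [roi_mean_reference()].
#'
#' @param values Numeric vector of nonnegative reference intensities, one per
#'   echo. Must not be constant: a zero-variance reference makes the slope of
#'   the two-parameter fit undefined (its denominator is the reference
#'   variance), so it is rejected here rather than at fit time.
#' @param w Scale parameter of the generating model (intensity units), or
#'   `NA` if not model-generated.
#' @param t2star_ms Decay constant of the generating model in ms, or `NA`.
#' @param source Either `"model"` or `"roi_mean"`.
#'
#' @return An object of class `reference_signal`.
#' @seealso [generate_reference()], [roi_mean_reference()]
#' @export
reference_signal <- function(values, w = NA_real_, t2star_ms = NA_real_,
                             source = c("model", "roi_mean")) {
  source <- match.arg(source)
  values <- as.double(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values)))
    stop("reference values must be finite, length >= 2", call. = FALSE)
  if (any(values < 0))
    stop("reference values must be nonnegative", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate reference: values have zero variance", call. = FALSE)
  structure(list(values = values, w = w, t2star_ms = t2star_ms,
                 source = source),
            class = "reference_signal")
}

#' @export
print.reference_signal <- function(x, ...) {
  cat(sprintf("<reference_signal> %d echoes, source = %s\n",
              length(x$values), x$source))
  if (identical(x$source, "model"))
    cat(sprintf("  W = %.4g, T2* = %.4g ms\n", x$w, x$t2star_ms))
  invisible(x)
}

#' Generate a model reference signal
#'
#' Evaluates the monoexponential signal model `R_k = W * exp(-TE_k / T2*)`
#' on an echo-time schedule.
#'
#' @param te_ms Strictly ascending echo times in ms.
#' @param w Positive scale `W` (intensity units).
#' @param t2star_ms Positive decay constant in ms.
#' @return A `reference_signal` with `source = "model"`.
#' @examples
#' generate_reference(te_schedule(), w = 100, t2star_ms = 48)
#' @export
generate_reference <- function(te_ms, w, t2star_ms) {
  te_ms <- as.double(te_ms)
  if (length(te_ms) < 2L || any(te_ms <= 0) || any(diff(te_ms) <= 0))
    stop("`te_ms` must be positive, strictly ascending, length >= 2",
         call. = FALSE)
  if (!is.finite(w) || w <= 0)
    stop("`w` must be positive", call. = FALSE)
  if (!is.finite(t2star_ms) || t2star_ms <= 0)
    stop("`t2star_ms` must be positive", call. = FALSE)
  reference_signal(w * exp(-te_ms / t2star_ms),
                   w = w, t2star_ms = t2star_ms, source = "model")
}

#' Reference signal from an ROI mean
#'
#' Averages the decay curves of the pixels selected by a logical mask —
#' the classical manual-ROI reference that the automatic optimizer
#' ([optimize_reference()]) is designed to replace. Provided for comparison.
#'
#' @param stack An [echo_stack()].
#' @param mask Logical matrix of the stack's spatial shape; `TRUE` pixels
#'   form the ROI.
#' @return A `reference_signal` with `source = "roi_mean"`.
#' @export
roi_mean_reference <- function(stack, mask) {
  stopifnot(inherits(stack, "echo_stack"))
  d <- dim(stack$intensities)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("`mask` must be a logical matrix matching the stack's spatial shape",
         call. = FALSE)
  if (!any(mask))
    stop("ROI mask selects no pixels", call. = FALSE)
  m <- .pixel_matrix(stack)
  reference_signal(colMeans(m[as.vector(mask), , drop = FALSE]),
                   source = "roi_mean")
}
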