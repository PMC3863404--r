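#' Parametric map
#'
#' A 2D per-pixel result map tagged with its kind. Invalid pixels (only
#' produced by the T2* fit) are stored as `NA`.
#'
#' @param values Numeric matrix.
#' @param kind One of `"SSM"`, `"FMM"`, `"SCM"`, `"T2STAR"`, `"W"`.
#' @return An object of class `parametric_map` (a matrix with a `kind`
#'   attribute).
#' @export
parametric_map <- function(values, kind = c("SSM", "FMM", "SCM", "T2STAR", "W")) {
  kind <- match.arg(kind)
  if (!is.matrix(values))
    stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("map values must be finite or NA", call. = FALSE)
  structure(values, kind = kind, class = c("parametric_map", "matrix", "array"))
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- as.vector(x)
  cat(sprintf("<parametric_map:%s> %d x %d", map_kind(x), nrow(x), ncol(x)))
  if (anyNA(v)) cat(sprintf(", %d invalid", sum(is.na(v))))
  cat(sprintf(", range [%.4g, %.4g]\n", min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

#' @rdname parametric_map
#' @param map A `parametric_map`.
#' @export
map_kind <- function(map) attr(map, "kind")

.check_fit_inputs <- function(stack, ref) {
  stopifnot(inherits(stack, "echo_stack"), inherits(ref, "reference_signal"))
  if (length(ref$values) != n_echoes(stack))
    stop("reference length (", length(ref$values),
         ") does not match stack echo count (", n_echoes(stack), ")",
         call. = FALSE)
}

#' Fit signal-strength and fluctuation-magnitude maps
#'
#' Per pixel, fits the two-parameter linear model `V_k = lambda * R_k + xi`
#' over the n echoes by ordinary least squares, minimizing
#' `MSE = (1/n) * sum_k (V_k - lambda * R_k - xi)^2`. The closed form is
#' \deqn{\lambda = \frac{\overline{VR} - \bar V \bar R}
#'                      {\overline{R^2} - \bar R^2}, \qquad
#'       \xi = \bar V - \lambda \bar R,}
#' where the overbar is the arithmetic mean over echoes. All `lambda` values
#' form the signal-strength map (SSM) and all `xi` values the
#' fluctuation-magnitude map (FMM). A pixel whose decay equals the reference
#' has `lambda = 1`, `xi = 0`; `lambda` scales with the pixel's relative
#' signal strength and `xi` absorbs the offset (fluctuation) the
#' one-parameter SCM model cannot represent. Negative `lambda` is retained
#' here; clamping for contrast scoring happens in [map_for_contrast()].
#'
#' @param stack An [echo_stack()].
#' @param ref A [reference_signal()] with matching echo count.
#' @return A list with elements `ssm` and `fmm`, each a [parametric_map()].
#' @examples
#' te <- te_schedule()
#' ref <- generate_reference(te, w = 100, t2star_ms = 48)
#' arr <- array(rep(ref$values, each = 4), dim = c(2, 2, 12))
#' fit <- fit_ssm_fmm(echo_stack(arr, te), ref)
#' fit$ssm[1, 1]  # 1: the pixel equals the reference
#' fit$fmm[1, 1]  # 0
#' @export
fit_ssm_fmm <- function(stack, ref) {
  .check_fit_inputs(stack, ref)
  d <- dim(stack$intensities)
  n <- length(ref$values)
  r <- ref$values
  m <- .pixel_matrix(stack)
  vbar <- rowMeans(m)
  vrbar <- as.vector(m %*% r) / n
  rbar <- mean(r)
  denom <- mean(r^2) - rbar^2   # variance of R (population form); > 0 by construction
  lambda <- (vrbar - vbar * rbar) / denom
  xi <- vbar - lambda * rbar
  list(ssm = parametric_map(matrix(lambda, d[1], d[2]), "SSM"),
       fmm = parametric_map(matrix(xi, d[1], d[2]), "FMM"))
}

#' Fit a similarity-coefficient map (baseline)
#'
#' The one-parameter baseline this package's two-parameter model extends:
#' per pixel, the least-squares scale `lambda = sum(V_k R_k) / sum(R_k^2)`
#' minimizing `sum_k (V_k - lambda * R_k)^2`, i.e. the intercept-free
#' special case of [fit_ssm_fmm()].
#'
#' @inheritParams fit_ssm_fmm
#' @return A [parametric_map()] of kind `"SCM"`.
#' @export
fit_scm <- function(stack, ref) {
  .check_fit_inputs(stack, ref)
  r <- ref$values
  if (all(r == 0)) stop("all-zero reference", call. = FALSE)  # unreachable via constructor
  d <- dim(stack$intensities)
  lambda <- as.vector(.pixel_matrix(stack) %*% r) / sum(r^2)
  parametric_map(matrix(lambda, d[1], d[2]), "SCM")
}

#' Fit a T2* map by log-linear regression (baseline)
#'
#' Per pixel, ordinary least squares of `log(V_k)` on `TE_k` over the echoes
#' with `V_k > 0`: the monoexponential model `V = W * exp(-TE / T2*)` gives
#' slope `-1/T2*` and intercept `log W`. Pixels with fewer than two positive
#' echoes, a degenerate TE subset, or a nonpositive fitted decay rate
#' (slope >= 0, i.e. non-decaying signal) are flagged invalid (`NA`).
#'
#' @param stack An [echo_stack()].
#' @return A list with elements `t2star` (kind `"T2STAR"`, ms) and
#'   `w` (kind `"W"`, intensity units), each a [parametric_map()].
#' @export
fit_t2star_map <- function(stack) {
  stopifnot(inherits(stack, "echo_stack"))
  d <- dim(stack$intensities)
  te <- stack$te_ms
  m <- .pixel_matrix(stack)
  pos <- m > 0
  logv <- ifelse(pos, log(pmax(m, .Machine$double.xmin)), 0)
  k <- rowSums(pos)                      # usable echoes per pixel
  sx <- as.vector(pos %*% te)
  sxx <- as.vector(pos %*% te^2)
  sy <- rowSums(logv)
  sxy <- rowSums(logv * rep(te, each = nrow(m)))
  dnm <- k * sxx - sx^2                  # 0 when < 2 distinct TEs usable
  slope <- (k * sxy - sx * sy) / dnm
  intercept <- (sy - slope * sx) / k
  bad <- k < 2 | dnm <= 0 | !is.finite(slope) | slope >= 0
  t2 <- -1 / slope
  w <- exp(intercept)
  t2[bad] <- NA_real_
  w[bad] <- NA_real_
  list(t2star = parametric_map(matrix(t2, d[1], d[2]), "T2STAR"),
       w = parametric_map(matrix(w, d[1], d[2]), "W"))
}

#' Per-pixel residual mean squared error
#'
#' Evaluates `MSE_ij = (1/n) * sum_k (V_ijk - lambda_ij * R_k - xi_ij)^2`
#' for given coefficient maps. At the [fit_ssm_fmm()] optimum this is the
#' minimum over `(lambda, xi)`; with an SCM map and `xi = 0` it scores the
#' nested one-parameter model, which can never beat the two-parameter fit.
#'
#' @inheritParams fit_ssm_fmm
#' @param lambda_map Matrix (or `parametric_map`) of slopes.
#' @param xi_map Matrix of intercepts, or `NULL` / a scalar 0 for the
#'   intercept-free model.
#' @return Numeric matrix of per-pixel MSE values.
#' @export
residual_mse <- function(stack, ref, lambda_map, xi_map = NULL) {
  .check_fit_inputs(stack, ref)
  d <- dim(stack$intensities)
  if (is.null(xi_map)) xi_map <- matrix(0, d[1], d[2])
  if (length(xi_map) == 1L) xi_map <- matrix(as.double(xi_map), d[1], d[2])
  if (!identical(dim(lambda_map)[1:2], d[1:2]) ||
      !identical(dim(xi_map)[1:2], d[1:2]))
    stop("coefficient maps must match the stack's spatial shape", call. = FALSE)
  m <- .pixel_matrix(stack)
  lam <- as.vector(lambda_map)
  xi <- as.vector(xi_map)
  resid <- m - outer(lam, ref$values) - xi
  matrix(rowMeans(resid^2), d[1], d[2])
}
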