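#' Windowed local contrast index
#'
#' No-reference contrast score: for every fully interior `window x window`
#' neighbourhood the local contrast is `|m_f - m_b| / (m_f + m_b)`, with
#' `m_f` the centre pixel (foreground) and `m_b` the mean of the remaining
#' window pixels (background); the index is the mean of the local contrasts
#' over all retained windows. Windows whose denominator is zero, or that
#' contain any invalid (`NA`) pixel, are skipped. Because the score is a
#' ratio it is invariant to rescaling the image, and on nonnegative input
#' it lies in `[0, 1]`.
#'
#' @param image Numeric matrix, nonnegative where valid (`NA` = invalid).
#' @param window Odd window side length, at least 3, smaller than both
#'   image dimensions (default 7).
#' @return A single CI value in `[0, 1]`.
#' @examples
#' img <- matrix(1, 7, 7); img[4, 4] <- 3
#' local_contrast_index(img)  # (3 - 1) / (3 + 1) = 0.5
#' @export
local_contrast_index <- function(image, window = 7L) {
  if (!is.matrix(image)) image <- as.matrix(image)
  storage.mode(image) <- "double"
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (nrow(image) < window || ncol(image) < window)
    stop("image (", nrow(image), " x ", ncol(image),
         ") is smaller than the ", window, " x ", window, " window",
         call. = FALSE)
  if (any(image < 0, na.rm = TRUE))
    stop("image must be nonnegative where valid; transform maps with ",
         "map_for_contrast() first", call. = FALSE)
  if (any(is.infinite(image)))
    stop("image must be finite or NA", call. = FALSE)

  na <- is.na(image)
  x <- ifelse(na, 0, image)
  wsum <- .box_sum(x, window)            # window sums at interior centres
  nacount <- .box_sum(na * 1.0, window)
  half <- (window - 1L) %/% 2L
  centre <- image[(half + 1L):(nrow(image) - half),
                  (half + 1L):(ncol(image) - half), drop = FALSE]
  m_f <- centre
  m_b <- (wsum - ifelse(is.na(centre), 0, centre)) / (window^2 - 1)
  denom <- m_f + m_b
  keep <- nacount == 0 & denom > 0
  if (!any(keep))
    stop("CI undefined: every window is skipped (all-zero or invalid)",
         call. = FALSE)
  mean(abs(m_f[keep] - m_b[keep]) / denom[keep])
}

# dense window sums over all fully interior centres, via an integral image
.box_sum <- function(x, window) {
  ii <- rbind(0, cbind(0, apply(apply(x, 2, cumsum), 1, cumsum)))
  # after the double apply/transpose, ii[r+1, c+1] = sum of x[1:r, 1:c]
  ii <- t(ii)
  nr <- nrow(x); nc <- ncol(x)
  r0 <- 1:(nr - window + 1L); c0 <- 1:(nc - window + 1L)
  ii[r0 + window, c0 + window, drop = FALSE] -
    ii[r0 + window, c0, drop = FALSE] -
    ii[r0, c0 + window, drop = FALSE] +
    ii[r0, c0, drop = FALSE]
}

#' Contrast improvement index
#'
#' Ratio `CII = CI_map / CI_ori` of a derived map's contrast index to that
#' of an original echo image. Values above 1 mean the map shows more local
#' contrast than the echo image it is compared against.
#'
#' @param ci_map CI of the derived map.
#' @param ci_ori CI of the original image; must be positive.
#' @return The CII ratio.
#' @export
contrast_improvement_index <- function(ci_map, ci_ori) {
  stopifnot(is.numeric(ci_map), is.numeric(ci_ori))
  if (any(!is.finite(ci_ori)) || any(ci_ori <= 0))
    stop("`ci_ori` must be positive: CII is undefined for a zero-contrast ",
         "original", call. = FALSE)
  ci_map / ci_ori
}

#' Prepare a parametric map for contrast scoring
#'
#' CI presumes nonnegative luminance, while fitted maps can be signed:
#' SSM/SCM slopes may dip below zero in noise (clamped to 0, consistent with
#' interpreting the slope as a nonnegative signal strength) and the FMM
#' intercept is signed by construction (scored on its magnitude, matching
#' the map's name). T2*/W maps pass through with invalid pixels kept as
#' `NA` so windows touching them are skipped.
#'
#' @param map A [parametric_map()].
#' @return A numeric matrix suitable for [local_contrast_index()].
#' @export
map_for_contrast <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  v <- unclass(map)
  attr(v, "kind") <- NULL
  switch(map_kind(map),
         SSM = ,
         SCM = pmax(v, 0),
         FMM = abs(v),
         v)
}

#' Contrast report for a stack and its derived maps
#'
#' Computes the contrast index of every original echo image and of each
#' supplied map (after [map_for_contrast()]), and the contrast improvement
#' index of every map against every echo. This reproduces the objective
#' evaluation layout: CI per echo (labelled `echo_01` ...), CI per map, and
#' CII ratios with their per-map averages.
#'
#' @param stack An [echo_stack()].
#' @param maps Named list of [parametric_map()] objects (names become
#'   labels; defaults to each map's kind).
#' @param window CI window size (default 7).
#' @param mask_threshold Optional air mask: pixels whose mean intensity
#'   over the echoes falls below this value are treated as invalid in
#'   every image and map, so CI windows touching them are skipped.
#'   Default `NULL` (off): all pixels participate.
#' @return An object of class `contrast_report`: list with data frames
#'   `ci` (columns `label`, `ci`) and `cii` (columns `map`, `original`,
#'   `cii`), plus `mean_cii` (named vector, per-map mean over echoes).
#' @export
contrast_report <- function(stack, maps, window = 7L, mask_threshold = NULL) {
  stopifnot(inherits(stack, "echo_stack"), is.list(maps), length(maps) > 0)
  labels <- names(maps)
  if (is.null(labels) || any(labels == ""))
    labels <- vapply(maps, map_kind, character(1))
  n <- n_echoes(stack)
  d <- dim(stack$intensities)
  air <- matrix(FALSE, d[1], d[2])
  if (!is.null(mask_threshold)) {
    stopifnot(is.finite(mask_threshold))
    air <- matrix(rowMeans(.pixel_matrix(stack)) < mask_threshold, d[1], d[2])
  }
  masked <- function(img) { img[air] <- NA_real_; img }
  echo_labels <- sprintf("echo_%02d", seq_len(n))
  ci_echo <- vapply(seq_len(n), function(k)
    local_contrast_index(masked(stack$intensities[, , k]), window),
    numeric(1))
  ci_map <- vapply(maps, function(m)
    local_contrast_index(masked(map_for_contrast(m)), window), numeric(1))
  ci <- data.frame(label = c(echo_labels, labels),
                   ci = c(ci_echo, ci_map),
                   stringsAsFactors = FALSE)
  cii <- data.frame(
    map = rep(labels, each = n),
    original = rep(echo_labels, times = length(labels)),
    cii = as.vector(vapply(ci_map, contrast_improvement_index,
                           numeric(n), ci_ori = ci_echo)),
    stringsAsFactors = FALSE)
  mean_cii <- tapply(cii$cii, cii$map, mean)[labels]
  structure(list(ci = ci, cii = cii, mean_cii = mean_cii),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("<contrast_report>\n  CI per image:\n")
  for (i in seq_len(nrow(x$ci)))
    cat(sprintf("    %-8s %.4f\n", x$ci$label[i], x$ci$ci[i]))
  cat("  mean CII over echoes:\n")
  for (nm in names(x$mean_cii))
    cat(sprintf("    %-8s %.4f\n", nm, x$mean_cii[[nm]]))
  invisible(x)
}
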