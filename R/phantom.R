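#' Phantom specification
#'
#' Describes a synthetic multiecho acquisition: image shape, tissue regions
#' (each a geometry with its own `W` and T2*), TE schedule, noise model and
#' seed. Regions are painted in order, last wins, over a background with
#' `w = 0`. The seed fully determines the generated stack; there is no
#' dependence on the caller's random state.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param regions List of region descriptors from [region_disk()],
#'   [region_rect()] or [region_line()].
#' @param te_ms Echo-time schedule in ms (default [te_schedule()]).
#' @param noise_model One of `"none"`, `"gaussian"` (additive, clipped at
#'   0) or `"rician"` (magnitude of the clean signal plus complex Gaussian
#'   noise — the noise law of magnitude MR images).
#' @param noise_sigma Noise standard deviation, intensity units.
#' @param seed Integer seed; required.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [vein_phantom_spec()]
#' @export
phantom_spec <- function(shape, regions, te_ms = te_schedule(),
                         noise_model = c("none", "gaussian", "rician"),
                         noise_sigma = 0, seed) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("`seed` is required", call. = FALSE)
  if (!is.list(regions) || length(regions) == 0 ||
      !all(vapply(regions, inherits, logical(1), "phantom_region")))
    stop("`regions` must be a nonempty list of phantom regions", call. = FALSE)
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_model != "none" && noise_sigma == 0)
    noise_model <- "none"
  te_ms <- as.double(te_ms)
  structure(list(shape = shape, regions = regions, te_ms = te_ms,
                 noise_model = noise_model, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.region <- function(geometry, params, w, t2star_ms) {
  if (!is.finite(w) || w < 0) stop("region `w` must be >= 0", call. = FALSE)
  if (!is.finite(t2star_ms) || t2star_ms <= 0)
    stop("region `t2star_ms` must be positive", call. = FALSE)
  structure(list(geometry = geometry, params = params,
                 w = w, t2star_ms = t2star_ms),
            class = "phantom_region")
}

#' Phantom region geometries
#'
#' Building blocks for [phantom_spec()]: a filled disk, an axis-aligned
#' rectangle, and a thick line segment (vessel-like structure). Coordinates
#' are 1-based pixel indices (row, col).
#'
#' @param center,centre `c(row, col)` of the disk centre.
#' @param radius Disk radius in pixels.
#' @param w Region signal scale `W` (intensity units, >= 0).
#' @param t2star_ms Region decay constant in ms (> 0).
#' @return A `phantom_region` descriptor.
#' @name phantom_regions
NULL

#' @rdname phantom_regions
#' @export
region_disk <- function(center, radius, w, t2star_ms)
  .region("disk", list(center = as.double(center), radius = as.double(radius)),
          w, t2star_ms)

#' @rdname phantom_regions
#' @param row_range,col_range Inclusive index ranges `c(from, to)`.
#' @export
region_rect <- function(row_range, col_range, w, t2star_ms)
  .region("rect", list(row_range = as.integer(row_range),
                       col_range = as.integer(col_range)),
          w, t2star_ms)

#' @rdname phantom_regions
#' @param from,to Endpoints `c(row, col)` of the segment.
#' @param thickness Full line thickness in pixels (default 1).
#' @export
region_line <- function(from, to, thickness = 1, w, t2star_ms)
  .region("line", list(from = as.double(from), to = as.double(to),
                       thickness = as.double(thickness)),
          w, t2star_ms)

.region_mask <- function(region, shape) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  p <- region$params
  mask <- switch(region$geometry,
    disk = (rows - p$center[1])^2 + (cols - p$center[2])^2 <= p$radius^2,
    rect = {
      if (any(p$row_range < 1) || any(p$col_range < 1) ||
          p$row_range[2] > shape[1] || p$col_range[2] > shape[2])
        stop("rectangle extends outside the image", call. = FALSE)
      rows >= p$row_range[1] & rows <= p$row_range[2] &
        cols >= p$col_range[1] & cols <= p$col_range[2]
    },
    line = {
      # distance from each pixel centre to the segment
      d <- p$to - p$from
      len2 <- sum(d^2)
      t <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((rows - p$from[1]) * d[1] +
                         (cols - p$from[2]) * d[2]) / len2))
      dist2 <- (rows - (p$from[1] + t * d[1]))^2 +
               (cols - (p$from[2] + t * d[2]))^2
      dist2 <= (p$thickness / 2)^2
    })
  if (!any(mask))
    stop("region `", region$geometry, "` lies entirely outside the image",
         call. = FALSE)
  mask
}

#' Generate a synthetic multiecho phantom
#'
#' Builds per-pixel ground-truth `W` and T2* maps from the region list
#' (painted in order, last wins) and evaluates the clean signal
#' `W * exp(-TE_k / T2*)` at every echo, then adds noise: Gaussian noise is
#' additive `N(0, sigma)` clipped at 0 (intensities are magnitudes), Rician
#' noise is `sqrt((clean + e1)^2 + e2^2)` with independent `N(0, sigma)`
#' components. Generation is bit-reproducible from the spec's seed and
#' leaves the caller's RNG state untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (an [echo_stack()]) and `truth` (class
#'   `phantom_truth`: list of matrices `w_map`, `t2star_map` and integer
#'   `region_labels`, 0 = background).
#' @examples
#' ph <- generate_phantom(vein_phantom_spec(shape = c(32, 32), seed = 1))
#' ph$stack
#' table(ph$truth$region_labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  w_map <- matrix(0, shape[1], shape[2])
  t2_map <- matrix(1, shape[1], shape[2])   # placeholder where w = 0
  labels <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(spec$regions)) {
    reg <- spec$regions[[i]]
    mask <- .region_mask(reg, shape)
    w_map[mask] <- reg$w
    t2_map[mask] <- reg$t2star_ms
    labels[mask] <- i
  }
  n <- length(spec$te_ms)
  clean <- array(0, dim = c(shape, n))
  for (k in seq_len(n))
    clean[, , k] <- w_map * exp(-spec$te_ms[k] / t2_map)

  noisy <- .with_seed(spec$seed, {
    switch(spec$noise_model,
      none = clean,
      gaussian = pmax(clean + stats::rnorm(length(clean),
                                           sd = spec$noise_sigma), 0),
      rician = sqrt((clean + stats::rnorm(length(clean),
                                          sd = spec$noise_sigma))^2 +
                    stats::rnorm(length(clean), sd = spec$noise_sigma)^2))
  })
  dim(noisy) <- c(shape, n)

  list(stack = echo_stack(noisy, spec$te_ms),
       truth = structure(list(w_map = w_map, t2star_map = t2_map,
                              region_labels = labels),
                         class = "phantom_truth"))
}

# evaluate expr under a private RNG state, restoring the caller's afterwards
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default vein phantom
#'
#' The package's standard test object, emulating a T2*-weighted brain
#' slice: a large tissue disk (`W = 100`, T2* = 48 ms) containing two thin
#' fast-decaying vein-like line segments (T2* = 12 ms) and a small
#' slower-decaying nodule, over an air background (`W = 0`), on the
#' 12-echo schedule. Default noise is Rician with sigma 1 (1% of tissue
#' `W`) — the magnitude-image noise law, which matters here: in air it
#' yields strictly positive Rayleigh intensities, the regime in which
#' derived maps can out-contrast the originals.
#'
#' @param shape Image shape (default `c(96, 96)`).
#' @param noise_model,noise_sigma Passed to [phantom_spec()].
#' @param seed Integer seed; required.
#' @return A [phantom_spec()].
#' @export
vein_phantom_spec <- function(shape = c(96, 96),
                              noise_model = "rician", noise_sigma = 1,
                              seed) {
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  rad <- 0.42 * min(shape)
  regions <- list(
    region_disk(ctr, rad, w = 100, t2star_ms = 48),
    region_line(ctr + c(-0.25, -0.28) * shape,
                ctr + c(0.22, 0.10) * shape,
                thickness = max(2, 0.03 * min(shape)),
                w = 110, t2star_ms = 12),
    region_line(ctr + c(0.20, -0.15) * shape,
                ctr + c(-0.05, 0.30) * shape,
                thickness = max(2, 0.02 * min(shape)),
                w = 110, t2star_ms = 12),
    region_disk(ctr + c(-0.18, 0.18) * shape, 0.06 * min(shape),
                w = 80, t2star_ms = 70))
  phantom_spec(shape = shape, regions = regions,
               noise_model = noise_model, noise_sigma = noise_sigma,
               seed = seed)
}
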