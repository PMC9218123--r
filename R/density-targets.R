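#' Gaussian kernel specification for density targets
#'
#' A density target places one unit of mass per colony: the box center is
#' stamped onto an empty map and blurred with a Gaussian kernel. The kernel is
#' truncated at `truncation_radius` and renormalized per colony so each colony
#' contributes exactly unit mass even when clipped at the map edge.
#'
#' In adaptive mode the standard deviation is `0.25 x` the mean box side at
#' target resolution, floored at 0.4 px; the floor keeps an isolated kernel's
#' peak `1/(2*pi*sigma^2) <= 1` so the map remains a valid per-pixel
#' probability for the cross-entropy loss.
#'
#' @param sigma_blur Gaussian standard deviation in pixels (ignored when
#'   `adaptive = TRUE` and an annotation is available to resolve it).
#' @param truncation_radius kernel support radius in pixels; default
#'   `4 * sigma`, and at least `3 * sigma` is required.
#' @param adaptive resolve sigma from the annotation's mean box side?
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma_blur = NULL, truncation_radius = NULL,
                        adaptive = is.null(sigma_blur)) {
  if (!is.null(sigma_blur)) {
    assert_scalar_number(sigma_blur, "sigma_blur", lower = 0.4)
    if (!is.null(truncation_radius) && truncation_radius < 3 * sigma_blur) {
      stop_sndm("`truncation_radius` must be at least 3 * sigma_blur")
    }
  }
  structure(list(sigma_blur = sigma_blur, truncation_radius = truncation_radius,
                 adaptive = isTRUE(adaptive)),
            class = "kernel_spec")
}

resolve_sigma <- function(kernel, annotation, target_shape) {
  if (!kernel$adaptive) return(kernel$sigma_blur)
  b <- annotation$boxes
  if (nrow(b) == 0L) return(max(0.4, kernel$sigma_blur %||% 1))
  sy <- target_shape[1] / annotation$geometry$image_height
  sx <- target_shape[2] / annotation$geometry$image_width
  mean_side <- mean(((b$x_max - b$x_min) * sx + (b$y_max - b$y_min) * sy) / 2)
  max(0.4, 0.25 * mean_side)
}

#' Colony centers from bounding boxes
#'
#' The colony center is the bounding-box midpoint, rescaled from annotation
#' resolution to the density-map resolution. Coordinates are 0-based
#' `(row, col)` reals on the target grid; order follows the box order.
#'
#' @param annotation a `colony_annotation`.
#' @param target_shape integer `(H_t, W_t)` of the density map.
#' @return a two-column matrix `(row, col)` with one row per box.
#' @export
centers_from_bboxes <- function(annotation, target_shape) {
  stopifnot(inherits(annotation, "colony_annotation"))
  if (any(target_shape < 1)) stop_sndm("`target_shape` must be positive")
  g <- annotation$geometry
  b <- annotation$boxes
  if (nrow(b) > 0L &&
      (any(b$x_min < 0) || any(b$y_min < 0) ||
       any(b$x_max > g$image_width) || any(b$y_max > g$image_height))) {
    stop_sndm("invalid annotation: box outside image bounds")
  }
  sy <- target_shape[1] / g$image_height
  sx <- target_shape[2] / g$image_width
  cbind(row = (b$y_min + b$y_max) / 2 * sy,
        col = (b$x_min + b$x_max) / 2 * sx)
}

# Unit-mass truncated Gaussian stamped at one (row, col) center; returns the
# indices and values to add. Renormalized over the in-map truncated support.
stamp_kernel <- function(center, shape, sigma, trunc_r) {
  r0 <- max(0L, floor(center[1] - trunc_r)); r1 <- min(shape[1] - 1L, ceiling(center[1] + trunc_r))
  c0 <- max(0L, floor(center[2] - trunc_r)); c1 <- min(shape[2] - 1L, ceiling(center[2] + trunc_r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, `+`)
  val <- exp(-d2 / (2 * sigma^2))
  val[d2 > trunc_r^2] <- 0
  s <- sum(val)
  if (s <= 0) stop_sndm("kernel support empty; center too far outside the map")
  list(rows = rows + 1L, cols = cols + 1L, val = val / s)
}

#' Render a ground-truth density map from colony centers
#'
#' Each center contributes a truncated Gaussian kernel renormalized to unit
#' mass (after truncation and edge clipping), so the pixel sum of the map
#' equals the number of centers exactly up to float tolerance. Rendering is
#' additive, hence superposition holds: rendering the union of two center
#' sets equals the pixelwise sum of rendering each.
#'
#' @param centers two-column matrix of `(row, col)` 0-based centers (as from
#'   [centers_from_bboxes()]).
#' @param target_shape integer `(H_t, W_t)`.
#' @param kernel a [kernel_spec()] with a resolved `sigma_blur`.
#' @return object of class `density_target`: `map` (matrix), `count`,
#'   `sigma`, `scale_factor`.
#' @export
render_density_target <- function(centers, target_shape, kernel = kernel_spec(1)) {
  if (is.null(centers)) centers <- matrix(numeric(), 0, 2)
  centers <- as.matrix(centers)
  if (ncol(centers) == 0L) centers <- matrix(numeric(), 0, 2)
  sigma <- kernel$sigma_blur
  if (is.null(sigma)) stop_sndm("kernel sigma unresolved; give `sigma_blur` or use density_target_from_annotation()")
  trunc_r <- kernel$truncation_radius %||% (4 * sigma)
  if (trunc_r < 3 * sigma) stop_sndm("`truncation_radius` must be at least 3 * sigma_blur")
  map <- matrix(0, target_shape[1], target_shape[2])
  n <- nrow(centers)
  if (n > 0L) {
    if (any(centers[, 1] < 0) || any(centers[, 1] > target_shape[1] - 1) ||
        any(centers[, 2] < 0) || any(centers[, 2] > target_shape[2] - 1)) {
      stop_sndm("center outside the target map")
    }
    for (i in seq_len(n)) {
      st <- stamp_kernel(centers[i, ], target_shape, sigma, trunc_r)
      map[st$rows, st$cols] <- map[st$rows, st$cols] + st$val
    }
  }
  structure(list(map = map, count = as.numeric(n), sigma = sigma,
                 scale_factor = 1),
            class = "density_target")
}

#' Density target straight from an annotation
#'
#' Convenience composition of [centers_from_bboxes()] and
#' [render_density_target()], resolving an adaptive kernel sigma from the
#' mean box side when requested.
#'
#' @inheritParams centers_from_bboxes
#' @param kernel a [kernel_spec()].
#' @return a `density_target`; its `scale_factor` records the ratio of
#'   annotation to target resolution.
#' @export
density_target_from_annotation <- function(annotation, target_shape,
                                           kernel = kernel_spec()) {
  sigma <- resolve_sigma(kernel, annotation, target_shape)
  k <- kernel_spec(sigma_blur = sigma, truncation_radius = kernel$truncation_radius,
                   adaptive = FALSE)
  ctr <- centers_from_bboxes(annotation, target_shape)
  out <- render_density_target(ctr, target_shape, k)
  out$scale_factor <- annotation$geometry$image_height / target_shape[1]
  out
}

#' @export
print.density_target <- function(x, ...) {
  cat(sprintf("<density_target> %dx%d, count %.6f, sigma %.2f px\n",
              nrow(x$map), ncol(x$map), x$count, x$sigma))
  invisible(x)
}

#' Read a count off a density map
#'
#' The total number of objects is the sum over all pixels of the density map.
#' Works for ground-truth targets and for predicted maps alike.
#'
#' @param map numeric matrix with non-negative entries, or a
#'   `density_target`.
#' @return the scalar pixel sum.
#' @export
count_from_map <- function(map) {
  if (inherits(map, "density_target")) map <- map$map
  if (any(map < 0)) stop_sndm("density map entries must be non-negative")
  sum(map)
}

#' Read / write density maps as 32-bit float TIFF
#'
#' Maps are stored one per file; the convention for ground-truth targets is
#' `<image_id>.target.tiff`. TIFF sample values live in `[0, 1]`, but target
#' pixels can exceed 1 where colonies overlap; such maps are stored divided
#' by their maximum, with the scale recorded in a `<path>.scale.json`
#' sidecar that `read_density_map()` applies transparently.
#'
#' @param map numeric matrix (or `density_target`).
#' @param path TIFF file path.
#' @return `read_density_map()` returns a numeric matrix.
#' @export
write_density_map <- function(map, path) {
  if (inherits(map, "density_target")) map <- map$map
  scale <- max(1, max(map))
  tiff::writeTIFF(map / scale, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(path, ".scale.json")
  if (scale > 1) {
    jsonlite::write_json(list(scale = scale), sidecar, auto_unbox = TRUE,
                         digits = NA)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  sidecar <- paste0(path, ".scale.json")
  if (file.exists(sidecar)) {
    m <- m * jsonlite::read_json(sidecar)$scale
  }
  m
}

#' Loss view of a density target
#'
#' Binary cross entropy needs targets inside `[0, 1]`; overlapping colonies
#' can push density-target pixels above 1 (superposed kernels). `loss_view()`
#' clips the map to `[eps, 1 - eps]` for use inside the loss only; counts are
#' always computed on the unclipped map, which retains conservation. A warning
#' is emitted whenever clipping actually truncated a pixel above `1 - eps`.
#'
#' @param target a `density_target` (or bare matrix).
#' @param eps clipping margin in `(0, 0.5)`.
#' @return matrix with entries in `[eps, 1 - eps]`.
#' @export
loss_view <- function(target, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5) {
    stop_sndm("`eps` must lie in (0, 0.5)")
  }
  m <- if (inherits(target, "density_target")) target$map else target
  if (any(m > 1 - eps)) {
    rlang::warn(sprintf(
      "%d density-target pixel(s) exceed 1 - eps (overlapping colonies); clipped for the loss",
      sum(m > 1 - eps)), class = "sndm_clip_warning")
  }
  m[] <- pmin(1 - eps, pmax(eps, m))
  m
}
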