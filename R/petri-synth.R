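#' Count distributions for synthetic dishes
#'
#' Annotated colony-counting collections are dominated by sparsely populated
#' dishes: most images carry fewer than 50 colonies and a sizeable fraction are
#' empty, while crowded plates up to 100 colonies form a thin tail.
#' `count_mixture()` reproduces that shape as an explicit two-component
#' mixture: with probability `p_low` the count is drawn from a negative
#' binomial truncated to `[0, low_max]`, otherwise uniformly from
#' `[low_max + 1, max_count]`. `count_nbinom()` is a single truncated negative
#' binomial, convenient for heavy-tailed-toward-zero designs.
#'
#' @param p_low probability mass assigned to the sparse component
#'   (`count <= low_max`); the default 0.85 mirrors typical plate collections.
#' @param low_max largest count of the sparse component (default 49, so the
#'   sparse component is "fewer than 50 colonies").
#' @param max_count hard upper bound on the modeled count (default 100).
#' @param mu,size negative-binomial mean and dispersion of the sparse
#'   component.
#' @return an object of class `count_dist`.
#' @export
count_mixture <- function(p_low = 0.85, low_max = 49L, max_count = 100L,
                          mu = 15, size = 1.6) {
  assert_scalar_number(p_low, "p_low", 0, 1)
  if (low_max >= max_count) stop_sndm("`low_max` must be below `max_count`")
  structure(list(type = "mixture", p_low = p_low, low_max = as.integer(low_max),
                 max_count = as.integer(max_count), mu = mu, size = size),
            class = "count_dist")
}

#' @rdname count_mixture
#' @export
count_nbinom <- function(mu = 15, size = 1, max_count = 100L) {
  structure(list(type = "nbinom", mu = mu, size = size,
                 max_count = as.integer(max_count)),
            class = "count_dist")
}

# Draw from a negative binomial truncated to [0, max] by inverse-cdf on the
# renormalized probability table (exact, vectorized).
rnbinom_trunc <- function(n, mu, size, max) {
  p <- stats::dnbinom(0:max, size = size, mu = mu)
  sample(0:max, n, replace = TRUE, prob = p / sum(p))
}

#' Sample colony counts from a count distribution
#'
#' @param dist a [count_mixture()] / [count_nbinom()] object.
#' @param n number of draws.
#' @param seed optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return integer vector of length `n`, each in `[0, max_count]`.
#' @export
sample_counts <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "count_dist"))
  with_seed(seed, {
    if (dist$type == "mixture") {
      low <- stats::runif(n) < dist$p_low
      out <- integer(n)
      if (any(low)) {
        out[low] <- rnbinom_trunc(sum(low), dist$mu, dist$size, dist$low_max)
      }
      if (any(!low)) {
        out[!low] <- sample((dist$low_max + 1L):dist$max_count, sum(!low),
                            replace = TRUE)
      }
      out
    } else {
      rnbinom_trunc(n, dist$mu, dist$size, dist$max_count)
    }
  })
}

#' Parameters of the synthetic Petri-dish scene generator
#'
#' Defines the study conditions emulated by the generator: a circular dish on
#' a dark background, 0--100 colonies per image with most dishes carrying
#' fewer than 50, colony radii spread over a log-normal (so dishes mix small
#' and large colonies), colonies allowed to overlap and to sit near the dish
#' edge, and three illumination setups.
#'
#' @param image_size side length of the square RGB image, in pixels.
#' @param count_distribution a [count_mixture()]-style object.
#' @param radius_meanlog,radius_sdlog log-normal parameters of the colony
#'   radius in pixels (defaults give radii of roughly 2--5 px at 96 px dishes;
#'   radii scale with `image_size / 96` so scenes look alike across sizes).
#' @param illumination one of `"uniform"`, `"gradient"`, `"vignette"`, or
#'   `"random"` to draw one of the three per scene.
#' @param overlap_allowed may colony disks overlap each other?
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed attached to the parameter set; [generate_scene()]
#'   uses it unless an explicit seed is passed.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_size = 96L,
                         count_distribution = count_mixture(),
                         radius_meanlog = log(3), radius_sdlog = 0.3,
                         illumination = "random",
                         overlap_allowed = TRUE,
                         noise_sd = 0.01,
                         seed = 1L) {
  if (image_size < 32) stop_sndm("`image_size` must be at least 32 px")
  illumination <- match.arg(illumination,
                            c("random", "uniform", "gradient", "vignette"))
  stopifnot(inherits(count_distribution, "count_dist"))
  assert_scalar_number(radius_sdlog, "radius_sdlog", 0, 2)
  structure(list(image_size = as.integer(image_size),
                 count_distribution = count_distribution,
                 radius_meanlog = radius_meanlog,
                 radius_sdlog = radius_sdlog,
                 illumination = illumination,
                 overlap_allowed = isTRUE(overlap_allowed),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_params")
}

new_dish_geometry <- function(image_width, image_height, cx, cy, r) {
  if (r <= 0) stop_sndm("dish radius must be positive")
  if (cx - r < 0 || cy - r < 0 || cx + r > image_width - 1 ||
      cy + r > image_height - 1) {
    stop_sndm("dish circle must lie fully inside the image bounds")
  }
  list(image_width = as.integer(image_width),
       image_height = as.integer(image_height),
       dish_center_x = cx, dish_center_y = cy, dish_radius = r)
}

#' Construct a colony annotation
#'
#' Bounding boxes use 0-based pixel coordinates and half-open intervals
#' `[x_min, x_max) x [y_min, y_max)`; the colony center is taken to be the box
#' midpoint. Every box center must lie inside the dish circle.
#'
#' @param image_id character id of the image.
#' @param geometry dish geometry list (image size, dish center and radius).
#' @param boxes tibble/data frame with columns `x_min, y_min, x_max, y_max`
#'   and optionally `label`.
#' @return an object of class `colony_annotation`.
#' @export
colony_annotation <- function(image_id, geometry, boxes = NULL) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- tibble::tibble(x_min = numeric(), y_min = numeric(),
                            x_max = numeric(), y_max = numeric(),
                            label = character())
  } else {
    boxes <- tibble::as_tibble(boxes)
    if (!"label" %in% names(boxes)) boxes$label <- NA_character_
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
      stop_sndm("every box must satisfy x_min < x_max and y_min < y_max")
    }
    cx <- (boxes$x_min + boxes$x_max) / 2
    cy <- (boxes$y_min + boxes$y_max) / 2
    d2 <- (cx - geometry$dish_center_x)^2 + (cy - geometry$dish_center_y)^2
    if (any(d2 >= geometry$dish_radius^2)) {
      stop_sndm("every box center must lie inside the dish circle")
    }
  }
  structure(list(image_id = as.character(image_id), geometry = geometry,
                 boxes = boxes),
            class = "colony_annotation")
}

#' @export
print.colony_annotation <- function(x, ...) {
  cat(sprintf("<colony_annotation> %s: %d boxes, %dx%d px, dish r=%.1f\n",
              x$image_id, nrow(x$boxes), x$geometry$image_width,
              x$geometry$image_height, x$geometry$dish_radius))
  invisible(x)
}

#' Number of annotated colonies
#' @param annotation a `colony_annotation`.
#' @return integer count (number of boxes).
#' @export
annotation_count <- function(annotation) {
  stopifnot(inherits(annotation, "colony_annotation"))
  nrow(annotation$boxes)
}

# Background illumination field (H x W), multiplicative around 1.
illumination_field <- function(size, mode) {
  xs <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  ys <- matrix(rep(seq_len(size) - 1, times = size), size, size)
  switch(mode,
    uniform = matrix(1, size, size),
    gradient = {
      theta <- stats::runif(1, 0, 2 * pi)
      proj <- (cos(theta) * xs + sin(theta) * ys) / size
      1 + 0.25 * (proj - mean(proj))
    },
    vignette = {
      c0 <- (size - 1) / 2
      d <- sqrt((xs - c0)^2 + (ys - c0)^2) / (size / 2)
      1.08 - 0.3 * d^2
    })
}

# Draw colony centers (0-based x, y) and radii inside the dish.
draw_colonies <- function(n, geom, params) {
  scale <- params$image_size / 96
  r <- pmax(0.8, stats::rlnorm(n, params$radius_meanlog, params$radius_sdlog) *
              scale)
  cx <- numeric(n); cy <- numeric(n)
  max_tries <- 200L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      # uniform in the disk; cap the placement radius 1 px inside the rim so
      # the box midpoint (quantized by floor/ceil, +-0.5 px per axis) stays
      # strictly inside the dish circle while colonies still touch the edge
      rho <- (geom$dish_radius - 1) * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      x <- geom$dish_center_x + rho * cos(ang)
      y <- geom$dish_center_y + rho * sin(ang)
      if (!params$overlap_allowed && i > 1L) {
        if (any(sqrt((x - cx[seq_len(i - 1)])^2 + (y - cy[seq_len(i - 1)])^2) <
                r[i] + r[seq_len(i - 1)])) next
      }
      cx[i] <- x; cy[i] <- y; ok <- TRUE
      break
    }
    if (!ok) stop_sndm("could not place colony %d without overlap", i)
  }
  list(cx = cx, cy = cy, r = r)
}

#' Generate one synthetic Petri-dish scene
#'
#' Renders an RGB image of a circular dish with soft-edged colony blobs plus
#' an illumination background and additive Gaussian noise, together with its
#' bounding-box annotation, the dish coverage fraction and the mean colony
#' size. Identical parameters and seed reproduce the scene bit-exactly.
#'
#' @param params a [scene_params()] object.
#' @param count_override optional fixed colony count in `[0, 100]`; when
#'   `NULL` the count is drawn from `params$count_distribution`.
#' @param seed integer seed; defaults to `params$seed`.
#' @return an object of class `petri_scene` with fields `image`
#'   (`H x W x 3` array in `[0, 1]`), `annotation`, `coverage` (fraction of the
#'   dish interior covered by colonies) and `mean_colony_size` (`NA` for an
#'   empty dish).
#' @export
generate_scene <- function(params, count_override = NULL, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(count_override)) {
    if (count_override < 0 || count_override > 100) {
      stop_sndm("count out of modeled range (0-100): %s", count_override)
    }
  }
  with_seed(seed, {
    size <- params$image_size
    c0 <- (size - 1) / 2
    geom <- new_dish_geometry(size, size, c0, c0, 0.46 * size)
    n <- if (is.null(count_override)) {
      sample_counts(params$count_distribution, 1L)
    } else {
      as.integer(count_override)
    }
    mode <- if (params$illumination == "random") {
      sample(c("uniform", "gradient", "vignette"), 1L)
    } else {
      params$illumination
    }

    xs <- matrix(rep(seq_len(size) - 1, each = size), size, size)  # x varies by col
    ys <- matrix(rep(seq_len(size) - 1, times = size), size, size) # y varies by row
    dish_d <- sqrt((xs - geom$dish_center_x)^2 + (ys - geom$dish_center_y)^2)
    inside <- dish_d <= geom$dish_radius
    rim <- dish_d > geom$dish_radius & dish_d <= geom$dish_radius + 1.5

    illum <- illumination_field(size, mode)
    agar <- c(0.52, 0.44, 0.32)
    outside_col <- c(0.10, 0.10, 0.11)
    colony_col <- c(0.88, 0.84, 0.72)

    blob <- matrix(0, size, size)  # colony opacity field in [0, 1]
    mask <- matrix(FALSE, size, size)
    ann_boxes <- NULL
    if (n > 0L) {
      col_par <- draw_colonies(n, geom, params)
      amp <- stats::runif(n, 0.85, 1)
      edge <- pmax(0.5, 0.18 * col_par$r)
      for (i in seq_len(n)) {
        r <- col_par$r[i]
        x0 <- max(0, floor(col_par$cx[i] - r - 3 * edge[i]))
        x1 <- min(size - 1, ceiling(col_par$cx[i] + r + 3 * edge[i]))
        y0 <- max(0, floor(col_par$cy[i] - r - 3 * edge[i]))
        y1 <- min(size - 1, ceiling(col_par$cy[i] + r + 3 * edge[i]))
        rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
        d <- sqrt(outer((y0:y1) - col_par$cy[i], (x0:x1) - col_par$cx[i],
                        function(a, b) a^2 + b^2))
        prof <- amp[i] / (1 + exp((d - r) / edge[i]))
        blob[rows, cols] <- pmax(blob[rows, cols], prof)
        mask[rows, cols] <- mask[rows, cols] | (d <= r)
      }
      ann_boxes <- tibble::tibble(
        x_min = pmax(0, floor(col_par$cx - col_par$r)),
        y_min = pmax(0, floor(col_par$cy - col_par$r)),
        x_max = pmin(size, ceiling(col_par$cx + col_par$r)),
        y_max = pmin(size, ceiling(col_par$cy + col_par$r)),
        label = "colony")
    }

    img <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      base <- matrix(outside_col[ch], size, size)
      base[inside] <- (agar[ch] * illum[inside])
      base[rim] <- 0.75
      plane <- base * (1 - blob) + colony_col[ch] * blob * illum
      plane <- plane + stats::rnorm(size * size, 0, params$noise_sd)
      img[, , ch] <- pmin(1, pmax(0, plane))
    }

    ann <- colony_annotation(
      image_id = sprintf("scene_seed%s_n%d", format(seed), n),
      geometry = geom, boxes = ann_boxes)
    structure(list(image = img, annotation = ann,
                   coverage = sum(mask & inside) / sum(inside),
                   mean_colony_size = mean_colony_size(ann),
                   illumination = mode, seed = seed),
              class = "petri_scene")
  })
}

#' @export
print.petri_scene <- function(x, ...) {
  cat(sprintf("<petri_scene> %d colonies, %dx%d px, coverage %.3f, illum %s\n",
              annotation_count(x$annotation), dim(x$image)[1], dim(x$image)[2],
              x$coverage, x$illumination))
  invisible(x)
}

#' Mean colony size of an annotation
#'
#' The mean over boxes of the equivalent diameter `sqrt(width * height)`, in
#' pixels. An empty annotation has no defined colony size and returns
#' `NA_real_` (never silently 0).
#'
#' @param annotation a `colony_annotation`.
#' @return mean equivalent diameter in pixels, or `NA_real_` if no boxes.
#' @export
mean_colony_size <- function(annotation) {
  stopifnot(inherits(annotation, "colony_annotation"))
  b <- annotation$boxes
  if (nrow(b) == 0L) return(NA_real_)
  mean(sqrt((b$x_max - b$x_min) * (b$y_max - b$y_min)))
}

#' Dish coverage fraction
#'
#' Fraction of the dish interior covered by the colony mask: true mask pixels
#' inside the dish circle divided by all pixels inside the dish circle.
#'
#' @param annotation a `colony_annotation` carrying the dish geometry.
#' @param colony_mask logical matrix of the same shape as the image, `TRUE`
#'   where a colony covers the pixel.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage_factor <- function(annotation, colony_mask) {
  stopifnot(inherits(annotation, "colony_annotation"))
  g <- annotation$geometry
  if (g$dish_radius <= 0) stop_sndm("coverage undefined for a zero-radius dish")
  if (!is.logical(colony_mask) ||
      !all(dim(colony_mask) == c(g$image_height, g$image_width))) {
    stop_sndm("`colony_mask` must be a logical image-shaped matrix")
  }
  xs <- matrix(rep(seq_len(g$image_width) - 1, each = g$image_height),
               g$image_height, g$image_width)
  ys <- matrix(rep(seq_len(g$image_height) - 1, times = g$image_width),
               g$image_height, g$image_width)
  inside <- (xs - g$dish_center_x)^2 + (ys - g$dish_center_y)^2 <=
    g$dish_radius^2
  sum(colony_mask & inside) / sum(inside)
}

annotation_to_list <- function(ann, file = NA_character_) {
  g <- ann$geometry
  list(id = ann$image_id, file = file,
       width = g$image_width, height = g$image_height,
       dish = list(cx = g$dish_center_x, cy = g$dish_center_y,
                   r = g$dish_radius),
       colonies = if (nrow(ann$boxes) == 0L) list() else
         purrr::pmap(ann$boxes, function(x_min, y_min, x_max, y_max, label) {
           list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                label = label)
         }))
}

#' Read / write colony annotations (JSON)
#'
#' The on-disk schema is a single JSON file
#' `{"images": [{"id","file","width","height","dish":{"cx","cy","r"},
#' "colonies":[{"x_min","y_min","x_max","y_max","label"}]}]}`.
#'
#' @param annotations list of `colony_annotation` objects.
#' @param path file path.
#' @param files optional character vector of image file names, parallel to
#'   `annotations`.
#' @return `read_annotations()` returns a named list of `colony_annotation`.
#' @export
write_annotations <- function(annotations, path, files = NULL) {
  if (inherits(annotations, "colony_annotation")) annotations <- list(annotations)
  files <- files %||% rep(NA_character_, length(annotations))
  obj <- list(images = purrr::map2(annotations, files, annotation_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path)
  anns <- purrr::map(obj$images, function(im) {
    geom <- new_dish_geometry(im$width, im$height, im$dish$cx, im$dish$cy,
                              im$dish$r)
    boxes <- if (length(im$colonies) == 0L) NULL else
      purrr::map_dfr(im$colonies, function(b) {
        tibble::tibble(x_min = b$x_min, y_min = b$y_min, x_max = b$x_max,
                       y_max = b$y_max,
                       label = b$label %||% NA_character_)
      })
    ann <- colony_annotation(im$id, geom, boxes)
    attr(ann, "file") <- im$file
    ann
  })
  names(anns) <- purrr::map_chr(obj$images, "id")
  anns
}

#' Generate and write a synthetic annotated dataset
#'
#' Renders `n_images` scenes, writes them as 8-bit RGB PNGs plus one
#' `annotations.json`, and writes a `manifest.json` assigning images to
#' train/validation/test splits (default proportions 8:1:1).
#'
#' @param n_images number of scenes (>= 1).
#' @param params a [scene_params()] object.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-image seeds are derived from it.
#' @param split named fractions for train/val/test (must sum to 1).
#' @return invisibly, the manifest: a list with `images` (tibble of id, file,
#'   count, split) and `split_fractions`.
#' @export
generate_dataset <- function(n_images, params, out_dir, seed = params$seed,
                             split = c(train = 0.8, val = 0.1, test = 0.1)) {
  if (n_images < 1) stop_sndm("`n_images` must be >= 1")
  if (abs(sum(split) - 1) > 1e-8) stop_sndm("split fractions must sum to 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_sndm("cannot create output dir %s", out_dir)
  seeds <- derive_seeds(seed, n_images)
  anns <- vector("list", n_images)
  files <- character(n_images)
  counts <- integer(n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(params, seed = seeds[i])
    id <- sprintf("scene_%05d", i)
    sc$annotation$image_id <- id
    files[i] <- paste0(id, ".png")
    counts[i] <- annotation_count(sc$annotation)
    png::writePNG(sc$image, file.path(out_dir, files[i]))
    anns[[i]] <- sc$annotation
  }
  write_annotations(anns, file.path(out_dir, "annotations.json"), files = files)

  n_val <- round(split[["val"]] * n_images)
  n_test <- round(split[["test"]] * n_images)
  idx <- with_seed(seeds[1], sample.int(n_images))
  assign_split <- rep("train", n_images)
  assign_split[idx[seq_len(n_val)]] <- "val"
  if (n_test > 0) assign_split[idx[n_val + seq_len(n_test)]] <- "test"
  manifest <- list(
    images = tibble::tibble(id = sprintf("scene_%05d", seq_len(n_images)),
                            file = files, count = counts, split = assign_split),
    split_fractions = as.list(split))
  jsonlite::write_json(
    list(split_fractions = as.list(split),
         train = manifest$images$id[assign_split == "train"],
         val = manifest$images$id[assign_split == "val"],
         test = manifest$images$id[assign_split == "test"]),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a generated dataset back into memory
#'
#' @param dir directory written by [generate_dataset()].
#' @return list with `annotations` (named list), `images` (named list of
#'   arrays) and `manifest` (parsed manifest.json).
#' @export
read_dataset <- function(dir) {
  anns <- read_annotations(file.path(dir, "annotations.json"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  imgs <- purrr::map(anns, function(a) {
    f <- attr(a, "file")
    img <- png::readPNG(file.path(dir, f))
    img
  })
  list(annotations = anns, images = imgs, manifest = manifest)
}
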