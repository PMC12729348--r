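#' Specification of a synthetic ultrasound phantom
#'
#' Describes the geometry and appearance of a speckle-textured phantom with a
#' single hypoechoic nerve cross-section. The `wrist` default places a larger
#' nerve superficially (cross-sectional area 9.8 +/- 2.4 mm^2, the reference
#' range for the median nerve at the wrist crease); the `forearm` default
#' places a smaller nerve deeper (6.0 +/- 1.5 mm^2, matching the magnitude of
#' manual forearm measurements). Intensities live in \[0, 1\] and are
#' quantized to 8 bits only at I/O.
#'
#' @param site "wrist" or "forearm"; selects depth range, area distribution
#'   and band layout defaults.
#' @param image_height,image_width canvas size in pixels (the pre-padding
#'   acquisition geometry; the desk-scale default is 128 x 87).
#' @param pixel_spacing isotropic calibration in mm/pixel (default 0.1).
#' @param nerve_csa_mean,nerve_csa_sd nerve area distribution in mm^2.
#' @param nerve_depth_range ordered fraction of image height for the nerve
#'   center.
#' @param nerve_aspect_range ellipse major/minor axis ratio bounds.
#' @param boundary_irregularity amplitude of the low-order radial Fourier
#'   perturbation (fraction of local radius).
#' @param nerve_echo_level interior intensity (hypoechoic, dark).
#' @param rim_echo_level epineurial rim intensity (hyperechoic, bright).
#' @param background_bands number of horizontal tissue layers.
#' @param speckle_grain correlation length of the multiplicative speckle
#'   texture, pixels.
#' @param speckle_contrast contrast of the speckle texture (0 disables it).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(site = c("wrist", "forearm"),
                         image_height = 128L, image_width = 87L,
                         pixel_spacing = 0.1,
                         nerve_csa_mean = NULL, nerve_csa_sd = NULL,
                         nerve_depth_range = NULL,
                         nerve_aspect_range = c(1.2, 2.2),
                         boundary_irregularity = 0.15,
                         nerve_echo_level = 0.18,
                         rim_echo_level = 0.8,
                         background_bands = NULL,
                         speckle_grain = 2,
                         speckle_contrast = 0.35) {
  site <- match.arg(site)
  if (is.null(nerve_csa_mean))
    nerve_csa_mean <- if (site == "wrist") 9.8 else 6.0
  if (is.null(nerve_csa_sd))
    nerve_csa_sd <- if (site == "wrist") 2.4 else 1.5
  if (is.null(nerve_depth_range))
    nerve_depth_range <- if (site == "wrist") c(0.22, 0.42) else c(0.5, 0.72)
  if (is.null(background_bands))
    background_bands <- if (site == "wrist") 3L else 4L
  stopifnot(nerve_csa_mean > 0, nerve_csa_sd >= 0, pixel_spacing > 0,
            length(nerve_depth_range) == 2,
            all(nerve_depth_range >= 0), all(nerve_depth_range <= 1),
            nerve_depth_range[1] <= nerve_depth_range[2],
            all(nerve_aspect_range >= 1), boundary_irregularity >= 0,
            background_bands >= 1, speckle_grain > 0, speckle_contrast >= 0)
  structure(list(site = site, image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 pixel_spacing = pixel_spacing,
                 nerve_csa_mean = nerve_csa_mean, nerve_csa_sd = nerve_csa_sd,
                 nerve_depth_range = nerve_depth_range,
                 nerve_aspect_range = nerve_aspect_range,
                 boundary_irregularity = boundary_irregularity,
                 nerve_echo_level = nerve_echo_level,
                 rim_echo_level = rim_echo_level,
                 background_bands = as.integer(background_bands),
                 speckle_grain = speckle_grain,
                 speckle_contrast = speckle_contrast),
            class = "phantom_spec")
}

#' Simulated human rater
#'
#' Models an imperfect manual tracing as an independent radial Gaussian
#' perturbation of each boundary vertex: displacement ~
#' Normal(boundary_bias, vertex_jitter_sd) in mm along the ray from the
#' nerve centroid. A positive bias over-traces (larger areas), a negative
#' bias under-traces.
#'
#' @param vertex_jitter_sd radial jitter SD in mm (>= 0).
#' @param boundary_bias systematic radial offset in mm (may be negative).
#' @return an object of class `rater_model`.
#' @export
rater_model <- function(vertex_jitter_sd = 0.05, boundary_bias = 0) {
  stopifnot(vertex_jitter_sd >= 0)
  structure(list(vertex_jitter_sd = vertex_jitter_sd,
                 boundary_bias = boundary_bias),
            class = "rater_model")
}

#' Sample a nerve cross-section geometry
#'
#' Draws a target area from Normal(nerve_csa_mean, nerve_csa_sd) truncated at
#' 0.5 mm^2 and an aspect ratio from `nerve_aspect_range`, builds an ellipse
#' perturbed radially by a low-order Fourier series with amplitude
#' `boundary_irregularity`, rescales the polygon so its shoelace area equals
#' the drawn area exactly, and places it at a depth drawn from
#' `nerve_depth_range`. Geometries that do not fit inside the canvas are
#' rejected and resampled (at most 100 tries).
#'
#' @param spec a [phantom_spec]. Randomness comes from R's RNG stream.
#' @param n_vertices polygon resolution (default 48).
#' @return an object of class `nerve_geometry`: list(center, polygon,
#'   true_area) with polygon in 0-based pixel coordinates and true_area in
#'   mm^2.
#' @export
sample_nerve_geometry <- function(spec, n_vertices = 48L) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height; w <- spec$image_width; ps <- spec$pixel_spacing
  margin <- 3
  for (try in seq_len(100L)) {
    repeat {
      area_mm2 <- stats::rnorm(1, spec$nerve_csa_mean, spec$nerve_csa_sd)
      if (area_mm2 >= 0.5) break
    }
    aspect <- stats::runif(1, spec$nerve_aspect_range[1], spec$nerve_aspect_range[2])
    area_px <- area_mm2 / ps^2
    b <- sqrt(area_px / (pi * aspect))  # semi-minor (vertical)
    a <- aspect * b                     # semi-major (horizontal)
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    pert <- rep(0, n_vertices)
    if (spec$boundary_irregularity > 0) {
      for (k in 2:5) {
        amp <- spec$boundary_irregularity * stats::runif(1, 0.2, 1) / (k - 1)
        pert <- pert + amp * cos(k * theta + stats::runif(1, 0, 2 * pi))
      }
      mx <- max(abs(pert))
      if (mx > spec$boundary_irregularity)
        pert <- pert * spec$boundary_irregularity / mx
    }
    px <- a * cos(theta) * (1 + pert)
    py <- b * sin(theta) * (1 + pert)
    poly <- cbind(px, py)
    # rescale so the polygon area equals the drawn area exactly
    poly <- poly * sqrt(area_px / shoelace_area(poly))
    cy <- stats::runif(1, spec$nerve_depth_range[1], spec$nerve_depth_range[2]) * h
    cx <- stats::runif(1, 0.35, 0.65) * w
    poly[, 1] <- poly[, 1] + cx
    poly[, 2] <- poly[, 2] + cy
    if (all(poly[, 1] >= margin) && all(poly[, 1] <= w - 1 - margin) &&
        all(poly[, 2] >= margin) && all(poly[, 2] <= h - 1 - margin)) {
      colnames(poly) <- c("x", "y")
      return(structure(list(center = c(x = cx, y = cy), polygon = poly,
                            true_area = shoelace_area(poly) * ps^2,
                            pixel_spacing = ps),
                       class = "nerve_geometry"))
    }
  }
  stop("nerve geometry cannot fit in the canvas after 100 attempts")
}

# correlated speckle texture: standardized smoothed Gaussian field
speckle_field <- function(h, w, grain) {
  g <- matrix(stats::rnorm(h * w), h, w)
  if (grain > 0.5) {
    sigma <- grain / 2
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    pad_conv <- function(m, kv) {
      # convolve columns with replicate padding via banded matrix product
      n <- nrow(m); hl <- (length(kv) - 1L) / 2L
      idx <- outer(seq_len(n), seq(-hl, hl), "+")
      idx[idx < 1L] <- 1L; idx[idx > n] <- n
      out <- matrix(0, n, ncol(m))
      for (t in seq_along(kv)) out <- out + kv[t] * m[idx[, t], , drop = FALSE]
      out
    }
    g <- pad_conv(g, k)
    g <- t(pad_conv(t(g), k))
  }
  s <- stats::sd(as.vector(g))
  if (s > 0) g <- (g - mean(g)) / s
  g
}

#' Render a phantom image from a nerve geometry
#'
#' Background = horizontal tissue bands with per-band base intensities
#' modulated by multiplicative correlated speckle; the nerve interior is set
#' to the hypoechoic `nerve_echo_level` (with its own speckle), surrounded by
#' a thin bright epineurial rim at `rim_echo_level`. Intensities are clipped
#' to \[0, 1\]. With `speckle_contrast = 0` and one band the image is a
#' deterministic piecewise-constant map.
#'
#' @param geom a [sample_nerve_geometry()] result.
#' @param spec the [phantom_spec] used to draw it.
#' @return numeric matrix (height x width) in \[0, 1\].
#' @export
render_phantom <- function(geom, spec) {
  h <- spec$image_height; w <- spec$image_width
  nb <- spec$background_bands
  # band base intensities: alternate around mid-gray, drawn once per image
  base <- stats::runif(nb, 0.3, 0.6)
  edges <- round(seq(0, h, length.out = nb + 1L))
  img <- matrix(0, h, w)
  for (b in seq_len(nb)) {
    rows <- (edges[b] + 1L):edges[b + 1L]
    img[rows, ] <- base[b]
  }
  if (spec$speckle_contrast > 0) {
    fld <- speckle_field(h, w, spec$speckle_grain)
    img <- img * (1 + spec$speckle_contrast * fld)
  }
  mask <- rasterize_mask(geom, h, w)
  rim <- dilate4(mask) - mask
  nerve_tex <- matrix(spec$nerve_echo_level, h, w)
  if (spec$speckle_contrast > 0)
    nerve_tex <- nerve_tex *
      (1 + 0.5 * spec$speckle_contrast * speckle_field(h, w, spec$speckle_grain))
  img[mask == 1L] <- nerve_tex[mask == 1L]
  img[rim == 1L] <- spec$rim_echo_level
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# one-pixel 4-connected dilation (used for the epineurial rim)
dilate4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  out[-1, ] <- pmax(out[-1, ], mask[-h, ])
  out[-h, ] <- pmax(out[-h, ], mask[-1, ])
  out[, -1] <- pmax(out[, -1], mask[, -w])
  out[, -w] <- pmax(out[, -w], mask[, -1])
  out
}

#' Rasterize a nerve geometry to its ground-truth mask
#'
#' @param geom a `nerve_geometry` (or any list with a `polygon` matrix).
#' @param height,width raster size.
#' @return 0/1 integer matrix; errors if the polygon is degenerate or lies
#'   fully outside the canvas.
#' @export
rasterize_mask <- function(geom, height, width) {
  poly <- if (is.matrix(geom)) geom else geom$polygon
  if (!is.matrix(poly) || nrow(poly) < 3) stop("degenerate polygon")
  if (all(poly[, 1] < 0) || all(poly[, 1] > width - 1) ||
      all(poly[, 2] < 0) || all(poly[, 2] > height - 1))
    stop("polygon lies outside the canvas")
  polygon_fill(poly, height, width)
}

#' Simulate a manual tracing of a nerve boundary
#'
#' Displaces each polygon vertex radially (from the polygon centroid) by
#' Normal(boundary_bias, vertex_jitter_sd) mm converted to pixels. Radial
#' displacement preserves the angular order of vertices about the centroid,
#' so the tracing remains a simple polygon; radii are clamped to stay
#' positive.
#'
#' @param geom a `nerve_geometry`.
#' @param rater a [rater_model].
#' @param pixel_spacing mm/pixel (defaults to the geometry's own).
#' @return n x 2 matrix of traced (x, y) vertices, class `tracing`.
#' @export
simulate_tracing <- function(geom, rater, pixel_spacing = geom$pixel_spacing) {
  stopifnot(inherits(rater, "rater_model"))
  poly <- geom$polygon
  cen <- polygon_centroid(poly)
  dx <- poly[, 1] - cen[1]; dy <- poly[, 2] - cen[2]
  r <- sqrt(dx^2 + dy^2)
  disp_px <- stats::rnorm(nrow(poly), rater$boundary_bias,
                          rater$vertex_jitter_sd) / pixel_spacing
  r_new <- pmax(r + disp_px, 0.5)
  scale <- r_new / r
  out <- cbind(cen[1] + dx * scale, cen[2] + dy * scale)
  colnames(out) <- c("x", "y")
  class(out) <- c("tracing", class(out))
  out
}

#' Generate a phantom dataset
#'
#' Produces `n` image-mask-tracing triplets under a seeded RNG stream.
#' Identical (spec, rater, seed) inputs give identical datasets.
#'
#' @param n number of phantoms.
#' @param spec a [phantom_spec].
#' @param rater a [rater_model] (default: jitter 0.05 mm, no bias).
#' @param seed integer seed.
#' @param id_prefix identifier prefix for the pairs.
#' @return list of length `n`; each element has `image`, `mask` (ground
#'   truth), `tracing`, `manual_mask` (filled tracing), `id`, and `meta`
#'   (site, true_area mm^2, pixel_spacing, seed).
#' @export
simulate_phantom_dataset <- function(n, spec, rater = rater_model(),
                                     seed = 1L, id_prefix = spec$site) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    geom <- sample_nerve_geometry(spec)
    img <- render_phantom(geom, spec)
    mask <- rasterize_mask(geom, spec$image_height, spec$image_width)
    tr <- simulate_tracing(geom, rater)
    manual <- polygon_fill(tr, spec$image_height, spec$image_width)
    out[[i]] <- list(image = img, mask = mask, tracing = tr,
                     manual_mask = manual,
                     id = sprintf("%s_%04d", id_prefix, i),
                     meta = list(site = spec$site, true_area = geom$true_area,
                                 pixel_spacing = spec$pixel_spacing,
                                 seed = seed))
  }
  out
}

#' Write a phantom triplet to disk
#'
#' Image and mask as 8-bit grayscale PNG (mask values 0/255), tracing as a
#' CSV with header "x,y" (0-based pixel coordinates), plus a JSON sidecar
#' carrying pixel_spacing, site, true_area and seed.
#'
#' @param pair one element of [simulate_phantom_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
write_phantom <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, pair$id)
  png::writePNG(pair$image, paste0(base, ".png"))
  png::writePNG(pair$mask * 1.0, paste0(base, "_mask.png"))
  utils::write.csv(as.data.frame(unclass(pair$tracing)),
                   paste0(base, "_tracing.csv"), row.names = FALSE)
  jsonlite::write_json(pair$meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, c(".png", "_mask.png", "_tracing.csv", ".json")))
}

#' Read a phantom triplet back from disk
#' @param dir directory written by [write_phantom()].
#' @param id the pair identifier.
#' @return a pair list as produced by [simulate_phantom_dataset()] (without
#'   `manual_mask`).
#' @export
read_phantom <- function(dir, id) {
  base <- file.path(dir, id)
  img <- png::readPNG(paste0(base, ".png"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask_raw <- png::readPNG(paste0(base, "_mask.png"))
  if (length(dim(mask_raw)) == 3) mask_raw <- mask_raw[, , 1]
  tr <- as.matrix(utils::read.csv(paste0(base, "_tracing.csv")))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  list(image = img, mask = binarize(mask_raw * 255), tracing = tr,
       id = id, meta = meta)
}
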