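#' Intensity-augmentation protocol
#'
#' The enumerated parameter sets of the 11-variant expansion: three CLAHE
#' settings (clip limit as a fraction of the tile pixel count, with tile
#' grid), four gamma values, three multiplicative speckle-noise levels, plus
#' the retained original. Each setting is applied independently to the
#' original image, never in combination; masks pass through untouched.
#'
#' @param clahe_settings list of `list(clip_limit=, tile_grid=c(rows, cols))`.
#' @param gamma_values numeric vector of gamma exponents.
#' @param speckle_levels numeric vector of speckle noise variances.
#' @param include_original keep the unmodified image as the first variant.
#' @return an object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(clahe_settings = list(
                                list(clip_limit = 0.01, tile_grid = c(8L, 8L)),
                                list(clip_limit = 0.02, tile_grid = c(8L, 8L)),
                                list(clip_limit = 0.03, tile_grid = c(16L, 16L))),
                              gamma_values = c(0.70, 0.80, 1.20, 1.30),
                              speckle_levels = c(0.10, 0.20, 0.30),
                              include_original = TRUE) {
  stopifnot(all(vapply(clahe_settings, function(s)
    s$clip_limit > 0 && s$clip_limit <= 1 && length(s$tile_grid) == 2, TRUE)),
    all(gamma_values > 0), all(speckle_levels >= 0))
  structure(list(clahe_settings = clahe_settings,
                 gamma_values = gamma_values,
                 speckle_levels = speckle_levels,
                 include_original = include_original),
            class = "augmentation_spec")
}

#' Expansion factor of an augmentation protocol
#' @param spec an [augmentation_spec].
#' @return variants emitted per input pair (11 at the defaults).
#' @export
expansion_factor <- function(spec) {
  as.integer(spec$include_original) + length(spec$clahe_settings) +
    length(spec$gamma_values) + length(spec$speckle_levels)
}

#' Gamma correction
#'
#' Pixel-wise power law out = in^gamma on normalized intensities; monotone
#' with fixed endpoints. gamma < 1 brightens, gamma > 1 darkens.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param gamma exponent > 0.
#' @return transformed matrix in \[0, 1\].
#' @export
apply_gamma <- function(image, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  if (any(image < 0) || any(image > 1)) stop("intensities outside [0, 1]")
  image^gamma
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization on 256 bins with the histogram clipped at
#' `clip_limit` x (tile pixel count); the clipped excess is redistributed
#' uniformly across bins. Each pixel is remapped by bilinear interpolation
#' between the equalization mappings of the four nearest tile centers
#' (clamped at the borders), the standard scheme that removes tile seams.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param clip_limit fraction of the tile pixel count in (0, 1].
#' @param tile_grid integer (rows, cols) tile layout; tiles must be at least
#'   8 pixels on a side.
#' @return equalized matrix in \[0, 1\].
#' @export
apply_clahe <- function(image, clip_limit, tile_grid = c(8L, 8L)) {
  if (clip_limit <= 0 || clip_limit > 1) stop("clip_limit must be in (0, 1]")
  h <- nrow(image); w <- ncol(image)
  tr <- as.integer(tile_grid[1]); tc <- as.integer(tile_grid[2])
  if (tr < 1 || tc < 1 || h %/% tr < 8 || w %/% tc < 8)
    stop("invalid tile grid: tiles must be at least 8 px")
  nbins <- 256L
  v <- pmin(pmax(floor(image * (nbins - 1) + 0.5), 0), nbins - 1)  # 0..255
  # tile index per row/col (equal-ish partition)
  row_tile <- pmin(floor((seq_len(h) - 1) * tr / h), tr - 1) + 1
  col_tile <- pmin(floor((seq_len(w) - 1) * tc / w), tc - 1) + 1
  # per-tile clipped-histogram CDF lookup tables
  luts <- array(0, dim = c(tr, tc, nbins))
  for (a in seq_len(tr)) for (b in seq_len(tc)) {
    vals <- v[row_tile == a, col_tile == b]
    npix <- length(vals)
    hist_ <- tabulate(vals + 1L, nbins = nbins)
    clip <- max(1, clip_limit * npix)
    excess <- sum(pmax(hist_ - clip, 0))
    hist_ <- pmin(hist_, clip) + excess / nbins
    cdf <- cumsum(hist_)
    cdf_min <- cdf[which(hist_ > 0)[1]]
    denom <- max(npix - cdf_min, .Machine$double.eps)
    luts[a, b, ] <- pmin(pmax((cdf - cdf_min) / denom, 0), 1)
  }
  # tile centers (pixel coordinates, 1-based) for bilinear blending
  centr <- (seq_len(tr) - 0.5) * h / tr
  centc <- (seq_len(tc) - 0.5) * w / tc
  rpos <- seq_len(h); cpos <- seq_len(w)
  r_lo <- pmin(pmax(findInterval(rpos, centr), 1), tr)
  r_hi <- pmin(r_lo + 1, tr)
  r_lo <- ifelse(rpos < centr[1], 1L, r_lo)
  wr <- ifelse(r_hi == r_lo, 0,
               (rpos - centr[r_lo]) / (centr[r_hi] - centr[r_lo]))
  wr <- pmin(pmax(wr, 0), 1)
  c_lo <- pmin(pmax(findInterval(cpos, centc), 1), tc)
  c_hi <- pmin(c_lo + 1, tc)
  wc <- ifelse(c_hi == c_lo, 0,
               (cpos - centc[c_lo]) / (centc[c_hi] - centc[c_lo]))
  wc <- pmin(pmax(wc, 0), 1)
  # gather the four corner mappings for every pixel
  vi <- as.vector(v) + 1L
  RL <- rep(r_lo, times = w); RH <- rep(r_hi, times = w)
  WR <- rep(wr, times = w)
  CL <- rep(c_lo, each = h); CH <- rep(c_hi, each = h)
  WC <- rep(wc, each = h)
  g <- function(ri, ci) luts[cbind(ri, ci, vi)]
  out <- (1 - WR) * (1 - WC) * g(RL, CL) + (1 - WR) * WC * g(RL, CH) +
    WR * (1 - WC) * g(RH, CL) + WR * WC * g(RH, CH)
  matrix(out, h, w)
}

#' Multiplicative speckle noise
#'
#' out = clip(in + in * n, 0, 1) with n i.i.d. Normal(0, v) per pixel - the
#' additive-multiplicative speckle convention in which the stated level is
#' the noise variance. Randomness comes from R's RNG stream.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param v noise variance >= 0.
#' @return noisy matrix clipped to \[0, 1\].
#' @export
apply_speckle <- function(image, v) {
  if (v < 0) stop("speckle variance must be non-negative")
  if (v == 0) return(image)
  n <- matrix(stats::rnorm(length(image), 0, sqrt(v)), nrow(image), ncol(image))
  out <- image + image * n
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Expand a dataset by the augmentation protocol
#'
#' Emits, per input pair, the retained original plus one variant per
#' parameter setting, each tagged with its provenance. Masks (and manual
#' masks and metadata) are copied bit-exactly; only image intensities change.
#'
#' @param pairs list of image-mask pairs.
#' @param spec an [augmentation_spec].
#' @param seed integer seed for the speckle draws.
#' @return expanded list of pairs, `length(pairs) * expansion_factor(spec)`,
#'   each with a `provenance` element (`list(source_id, kind, params)`).
#' @export
expand_dataset <- function(pairs, spec = augmentation_spec(), seed = 1L) {
  stopifnot(inherits(spec, "augmentation_spec"))
  set.seed(seed)
  out <- list()
  for (p in pairs) {
    emit <- function(img, kind, params, tag) {
      q <- p
      q$image <- img
      q$id <- paste0(p$id, "_", tag)
      q$provenance <- list(source_id = p$id, kind = kind, params = params)
      q
    }
    if (spec$include_original)
      out[[length(out) + 1L]] <- emit(p$image, "original", list(), "orig")
    for (k in seq_along(spec$clahe_settings)) {
      s <- spec$clahe_settings[[k]]
      out[[length(out) + 1L]] <-
        emit(apply_clahe(p$image, s$clip_limit, s$tile_grid), "clahe", s,
             paste0("clahe", k))
    }
    for (k in seq_along(spec$gamma_values)) {
      g <- spec$gamma_values[k]
      out[[length(out) + 1L]] <-
        emit(apply_gamma(p$image, g), "gamma", list(gamma = g),
             paste0("gamma", k))
    }
    for (k in seq_along(spec$speckle_levels)) {
      v <- spec$speckle_levels[k]
      out[[length(out) + 1L]] <-
        emit(apply_speckle(p$image, v), "speckle", list(v = v),
             paste0("speckle", k))
    }
  }
  out
}

#' Augmentation manifest
#' @param pairs an [expand_dataset()] result.
#' @return data.frame (id, source_id, kind, params).
#' @export
augmentation_manifest <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    pr <- p$provenance
    if (is.null(pr)) pr <- list(source_id = p$id, kind = "original", params = list())
    data.frame(id = p$id, source_id = pr$source_id, kind = pr$kind,
               params = paste(unlist(pr$params), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
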