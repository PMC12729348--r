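# Independent reference implementations used as oracles. These deliberately
# use naive algorithms (per-pixel loops, direct summation) and double
# precision so they share no code path with the package internals.

# even-odd ray-casting point-in-polygon (counts boundary points as inside)
ref_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test
    d2 <- (xj - xi)^2 + (yj - yi)^2
    if (d2 > 0) {
      t <- ((px - xi) * (xj - xi) + (py - yi) * (yj - yi)) / d2
      if (t >= 0 && t <= 1) {
        dx <- px - (xi + t * (xj - xi)); dy <- py - (yi + t * (yj - yi))
        if (dx * dx + dy * dy < 1e-18) return(TRUE)
      }
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

ref_fill <- function(poly, height, width) {
  m <- matrix(0L, height, width)
  for (i in seq_len(height))
    for (j in seq_len(width))
      m[i, j] <- as.integer(ref_point_in_polygon(j - 1, i - 1, poly))
  m
}

# per-pixel confusion loop
ref_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] != 0; t <- truth[i, j] != 0
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# naive double-precision network layers
ref_conv3 <- function(x, w, b, relu = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]; Cout <- dim(w)[4]
  y <- array(0, dim = c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    acc <- matrix(b[co], H, W)
    for (ci in 1:Cin) for (ki in 1:3) for (kj in 1:3) {
      di <- ki - 2; dj <- kj - 2
      xs <- matrix(0, H, W)
      i_rng <- max(1, 1 - di):min(H, H - di)
      j_rng <- max(1, 1 - dj):min(W, W - dj)
      xs[i_rng, j_rng] <- x[i_rng + di, j_rng + dj, ci, n]
      acc <- acc + w[ki, kj, ci, co] * xs
    }
    if (relu) acc[acc < 0] <- 0
    y[, , co, n] <- acc
  }
  y
}

ref_pool2 <- function(x) {
  d <- dim(x)
  y <- array(0, dim = c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (n in 1:d[4]) for (c in 1:d[3])
    for (i in 1:(d[1] / 2)) for (j in 1:(d[2] / 2))
      y[i, j, c, n] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
  y
}

ref_upconv2 <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]; Cout <- dim(w)[4]
  y <- array(0, dim = c(2 * H, 2 * W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    out <- matrix(b[co], 2 * H, 2 * W)
    for (ki in 1:2) for (kj in 1:2) for (ci in 1:Cin)
      out[seq(ki, 2 * H, 2), seq(kj, 2 * W, 2)] <-
        out[seq(ki, 2 * H, 2), seq(kj, 2 * W, 2)] + w[ki, kj, ci, co] * x[, , ci, n]
    y[, , co, n] <- out
  }
  y
}

ref_forward <- function(model, x) {
  p <- model$params; d <- model$config$depth
  skips <- list(); a <- x
  for (l in seq_len(d - 1)) {
    a <- ref_conv3(a, p[[paste0("enc", l, "_w1")]], p[[paste0("enc", l, "_b1")]], TRUE)
    a <- ref_conv3(a, p[[paste0("enc", l, "_w2")]], p[[paste0("enc", l, "_b2")]], TRUE)
    skips[[l]] <- a
    a <- ref_pool2(a)
  }
  a <- ref_conv3(a, p$bott_w1, p$bott_b1, TRUE)
  a <- ref_conv3(a, p$bott_w2, p$bott_b2, TRUE)
  for (l in rev(seq_len(d - 1))) {
    up <- ref_upconv2(a, p[[paste0("dec", l, "_wu")]], p[[paste0("dec", l, "_bu")]])
    a <- usnerveseg:::abind4(up, skips[[l]])
    a <- ref_conv3(a, p[[paste0("dec", l, "_w1")]], p[[paste0("dec", l, "_b1")]], TRUE)
    a <- ref_conv3(a, p[[paste0("dec", l, "_w2")]], p[[paste0("dec", l, "_b2")]], TRUE)
  }
  logits <- usnerveseg:::conv1x1_fwd(a, p$out_w, p$out_b)
  usnerveseg:::softmax_ch(logits)
}

# random simple (star-shaped) polygon around a center
random_simple_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  theta <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

# small 64x64 phantom configuration used by fast training tests
small_canvas <- function() canvas_spec(64L, 44L, 64L, 64L)

small_phantom_spec <- function(site = "wrist") {
  phantom_spec(site, image_height = 64L, image_width = 44L,
               pixel_spacing = 0.2)
}

make_small_pairs <- function(n, seed, site = "wrist",
                             rater = rater_model()) {
  preprocess_pairs(
    simulate_phantom_dataset(n, small_phantom_spec(site), rater, seed = seed),
    small_canvas())
}

# the augmentation protocol with CLAHE tile grids rescaled for 64 px images
# (same clip limits, gammas and speckle levels; tiles stay at >= 8 px)
small_augmentation_spec <- function() {
  augmentation_spec(clahe_settings = list(
    list(clip_limit = 0.01, tile_grid = c(4L, 4L)),
    list(clip_limit = 0.02, tile_grid = c(4L, 4L)),
    list(clip_limit = 0.03, tile_grid = c(8L, 8L))))
}
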