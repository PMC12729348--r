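test_that("default augmentation protocol matches the published settings", {
  sp <- augmentation_spec()
  expect_equal(length(sp$clahe_settings), 3)
  expect_equal(sp$clahe_settings[[1]]$clip_limit, 0.01)
  expect_equal(sp$clahe_settings[[3]]$tile_grid, c(16L, 16L))
  expect_equal(sp$gamma_values, c(0.70, 0.80, 1.20, 1.30))
  expect_equal(sp$speckle_levels, c(0.10, 0.20, 0.30))
  expect_true(sp$include_original)
  expect_equal(expansion_factor(sp), 11L)
})

test_that("gamma correction is the exact power law and gamma > 1 darkens", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(apply_gamma(img, 1), img)
  expect_equal(apply_gamma(matrix(0.25, 1, 1), 0.5), matrix(0.5, 1, 1))
  set.seed(6)
  for (k in 1:10) {
    im <- matrix(runif(256), 16, 16)
    expect_lte(mean(apply_gamma(im, 1.30)), mean(im))
    expect_true(all(apply_gamma(im, 0.7) >= 0 & apply_gamma(im, 0.7) <= 1))
  }
  expect_error(apply_gamma(img, 0), "positive")
})

test_that("CLAHE equalizes local contrast without degenerate artifacts", {
  # constant image stays constant
  cimg <- matrix(0.4, 64, 64)
  out <- apply_clahe(cimg, 0.02, c(8, 8))
  expect_lt(diff(range(out)), 1e-12)

  # entropy of a low-contrast blob image does not decrease
  ent <- function(m) {
    h <- tabulate(pmin(floor(m * 255) + 1, 256), 256)
    p <- h[h > 0] / sum(h)
    -sum(p * log(p))
  }
  for (s in 1:20) {
    set.seed(s)
    xg <- outer(seq(-1, 1, length.out = 128), seq(-1, 1, length.out = 128),
                function(a, b) exp(-(a^2 + b^2)))
    im <- 0.45 + 0.1 * xg + matrix(rnorm(128^2, 0, 0.01), 128, 128)
    im <- pmin(pmax(im, 0), 1)
    expect_gte(ent(apply_clahe(im, 0.02, c(8, 8))) + 1e-9, ent(im))
  }

  # the three published settings act differently on a speckle phantom
  ps <- phantom_spec("wrist", image_height = 128L, image_width = 128L)
  set.seed(8)
  g <- sample_nerve_geometry(ps)
  img <- render_phantom(g, ps)
  outs <- lapply(augmentation_spec()$clahe_settings, function(s)
    apply_clahe(img, s$clip_limit, s$tile_grid))
  expect_gt(max(abs(outs[[1]] - outs[[2]])), 0)
  expect_gt(max(abs(outs[[1]] - outs[[3]])), 0)
  expect_gt(max(abs(outs[[2]] - outs[[3]])), 0)

  expect_error(apply_clahe(img, 0.02, c(64, 64)), "tile")
})

test_that("speckle noise has the stated multiplicative variance", {
  img <- matrix(0.5, 400, 250)  # 1e5 pixels
  expect_identical(apply_speckle(img, 0), img)
  set.seed(10)
  out <- apply_speckle(img, 0.10)
  ratio <- (out - img) / img
  clipped <- out == 0 | out == 1
  expect_lt(abs(stats::var(as.vector(ratio[!clipped])) - 0.10) / 0.10, 0.05)
  set.seed(77); a <- apply_speckle(img, 0.2)
  set.seed(77); b <- apply_speckle(img, 0.2)
  expect_identical(a, b)
  expect_error(apply_speckle(img, -0.1), "non-negative")
})

test_that("dataset expansion yields the published counts with untouched masks", {
  set.seed(12)
  # 128 px on a side so the 16x16 CLAHE grid keeps tiles at 8 px
  mk <- function(n, prefix) lapply(seq_len(n), function(i) {
    list(image = matrix(runif(128 * 128), 128, 128),
         mask = matrix(rbinom(128 * 128, 1, 0.1), 128, 128),
         id = sprintf("%s%03d", prefix, i),
         meta = list(site = "wrist", true_area = 9, pixel_spacing = 0.1))
  })
  wrist <- mk(35, "w"); forearm <- mk(26, "f")
  ew <- expand_dataset(wrist, seed = 1)
  ef <- expand_dataset(forearm, seed = 1)
  expect_length(ew, 385)
  expect_length(ef, 286)
  expect_length(expand_dataset(list(), seed = 1), 0)

  # masks and metadata are bit-identical to their source
  src <- setNames(wrist, vapply(wrist, `[[`, "", "id"))
  for (p in ew[1:44]) {
    expect_identical(p$mask, src[[p$provenance$source_id]]$mask)
    expect_identical(p$meta, src[[p$provenance$source_id]]$meta)
    expect_true(all(p$image >= 0 & p$image <= 1))
  }
  # variant kinds appear in the declared proportions
  kinds <- table(vapply(ew, function(p) p$provenance$kind, ""))
  expect_equal(as.integer(kinds[c("original", "clahe", "gamma", "speckle")]),
               c(35L, 105L, 140L, 105L))
})
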