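test_that("sampled geometry reproduces analytic areas and stated moments", {
  ps <- phantom_spec("wrist", boundary_irregularity = 0, nerve_csa_sd = 0,
                     nerve_aspect_range = c(1, 1))
  set.seed(1)
  g <- sample_nerve_geometry(ps)
  # a regular 48-gon's shoelace area recovers the circle area well within 0.5%
  expect_equal(g$true_area, 9.8, tolerance = 0.005)
  expect_gte(nrow(g$polygon), 12)

  # Monte-Carlo: sample mean of the drawn areas matches the stated moments
  ps2 <- phantom_spec("wrist")
  set.seed(42)
  areas <- replicate(1000, sample_nerve_geometry(ps2)$true_area)
  se <- 2.4 / sqrt(1000)
  expect_lt(abs(mean(areas) - 9.8), 3 * se)
})

test_that("impossible geometry is rejected with an error", {
  ps <- phantom_spec("wrist", image_height = 128L, image_width = 128L,
                     nerve_csa_mean = 1e6, nerve_csa_sd = 0)
  set.seed(1)
  expect_error(sample_nerve_geometry(ps), "cannot fit")
})

test_that("rendered phantoms are hypoechoic inside the nerve and seeded", {
  ps <- phantom_spec("wrist")
  for (s in 1:20) {
    set.seed(s)
    g <- sample_nerve_geometry(ps)
    img <- render_phantom(g, ps)
    m <- rasterize_mask(g, ps$image_height, ps$image_width)
    expect_lt(mean(img[m == 1]), mean(img[m == 0]))
    expect_true(all(img >= 0 & img <= 1))
  }
  # determinism: same seed, same image
  set.seed(99); g <- sample_nerve_geometry(ps); i1 <- render_phantom(g, ps)
  set.seed(99); g2 <- sample_nerve_geometry(ps); i2 <- render_phantom(g2, ps)
  expect_identical(i1, i2)
})

test_that("noise-free single-band phantom is piecewise constant", {
  ps <- phantom_spec("wrist", speckle_contrast = 0, background_bands = 1L)
  set.seed(3)
  g <- sample_nerve_geometry(ps)
  img <- render_phantom(g, ps)
  expect_lte(length(unique(as.vector(img))), 3)  # background, nerve, rim
})

test_that("rasterization recovers polygon area within discretization error", {
  # axis-aligned integer square: exact count
  sq <- cbind(c(10, 19, 19, 10), c(10, 10, 19, 19))
  expect_equal(sum(polygon_fill(sq, 32, 32)), 100)

  ps <- phantom_spec("wrist", pixel_spacing = 0.1)
  set.seed(11)
  for (k in 1:25) {
    g <- sample_nerve_geometry(ps)
    if (g$true_area < 4) next
    m <- rasterize_mask(g, ps$image_height, ps$image_width)
    csa <- sum(m) * 0.1^2
    expect_lt(abs(csa - g$true_area) / g$true_area, 0.02)
  }
  expect_error(rasterize_mask(list(polygon = sq + 1000), 32, 32), "outside")
})

test_that("simulated tracings behave like an imperfect rater", {
  ps <- phantom_spec("wrist")
  set.seed(5)
  g <- sample_nerve_geometry(ps)

  # zero jitter, zero bias: identity
  tr0 <- simulate_tracing(g, rater_model(0, 0))
  expect_equal(unclass(tr0), unclass(g$polygon), tolerance = 1e-12,
               ignore_attr = TRUE)

  # positive bias strictly enlarges the filled area (annulus expansion)
  for (s in 1:20) {
    set.seed(s)
    g2 <- sample_nerve_geometry(ps)
    tr <- simulate_tracing(g2, rater_model(0, 0.1))
    a_tr <- sum(polygon_fill(tr, ps$image_height, ps$image_width)) * 0.1^2
    expect_gt(a_tr, g2$true_area)
  }

  # symmetric jitter: mean filled area unbiased (within 3 SE over 200 reps)
  set.seed(7)
  g3 <- sample_nerve_geometry(ps)
  areas <- replicate(200, {
    tr <- simulate_tracing(g3, rater_model(0.08, 0))
    sum(polygon_fill(tr, ps$image_height, ps$image_width)) * 0.1^2
  })
  expect_lt(abs(mean(areas) - g3$true_area),
            3 * stats::sd(areas) / sqrt(200))
})

test_that("wrist phantoms sit shallower and larger than forearm phantoms", {
  pw <- phantom_spec("wrist"); pf <- phantom_spec("forearm")
  expect_lt(mean(pw$nerve_depth_range), mean(pf$nerve_depth_range))
  set.seed(21)
  gw <- replicate(100, {
    g <- sample_nerve_geometry(pw); c(g$center["y"], g$true_area)
  })
  gf <- replicate(100, {
    g <- sample_nerve_geometry(pf); c(g$center["y"], g$true_area)
  })
  expect_lt(mean(gw[1, ]), mean(gf[1, ]))   # shallower centroids
  expect_gt(mean(gw[2, ]), mean(gf[2, ]))   # larger CSA
})

test_that("phantom datasets are deterministic and round-trip through disk", {
  ps <- phantom_spec("wrist")
  d1 <- simulate_phantom_dataset(3, ps, rater_model(), seed = 123)
  d2 <- simulate_phantom_dataset(3, ps, rater_model(), seed = 123)
  expect_identical(d1, d2)

  dir <- withr::local_tempdir()
  write_phantom(d1[[1]], dir)
  back <- read_phantom(dir, d1[[1]]$id)
  expect_identical(back$mask, d1[[1]]$mask)
  # 8-bit quantization: images agree to half a grey level
  expect_lt(max(abs(back$image - d1[[1]]$image)), 0.5 / 255)
  expect_equal(back$meta$true_area, d1[[1]]$meta$true_area, tolerance = 1e-9)
  expect_equal(unname(back$tracing), unname(unclass(d1[[1]]$tracing)),
               tolerance = 1e-6)
})

test_that("rater agreement improves monotonically as jitter vanishes", {
  ps <- phantom_spec("wrist")
  iccs <- sapply(c(0.3, 0.12, 0.02), function(jit) {
    set.seed(31)
    areas <- replicate(60, {
      g <- sample_nerve_geometry(ps)
      a1 <- sum(polygon_fill(simulate_tracing(g, rater_model(jit, 0)),
                             ps$image_height, ps$image_width))
      a2 <- sum(polygon_fill(simulate_tracing(g, rater_model(jit, 0)),
                             ps$image_height, ps$image_width))
      c(a1, a2) * 0.1^2
    })
    icc_2_1(t(areas))$icc
  })
  expect_true(all(diff(iccs) > 0))
  expect_gt(iccs[3], 0.99)
})
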