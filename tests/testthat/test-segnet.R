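test_that("forward pass satisfies its shape and normalization contracts", {
  cfg <- unet_config(input_size = c(64L, 64L), base_filters = 4L)
  set.seed(1)
  model <- build_unet(cfg)
  x <- array(runif(64 * 64), dim = c(64, 64, 1, 1))
  fw <- unet_forward(model, x)
  expect_equal(dim(fw$prob), c(64L, 64L, 2L, 1L))
  sums <- fw$prob[, , 1, 1] + fw$prob[, , 2, 1]
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_error(unet_config(input_size = c(60L, 64L)), "divisible")
})

test_that("doubling base filters strictly increases the parameter count", {
  n1 <- count_params(build_unet(unet_config(base_filters = 8L)))
  n2 <- count_params(build_unet(unet_config(base_filters = 16L)))
  expect_gt(n2, n1)
})

test_that("float kernels agree with a naive double-precision network", {
  set.seed(1)
  cfg <- unet_config(input_size = c(16L, 16L), depth = 2L, base_filters = 2L)
  model <- build_unet(cfg)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  fw <- unet_forward(model, x)
  expect_lt(max(abs(fw$prob - ref_forward(model, x))), 1e-5)
})

test_that("analytic gradients match finite differences of the reference net", {
  set.seed(1)
  cfg <- unet_config(input_size = c(16L, 16L), depth = 2L, base_filters = 2L)
  model <- build_unet(cfg)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), dim = c(16, 16, 2))
  fw <- unet_forward(model, x, keep_cache = TRUE)
  l <- usnerveseg:::ce_loss(fw$prob, y)
  g <- usnerveseg:::unet_backward(model, fw, l$dlogits)
  ref_loss <- function(m) usnerveseg:::ce_loss(ref_forward(m, x), y)$loss
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(length(p), 4))) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + eps
      lp <- ref_loss(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- ref_loss(m2)
      fd <- (lp - lm) / (2 * eps)
      if (abs(fd) > 1e-5 || abs(g[[nm]][i]) > 1e-5)
        expect_lt(abs(fd - g[[nm]][i]) / max(abs(fd), abs(g[[nm]][i])), 1e-3)
    }
  }
})

test_that("training overfits a singleton and predicts it back (sanity oracle)", {
  pairs <- make_small_pairs(1, seed = 17)
  cfg <- unet_config(input_size = c(64L, 64L), base_filters = 8L)
  # 200 optimization steps on one image
  tcfg <- train_config(learning_rate = 1e-3, epochs = 200L, batch_size = 1L,
                       validation_fraction = 0, seed = 17L)
  fit <- train_unet(pairs, cfg, tcfg)
  expect_equal(nrow(fit$curves), 200)
  expect_true(all(is.finite(fit$curves$train_loss)))
  pred <- predict_mask(fit$model, pairs[[1]]$image)
  cc <- confusion(pred, pairs[[1]]$mask)
  expect_gt(dice(cc), 0.99)
})

test_that("training descends and is deterministic under a fixed seed", {
  pairs <- make_small_pairs(12, seed = 23)
  cfg <- unet_config(input_size = c(64L, 64L), base_filters = 4L)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 4L, seed = 5L)
  f1 <- train_unet(pairs, cfg, tcfg)
  expect_lt(tail(f1$curves$train_loss, 1), f1$curves$train_loss[1])
  f2 <- train_unet(pairs, cfg, tcfg)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$model$params, f2$model$params)
  expect_error(train_unet(list(), cfg, tcfg), "empty")
})

test_that("mask prediction breaks probability ties toward background", {
  cfg <- unet_config(input_size = c(16L, 16L), depth = 2L, base_filters = 2L)
  set.seed(2)
  model <- build_unet(cfg)
  # zero all weights: logits identical across classes -> uniform 0.5/0.5
  model$params <- lapply(model$params, function(p) p * 0)
  pred <- predict_mask(model, matrix(0.5, 16, 16))
  expect_true(all(pred == 0L))
  expect_error(predict_mask(model, matrix(0.5, 8, 8)), "size")
})
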