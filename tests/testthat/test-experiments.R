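test_that("seeded splits reproduce the published test-set arithmetic", {
  expect_length(make_split(885, 0.2, seed = 1)$test, 177)
  expect_length(make_split(786, 0.2, seed = 1)$test, 157)
  expect_length(make_split(385, 0.2, seed = 1)$test, 77)
  expect_length(make_split(286, 0.2, seed = 1)$test, 57)
  sp <- make_split(10, 0.2, seed = 3)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(make_split(100, 0.2, 9), make_split(100, 0.2, 9))
  expect_false(identical(make_split(100, 0.2, 9)$test,
                         make_split(100, 0.2, 10)$test))
  expect_error(make_split(100, 1.2), "test_fraction")
  expect_error(make_split(1, 0.2), "at least 2")
})

test_that("cross-generalization refuses leaking ids and reports both domains", {
  pairs <- make_small_pairs(6, seed = 40)
  expect_error(run_cross_generalization(pairs, pairs,
                                        unet_config(c(64L, 64L), base_filters = 4L),
                                        train_config(epochs = 1L)),
               "leakage")
})

test_that("baseline experiment is deterministic and rejects empty data", {
  cfg <- unet_config(c(64L, 64L), base_filters = 4L)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 2L, seed = 11L)
  pairs <- make_small_pairs(12, seed = 41)
  r1 <- run_baseline(pairs, cfg, tcfg)
  r2 <- run_baseline(pairs, cfg, tcfg)
  expect_identical(r1$summary, r2$summary)
  expect_equal(r1$n_test, 2)
  expect_equal(r1$n_train, 10)
  expect_true(all(c("dice", "iou", "accuracy", "precision", "specificity",
                    "sensitivity") %in% names(r1$metrics)))
  expect_error(run_baseline(list(), cfg, tcfg), "empty")
})

test_that("experiment reports round-trip to disk with a manifest", {
  cfg <- unet_config(c(64L, 64L), base_filters = 4L)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 1L, seed = 12L)
  pairs <- make_small_pairs(10, seed = 42)
  rep <- run_baseline(pairs, cfg, tcfg)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "curves.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$seed, 12)
  expect_equal(mf$design, "baseline")
  # metrics CSV carries every overlap metric
  m <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_true(all(c("dice", "iou", "accuracy", "precision", "specificity",
                    "sensitivity") %in% names(m)))
  # rerunning from the same configuration reproduces the summary bit-exactly
  rep2 <- run_baseline(pairs, cfg, tcfg)
  dir2 <- withr::local_tempdir()
  write_report(rep2, dir2)
  expect_identical(readLines(file.path(dir, "summary.csv")),
                   readLines(file.path(dir2, "summary.csv")))
})

test_that("combined trials emit one row per trial with floor-sized test sets", {
  cfg <- unet_config(c(64L, 64L), base_filters = 4L)
  tcfg <- train_config(learning_rate = 1e-3, epochs = 1L, seed = 13L)
  pairs <- make_small_pairs(11, seed = 43)
  rep <- run_combined_trials(pairs, cfg, tcfg, n_trials = 3L)
  expect_equal(nrow(rep$trials), 3)
  expect_true(all(rep$trials$n_test == floor(0.2 * 11)))
  expect_equal(rep$trials$seed, 13L + 1:3)
  expect_true(is.finite(rep$spread))
})
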