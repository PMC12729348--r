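#' Seeded train/test split plan
#'
#' Shuffles indices with the seed, then partitions with
#' n_test = floor(n_total * test_fraction) - the rounding convention that
#' matches an 80-20 split of 786 giving 157 test images.
#'
#' @param n_total number of items (>= 2).
#' @param test_fraction fraction held out, in (0, 1) (default 0.2).
#' @param seed integer seed.
#' @return list(train, test): disjoint 1-based index vectors covering
#'   1..n_total.
#' @export
make_split <- function(n_total, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (n_total < 2) stop("need at least 2 items")
  n_test <- floor(n_total * test_fraction)
  set.seed(seed)
  perm <- sample.int(n_total)
  list(train = sort(perm[(n_test + 1):n_total]),
       test = sort(perm[seq_len(n_test)]))
}

#' Shift a phantom dataset to a different intensity domain
#'
#' Applies a fixed gamma remapping (and optional contrast stretch) to every
#' image, emulating acquisition-setting differences between datasets; masks
#' and geometry are untouched.
#'
#' @param pairs phantom pairs.
#' @param gamma gamma exponent of the shift (default 0.6, a strong
#'   brightening outside the augmentation grid's 0.7-1.3 range).
#' @return shifted pairs with ids suffixed "_shift".
#' @export
shift_domain <- function(pairs, gamma = 0.6) {
  lapply(pairs, function(p) {
    p$image <- apply_gamma(p$image, gamma)
    p$id <- paste0(p$id, "_shift")
    p
  })
}

#' Baseline experiment: split, train, evaluate
#'
#' Mirrors the single-dataset design: an 80-20 seeded split, training on the
#' train side, pixel-overlap metrics and CSA agreement on the held-out test
#' side.
#'
#' @param pairs preprocessed image-mask pairs.
#' @param net_cfg,tr_cfg network and training configurations.
#' @param test_fraction held-out fraction (default 0.2).
#' @return object of class `experiment_report`: list(design, n_train, n_test,
#'   metrics, summary, agreement, curves, seed).
#' @export
run_baseline <- function(pairs, net_cfg, tr_cfg, test_fraction = 0.2) {
  if (length(pairs) == 0) stop("baseline: empty dataset")
  sp <- make_split(length(pairs), test_fraction, seed = tr_cfg$seed)
  fit <- train_unet(pairs[sp$train], net_cfg, tr_cfg)
  test <- predict_pairs(fit$model, pairs[sp$test])
  metrics <- evaluate_pairs(test)
  # summarize only metrics defined on every test image: an empty predicted
  # mask leaves precision undefined (NA); per-image records keep everything
  mcols <- c("dice", "iou", "accuracy", "precision", "specificity",
             "sensitivity")
  ok <- mcols[colSums(is.na(metrics[mcols])) == 0]
  agr <- if (!is.null(test[[1]]$manual_mask) && length(test) >= 5) {
    cr <- csa_records(test)
    agreement_report(cr$manual_csa, cr$predicted_csa)
  } else NULL
  structure(list(design = "baseline", n_train = length(sp$train),
                 n_test = length(sp$test), metrics = metrics,
                 summary = summarize_metrics(metrics[ok]), agreement = agr,
                 curves = fit$curves, model = fit$model, seed = tr_cfg$seed),
            class = "experiment_report")
}

#' Cross-dataset generalization experiment
#'
#' Trains on the whole of dataset A and evaluates on the whole of dataset B
#' (no split), asserting id-disjointness first - the design that exposes a
#' domain gap when B's intensity statistics differ from A's.
#'
#' @param train_pairs dataset A.
#' @param test_pairs dataset B.
#' @param net_cfg,tr_cfg configurations.
#' @return `experiment_report` with in-domain (`summary_train_domain`,
#'   metrics on A itself) and cross-domain (`summary`) results.
#' @export
run_cross_generalization <- function(train_pairs, test_pairs, net_cfg, tr_cfg) {
  ids_a <- vapply(train_pairs, `[[`, "", "id")
  ids_b <- vapply(test_pairs, `[[`, "", "id")
  if (length(intersect(ids_a, ids_b)) > 0)
    stop("train and test datasets share image ids (leakage)")
  fit <- train_unet(train_pairs, net_cfg, tr_cfg)
  cross <- evaluate_pairs(predict_pairs(fit$model, test_pairs))
  within <- evaluate_pairs(predict_pairs(fit$model, train_pairs))
  # cross-dataset reporting is IoU/Dice only: with a hard domain shift the
  # predicted mask can be empty, leaving precision undefined
  structure(list(design = "cross_generalization",
                 n_train = length(train_pairs), n_test = length(test_pairs),
                 metrics = cross,
                 summary = summarize_metrics(cross[c("dice", "iou")]),
                 summary_train_domain = summarize_metrics(within[c("dice", "iou")]),
                 curves = fit$curves, model = fit$model, seed = tr_cfg$seed),
            class = "experiment_report")
}

#' Repeated randomized-split trials on a combined dataset
#'
#' Runs `n_trials` independent seeded 80-20 splits (trial seed =
#' base seed + trial index), training and evaluating each, and tabulates
#' per-trial mean +/- SD IoU and Dice - the stability design for a merged
#' dataset.
#'
#' @param pairs combined dataset.
#' @param net_cfg,tr_cfg configurations; `tr_cfg$seed` is the base seed.
#' @param n_trials number of trials (default 5).
#' @param test_fraction held-out fraction.
#' @return `experiment_report` with a `trials` data.frame (trial, seed,
#'   n_test, iou_mean, iou_sd, dice_mean, dice_sd) and `spread`, the
#'   max - min of per-trial mean Dice.
#' @export
run_combined_trials <- function(pairs, net_cfg, tr_cfg, n_trials = 5L,
                                test_fraction = 0.2) {
  if (length(pairs) == 0) stop("combined trials: empty dataset")
  rows <- list(); all_metrics <- list()
  for (tr in seq_len(n_trials)) {
    seed_t <- tr_cfg$seed + tr
    cfg_t <- tr_cfg
    cfg_t$seed <- seed_t
    sp <- make_split(length(pairs), test_fraction, seed = seed_t)
    fit <- train_unet(pairs[sp$train], net_cfg, cfg_t)
    m <- evaluate_pairs(predict_pairs(fit$model, pairs[sp$test]))
    rows[[tr]] <- data.frame(trial = tr, seed = seed_t, n_test = length(sp$test),
                             iou_mean = mean(m$iou), iou_sd = stats::sd(m$iou),
                             dice_mean = mean(m$dice), dice_sd = stats::sd(m$dice))
    all_metrics[[tr]] <- m
  }
  trials <- do.call(rbind, rows)
  structure(list(design = "combined_trials", n_trials = n_trials,
                 trials = trials, spread = max(trials$dice_mean) - min(trials$dice_mean),
                 metrics = all_metrics, seed = tr_cfg$seed),
            class = "experiment_report")
}

#' Write an experiment report to disk
#'
#' Per-image metrics and the mean/SD summary as CSV, learning curves as CSV,
#' the agreement report (with Bland-Altman plot data CSV) as JSON, and a run
#' manifest (design, sizes, seed, package version) as JSON for provenance.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  add <- function(p) paths <<- c(paths, p)
  if (!is.null(report$metrics) && is.data.frame(report$metrics)) {
    utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
    add(file.path(dir, "metrics.csv"))
  }
  if (!is.null(report$summary)) {
    utils::write.csv(cbind(stat = rownames(report$summary), report$summary),
                     file.path(dir, "summary.csv"), row.names = FALSE)
    add(file.path(dir, "summary.csv"))
  }
  if (!is.null(report$curves)) {
    utils::write.csv(report$curves, file.path(dir, "curves.csv"),
                     row.names = FALSE)
    add(file.path(dir, "curves.csv"))
  }
  if (!is.null(report$trials)) {
    utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                     row.names = FALSE)
    add(file.path(dir, "trials.csv"))
  }
  if (!is.null(report$agreement)) {
    agr <- unclass(report$agreement)
    utils::write.csv(agr$ba_data, file.path(dir, "bland_altman.csv"),
                     row.names = FALSE)
    agr$ba_data <- NULL
    jsonlite::write_json(agr, file.path(dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(dir, c("bland_altman.csv", "agreement.json")))
  }
  manifest <- list(design = report$design, n_train = report$n_train,
                   n_test = report$n_test, n_trials = report$n_trials,
                   seed = report$seed,
                   package_version = as.character(utils::packageVersion("usnerveseg")))
  jsonlite::write_json(manifest[!vapply(manifest, is.null, TRUE)],
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  add(file.path(dir, "manifest.json"))
  invisible(paths)
}
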