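#' Pixel-wise confusion counts between predicted and true masks
#'
#' @param pred,truth 0/1 matrices of identical dimensions (1 = nerve).
#' @return object of class `confusion_counts`: list(TP, TN, FP, FN).
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask dimension mismatch")
  p <- pred != 0; t <- truth != 0
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

# empty-vs-empty masks agree perfectly by convention; other zero denominators
# yield NA (the undefined marker)
safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Overlap metrics from confusion counts
#'
#' Dice = 2TP / ((TP+FP) + (TP+FN)); IoU = TP / (TP+FP+FN); accuracy,
#' precision, specificity and sensitivity follow their standard pixel-count
#' definitions. When TP+FP+FN = 0 (both masks empty) Dice and IoU are 1 by
#' convention; any other zero denominator returns NA.
#'
#' @param c a `confusion_counts`.
#' @return numeric value in \[0, 1\] (or NA).
#' @name overlap-metrics
NULL

#' @rdname overlap-metrics
#' @export
dice <- function(c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  2 * c$TP / ((c$TP + c$FP) + (c$TP + c$FN))
}

#' @rdname overlap-metrics
#' @export
iou <- function(c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  c$TP / (c$TP + c$FP + c$FN)
}

#' @rdname overlap-metrics
#' @export
accuracy <- function(c) safe_div(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN)

#' @rdname overlap-metrics
#' @export
precision <- function(c) safe_div(c$TP, c$TP + c$FP)

#' @rdname overlap-metrics
#' @export
specificity <- function(c) safe_div(c$TN, c$TN + c$FP)

#' @rdname overlap-metrics
#' @export
sensitivity <- function(c) safe_div(c$TP, c$TP + c$FN)

#' All six overlap metrics for one mask pair
#'
#' @param pred,truth 0/1 matrices.
#' @param image_id identifier carried into the record.
#' @return one-row data.frame (image_id, dice, iou, accuracy, precision,
#'   specificity, sensitivity).
#' @export
metric_record <- function(pred, truth, image_id = NA_character_) {
  cc <- confusion(pred, truth)
  data.frame(image_id = image_id, dice = dice(cc), iou = iou(cc),
             accuracy = accuracy(cc), precision = precision(cc),
             specificity = specificity(cc), sensitivity = sensitivity(cc),
             stringsAsFactors = FALSE)
}

#' Evaluate predictions over a list of pairs
#'
#' @param pairs pairs carrying `pred` masks (see [predict_pairs()]).
#' @param truth_field which mask to score against (default `"mask"`).
#' @return data.frame of per-image metric records with a `site` column.
#' @export
evaluate_pairs <- function(pairs, truth_field = "mask") {
  recs <- lapply(pairs, function(p) {
    r <- metric_record(p$pred, p[[truth_field]], image_id = p$id)
    r$site <- if (!is.null(p$meta$site)) p$meta$site else NA_character_
    r
  })
  do.call(rbind, recs)
}

#' Aggregate metric records as mean and sample SD
#'
#' @param records data.frame of metric records.
#' @param strict error (rather than flag SD = 0) on a single record.
#' @return data.frame with rows `mean` and `sd` per metric column.
#' @export
summarize_metrics <- function(records, strict = TRUE) {
  if (is.null(records) || nrow(records) == 0) stop("no metric records")
  cols <- intersect(c("dice", "iou", "accuracy", "precision", "specificity",
                      "sensitivity"), names(records))
  if (any(is.na(records[cols]))) stop("undefined metric values present")
  if (nrow(records) == 1 && strict)
    stop("single record: sample SD undefined in strict mode")
  m <- vapply(records[cols], mean, numeric(1))
  s <- if (nrow(records) == 1) {
    stats::setNames(rep(0, length(cols)), cols)
  } else {
    vapply(records[cols], stats::sd, numeric(1))
  }
  out <- rbind(mean = m, sd = s)
  as.data.frame(out)
}
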