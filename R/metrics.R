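# Per-pixel segmentation evaluation.  Each pixel is one classification
# decision: TP = predicted foreground that is truly foreground, FP =
# predicted foreground on true background, FN = missed true foreground, TN =
# the rest.  From the counts:
#
#   accuracy  = (TP + TN) / (TP + TN + FP + FN)
#   overlap   = |A & B| / |A | B|          (Jaccard index of the foregrounds)
#   precision = TP / (TP + FP),  recall = TP / (TP + FN)
#   F         = 2 P R / (P + R)            (harmonic mean)
#
# Degenerate denominators follow fixed conventions (see score_masks) so that
# identical empty masks score perfect and a total miss scores zero.

#' Per-pixel confusion counts between two binary masks
#'
#' @param predicted,reference Binary mask matrices of identical shape.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(predicted, reference) {
  assert_binary_mask(predicted, "predicted")
  assert_binary_mask(reference, "reference")
  if (!identical(dim(predicted), dim(reference)))
    stop("mask shapes differ", call. = FALSE)
  tp <- sum(predicted == 1 & reference == 1)
  fp <- sum(predicted == 1 & reference == 0)
  fn <- sum(predicted == 0 & reference == 1)
  tn <- length(predicted) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Score a predicted mask against a reference mask
#'
#' Degenerate conventions: precision with `tp + fp = 0` is 1 if `fn = 0` else
#' 0 (and symmetrically for recall); overlap with an empty union is 1; F with
#' `P + R = 0` is 0.
#'
#' @param predicted,reference Binary mask matrices of identical shape.
#' @param pair_id Identifier copied into the record.
#' @return One-row data frame: `pair_id`, confusion counts, `accuracy`,
#'   `overlap`, `precision`, `recall`, `f_measure`.
#' @export
score_masks <- function(predicted, reference, pair_id = NA_character_) {
  cc <- confusion_counts(predicted, reference)
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  accuracy <- (cc$tp + cc$tn) / total
  uni <- cc$tp + cc$fp + cc$fn
  overlap <- if (uni == 0) 1 else cc$tp / uni
  precision <- if (cc$tp + cc$fp == 0) (if (cc$fn == 0) 1 else 0) else
    cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$tp + cc$fn == 0) (if (cc$fp == 0) 1 else 0) else
    cc$tp / (cc$tp + cc$fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.frame(pair_id = as.character(pair_id), tp = cc$tp, fp = cc$fp,
             fn = cc$fn, tn = cc$tn, accuracy = accuracy, overlap = overlap,
             precision = precision, recall = recall, f_measure = f,
             stringsAsFactors = FALSE)
}

#' Score a list of predictions against reference masks
#'
#' @param predicted List of binary masks.
#' @param reference List of reference masks (or [image_pair()]s, whose
#'   `mask`/`clean_mask` is used).
#' @param pair_ids Identifiers; defaults to the pairs' ids when available.
#' @param use_clean Use `clean_mask` of an [image_pair()] when present.
#' @return Data frame of per-image [score_masks()] records.
#' @export
score_cohort <- function(predicted, reference, pair_ids = NULL,
                         use_clean = FALSE) {
  stopifnot(length(predicted) == length(reference))
  refm <- lapply(reference, function(r) {
    if (inherits(r, "image_pair")) {
      if (use_clean && !is.null(r$clean_mask)) r$clean_mask else r$mask
    } else r
  })
  if (is.null(pair_ids))
    pair_ids <- vapply(seq_along(reference), function(i) {
      r <- reference[[i]]
      if (inherits(r, "image_pair")) r$pair_id else as.character(i)
    }, character(1))
  do.call(rbind, lapply(seq_along(predicted), function(i)
    score_masks(predicted[[i]], refm[[i]], pair_ids[i])))
}

METRIC_NAMES <- c("accuracy", "overlap", "precision", "recall", "f_measure")

#' Cohort summary of one metric (min / max / mean / sd)
#'
#' Standard deviation uses the population convention (divide by n).
#'
#' @param records Nonempty data frame of [score_masks()] records.
#' @param metric_name One of `"accuracy"`, `"overlap"`, `"precision"`,
#'   `"recall"`, `"f_measure"`.
#' @return One-row data frame: `metric`, `minimum`, `maximum`, `mean`,
#'   `standard_deviation`.
#' @export
summarize_metrics <- function(records, metric_name = "f_measure") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data frame", call. = FALSE)
  if (!metric_name %in% METRIC_NAMES)
    stop("unknown metric '", metric_name, "'; expected one of: ",
         paste(METRIC_NAMES, collapse = ", "), call. = FALSE)
  v <- records[[metric_name]]
  data.frame(metric = metric_name, minimum = min(v), maximum = max(v),
             mean = mean(v), standard_deviation = sqrt(mean((v - mean(v))^2)),
             stringsAsFactors = FALSE)
}

#' Compare methods scored on the same images
#'
#' One row per method with mean and population sd of accuracy, overlap and
#' F-measure; all methods must cover the same `pair_id` set.
#'
#' @param per_method_records Named list of [score_cohort()] data frames.
#' @return Data frame with one row per method, CSV-writable.
#' @export
compare_methods <- function(per_method_records) {
  stopifnot(is.list(per_method_records), length(per_method_records) > 0,
            !is.null(names(per_method_records)))
  ids <- lapply(per_method_records, function(r) sort(r$pair_id))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]])))
    stop("methods were not scored on the same pair_id sets", call. = FALSE)
  rows <- lapply(names(per_method_records), function(m) {
    r <- per_method_records[[m]]
    s <- function(metric) summarize_metrics(r, metric)
    a <- s("accuracy"); o <- s("overlap"); f <- s("f_measure")
    data.frame(method = m,
               accuracy_mean = a$mean, accuracy_sd = a$standard_deviation,
               overlap_mean = o$mean, overlap_sd = o$standard_deviation,
               f_mean = f$mean, f_sd = f$standard_deviation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
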