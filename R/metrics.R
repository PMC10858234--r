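#' Match labeled predictions to labeled ground truth
#'
#' A prediction and a ground-truth vertebra match (true positive) when they
#' carry the same anatomical label AND their IoU strictly exceeds the
#' threshold. The threshold must exceed 0.5, which guarantees each mask can
#' match at most one counterpart. Unmatched predictions are false positives,
#' unmatched ground-truth vertebrae false negatives. Requiring label
#' equality makes a label shift (the missed-vertebra failure mode) score
#' zero true positives: identification is part of quality.
#'
#' @param preds named list of prediction masks (names = anatomical labels),
#'   e.g. from [spine_masks()].
#' @param gts named list of ground-truth masks.
#' @param iou_threshold matching threshold, in (0.5, 1].
#' @param ignore_unannotated drop predictions whose class has no ground
#'   truth annotation instead of counting them as false positives (some
#'   public datasets annotate only a subset of visible vertebrae, which
#'   makes the default accounting pessimistic).
#' @return an object of class `match_set` with elements `tp`
#'   (data.frame: label, iou), `fp` (labels), `fn` (labels),
#'   `iou_threshold`.
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.7,
                            ignore_unannotated = FALSE) {
  stopifnot(iou_threshold > 0.5, iou_threshold <= 1)
  pl <- names(preds); gl <- names(gts)
  if (length(preds) && (is.null(pl) || anyDuplicated(pl)))
    stop("predictions must be uniquely named by label", call. = FALSE)
  if (length(gts) && (is.null(gl) || anyDuplicated(gl)))
    stop("ground truth must be uniquely named by label", call. = FALSE)
  if (ignore_unannotated) {
    preds <- preds[pl %in% gl]
    pl <- names(preds)
  }
  tp_lab <- character(0); tp_iou <- numeric(0)
  for (lab in intersect(pl, gl)) {
    iou <- mask_iou(preds[[lab]], gts[[lab]])
    if (iou > iou_threshold) {
      tp_lab <- c(tp_lab, lab)
      tp_iou <- c(tp_iou, iou)
    }
  }
  new_match_set(tp_lab, tp_iou,
                fp = setdiff(pl, tp_lab),
                fn = setdiff(gl, tp_lab),
                iou_threshold = iou_threshold)
}

# Constructor shared by match_instances() and randomized property tests.
new_match_set <- function(tp_labels, tp_ious, fp, fn, iou_threshold) {
  structure(list(
    tp = data.frame(label = as.character(tp_labels), iou = as.numeric(tp_ious),
                    stringsAsFactors = FALSE),
    fp = as.character(fp), fn = as.character(fn),
    iou_threshold = iou_threshold), class = "match_set")
}

#' Panoptic quality of a match set
#'
#' `PQ = sum of TP IoUs / (|TP| + |FP|/2 + |FN|/2)`, which factors exactly
#' into segmentation quality `SQ = mean TP IoU` (0 when there are no true
#' positives) times recognition quality `RQ = |TP| / (|TP| + |FP|/2 +
#' |FN|/2)`, the F-measure form of detection quality.
#'
#' @param match a `match_set` from [match_instances()].
#' @return `list(pq, sq, rq)`, each in `[0, 1]`, with `pq == sq * rq`.
#' @export
panoptic_quality <- function(match) {
  ntp <- nrow(match$tp); nfp <- length(match$fp); nfn <- length(match$fn)
  if (ntp + nfp + nfn == 0L)
    stop("empty evaluation: no predictions and no ground truth", call. = FALSE)
  denom <- ntp + nfp / 2 + nfn / 2
  sq <- if (ntp == 0L) 0 else sum(match$tp$iou) / ntp
  rq <- ntp / denom
  list(pq = sum(match$tp$iou) / denom, sq = sq, rq = rq)
}

#' Evaluate a labeled prediction against ground truth
#'
#' Per-class Dice on the label-matched mask pair (0 when a ground-truth
#' class has no same-labeled prediction), overall Dice as the unweighted
#' mean over classes present in the ground truth, and panoptic quality with
#' its SQ/RQ decomposition per class and pooled, at each matching threshold.
#'
#' @param pred a `labeled_spine` or a named list of prediction masks.
#' @param gt a named list of ground-truth masks (e.g. from
#'   [rasterize_annotation()]), or a `ground_truth_annotation` (rasterized
#'   at the prediction resolution).
#' @param thresholds IoU matching thresholds, each in (0.5, 1].
#' @param ignore_unannotated see [match_instances()].
#' @return an object of class `spine_eval`: `dice_per_class` (named),
#'   `dice_overall`, and `pq` — a data.frame with one row per (threshold,
#'   class) plus a pooled `"all"` row per threshold, columns
#'   `threshold, class, pq, sq, rq`.
#' @export
evaluate_spine <- function(pred, gt, thresholds = c(0.7, 0.8),
                           ignore_unannotated = FALSE) {
  preds <- if (inherits(pred, "labeled_spine")) spine_masks(pred) else pred
  if (inherits(gt, "ground_truth_annotation")) gt <- rasterize_annotation(gt)
  if (length(gt) == 0L)
    stop("ground truth holds no vertebrae", call. = FALSE)
  if (length(preds)) {
    check_same_dim(preds[[1]], gt[[1]])
  }

  dice <- vapply(names(gt), function(lab) {
    if (lab %in% names(preds)) mask_dice(preds[[lab]], gt[[lab]]) else 0
  }, numeric(1))

  rows <- list()
  for (th in thresholds) {
    ms <- match_instances(preds, gt, th, ignore_unannotated)
    pooled <- panoptic_quality(ms)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = th, class = "all",
      pq = pooled$pq, sq = pooled$sq, rq = pooled$rq)
    for (lab in names(gt)) {
      sub <- new_match_set(
        ms$tp$label[ms$tp$label == lab], ms$tp$iou[ms$tp$label == lab],
        fp = ms$fp[ms$fp == lab], fn = ms$fn[ms$fn == lab],
        iou_threshold = th)
      q <- panoptic_quality(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, class = lab, pq = q$pq, sq = q$sq, rq = q$rq)
    }
  }
  structure(list(dice_per_class = dice,
                 dice_overall = mean(dice),
                 pq = do.call(rbind, rows)),
            class = "spine_eval")
}

#' @export
print.spine_eval <- function(x, ...) {
  cat(sprintf("<spine_eval> overall Dice %.3f over %d classes\n",
              x$dice_overall, length(x$dice_per_class)))
  cat("  per-class Dice: ",
      paste(sprintf("%s=%.2f", names(x$dice_per_class), x$dice_per_class),
            collapse = " "), "\n", sep = "")
  pooled <- x$pq[x$pq$class == "all", ]
  for (i in seq_len(nrow(pooled)))
    cat(sprintf("  IoU>%.2f: PQ %.3f = SQ %.3f x RQ %.3f\n",
                pooled$threshold[i], pooled$pq[i], pooled$sq[i],
                pooled$rq[i]))
  invisible(x)
}
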