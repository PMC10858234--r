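# Canonical top-to-bottom vertebral vocabulary visible on lateral spine
# films. C2 is the first detectable body at the top of a cervical view; S1
# is commonly the last visible one at the bottom of a lumbar view. C1 is
# never emitted.
VERTEBRA_VOCAB <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5), "S1")

#' Find the reference vertebra among instance candidates
#'
#' The instance segmenter distinguishes the two anatomically distinctive
#' reference bodies — cone-shaped C2 (top of cervical films) and triangular
#' S1 (bottom of lumbar films) — from ordinary vertebrae. The
#' highest-confidence mask tagged C2 or S1 wins; when both classes appear on
#' one image (which single-region films should not produce) the single
#' highest-confidence reference is used and a warning is issued. Absence of
#' any reference tag is a valid outcome, not an error.
#'
#' @param instance_masks list of [instance_mask()] carrying class tags.
#' @return `list(ref_class, ref_mask)`; `ref_class` is `"C2"`, `"S1"` or
#'   `"none"` (in which case `ref_mask` is `NULL`).
#' @export
find_reference <- function(instance_masks) {
  tags <- vapply(instance_masks, function(m) m$class_tag, character(1))
  is_ref <- tags %in% c("C2", "S1")
  if (!any(is_ref)) return(list(ref_class = "none", ref_mask = NULL))
  if (all(c("C2", "S1") %in% tags))
    warning("both C2 and S1 tagged on one image; ",
            "using the highest-confidence reference", call. = FALSE)
  conf <- vapply(instance_masks, function(m) {
    if (is.na(m$confidence)) 0 else m$confidence
  }, numeric(1))
  conf[!is_ref] <- -Inf
  best <- which.max(conf)
  list(ref_class = tags[best], ref_mask = instance_masks[[best]])
}

#' Assign anatomical labels by zipping from the reference vertebra
#'
#' The reference detection is first localized among the sorted ensemble
#' masks by maximum IoU (which must exceed 0.5). With C2 as the anchor,
#' labels zip down the column (C2, C3, ..., C7, T1, ...); with S1 they zip
#' up (S1, then L5, L4, ..., L1, T12, T11, ...). Masks on the far side of
#' the reference (above C2 or below S1) are left unlabeled rather than
#' guessed, and labeling stops if the column outruns the anatomical
#' vocabulary (with a warning).
#'
#' @param sorted_masks ensemble masks ordered top-to-bottom (see
#'   [sort_masks()]).
#' @param ref_class `"C2"`, `"S1"` or `"none"`.
#' @param ref_mask the reference detection as an [instance_mask()].
#' @return an object of class `labeled_spine`: `vertebrae` (list of
#'   `list(mask, label)` in image order), `reference`, `direction`
#'   (`"zip_down"`, `"zip_up"` or `"none"`), `unlabeled`.
#' @export
assign_labels <- function(sorted_masks, ref_class, ref_mask = NULL) {
  if (identical(ref_class, "none") || is.null(ref_mask)) {
    return(new_labeled_spine(list(), "none", "none", sorted_masks))
  }
  stopifnot(ref_class %in% c("C2", "S1"))
  ious <- vapply(sorted_masks, function(m) mask_iou(m, ref_mask), numeric(1))
  anchor <- which.max(ious)
  if (length(ious) == 0L || ious[anchor] <= 0.5)
    stop("reference localization failure: no ensemble mask matches the ",
         ref_class, " detection at IoU > 0.5", call. = FALSE)

  n <- length(sorted_masks)
  labels <- rep(NA_character_, n)
  if (ref_class == "C2") {
    seq_lab <- VERTEBRA_VOCAB[seq(match("C2", VERTEBRA_VOCAB),
                                  length(VERTEBRA_VOCAB))]
    run <- anchor:n                      # zip down
    direction <- "zip_down"
  } else {
    seq_lab <- rev(VERTEBRA_VOCAB[seq(1, match("S1", VERTEBRA_VOCAB))])
    run <- anchor:1                      # zip up
    direction <- "zip_up"
  }
  if (length(run) > length(seq_lab)) {
    warning("more masks than the anatomical vocabulary allows beyond ",
            ref_class, "; extra masks left unlabeled", call. = FALSE)
    run <- run[seq_along(seq_lab)]
  }
  labels[run] <- seq_lab[seq_along(run)]

  labeled <- which(!is.na(labels))
  vertebrae <- lapply(labeled, function(i)
    list(mask = sorted_masks[[i]], label = labels[i]))
  new_labeled_spine(vertebrae, ref_class, direction,
                    sorted_masks[is.na(labels)])
}

new_labeled_spine <- function(vertebrae, reference, direction, unlabeled) {
  structure(list(vertebrae = vertebrae, reference = reference,
                 direction = direction, unlabeled = unlabeled),
            class = "labeled_spine")
}

#' Labels of a labeled spine, in image order
#' @param spine a `labeled_spine`.
#' @return character vector of anatomical labels, top to bottom.
#' @export
spine_labels <- function(spine) {
  vapply(spine$vertebrae, function(v) v$label, character(1))
}

#' Masks of a labeled spine as a named list
#' @param spine a `labeled_spine`.
#' @return list of `instance_mask`, named by anatomical label.
#' @export
spine_masks <- function(spine) {
  out <- lapply(spine$vertebrae, function(v) v$mask)
  names(out) <- spine_labels(spine)
  out
}

#' @export
print.labeled_spine <- function(x, ...) {
  cat(sprintf("<labeled_spine> reference: %s (%s) | %d labeled, %d unlabeled\n",
              x$reference, x$direction, length(x$vertebrae),
              length(x$unlabeled)))
  if (length(x$vertebrae))
    cat("  ", paste(spine_labels(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Segment, fuse and label one spine image
#'
#' Convenience wrapper chaining the ensemble, reference finding and label
#' assignment: [run_ensemble()] on the two candidate segmentations,
#' [find_reference()] on the instance candidates, [assign_labels()] on the
#' sorted result. Warnings from each stage are carried through. When no
#' reference is tagged the result is an unlabeled spine with
#' `reference = "none"` (the segmentation is still returned).
#'
#' @inheritParams run_ensemble
#' @return a `labeled_spine` with the underlying `spine_ensemble` attached
#'   as `$ensemble`.
#' @export
label_pipeline <- function(semantic, instance_masks, cfg = ensemble_config()) {
  ens <- run_ensemble(semantic, instance_masks, cfg)
  ref <- find_reference(instance_masks)
  spine <- assign_labels(ens$kept, ref$ref_class, ref$ref_mask)
  spine$ensemble <- ens
  spine
}
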