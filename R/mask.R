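#' Construct an instance mask
#'
#' The unit every ensemble rule operates on: one candidate vertebral body as
#' a binary raster, together with where it came from (`source`), an optional
#' anatomical class tag from the instance segmenter, an optional detection
#' confidence, and the rule that put it into the final set (`provenance`).
#'
#' All masks compared within one pipeline run must share identical raster
#' dimensions; set operations check this and fail loudly on a mismatch.
#'
#' @param pixels logical or 0/1 numeric matrix (rows = image rows, row index
#'   increasing downward). Must contain at least one foreground pixel and,
#'   when `check = TRUE`, exactly one 8-connected foreground component.
#' @param source one of `"semantic"`, `"instance"`, `"ensemble"`.
#' @param class_tag one of `"C2"`, `"S1"`, `"vertebra"`, `"none"`.
#' @param confidence detection confidence in `[0, 1]`, or `NA` when the
#'   producing segmenter does not report one.
#' @param provenance which ensemble rule produced the mask: one of
#'   `"agreement_union"`, `"instance_takeover"`, `"pickup"`, `"raw"`.
#' @param check verify the single-component invariant (costs one labeling
#'   pass; internal callers that construct masks from already-labeled
#'   components skip it).
#' @return an object of class `instance_mask`.
#' @export
instance_mask <- function(pixels,
                          source = c("instance", "semantic", "ensemble"),
                          class_tag = c("none", "C2", "S1", "vertebra"),
                          confidence = NA_real_,
                          provenance = c("raw", "agreement_union",
                                         "instance_takeover", "pickup"),
                          check = TRUE) {
  source <- match.arg(source)
  class_tag <- match.arg(class_tag)
  provenance <- match.arg(provenance)
  if (!is.matrix(pixels))
    stop("`pixels` must be a matrix", call. = FALSE)
  px <- pixels != 0
  storage.mode(px) <- "logical"
  if (!any(px))
    stop("empty mask: an instance mask needs at least one foreground pixel",
         call. = FALSE)
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop("`confidence` must lie in [0, 1]", call. = FALSE)
  if (check && n_components(px) != 1L)
    stop("mask has more than one 8-connected component; ",
         "split components upstream (see extract_instances())", call. = FALSE)
  structure(
    list(pixels = px, source = source, class_tag = class_tag,
         confidence = confidence, provenance = provenance),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  ctr <- mask_centroid(x)
  cat(sprintf(
    "<instance_mask> %dx%d raster | area %d px | centroid (%.1f, %.1f)\n",
    nrow(x$pixels), ncol(x$pixels), mask_area(x), ctr[1], ctr[2]))
  cat(sprintf("  source: %s | class: %s | confidence: %s | provenance: %s\n",
              x$source, x$class_tag,
              ifelse(is.na(x$confidence), "-",
                     sprintf("%.2f", x$confidence)),
              x$provenance))
  invisible(x)
}

is_instance_mask <- function(x) inherits(x, "instance_mask")

as_pixels <- function(x) {
  if (is_instance_mask(x)) x$pixels
  else if (is.matrix(x)) x != 0
  else stop("expected an instance_mask or a binary matrix", call. = FALSE)
}

check_same_dim <- function(a, b) {
  da <- dim(as_pixels(a)); db <- dim(as_pixels(b))
  if (!identical(da, db))
    stop(sprintf("incompatible raster dimensions: %dx%d vs %dx%d",
                 da[1], da[2], db[1], db[2]), call. = FALSE)
  invisible(TRUE)
}

#' Foreground area of a mask
#'
#' @param mask an [instance_mask()] or binary matrix.
#' @return number of foreground pixels.
#' @export
mask_area <- function(mask) sum(as_pixels(mask))

#' Centroid of a mask
#'
#' Mean foreground pixel coordinate, 0-based, as `c(row, col)` with the row
#' index increasing downward (image convention, so "down the spine" means
#' increasing row).
#'
#' @inheritParams mask_area
#' @return numeric length-2 vector `c(row, col)`.
#' @export
mask_centroid <- function(mask) {
  px <- as_pixels(mask)
  idx <- which(px, arr.ind = TRUE)
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

#' Agreement between two masks
#'
#' `area(a ∩ b) / max(area(a), area(b))`: symmetric, 1 exactly when the two
#' rasters are pixel-identical, 0 when disjoint. Two candidate masks from
#' different segmenters are considered the same vertebra when their agreement
#' exceeds the threshold eta.
#'
#' @param a,b masks sharing raster dimensions.
#' @return agreement in `[0, 1]`.
#' @export
mask_agreement <- function(a, b) {
  check_same_dim(a, b)
  pa <- as_pixels(a); pb <- as_pixels(b)
  sum(pa & pb) / max(sum(pa), sum(pb))
}

#' Fraction of an instance mask covered by a semantic mask
#'
#' `area(semantic ∩ instance) / area(instance)`. Not symmetric: a large value
#' combined with a small agreement flags a semantic blob spanning several
#' instance masks (the merged-vertebrae failure mode the takeover rule fixes).
#'
#' @param semantic the semantic-source mask (or blob).
#' @param instance the instance-source mask; the denominator is its area.
#' @return coverage fraction in `[0, 1]`.
#' @export
instance_overlap_fraction <- function(semantic, instance) {
  check_same_dim(semantic, instance)
  ps <- as_pixels(semantic); pi_ <- as_pixels(instance)
  sum(ps & pi_) / sum(pi_)
}

#' Intersection over union of two masks
#'
#' @inheritParams mask_agreement
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  check_same_dim(a, b)
  pa <- as_pixels(a); pb <- as_pixels(b)
  inter <- sum(pa & pb)
  inter / (sum(pa) + sum(pb) - inter)
}

#' Dice coefficient of two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; related to IoU by `dice = 2*iou / (1 + iou)`.
#'
#' @inheritParams mask_agreement
#' @return Dice in `[0, 1]`.
#' @export
mask_dice <- function(a, b) {
  check_same_dim(a, b)
  pa <- as_pixels(a); pb <- as_pixels(b)
  2 * sum(pa & pb) / (sum(pa) + sum(pb))
}

#' Union of two overlapping masks
#'
#' Pixelwise OR, used by the agreement rule: a matched semantic/instance pair
#' contributes the union of the two contours. The inputs must overlap —
#' the union of two disjoint masks would violate the single-component
#' invariant, and indicates an invalid pairing upstream.
#'
#' @inheritParams mask_agreement
#' @return an `instance_mask` with `source = "ensemble"` and
#'   `provenance = "agreement_union"`. The class tag and confidence of the
#'   instance-side input (if any) are carried over.
#' @export
mask_union <- function(a, b) {
  check_same_dim(a, b)
  px <- as_pixels(a) | as_pixels(b)
  if (n_components(px) != 1L)
    stop("union of the two masks is disconnected: invalid pairing",
         call. = FALSE)
  tag <- "none"; conf <- NA_real_
  for (m in list(a, b)) {
    if (is_instance_mask(m) && m$class_tag != "none") {
      tag <- m$class_tag
      conf <- m$confidence
    }
  }
  instance_mask(px, source = "ensemble", class_tag = tag, confidence = conf,
                provenance = "agreement_union", check = FALSE)
}

# 8-connected labeling of a logical matrix via the pixel adjacency graph.
# Returns an integer matrix, 0 = background, components numbered from 1.
# EBImage::bwlabel is 4-connected, hence this route.
label_components <- function(px) {
  lab <- matrix(0L, nrow(px), ncol(px))
  fg <- which(px)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(px)
  id <- integer(length(px)); id[fg] <- seq_along(fg)
  edges <- integer(0)
  for (off in c(1L, nr, nr + 1L, nr - 1L)) { # S, E, SE, NE neighbors
    from <- fg
    to <- fg + off
    ok <- to >= 1L & to <= length(px)
    # forbid wrap-around across matrix columns
    if (off == 1L) ok <- ok & (from %% nr != 0L)
    if (off == nr + 1L) ok <- ok & (from %% nr != 0L)
    if (off == nr - 1L) ok <- ok & (from %% nr != 1L)
    ok[ok] <- px[to[ok]]
    if (any(ok))
      edges <- c(edges, rbind(id[from[ok]], id[to[ok]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  lab[fg] <- igraph::components(g)$membership
  lab
}

n_components <- function(px) {
  fg <- which(px)
  if (length(fg) == 0L) return(0L)
  max(label_components(px))
}

fill_holes <- function(px) {
  EBImage::fillHull(matrix(as.integer(px), nrow(px), ncol(px))) != 0
}

#' Extract instance candidates from a semantic raster
#'
#' Realizes "contour approximation" on a per-pixel segmentation: each
#' 8-connected foreground component becomes one candidate mask, holes are
#' filled, and components below a minimum-area floor are discarded as
#' speckle. Two vertebrae merged by even a one-pixel bridge come out as a
#' single blob — the semantic failure mode the ensemble repairs downstream.
#'
#' @param raster binary matrix (or `instance_mask`), the semantic foreground.
#' @param min_area_px discard components smaller than this many pixels.
#' @return list of `instance_mask` objects with `source = "semantic"`;
#'   empty list for an all-background raster.
#' @export
extract_instances <- function(raster, min_area_px = 50) {
  px <- as_pixels(raster)
  if (!any(px)) return(list())
  px <- fill_holes(px)
  lab <- label_components(px)
  ks <- seq_len(max(lab))
  out <- list()
  for (k in ks) {
    comp <- lab == k
    if (sum(comp) < min_area_px) next
    out[[length(out) + 1L]] <-
      instance_mask(comp, source = "semantic", check = FALSE)
  }
  out
}

# Trace the outer contour of a mask as 0-based (row, col) boundary pixel
# centers, ordered around the component.
trace_contour <- function(mask) {
  px <- as_pixels(mask)
  ct <- EBImage::ocontour(matrix(as.integer(px), nrow(px), ncol(px)))[[1]]
  colnames(ct) <- c("row", "col")
  ct
}
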