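# Point-in-polygon over pixel centers. Pixel centers sit at integer
# (row, col) coordinates, 0-based. A pixel is foreground when its center is
# strictly inside the polygon (even-odd rule) OR lies exactly on the
# boundary: an axis-aligned rectangle with corners (10,10) and (40,30)
# therefore fills 31 x 21 = 651 pixels.
rasterize_polygon <- function(points, height, width) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  py <- points[, 1]; px <- points[, 2]     # y = row, x = col
  r0 <- max(0L, floor(min(py))); r1 <- min(height - 1L, ceiling(max(py)))
  c0 <- max(0L, floor(min(px))); c1 <- min(width - 1L, ceiling(max(px)))
  out <- matrix(FALSE, height, width)
  if (r1 < r0 || c1 < c0) return(out)
  rs <- r0:r1; cs <- c0:c1
  yy <- rep(rs, times = length(cs))
  xx <- rep(cs, each = length(rs))
  n <- length(py)
  inside <- rep(FALSE, length(yy))
  onedge <- rep(FALSE, length(yy))
  j <- n
  for (i in seq_len(n)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    cross <- ((y1 > yy) != (y2 > yy)) &
      (xx < (x2 - x1) * (yy - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    # exact-boundary test: collinear with the edge and within its extent
    d <- abs((x2 - x1) * (yy - y1) - (y2 - y1) * (xx - x1))
    onseg <- d < 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      xx >= pmin(x1, x2) - 1e-9 & xx <= pmax(x1, x2) + 1e-9 &
      yy >= pmin(y1, y2) - 1e-9 & yy <= pmax(y1, y2) + 1e-9
    onedge <- onedge | onseg
    j <- i
  }
  keep <- inside | onedge
  out[cbind(yy[keep] + 1L, xx[keep] + 1L)] <- TRUE
  out
}

polygon_area <- function(points) {
  y <- points[, 1]; x <- points[, 2]
  n <- nrow(points)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Proper (crossing) intersection between two segments; shared endpoints of
# adjacent edges do not count.
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

is_simple_polygon <- function(points) {
  n <- nrow(points)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next         # first and last edges are adjacent
      if (segments_cross(points[i, ], points[i %% n + 1L, ],
                         points[j, ], points[j %% n + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Build a ground-truth annotation
#'
#' Per-vertebra outline as 8 ordered landmark points (polygon corners plus
#' edge midpoints, the convention of landmark-annotated spine archives) and
#' an anatomical label. Polygons must be simple with positive area; labels
#' must be unique.
#'
#' @param vertebrae list of `list(label =, landmarks =)` where `landmarks`
#'   is an 8 x 2 matrix of 0-based `(row, col)` points in polygon order.
#' @param image_size integer `c(height, width)`.
#' @param source_id free-text identifier of the image.
#' @param reorder_landmarks re-order each vertebra's landmarks by angle
#'   about their centroid before validation, for datasets whose landmark
#'   order is not a polygon traversal.
#' @return object of class `ground_truth_annotation`.
#' @export
ground_truth_annotation <- function(vertebrae, image_size,
                                    source_id = "unknown",
                                    reorder_landmarks = FALSE) {
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  labs <- vapply(vertebrae, function(v) v$label, character(1))
  if (anyDuplicated(labs))
    stop("duplicate vertebra labels: ",
         paste(labs[duplicated(labs)], collapse = ", "), call. = FALSE)
  vertebrae <- lapply(vertebrae, function(v) {
    lm <- v$landmarks
    if (!is.matrix(lm) || nrow(lm) != 8L || ncol(lm) != 2L)
      stop("vertebra ", v$label, ": expected exactly 8 (row, col) landmarks",
           call. = FALSE)
    if (reorder_landmarks) {
      ang <- atan2(lm[, 1] - mean(lm[, 1]), lm[, 2] - mean(lm[, 2]))
      lm <- lm[order(ang), , drop = FALSE]
    }
    if (polygon_area(lm) <= 0)
      stop("vertebra ", v$label, ": degenerate polygon (zero area)",
           call. = FALSE)
    if (!is_simple_polygon(lm))
      stop("vertebra ", v$label, ": self-intersecting polygon", call. = FALSE)
    list(label = v$label, landmarks = lm)
  })
  structure(list(vertebrae = vertebrae,
                 image_size = as.integer(image_size),
                 source_id = source_id),
            class = "ground_truth_annotation")
}

#' @export
print.ground_truth_annotation <- function(x, ...) {
  cat(sprintf("<ground_truth_annotation> %s | %dx%d | %d vertebrae: %s\n",
              x$source_id, x$image_size[1], x$image_size[2],
              length(x$vertebrae),
              paste(vapply(x$vertebrae, `[[`, character(1), "label"),
                    collapse = " ")))
  invisible(x)
}

#' Save / load a ground-truth annotation as JSON
#'
#' @param ann a `ground_truth_annotation`.
#' @param path JSON file path.
#' @name annotation_io
#' @export
save_annotation <- function(ann, path) {
  obj <- list(
    source_id = ann$source_id,
    image_size = ann$image_size,
    vertebrae = lapply(ann$vertebrae, function(v)
      list(label = v$label, landmarks = unname(v$landmarks)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname annotation_io
#' @param reorder_landmarks see [ground_truth_annotation()].
#' @export
load_annotation <- function(path, reorder_landmarks = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(obj$vertebrae) || is.null(obj$image_size))
    stop("malformed annotation file: ", path, call. = FALSE)
  verts <- if (is.data.frame(obj$vertebrae)) {
    lapply(seq_len(nrow(obj$vertebrae)), function(i)
      list(label = obj$vertebrae$label[i],
           landmarks = matrix(unlist(obj$vertebrae$landmarks[[i]]),
                              ncol = 2, byrow = is.list(obj$vertebrae$landmarks[[i]]))))
  } else {
    lapply(obj$vertebrae, function(v)
      list(label = v$label,
           landmarks = matrix(unlist(v$landmarks), ncol = 2,
                              byrow = is.list(v$landmarks))))
  }
  ground_truth_annotation(verts, obj$image_size,
                          source_id = obj$source_id %||% "unknown",
                          reorder_landmarks = reorder_landmarks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize an annotation to labeled masks
#'
#' Fills each 8-landmark polygon on the annotation's pixel grid; pixel
#' centers on the polygon boundary are foreground.
#'
#' @param ann a `ground_truth_annotation`.
#' @return named list of `instance_mask` (names = labels).
#' @export
rasterize_annotation <- function(ann) {
  out <- lapply(ann$vertebrae, function(v) {
    px <- rasterize_polygon(v$landmarks, ann$image_size[1], ann$image_size[2])
    if (!any(px))
      stop("vertebra ", v$label, " rasterizes to an empty mask", call. = FALSE)
    instance_mask(px, source = "semantic", check = FALSE)
  })
  names(out) <- vapply(ann$vertebrae, `[[`, character(1), "label")
  out
}

#' Read / write binary masks as PNG
#'
#' Single-channel PNG, 0 = background, 255 = foreground.
#'
#' @param mask an `instance_mask` or binary matrix.
#' @param path PNG file path.
#' @name mask_png
#' @export
write_mask_png <- function(mask, path) {
  px <- as_pixels(mask)
  png::writePNG(matrix(as.numeric(px), nrow(px), ncol(px)), path)
  invisible(path)
}

#' @rdname mask_png
#' @return `read_mask_png` returns a logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Save / load an instance segmentation set
#'
#' A directory of per-instance mask PNGs plus a JSON sidecar
#' (`instances.json`) listing, per file, the class tag and optional
#' confidence.
#'
#' @param masks list of [instance_mask()].
#' @param dir directory (created if missing).
#' @name instance_set_io
#' @export
save_instance_set <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(masks), function(i) {
    f <- sprintf("instance_%03d.png", i)
    write_mask_png(masks[[i]], file.path(dir, f))
    e <- list(file = f, class_tag = masks[[i]]$class_tag)
    if (!is.na(masks[[i]]$confidence)) e$confidence <- masks[[i]]$confidence
    e
  })
  jsonlite::write_json(entries, file.path(dir, "instances.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname instance_set_io
#' @return `load_instance_set` returns a list of `instance_mask`.
#' @export
load_instance_set <- function(dir) {
  sidecar <- file.path(dir, "instances.json")
  if (!file.exists(sidecar))
    stop("missing instance sidecar: ", sidecar, call. = FALSE)
  entries <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  lapply(entries, function(e) {
    instance_mask(read_mask_png(file.path(dir, e$file)),
                  source = "instance",
                  class_tag = e$class_tag %||% "none",
                  confidence = as.numeric(e$confidence %||% NA_real_),
                  check = FALSE)
  })
}

#' Save / load a labeled spine as JSON (plus mask PNGs)
#'
#' `spine.json` lists per vertebra: label, area, centroid, traced contour
#' polygon and provenance; the masks themselves are stored as PNGs in a
#' `masks/` subdirectory so the file set round-trips exactly. This is the
#' same schema the evaluation functions read as a prediction.
#'
#' @param spine a `labeled_spine`.
#' @param dir output directory.
#' @name spine_io
#' @export
save_spine <- function(spine, dir) {
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  verts <- lapply(seq_along(spine$vertebrae), function(i) {
    v <- spine$vertebrae[[i]]
    f <- sprintf("%s.png", v$label)
    write_mask_png(v$mask, file.path(dir, "masks", f))
    ctr <- mask_centroid(v$mask)
    list(label = v$label, file = f, area = mask_area(v$mask),
         centroid = unname(round(ctr, 3)),
         provenance = v$mask$provenance,
         polygon = unname(trace_contour(v$mask)))
  })
  obj <- list(reference = spine$reference, direction = spine$direction,
              n_unlabeled = length(spine$unlabeled), vertebrae = verts)
  jsonlite::write_json(obj, file.path(dir, "spine.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname spine_io
#' @return `load_spine` returns a `labeled_spine` (without the unlabeled
#'   pool, which is not serialized).
#' @export
load_spine <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "spine.json"),
                             simplifyVector = FALSE)
  vertebrae <- lapply(obj$vertebrae, function(v) {
    m <- instance_mask(read_mask_png(file.path(dir, "masks", v$file)),
                       source = "ensemble", check = FALSE)
    m$provenance <- v$provenance
    list(mask = m, label = v$label)
  })
  new_labeled_spine(vertebrae, obj$reference, obj$direction, list())
}

#' Load / save an ensemble configuration as YAML
#'
#' Recognized keys: `eta`, `lambda`, `pickup_dedup_iou`, `min_area_px`;
#' missing keys take their defaults.
#'
#' @param path YAML file.
#' @name config_io
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- ensemble_config()
  do.call(ensemble_config, utils::modifyList(
    defaults[c("eta", "lambda", "pickup_dedup_iou", "min_area_px")],
    y[intersect(names(y), c("eta", "lambda", "pickup_dedup_iou",
                            "min_area_px"))]))
}

#' @rdname config_io
#' @param cfg an [ensemble_config()].
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Rows = classes, columns = metrics: per-class Dice plus PQ/SQ/RQ at each
#' matching threshold.
#'
#' @param report a `spine_eval` from [evaluate_spine()].
#' @param path JSON file path.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(
    dice_overall = report$dice_overall,
    dice_per_class = as.list(report$dice_per_class),
    panoptic = report$pq
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
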