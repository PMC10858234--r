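# Run expr with a private RNG stream: the global .Random.seed is restored
# afterwards, so all randomness in the package flows from explicit seeds.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic spine fixture
#'
#' Describes one synthetic lateral spine view: a column of quadrilateral
#' vertebral bodies stacked along a smooth curve, with the distinctively
#' shaped reference vertebra at one end — cone-shaped C2 at the top of a
#' cervical view, triangular S1 at the bottom of a lumbar view.
#'
#' @param region `"cervical"` or `"lumbar"`.
#' @param n_vertebrae number of bodies, 5 to 9.
#' @param image_size `c(height, width)` in pixels.
#' @param curve_amplitude lateral amplitude of the spinal curve, pixels.
#' @param gap_px mean inter-vertebral gap, pixels; must leave room for the
#'   generator's vertical corner perturbation (1 px), so at least 4.
#' @param seed integer seed; the fixture is a pure function of the spec.
#' @return a list of class `spine_spec`.
#' @export
spine_spec <- function(region = c("cervical", "lumbar"), n_vertebrae = 7,
                       image_size = c(512, 256), curve_amplitude = 20,
                       gap_px = 6, seed = 1) {
  region <- match.arg(region)
  stopifnot(n_vertebrae >= 5, n_vertebrae <= 9, gap_px >= 0,
            length(image_size) == 2)
  structure(list(region = region, n_vertebrae = as.integer(n_vertebrae),
                 image_size = as.integer(image_size),
                 curve_amplitude = curve_amplitude, gap_px = gap_px,
                 seed = as.integer(seed)),
            class = "spine_spec")
}

# Label sequence for a generated spine: cervical runs down from C2,
# lumbar runs up from S1.
synthetic_labels <- function(region, n) {
  if (region == "cervical") {
    VERTEBRA_VOCAB[seq(match("C2", VERTEBRA_VOCAB), length.out = n)]
  } else {
    rev(rev(VERTEBRA_VOCAB[seq_len(match("S1", VERTEBRA_VOCAB))])[seq_len(n)])
  }
}

#' Generate a synthetic labeled spine
#'
#' Stacks `n_vertebrae` convex quadrilateral bodies (stored as 8-landmark
#' polygons: 4 corners plus 4 edge midpoints) along a smooth vertical curve
#' with the requested inter-body gap. The reference body gets its
#' characteristic shape: the topmost cervical body tapers upward (cone-like
#' C2), the bottom lumbar body tapers downward (triangular S1). Corner
#' positions carry a small seeded perturbation (horizontal up to 2 px,
#' vertical up to 1 px) so no two fixtures are congruent. Deterministic
#' under a fixed spec.
#'
#' @param spec a [spine_spec()].
#' @return `list(annotation, masks)`: the [ground_truth_annotation()] and
#'   the per-vertebra masks as a named list (names = labels, top to
#'   bottom), pairwise disjoint.
#' @export
generate_spine <- function(spec) {
  stopifnot(inherits(spec, "spine_spec"))
  v_jitter <- 1
  if (spec$gap_px < 2 * v_jitter + 2)
    stop("bodies would overlap: gap_px must be at least ",
         2 * v_jitter + 2, " at the generator's corner jitter", call. = FALSE)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  n <- spec$n_vertebrae
  if (spec$region == "cervical") { w <- round(0.19 * W); h <- 30 }
  else                           { w <- round(0.24 * W); h <- 34 }
  total_h <- n * h + (n - 1) * spec$gap_px
  if (total_h > H - 20)
    stop("image too small for the requested column", call. = FALSE)
  top0 <- floor((H - total_h) / 2)

  with_seed(spec$seed, {
    phase <- stats::runif(1, 0, pi)
    labels <- synthetic_labels(spec$region, n)
    verts <- vector("list", n)
    for (i in seq_len(n)) {
      r0 <- top0 + (i - 1) * (h + spec$gap_px)
      t <- (i - 1) / max(1, n - 1)
      cc <- W / 2 + spec$curve_amplitude * sin(pi * t + phase)
      cc <- min(max(cc, w / 2 + 6), W - w / 2 - 6)
      wt <- w; wb <- w
      if (spec$region == "cervical" && i == 1L) wt <- round(0.4 * w)  # C2 cone
      if (spec$region == "lumbar" && i == n)    wb <- round(0.3 * w)  # S1 triangle
      jx <- stats::runif(4, -2, 2)           # per-corner horizontal jitter
      jy <- stats::runif(4, -v_jitter, v_jitter)
      tl <- c(r0 + jy[1],      cc - wt / 2 + jx[1])
      tr <- c(r0 + jy[2],      cc + wt / 2 + jx[2])
      br <- c(r0 + h + jy[3],  cc + wb / 2 + jx[3])
      bl <- c(r0 + h + jy[4],  cc - wb / 2 + jx[4])
      corners <- rbind(tl, tr, br, bl)
      mids <- (corners + corners[c(2, 3, 4, 1), ]) / 2
      lm <- rbind(tl, mids[1, ], tr, mids[2, ], br, mids[3, ], bl, mids[4, ])
      verts[[i]] <- list(label = labels[i], landmarks = unname(round(lm, 2)))
    }
    ann <- ground_truth_annotation(verts, spec$image_size,
                                   source_id = sprintf("synthetic_%s_seed%d",
                                                       spec$region, spec$seed))
    masks <- rasterize_annotation(ann)
    acc <- matrix(0L, H, W)
    for (m in masks) acc <- acc + m$pixels
    if (any(acc > 1L))
      stop("generated bodies overlap; increase gap_px", call. = FALSE)
    list(annotation = ann, masks = masks)
  })
}

#' Specification of the segmentation corruptions
#'
#' Describes how the two candidate segmentations degrade the ground truth,
#' mimicking the characteristic failure of each segmentation style: the
#' semantic source merges closely spaced neighbors into one blob; the
#' instance source drops vertebrae, preferentially the partially visible
#' ones at the image edge.
#'
#' @param p_merge probability that each inter-vertebral gap is bridged in
#'   the semantic raster.
#' @param p_drop probability that each vertebra is omitted from the instance
#'   list; doubled for the topmost and bottommost bodies.
#' @param boundary_jitter_px each corrupted mask is shifted by an integer
#'   offset up to this magnitude and grows a random 1-px fringe.
#' @param seed integer seed.
#' @return a list of class `corruption_spec`.
#' @export
corruption_spec <- function(p_merge = 0.2, p_drop = 0.2,
                            boundary_jitter_px = 1, seed = 1) {
  stopifnot(p_merge >= 0, p_merge <= 1, p_drop >= 0, p_drop <= 1,
            boundary_jitter_px >= 0)
  structure(list(p_merge = p_merge, p_drop = p_drop,
                 boundary_jitter_px = boundary_jitter_px,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

shift_mask <- function(px, dr, dc) {
  H <- nrow(px); W <- ncol(px)
  out <- matrix(FALSE, H, W)
  idx <- which(px, arr.ind = TRUE)
  r <- idx[, 1] + dr; c_ <- idx[, 2] + dc
  ok <- r >= 1 & r <= H & c_ >= 1 & c_ <= W
  out[cbind(r[ok], c_[ok])] <- TRUE
  out
}

# Additive boundary noise: each background pixel 4-adjacent to the mask is
# turned on with probability 0.25. Additive-only, so connectivity is kept.
fringe_mask <- function(px, prob = 0.25) {
  ring <- (shift_mask(px, 1, 0) | shift_mask(px, -1, 0) |
           shift_mask(px, 0, 1) | shift_mask(px, 0, -1)) & !px
  on <- which(ring)
  if (length(on)) px[on[stats::runif(length(on)) < prob]] <- TRUE
  px
}

jitter_mask <- function(px, j) {
  if (j <= 0) return(px)
  dr <- sample(-j:j, 1); dc <- sample(-j:j, 1)
  fringe_mask(shift_mask(px, dr, dc))
}

#' Corrupt ground truth into a semantic-style raster
#'
#' Union of all ground-truth masks with, per inter-vertebral gap, a bridging
#' band painted with probability `p_merge` (the merged-neighbors blob a
#' per-pixel segmenter produces when bodies nearly touch) and boundary
#' jitter applied per body.
#'
#' @param gt_masks named list of ground-truth masks, top to bottom.
#' @param cspec a [corruption_spec()].
#' @return binary matrix: the corrupted semantic foreground.
#' @export
corrupt_semantic <- function(gt_masks, cspec) {
  with_seed(cspec$seed, {
    px <- lapply(gt_masks, function(m) jitter_mask(as_pixels(m),
                                                   cspec$boundary_jitter_px))
    H <- nrow(px[[1]]); W <- ncol(px[[1]])
    out <- Reduce(`|`, px, matrix(FALSE, H, W))
    n <- length(px)
    if (n >= 2) {
      bridged <- stats::runif(n - 1) < cspec$p_merge
      for (g in which(bridged)) {
        up <- which(px[[g]], arr.ind = TRUE)
        lo <- which(px[[g + 1L]], arr.ind = TRUE)
        cols <- intersect(unique(up[, 2]), unique(lo[, 2]))
        mid <- stats::median(cols)
        half <- max(2, floor(length(cols) * 0.25))
        band_cols <- cols[abs(cols - mid) <= half]
        r_top <- max(up[up[, 2] %in% band_cols, 1])
        r_bot <- min(lo[lo[, 2] %in% band_cols, 1])
        if (r_bot > r_top) out[(r_top):(r_bot), band_cols] <- TRUE
      }
    }
    out
  })
}

#' Corrupt ground truth into an instance-style candidate list
#'
#' Each vertebra is independently kept with probability `1 - p_drop`
#' (`1 - 2 p_drop`, floored at 0, for the topmost and bottommost bodies —
#' partially visible edge vertebrae are what instance detectors miss).
#' Kept masks get boundary jitter. The reference vertebra, when kept,
#' carries its class tag (`C2` or `S1`) and a confidence drawn uniformly in
#' `[0.7, 1]`; all other kept masks are tagged `"vertebra"`.
#'
#' @param gt_masks named list of ground-truth masks (names = labels), top
#'   to bottom.
#' @param cspec a [corruption_spec()].
#' @return list of [instance_mask()] (possibly empty).
#' @export
corrupt_instance <- function(gt_masks, cspec) {
  labels <- names(gt_masks)
  n <- length(gt_masks)
  with_seed(cspec$seed + 1L, {
    p <- rep(cspec$p_drop, n)
    p[c(1L, n)] <- pmin(1, 2 * cspec$p_drop)
    kept <- stats::runif(n) >= p
    out <- list()
    for (i in which(kept)) {
      px <- jitter_mask(as_pixels(gt_masks[[i]]), cspec$boundary_jitter_px)
      if (!any(px)) next
      if (labels[i] %in% c("C2", "S1")) {
        tag <- labels[i]; conf <- stats::runif(1, 0.7, 1.0)
      } else {
        tag <- "vertebra"; conf <- stats::runif(1, 0.5, 0.95)
      }
      out[[length(out) + 1L]] <-
        instance_mask(px, source = "instance", class_tag = tag,
                      confidence = conf, check = FALSE)
    }
    out
  })
}

#' Write a benchmark suite of synthetic fixtures to disk
#'
#' Each fixture directory holds the ground-truth annotation (`gt.json`),
#' per-vertebra ground-truth mask PNGs (`gt_masks/`), the corrupted
#' semantic raster (`semantic.png`) and the corrupted instance set
#' (`instances/`). A `manifest.json` records the per-fixture specs; the
#' whole suite is a pure function of `seed`.
#'
#' @param n_spines number of fixtures.
#' @param dir output directory.
#' @param regions regions to sample from.
#' @param n_range allowed vertebra counts.
#' @param p_merge,p_drop,boundary_jitter_px corruption parameters, see
#'   [corruption_spec()].
#' @param seed master seed; per-fixture seeds are derived from it.
#' @return the manifest, invisibly.
#' @export
make_benchmark <- function(n_spines, dir, regions = c("cervical", "lumbar"),
                           n_range = 5:9, p_merge = 0.2, p_drop = 0.2,
                           boundary_jitter_px = 1, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", n_spines)
  for (i in seq_len(n_spines)) {
    fs <- fixture_spec(i, regions, n_range, p_merge, p_drop,
                       boundary_jitter_px, seed)
    fx <- build_fixture(fs)
    fdir <- file.path(dir, sprintf("fixture_%04d", i))
    dir.create(file.path(fdir, "gt_masks"), showWarnings = FALSE,
               recursive = TRUE)
    save_annotation(fx$annotation, file.path(fdir, "gt.json"))
    for (lab in names(fx$gt_masks))
      write_mask_png(fx$gt_masks[[lab]], file.path(fdir, "gt_masks",
                                                   paste0(lab, ".png")))
    write_mask_png(fx$semantic, file.path(fdir, "semantic.png"))
    save_instance_set(fx$instances, file.path(fdir, "instances"))
    manifest[[i]] <- list(fixture = basename(fdir), region = fs$spine$region,
                          n_vertebrae = fs$spine$n_vertebrae,
                          seed = fs$spine$seed)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Derive one fixture's specs from a master seed
#'
#' Fixture `i` of a benchmark run is a pure function of `(seed, i)`: region
#' and vertebra count are sampled from the allowed ranges under a derived
#' seed, and the spine/corruption specs carry derived seeds of their own.
#'
#' @param i fixture index (1-based).
#' @inheritParams make_benchmark
#' @return `list(spine = spine_spec, corr = corruption_spec)`.
#' @export
fixture_spec <- function(i, regions = c("cervical", "lumbar"),
                         n_range = 5:9, p_merge = 0.2, p_drop = 0.2,
                         boundary_jitter_px = 1, seed = 1) {
  base <- (seed * 10000L + i * 7L) %% 2000000000L
  with_seed(base, {
    region <- sample(regions, 1)
    n <- sample(n_range, 1)
    list(spine = spine_spec(region, n, seed = base + 1L),
         corr = corruption_spec(p_merge, p_drop, boundary_jitter_px,
                                seed = base + 2L))
  })
}

#' Generate one fixture in memory
#'
#' Ground truth plus both corrupted candidate segmentations, without
#' touching the filesystem.
#'
#' @param fs a fixture spec from [fixture_spec()].
#' @return `list(annotation, gt_masks, semantic, instances)`.
#' @export
build_fixture <- function(fs) {
  gt <- generate_spine(fs$spine)
  list(annotation = gt$annotation, gt_masks = gt$masks,
       semantic = corrupt_semantic(gt$masks, fs$corr),
       instances = corrupt_instance(gt$masks, fs$corr))
}
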