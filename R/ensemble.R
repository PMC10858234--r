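#' Ensemble configuration
#'
#' Tunable parameters of the fusion rules.
#'
#' @param eta agreement threshold in (0, 1). A semantic/instance pair is
#'   fused when their agreement exceeds `eta`; an instance mask takes over a
#'   semantic blob when agreement < `eta` but the blob covers more than
#'   `eta` of the instance mask. 0.6 is the recommended cutoff; results are
#'   stable for values roughly between 0.3 and 0.7.
#' @param lambda width of the pickup window in units of the standard
#'   deviation of kept-mask areas: an unused mask is re-admitted when its
#'   area lies within `lambda * sigma` of the mean kept area.
#' @param pickup_dedup_iou a picked-up mask must have IoU at most this value
#'   with every already-kept mask, so pickup can never re-admit a blob that
#'   duplicates a mask already in the final set.
#' @param min_area_px minimum component area for candidate extraction from
#'   the semantic raster (speckle floor).
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(eta = 0.6, lambda = 2.0,
                            pickup_dedup_iou = 0.25, min_area_px = 50) {
  stopifnot(eta > 0, eta < 1, lambda > 0,
            pickup_dedup_iou >= 0, pickup_dedup_iou <= 1,
            min_area_px >= 0)
  structure(list(eta = eta, lambda = lambda,
                 pickup_dedup_iou = pickup_dedup_iou,
                 min_area_px = min_area_px),
            class = "ensemble_config")
}

#' Rule A: fuse semantic/instance pairs in agreement
#'
#' Cross-compares every semantic candidate against every instance candidate
#' and greedily matches pairs one-to-one in descending order of agreement;
#' each matched pair with agreement strictly above `eta` contributes the
#' union of the two masks. Greedy one-to-one assignment prevents a single
#' semantic blob from forming unions with two instance masks, which would
#' re-merge vertebrae.
#'
#' @param semantic,instance lists of [instance_mask()] candidates.
#' @param cfg an [ensemble_config()].
#' @return `list(kept, semantic_rest, instance_rest)`: the agreement unions
#'   (provenance `"agreement_union"`) and the unmatched masks of each source.
#' @export
select_agreement_pairs <- function(semantic, instance, cfg = ensemble_config()) {
  ns <- length(semantic); ni <- length(instance)
  if (ns == 0L || ni == 0L)
    return(list(kept = list(), semantic_rest = semantic,
                instance_rest = instance))
  delta <- matrix(0, ns, ni)
  for (i in seq_len(ns))
    for (j in seq_len(ni))
      delta[i, j] <- mask_agreement(semantic[[i]], instance[[j]])
  ord <- order(delta, decreasing = TRUE)
  used_s <- logical(ns); used_i <- logical(ni)
  kept <- list()
  for (k in ord) {
    if (delta[k] <= cfg$eta) break
    i <- (k - 1L) %% ns + 1L
    j <- (k - 1L) %/% ns + 1L
    if (used_s[i] || used_i[j]) next
    used_s[i] <- TRUE; used_i[j] <- TRUE
    kept[[length(kept) + 1L]] <- mask_union(semantic[[i]], instance[[j]])
  }
  list(kept = kept,
       semantic_rest = semantic[!used_s],
       instance_rest = instance[!used_i])
}

#' Rule C: instance takeover of merged semantic blobs
#'
#' A semantic blob that spans several vertebrae agrees poorly with each
#' individual instance mask (agreement < eta) while covering most of it
#' (coverage > eta). Any remaining instance mask for which some remaining
#' semantic mask satisfies both conditions is taken directly into the final
#' set. The implicated semantic blob stays in the semantic rest: it may
#' cover several instance masks, and is screened later by the pickup rule
#' (where the area window and the deduplication test normally reject it).
#'
#' @param semantic_rest,instance_rest unmatched masks from
#'   [select_agreement_pairs()].
#' @inheritParams select_agreement_pairs
#' @return `list(kept, semantic_rest, instance_rest)` with `kept` holding
#'   the taken-over instance masks (provenance `"instance_takeover"`).
#' @export
separate_overlapping <- function(semantic_rest, instance_rest,
                                 cfg = ensemble_config()) {
  taken <- logical(length(instance_rest))
  kept <- list()
  for (j in seq_along(instance_rest)) {
    inst <- instance_rest[[j]]
    for (sem in semantic_rest) {
      if (mask_agreement(sem, inst) < cfg$eta &&
          instance_overlap_fraction(sem, inst) > cfg$eta) {
        m <- inst
        m$provenance <- "instance_takeover"
        kept[[length(kept) + 1L]] <- m
        taken[j] <- TRUE
        break
      }
    }
  }
  list(kept = kept,
       semantic_rest = semantic_rest,
       instance_rest = instance_rest[!taken])
}

#' Pickup rule: re-admit missed vertebrae by area statistics
#'
#' Computes the mean and (population) standard deviation of the kept-mask
#' areas once, then promotes any unused mask whose area falls within
#' `lambda * sigma` of the mean, provided it does not duplicate an
#' already-kept mask (IoU with every kept mask at most `pickup_dedup_iou`).
#' Candidates are processed closest-to-the-mean first; the statistics are
#' not recomputed during the pass, so admission decisions are deterministic
#' and order-independent given that processing order.
#'
#' @param kept non-empty list of already-kept masks (anchor statistics).
#' @param unused masks never kept by rules A or C.
#' @inheritParams select_agreement_pairs
#' @return `list(kept, unused, mu_area, sigma_area)` with promotions
#'   appended to `kept` (provenance `"pickup"`).
#' @export
pickup_missed <- function(kept, unused, cfg = ensemble_config()) {
  if (length(kept) == 0L)
    stop("ensemble failure: no kept masks to anchor the pickup statistics",
         call. = FALSE)
  areas <- vapply(kept, mask_area, numeric(1))
  mu <- mean(areas)
  sigma <- sqrt(mean((areas - mu)^2))
  if (length(unused)) {
    dist <- abs(vapply(unused, mask_area, numeric(1)) - mu)
    for (j in order(dist)) {
      if (dist[j] > cfg$lambda * sigma) next
      cand <- unused[[j]]
      ious <- vapply(kept, function(k) mask_iou(k, cand), numeric(1))
      if (all(ious <= cfg$pickup_dedup_iou)) {
        cand$provenance <- "pickup"
        kept[[length(kept) + 1L]] <- cand
        unused[[j]] <- NA  # mark promoted
      }
    }
    unused <- unused[!vapply(unused, function(x) identical(x, NA), logical(1))]
  }
  list(kept = kept, unused = unused, mu_area = mu, sigma_area = sigma)
}

#' Sort masks top-to-bottom
#'
#' Ascending centroid row; ties broken by ascending centroid column, then by
#' larger area. The sorted order is what the anatomical labeler zips along.
#'
#' @param kept list of masks.
#' @return the same masks, vertically ordered.
#' @export
sort_masks <- function(kept) {
  if (length(kept) <= 1L) return(kept)
  ctr <- t(vapply(kept, mask_centroid, numeric(2)))
  areas <- vapply(kept, mask_area, numeric(1))
  kept[order(ctr[, 1], ctr[, 2], -areas)]
}

#' Fuse a semantic and an instance segmentation of one spine image
#'
#' Runs the full rule-based ensemble: extract candidate blobs from the
#' semantic raster, fuse pairs in agreement (rule A), let instance masks
#' take over merged semantic blobs (rule C), pick up masks missed by one
#' source via the area window, and sort the final set top-to-bottom. Each
#' final mask records which rule produced it.
#'
#' When one source is empty the other side is kept wholesale (provenance
#' `"pickup"`) with a warning rather than failing: a single segmenter
#' producing nothing is a degraded input, not an invalid one.
#'
#' @param semantic binary matrix: the semantic foreground raster (or a
#'   pre-extracted list of `instance_mask` objects).
#' @param instance_masks list of [instance_mask()] from the instance
#'   segmenter, possibly empty.
#' @inheritParams select_agreement_pairs
#' @return an object of class `spine_ensemble`: `kept` (sorted mask list),
#'   `unused`, `counts` (masks per rule), `mu_area`, `sigma_area`, `config`.
#' @export
run_ensemble <- function(semantic, instance_masks, cfg = ensemble_config()) {
  sem <- if (is.list(semantic) && !is_instance_mask(semantic)) semantic
         else extract_instances(semantic, cfg$min_area_px)
  inst <- instance_masks
  if (length(sem) == 0L && length(inst) == 0L)
    stop("no candidate masks from either source", call. = FALSE)

  if (length(inst) == 0L || length(sem) == 0L) {
    side <- if (length(inst) == 0L) sem else inst
    warning("one segmentation source produced no candidates; ",
            "keeping the other side unchanged", call. = FALSE)
    kept <- lapply(side, function(m) { m$provenance <- "pickup"; m })
    areas <- vapply(kept, mask_area, numeric(1))
    res <- list(kept = sort_masks(kept), unused = list(),
                counts = c(agreement_union = 0L, instance_takeover = 0L,
                           pickup = length(kept)),
                mu_area = mean(areas),
                sigma_area = sqrt(mean((areas - mean(areas))^2)),
                config = cfg)
    return(structure(res, class = "spine_ensemble"))
  }

  a <- select_agreement_pairs(sem, inst, cfg)
  c_ <- separate_overlapping(a$semantic_rest, a$instance_rest, cfg)
  kept <- c(a$kept, c_$kept)
  p <- pickup_missed(kept, c(c_$semantic_rest, c_$instance_rest), cfg)
  prov <- vapply(p$kept, function(m) m$provenance, character(1))
  res <- list(
    kept = sort_masks(p$kept),
    unused = p$unused,
    counts = c(agreement_union = sum(prov == "agreement_union"),
               instance_takeover = sum(prov == "instance_takeover"),
               pickup = sum(prov == "pickup")),
    mu_area = p$mu_area,
    sigma_area = p$sigma_area,
    config = cfg
  )
  structure(res, class = "spine_ensemble")
}

#' @export
print.spine_ensemble <- function(x, ...) {
  cat(sprintf("<spine_ensemble> %d masks kept, %d unused\n",
              length(x$kept), length(x$unused)))
  cat(sprintf("  agreement unions: %d | instance takeovers: %d | pickups: %d\n",
              x$counts["agreement_union"], x$counts["instance_takeover"],
              x$counts["pickup"]))
  cat(sprintf("  kept-area mean %.1f px, sd %.1f px (eta = %.2f, lambda = %.1f)\n",
              x$mu_area, x$sigma_area, x$config$eta, x$config$lambda))
  invisible(x)
}

#' @export
summary.spine_ensemble <- function(object, ...) {
  ctr <- t(vapply(object$kept, mask_centroid, numeric(2)))
  data.frame(
    order = seq_along(object$kept),
    provenance = vapply(object$kept, function(m) m$provenance, character(1)),
    class_tag = vapply(object$kept, function(m) m$class_tag, character(1)),
    area = vapply(object$kept, mask_area, numeric(1)),
    centroid_row = round(ctr[, 1], 2),
    centroid_col = round(ctr[, 2], 2)
  )
}

#' Plot an ensemble result
#'
#' Draws the kept masks color-coded by producing rule on the image grid.
#'
#' @param x a `spine_ensemble`.
#' @param ... passed to [graphics::image()].
#' @export
plot.spine_ensemble <- function(x, ...) {
  dims <- dim(x$kept[[1]]$pixels)
  canvas <- matrix(0L, dims[1], dims[2])
  code <- c(agreement_union = 1L, instance_takeover = 2L, pickup = 3L)
  for (m in x$kept) canvas[m$pixels] <- code[[m$provenance]]
  graphics::image(t(canvas)[, dims[1]:1], col = c("black", "grey80",
                                                  "orange", "cyan"),
                  axes = FALSE, asp = dims[1] / dims[2], ...)
  graphics::legend("topright", fill = c("grey80", "orange", "cyan"),
                   legend = c("agreement union", "instance takeover",
                              "pickup"), bty = "n", cex = 0.8)
  invisible(x)
}
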