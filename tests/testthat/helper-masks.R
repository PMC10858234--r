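# Small mask builders and naive per-pixel oracles used across the suite.

# logical matrix with a filled rectangle, 1-based inclusive bounds
rect_mask <- function(H, W, r0, r1, c0, c1) {
  m <- matrix(FALSE, H, W)
  m[r0:r1, c0:c1] <- TRUE
  m
}

rect_instance <- function(H, W, r0, r1, c0, c1, ...) {
  instance_mask(rect_mask(H, W, r0, r1, c0, c1), ...)
}

# naive double-loop pixel counting: the independent oracle for every
# area-ratio metric
brute_counts <- function(a, b) {
  pa <- if (inherits(a, "instance_mask")) a$pixels else a
  pb <- if (inherits(b, "instance_mask")) b$pixels else b
  inter <- 0L; na <- 0L; nb <- 0L
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(ncol(pa))) {
      if (pa[i, j]) na <- na + 1L
      if (pb[i, j]) nb <- nb + 1L
      if (pa[i, j] && pb[i, j]) inter <- inter + 1L
    }
  }
  list(inter = inter, na = na, nb = nb)
}

# random single-component (rectangular) mask pair on a small raster;
# returns instance_mask objects sharing dimensions
random_mask_pair <- function(H = 40, W = 40) {
  rnd_rect <- function() {
    r0 <- sample(1:(H - 5), 1); c0 <- sample(1:(W - 5), 1)
    rect_instance(H, W, r0, min(H, r0 + sample(2:12, 1)),
                  c0, min(W, c0 + sample(2:12, 1)))
  }
  a <- rnd_rect()
  b <- switch(sample(3, 1),
              rnd_rect(),                                   # arbitrary
              a,                                            # identical
              { m <- rnd_rect(); m })                       # arbitrary again
  list(a = a, b = b)
}

# ---- shared corrupted-fixture suite (acceptance criteria 4 and 5) --------
# Built once per test run, memoized; 200 fixtures at the study conditions
# p_merge = 0.2, p_drop = 0.2, jitter 1 px.

.suite_cache <- new.env(parent = emptyenv())

recovered_count <- function(cands, gt_masks) {
  sum(vapply(gt_masks, function(g)
    any(vapply(cands, function(m) mask_iou(m, g) >= 0.5, logical(1))),
    logical(1)))
}

acceptance_suite <- function(n_fixtures = 200, master_seed = 424) {
  key <- sprintf("s%d_n%d", master_seed, n_fixtures)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  etas <- c(0.3, 0.5, 0.6, 0.7)
  rows <- vector("list", n_fixtures)
  for (i in seq_len(n_fixtures)) {
    fs <- fixture_spec(i, p_merge = 0.2, p_drop = 0.2,
                       boundary_jitter_px = 1, seed = master_seed)
    fx <- build_fixture(fs)
    gtm <- fx$gt_masks
    sem_cands <- extract_instances(fx$semantic)
    n_gt <- length(gtm)
    rec_eta <- numeric(length(etas)); names(rec_eta) <- as.character(etas)
    max_pair_iou <- 0
    lab_row <- list(ref_detected = FALSE, all_recovered = FALSE,
                    labels_correct = NA)
    for (k in seq_along(etas)) {
      ens <- suppressWarnings(
        run_ensemble(sem_cands, fx$instances, ensemble_config(eta = etas[k])))
      rec_eta[k] <- recovered_count(ens$kept, gtm)
      if (etas[k] == 0.6) {
        if (length(ens$kept) > 1) {
          for (p in seq_len(length(ens$kept) - 1))
            for (q in (p + 1):length(ens$kept))
              max_pair_iou <- max(max_pair_iou,
                                  mask_iou(ens$kept[[p]], ens$kept[[q]]))
        }
        ref <- find_reference(fx$instances)
        lab_row$ref_detected <- ref$ref_class != "none"
        lab_row$all_recovered <- rec_eta[k] == n_gt &&
          length(ens$kept) == n_gt
        if (lab_row$ref_detected && lab_row$all_recovered) {
          spine <- suppressWarnings(
            assign_labels(ens$kept, ref$ref_class, ref$ref_mask))
          lab_row$labels_correct <-
            identical(spine_labels(spine), names(gtm))
        }
      }
    }
    rows[[i]] <- list(
      n_gt = n_gt,
      rec_sem = recovered_count(sem_cands, gtm),
      rec_inst = recovered_count(fx$instances, gtm),
      rec_eta = rec_eta,
      max_pair_iou = max_pair_iou,
      labels = lab_row
    )
  }
  out <- list(
    n_gt = sum(vapply(rows, `[[`, numeric(1), "n_gt")),
    rec_sem = sum(vapply(rows, `[[`, numeric(1), "rec_sem")),
    rec_inst = sum(vapply(rows, `[[`, numeric(1), "rec_inst")),
    rec_eta = Reduce(`+`, lapply(rows, `[[`, "rec_eta")),
    max_pair_iou = max(vapply(rows, `[[`, numeric(1), "max_pair_iou")),
    label_eligible = sum(vapply(rows, function(r)
      isTRUE(r$labels$ref_detected) && isTRUE(r$labels$all_recovered),
      logical(1))),
    label_correct = sum(vapply(rows, function(r)
      isTRUE(r$labels$labels_correct), logical(1)))
  )
  .suite_cache[[key]] <- out
  out
}
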