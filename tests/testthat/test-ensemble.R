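test_that("config validates its ranges", {
  expect_error(ensemble_config(eta = 0))
  expect_error(ensemble_config(eta = 1))
  expect_error(ensemble_config(lambda = -1))
  cfg <- ensemble_config()
  expect_equal(cfg$eta, 0.6)
  expect_equal(cfg$lambda, 2.0)
})

test_that("agreement pairing fuses identical lists and leaves disjoint ones alone", {
  gt <- generate_spine(spine_spec("cervical", 6, seed = 3))
  sem <- lapply(gt$masks, function(m) { m$source <- "semantic"; m })
  names(sem) <- NULL
  res <- select_agreement_pairs(sem, unname(gt$masks))
  expect_length(res$kept, 6)
  expect_length(res$semantic_rest, 0)
  expect_length(res$instance_rest, 0)
  expect_true(all(vapply(res$kept, function(m)
    m$provenance == "agreement_union", logical(1))))
  # pixel content preserved by the unions
  for (k in seq_along(res$kept))
    expect_true(any(vapply(gt$masks, function(g)
      identical(g$pixels, res$kept[[k]]$pixels), logical(1))))

  top <- rect_instance(20, 40, 1, 5, 1, 10)
  bot <- rect_instance(20, 40, 12, 18, 20, 35)
  res2 <- select_agreement_pairs(list(top), list(bot))
  expect_length(res2$kept, 0)
  expect_length(res2$semantic_rest, 1)
  expect_length(res2$instance_rest, 1)
})

test_that("greedy pairing is one-to-one, by descending agreement, and maximal", {
  # hand-built case on one strip where row-order matching would differ:
  # delta(s1,i1) = 0.45, delta(s1,i2) = 0.84, delta(s2,i1) = 0.55
  H <- 3; W <- 200
  s1 <- rect_instance(H, W, 1, 1, 1, 50, source = "semantic")
  s2 <- rect_instance(H, W, 2, 2, 1, 50, source = "semantic")
  i1 <- instance_mask(rect_mask(H, W, 1, 1, 21, 50) |
                      rect_mask(H, W, 2, 2, 15, 50))
  i2 <- rect_instance(H, W, 1, 1, 9, 50)
  sem <- list(s1, s2); inst <- list(i1, i2)
  delta <- outer(seq_along(sem), seq_along(inst),
                 Vectorize(function(i, j) mask_agreement(sem[[i]], inst[[j]])))
  eta <- 0.5
  # independent oracle: enumerate every one-to-one assignment above eta
  best <- NULL
  for (perm in list(c(1, 2), c(2, 1))) {
    pairs <- list()
    used <- logical(2)
    for (i in 1:2) {
      j <- perm[i]
      if (delta[i, j] > eta && !used[j]) {
        pairs[[length(pairs) + 1L]] <- c(i, j); used[j] <- TRUE
      }
    }
    if (is.null(best) || length(pairs) > length(best)) best <- pairs
  }
  res <- select_agreement_pairs(sem, inst, ensemble_config(eta = eta))
  expect_length(res$kept, length(best))
  # greedy must take the globally largest delta first: (s1, i2)
  expect_true(delta[1, 2] == max(delta))
  expect_true(any(vapply(res$kept, function(m)
    identical(m$pixels, s1$pixels | i2$pixels), logical(1))))
  # and each source mask participates at most once
  expect_length(res$kept, 2)
  expect_length(res$semantic_rest, 0)
  expect_length(res$instance_rest, 0)
})

test_that("instance takeover separates a merged semantic blob", {
  # blob = pixel-union of two instance masks, 300 px each:
  # delta = 300/600 = 0.5 < 0.6 and delta_m = 1.0 > 0.6 for both
  H <- 60; W <- 30
  i1 <- rect_instance(H, W, 1, 15, 1, 20)    # 300 px
  i2 <- rect_instance(H, W, 16, 30, 1, 20)   # 300 px
  blob <- instance_mask(i1$pixels | i2$pixels, source = "semantic")
  expect_equal(mask_agreement(blob, i1), 0.5)
  expect_equal(instance_overlap_fraction(blob, i1), 1.0)
  res <- separate_overlapping(list(blob), list(i1, i2))
  expect_length(res$kept, 2)
  expect_true(all(vapply(res$kept, function(m)
    m$provenance == "instance_takeover", logical(1))))
  expect_length(res$semantic_rest, 1)   # blob stays for the pickup screen
  expect_length(res$instance_rest, 0)

  # disjoint instance mask: delta_m = 0, never taken
  far <- rect_instance(H, W, 40, 50, 22, 28)
  res2 <- separate_overlapping(list(blob), list(far))
  expect_length(res2$kept, 0)
  # coverage exactly at the threshold is not enough (strict inequality)
  half <- rect_instance(H, W, 21, 40, 1, 20)  # 400 px, 200 inside the blob
  expect_equal(instance_overlap_fraction(blob, half), 0.5)
  res3 <- separate_overlapping(list(blob), list(half),
                               ensemble_config(eta = 0.5))
  expect_length(res3$kept, 0)
})

test_that("pickup admits by the area window and rejects duplicates", {
  H <- 40; W <- 120
  kept <- list(rect_instance(H, W, 1, 10, 1, 10),     # 100 px
               rect_instance(H, W, 1, 10, 15, 24),
               rect_instance(H, W, 1, 10, 29, 38))
  # zero variance: only an exact-area disjoint mask can enter
  cand <- rect_instance(H, W, 20, 29, 1, 10)          # 100 px, disjoint
  res <- pickup_missed(kept, list(cand))
  expect_length(res$kept, 4)
  expect_equal(res$kept[[4]]$provenance, "pickup")
  expect_equal(res$sigma_area, 0)

  # mu = 100, sigma = sqrt(200/3) ~ 8.165, lambda 2 -> window [83.7, 116.3]
  kept2 <- list(rect_instance(H, W, 1, 9, 1, 10),     # 90
                rect_instance(H, W, 1, 10, 15, 24),   # 100
                rect_instance(H, W, 1, 11, 29, 38))   # 110
  merged <- rect_instance(H, W, 20, 29, 1, 20)        # 200 px double blob
  res2 <- pickup_missed(kept2, list(merged))
  expect_length(res2$kept, 3)
  expect_length(res2$unused, 1)
  expect_equal(res2$mu_area, 100)
  expect_equal(res2$sigma_area, sqrt(mean((c(90, 100, 110) - 100)^2)))

  # in-window area (110 within [83.7, 116.3]) but high IoU with a kept
  # mask: rejected as duplicate
  dup <- rect_instance(H, W, 1, 10, 1, 11)            # 110 px
  expect_gt(mask_iou(dup, kept2[[1]]), 0.25)
  res3 <- pickup_missed(kept2, list(dup))
  expect_length(res3$kept, 3)

  expect_error(pickup_missed(list(), list(cand)), "ensemble failure")
})

test_that("masks sort by centroid row with column and area tie-breaks", {
  H <- 60; W <- 60
  m30 <- rect_instance(H, W, 29, 33, 1, 5)
  m10 <- rect_instance(H, W, 9, 13, 1, 5)
  m20 <- rect_instance(H, W, 19, 23, 1, 5)
  out <- sort_masks(list(m30, m10, m20))
  expect_equal(vapply(out, function(m) mask_centroid(m)[["row"]], numeric(1)),
               c(10, 20, 30))
  # equal rows: ascending column wins
  a <- rect_instance(H, W, 1, 5, 4, 8)    # col centroid 5
  b <- rect_instance(H, W, 1, 5, 39, 43)  # col centroid 40
  out2 <- sort_masks(list(b, a))
  expect_equal(mask_centroid(out2[[1]])[["col"]], 5)
  # randomized permutations of one spine always give the same order
  gt <- generate_spine(spine_spec("lumbar", 7, seed = 9))
  ref_order <- names(sort(vapply(gt$masks, function(m)
    mask_centroid(m)[["row"]], numeric(1))))
  set.seed(21)
  for (rep in 1:5) {
    perm <- sample(seq_along(gt$masks))
    srt <- sort_masks(unname(gt$masks)[perm])
    got <- vapply(srt, function(m) names(gt$masks)[vapply(
      gt$masks, function(g) identical(g$pixels, m$pixels), logical(1))],
      character(1))
    expect_equal(got, ref_order)
  }
})

test_that("the ensemble is a fixed point on agreeing sources", {
  gt <- generate_spine(spine_spec("cervical", 6, seed = 5))
  sem_raster <- Reduce(`|`, lapply(gt$masks, `[[`, "pixels"))
  for (eta in c(0.2, 0.6, 0.9)) {
    ens <- run_ensemble(sem_raster, unname(gt$masks),
                        ensemble_config(eta = eta))
    expect_length(ens$kept, 6)
    expect_equal(unname(ens$counts),
                 c(6L, 0L, 0L))
    for (k in seq_along(ens$kept))
      expect_identical(ens$kept[[k]]$pixels,
                       unname(gt$masks)[[k]]$pixels)
  }
})

test_that("the ensemble repairs a merge plus a drop in one image", {
  gt <- generate_spine(spine_spec("cervical", 6, seed = 8))
  masks <- unname(gt$masks)
  # semantic source merges vertebrae 3 and 4
  cs <- corruption_spec(p_merge = 0, p_drop = 0, boundary_jitter_px = 0,
                        seed = 1)
  sem <- corrupt_semantic(gt$masks, cs)
  r3 <- which(masks[[3]]$pixels, arr.ind = TRUE)
  r4 <- which(masks[[4]]$pixels, arr.ind = TRUE)
  cols <- intersect(unique(r3[, 2]), unique(r4[, 2]))[10:20]
  sem[max(r3[, 1]):min(r4[, 1]), cols] <- TRUE
  # instance source drops vertebra 6
  inst <- masks[-6]
  ens <- run_ensemble(sem, inst)
  expect_length(ens$kept, 6)
  # v1, v2, v5 fuse by agreement; v3, v4 are taken from the instance side
  # out of the merged blob; v6 comes back through the pickup window
  expect_equal(ens$counts[["agreement_union"]], 3L)
  expect_equal(ens$counts[["instance_takeover"]], 2L)
  expect_equal(ens$counts[["pickup"]], 1L)
  # vertebra 6 recovered from the semantic side by pickup
  expect_gte(mask_iou(ens$kept[[6]], masks[[6]]), 0.99)
  expect_equal(sum(ens$counts), length(ens$kept))
})

test_that("degenerate inputs degrade gracefully or fail loudly", {
  gt <- generate_spine(spine_spec("lumbar", 5, seed = 2))
  sem_raster <- Reduce(`|`, lapply(gt$masks, `[[`, "pixels"))
  expect_warning(ens <- run_ensemble(sem_raster, list()), "no candidates")
  expect_length(ens$kept, 5)
  expect_true(all(vapply(ens$kept, function(m) m$provenance == "pickup",
                         logical(1))))
  expect_error(run_ensemble(matrix(FALSE, 10, 10), list()), "no candidate")
})

test_that("kept masks never overlap beyond the dedup threshold", {
  for (i in 1:10) {
    fx <- build_fixture(fixture_spec(i, seed = 99))
    ens <- suppressWarnings(run_ensemble(fx$semantic, fx$instances))
    n <- length(ens$kept)
    expect_equal(sum(ens$counts), n)
    if (n > 1) {
      for (p in 1:(n - 1)) for (q in (p + 1):n)
        expect_lte(mask_iou(ens$kept[[p]], ens$kept[[q]]), 0.25)
    }
  }
})
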