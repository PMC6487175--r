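test_that("segment tallies reproduce direct count arithmetic", {
  t1 <- new_segment_tally(1L, 200L, 120L, 80L)
  expect_equal(t1$artery_fraction, 0.600)
  expect_equal(t1$vein_fraction, 0.400)
  expect_equal(t1$judged_class, AV_ARTERY)

  t6 <- new_segment_tally(6L, 459L, 0L, 459L)
  expect_equal(t6$artery_fraction, 0)
  expect_equal(t6$vein_fraction, 1)
  expect_equal(multiloss_judge(t6), AV_VEIN)

  tie <- new_segment_tally(9L, 10L, 5L, 5L)
  expect_equal(tie$judged_class, AV_TIE)
  expect_equal(multiloss_judge(tie), AV_TIE)

  expect_error(new_segment_tally(1L, 10L, 9L, 9L), class = "avrefine_TallyError")
})

test_that("the judgment is the class with the smaller segment-level loss", {
  # max(1 - P_artery, 1 - P_vein) with P = 1 - fraction: majority wins
  frac_cases <- list(c(0.600, 0.400, AV_ARTERY),
                     c(0.100, 0.900, AV_VEIN),
                     c(0.5, 0.5, AV_TIE))
  for (fc in frac_cases) {
    tal <- new_segment_tally(1L, 1000L, as.integer(1000 * fc[1]),
                             as.integer(1000 * fc[2]))
    expect_equal(multiloss_judge(tal), as.integer(fc[3]))
  }
})

test_that("tally_segment matches brute-force counting on small rasters", {
  for (seed in c(41, 42)) {
    mask <- random_blob_mask(40, 40, seed, n_blobs = 4)
    if (!any(mask)) next
    part <- segment_mask(mask)
    pred <- random_label_raster(40, 40, seed + 100, p_bg = 0.3)
    for (s in part$segments) {
      if (part$n_vessel[s$id] == 0) next
      tal <- tally_segment(part, s$id, pred)
      bf <- brute_tally_counts(part$assignment, s$id, pred)
      expect_equal(tal$total_pixels, unname(bf["total"]))
      expect_equal(tal$artery_pixels, unname(bf["artery"]))
      expect_equal(tal$vein_pixels, unname(bf["vein"]))
    }
  }
})

test_that("refinement flips a noisy segment to its majority class", {
  bar <- make_bar_mask(12, 60, 5:8, 6:55)      # 200 vessel px, one segment
  part <- segment_mask(bar)
  truth <- matrix(AV_BACKGROUND, 12, 60)
  truth[as.matrix(bar)] <- AV_ARTERY
  pred <- truth
  withr::with_seed(5, {
    flip <- sample(which(as.matrix(bar)), 40)  # 20% flipped
  })
  pred[flip] <- AV_VEIN
  refined <- refine_labels(label_raster(pred), part)
  expect_true(all(refined[as.matrix(bar)] == AV_ARTERY))
  # pixels outside the mask untouched
  expect_true(all(refined[!as.matrix(bar)] == AV_BACKGROUND))
})

test_that("refinement is idempotent and preserves the vessel mask", {
  for (seed in c(51, 52, 53)) {
    case <- generate_case(vasculature_spec(image_size = c(96L, 96L), seed = seed))
    r1 <- refine_labels(case$prediction, case$partition)
    r2 <- refine_labels(r1, case$partition)
    expect_identical(r1, r2)
    out_mask <- !as.matrix(case$mask)
    expect_identical(r1[out_mask], case$prediction[out_mask])
  }
})

test_that("stray predictions outside the mask are never altered", {
  bar <- make_bar_mask(20, 40, 9:11, 5:35)
  part <- segment_mask(bar)
  pred <- matrix(AV_BACKGROUND, 20, 40)
  pred[as.matrix(bar)] <- AV_VEIN
  pred[2, 2] <- AV_ARTERY; pred[18, 38] <- AV_VEIN  # stray outside mask
  refined <- refine_labels(label_raster(pred), part)
  expect_equal(refined[2, 2], AV_ARTERY)
  expect_equal(refined[18, 38], AV_VEIN)
})

test_that("majority-vote recovery beats the Hoeffding bound", {
  # n votes, flip rate eps: P(correct) >= 1 - exp(-2 n (0.5 - eps)^2)
  n <- 60L; eps <- 0.3; reps <- 300L
  bound <- 1 - exp(-2 * n * (0.5 - eps)^2)
  mc_se <- sqrt(bound * (1 - bound) / reps)
  withr::with_seed(99, {
    ok <- 0L
    for (i in seq_len(reps)) {
      flips <- stats::runif(n) < eps
      tal <- new_segment_tally(1L, n, sum(!flips), sum(flips))  # truth ARTERY
      if (multiloss_judge(tal) == AV_ARTERY) ok <- ok + 1L
    }
  })
  expect_gte(ok / reps, bound - 3 * mc_se)
})

test_that("matching range is the first radius achieving maximal overlap", {
  ref <- make_bar_mask(20, 50, 10:12, 5:45)
  part <- segment_mask(ref)
  # identical prediction: radius 0
  mr0 <- matching_range(part, ref, part$segments[[1]]$id)
  expect_equal(mr0$radius, 0L)
  expect_equal(mr0$overlap, sum(ref))
  # prediction shifted 2 px laterally
  shifted <- make_bar_mask(20, 50, 12:14, 5:45)
  mr2 <- matching_range(part, shifted, part$segments[[1]]$id)
  expect_equal(mr2$radius, 2L)
  # brute-force sweep oracle: overlap at r = 0..5 via naive dilation
  naive_overlap <- vapply(0:5, function(r) {
    vj <- part$assignment == part$segments[[1]]$id
    grown <- matrix(FALSE, 20, 50)
    for (idx in which(vj)) {
      pr <- ((idx - 1) %% 20) + 1; pc <- ((idx - 1) %/% 20) + 1
      for (dr in -r:r) for (dc in -r:r) {
        if (dr^2 + dc^2 > r^2) next
        rr <- pr + dr; cc <- pc + dc
        if (rr >= 1 && rr <= 20 && cc >= 1 && cc <= 50) grown[rr, cc] <- TRUE
      }
    }
    sum(grown & as.matrix(shifted))
  }, 0)
  expect_equal(mr2$radius, which.max(naive_overlap) - 1L)
  # empty prediction: degenerate plateau at 0
  empty <- vessel_mask(matrix(FALSE, 20, 50))
  mr_e <- matching_range(part, empty, part$segments[[1]]$id)
  expect_equal(mr_e$radius, 0L)
  expect_equal(mr_e$overlap, 0L)
})

test_that("mismatch ratio is the relative absolute thickness discrepancy", {
  expect_equal(mismatch_ratio(5, 5), 0)
  expect_equal(mismatch_ratio(5, 6), 0.2)
  expect_equal(mismatch_ratio(5, 4), 0.2)
  expect_error(mismatch_ratio(0, 3), class = "avrefine_ZeroThickness")
})

test_that("weight map carries 1 + MisR inside matched segments, 1 outside", {
  expect_equal(weight_map(list(), numeric(0), c(5, 5)), matrix(1, 5, 5))
  m <- matrix(FALSE, 5, 5); m[2, 1:5] <- TRUE; m[3, 1:5] <- TRUE
  W <- weight_map(list(`1` = m), c(`1` = 0.2), c(5, 5))
  expect_equal(sum(W == 1.2), 10)
  expect_equal(sum(W == 1.0), 15)
  W0 <- weight_map(list(`1` = m), c(`1` = 0), c(5, 5))
  expect_equal(W0, matrix(1, 5, 5))
  expect_error(weight_map(list(`1` = m), c(`2` = 0.1), c(5, 5)),
               class = "avrefine_WeightError")
})

test_that("weighted loss is the weighted L1 deviation from one-hot labels", {
  lab <- label_raster(matrix(c(AV_ARTERY, AV_VEIN, AV_BACKGROUND, AV_ARTERY), 2, 2))
  perfect <- probs_from_labels(lab, p_top = 1)
  expect_equal(weighted_loss(perfect, lab)$total, 0)

  one <- label_raster(matrix(AV_ARTERY, 1, 1))
  p <- prob_raster(array(c(0.8, 0.15, 0.05), c(1, 1, 3)))
  expect_equal(weighted_loss(p, one, matrix(1.2, 1, 1))$total, 0.24)

  # all weights 1: plain L1 deviation
  probs <- probs_from_labels(lab, p_top = 0.7)
  l <- weighted_loss(probs, lab)
  expect_equal(l$total, sum(1 - 0.7) * 4)
  expect_error(weighted_loss(probs, label_raster(matrix(AV_ARTERY, 3, 3))),
               class = "avrefine_DimensionError")
})

test_that("the full segment-loss pipeline reports MisR and weighted loss", {
  case <- generate_case(vasculature_spec(image_size = c(96L, 96L), seed = 61))
  rep <- segment_loss_report(case$partition, case$truth, case$prob_prediction)
  expect_true(all(rep$per_segment_misr >= 0))
  expect_true(all(rep$weights >= 1))
  expect_equal(rep$total_weighted_loss, sum(rep$per_pixel_loss))
  # prediction mask equals truth mask here (no jitter), so thickness of
  # each matched segment is close to the reference and weights stay modest
  expect_true(all(rep$matching_radius >= 0))
})

test_that("tally_table mirrors the worked-example columns", {
  case <- generate_case(vasculature_spec(image_size = c(96L, 96L), seed = 62))
  tt <- tally_table(case$partition, case$prediction, truth = case$truth)
  expect_named(tt, c("segment_id", "total_pixels", "reference_class",
                     "artery_pixels", "vein_pixels", "artery_fraction",
                     "vein_fraction", "judged_class"))
  expect_true(all(tt$artery_pixels + tt$vein_pixels <= tt$total_pixels))
  expect_equal(tt$artery_fraction, tt$artery_pixels / tt$total_pixels)
})
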