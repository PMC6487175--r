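test_that("skeletonize handles degenerate and already-thin inputs", {
  empty <- vessel_mask(matrix(FALSE, 10, 10))
  s <- skeletonize(empty)
  expect_false(any(s$pixels))
  expect_equal(nrow(s$junctions), 0L)

  line <- matrix(FALSE, 9, 20); line[5, 3:18] <- TRUE
  s2 <- skeletonize(vessel_mask(line))
  expect_identical(s2$pixels, line)
})

test_that("a solid bar skeletonizes to its medial centerline", {
  bar <- make_bar_mask(20, 60, 8:12, 5:55)
  s <- skeletonize(bar)
  px <- which(s$pixels, arr.ind = TRUE)
  expect_true(all(as.matrix(bar)[px]))   # skeleton is a subset of the mask
  # centerline: length close to the bar length, every pixel within 2.5 px
  # of the medial row
  expect_gt(nrow(px), 43)
  expect_lte(nrow(px), 53)
  expect_true(all(abs(px[, 1] - 10) <= 2.5))
  # coverage: every mask pixel within the bar half-width of the skeleton,
  # plus the ~1.5 px end-retreat that thinning leaves at blunt bar ends
  d <- matrix(as.numeric(EBImage::distmap(!s$pixels)), 20, 60)
  expect_true(all(d[as.matrix(bar)] <= 4))
})

brute_junctions <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  out <- NULL
  for (idx in which(skel)) {
    r <- ((idx - 1) %% h) + 1; c <- ((idx - 1) %/% h) + 1
    n <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && skel[rr, cc]) n <- n + 1
    }
    if (n >= 3) out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

test_that("junction detection finds exactly the >=3-neighbor pixels", {
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_equal(nrow(detect_junctions(line)), 0L)

  # two crossing 1-px lines: the center plus its 4 arm neighbors (which
  # gain diagonal contacts across the crossing) form the junction cluster
  plus <- matrix(FALSE, 9, 9); plus[5, 2:8] <- TRUE; plus[2:8, 5] <- TRUE
  j <- detect_junctions(plus)
  expect_equal(unname(j), unname(brute_junctions(plus)))
  expect_true(any(j[, 1] == 5 & j[, 2] == 5))
  # removing the cluster separates the four arms into four segments
  skel <- structure(list(pixels = plus, junctions = j), class = "skeleton_map")
  expect_length(decompose_segments(skel), 4L)

  yshape <- matrix(FALSE, 9, 9)
  yshape[5, 5] <- TRUE
  yshape[cbind(2:4, 5)] <- TRUE        # north arm
  yshape[cbind(6:8, 6:8)] <- TRUE      # SE arm
  yshape[cbind(6:8, 4:2)] <- TRUE      # SW arm
  jy <- detect_junctions(yshape)
  expect_equal(unname(jy), unname(brute_junctions(yshape)))
  expect_equal(nrow(jy), 1L)
  expect_equal(unname(jy[1, ]), c(5L, 5L))
})

test_that("segment decomposition partitions the skeleton minus junctions", {
  # straight line: one segment holding every pixel
  line <- matrix(FALSE, 9, 40); line[5, 3:38] <- TRUE
  segs <- decompose_segments(skeletonize(vessel_mask(line)))
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$length, 36L)

  # Y-shape: three segments partitioning skeleton minus the junction
  yshape <- matrix(FALSE, 11, 11)
  yshape[6, 6] <- TRUE
  yshape[cbind(2:5, 6)] <- TRUE
  yshape[cbind(7:10, 7:10)] <- TRUE
  yshape[cbind(7:10, 5:2)] <- TRUE
  skel <- structure(list(pixels = yshape, junctions = detect_junctions(yshape)),
                    class = "skeleton_map")
  segs_y <- decompose_segments(skel)
  expect_length(segs_y, 3L)
  all_px <- do.call(rbind, lapply(segs_y, function(s) s$pixels))
  expect_equal(nrow(all_px), sum(yshape) - 1L)
  got <- sort((all_px[, 2] - 1) * 11 + all_px[, 1])
  want <- setdiff(which(yshape), (6 - 1) * 11 + 6)
  expect_equal(got, want)
})

test_that("max_length splits a long segment into consecutive runs", {
  line <- matrix(FALSE, 5, 110); line[3, 6:105] <- TRUE
  skel <- skeletonize(vessel_mask(line))
  segs <- decompose_segments(skel, max_length = 30)
  expect_equal(vapply(segs, function(s) s$length, 0L), c(30L, 30L, 30L, 10L))
  # runs are consecutive along the path
  cols <- unlist(lapply(segs, function(s) s$pixels[, 2]))
  expect_true(all(diff(cols) %in% c(-1L, 1L)))
})

test_that("vessel pixels go to the segment of their nearest skeleton pixel", {
  # two parallel bars with hand-made centerlines: exact counts
  m <- matrix(FALSE, 20, 50)
  m[3:7, ] <- TRUE; m[13:17, ] <- TRUE
  seg1 <- structure(list(id = 1L, pixels = cbind(rep(5L, 50), 1:50), length = 50L),
                    class = "skeleton_segment")
  seg2 <- structure(list(id = 2L, pixels = cbind(rep(15L, 50), 1:50), length = 50L),
                    class = "skeleton_segment")
  part <- partition_vessel_pixels(vessel_mask(m), list(seg1, seg2))
  expect_equal(unname(part$n_vessel), c(250, 250))
  expect_equal(unname(part$thickness), c(5, 5))
  expect_true(all(part$assignment[3:7, ] == 1L))
  expect_true(all(part$assignment[13:17, ] == 2L))
  # partition property
  expect_equal(sum(part$n_vessel), sum(m))
  expect_error(partition_vessel_pixels(vessel_mask(m), list()),
               class = "avrefine_EmptySkeleton")
})

test_that("partition agrees with the all-pairs brute-force oracle", {
  for (seed in c(21, 22, 23)) {
    mask <- random_blob_mask(48, 48, seed, n_blobs = 5)
    if (!any(mask)) next
    skel <- skeletonize(mask)
    segs <- decompose_segments(skel)
    part <- partition_vessel_pixels(mask, segs)
    expect_identical(part$assignment, brute_assignment(mask, segs))
  }
})

test_that("thickness recovers known bar widths within one pixel", {
  for (w in c(2, 3, 5, 8)) {
    bar <- make_bar_mask(30, 110, 10:(9 + w), 6:105)
    part <- segment_mask(bar)
    expect_length(part$segments, 1L)
    expect_lte(abs(part$thickness[1] - w), 1)
    # constant-width bar: Tp matches TVj within discretization
    expect_lte(abs(segment_length_stat(part, 1L)), 1.2)
    expect_gte(segment_length_stat(part, 1L), -1)
  }
})

test_that("skeleton reconstructs from segment pixels plus junctions", {
  mask <- random_blob_mask(60, 60, seed = 31, n_blobs = 6)
  skel <- skeletonize(mask)
  segs <- decompose_segments(skel)
  got <- matrix(FALSE, 60, 60)
  for (s in segs) got[s$pixels] <- TRUE
  if (nrow(skel$junctions) > 0) got[skel$junctions] <- TRUE
  expect_identical(got, skel$pixels)
  expect_equal(sum(vapply(segs, function(s) s$length, 0L)),
               sum(skel$pixels) - nrow(skel$junctions))
})

test_that("segment report exports the per-segment quantities", {
  bar <- make_bar_mask(20, 60, 8:12, 5:55)
  part <- segment_mask(bar)
  rep <- segment_report(part)
  expect_named(rep, c("segment_id", "length", "thickness", "max_diameter",
                      "length_stat", "n_vessel_pixels"))
  expect_equal(rep$n_vessel_pixels, sum(bar))
})
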