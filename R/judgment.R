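## The multiloss segment-wise judgment: per-segment class tallies, the
## majority judgment, pixel-wise -> segment-wise label refinement, and the
## mismatch-ratio weighted segment-level loss.

#' Tally predicted classes within one segment
#'
#' Counts the predicted artery and vein pixels among a segment's vessel
#' pixels `V_j`. Fractions are taken over all vessel pixels of the
#' segment, so pixels the classifier called background inside the mask
#' carry no vote (the judgment is an artery-vs-vein decision). The
#' segment-level losses of the two vessel classes are
#' `P_artery = 1 - artery_fraction` and `P_vein = 1 - vein_fraction`.
#'
#' @param partition a `segment_partition` from
#'   [partition_vessel_pixels()].
#' @param segment_id id of the segment to tally.
#' @param predicted a [label_raster()] of pixel-wise predictions, same
#'   dimensions as the partition's mask.
#' @return A `segment_tally`: list with `segment_id`, `total_pixels`,
#'   `artery_pixels`, `vein_pixels`, `artery_fraction`, `vein_fraction`,
#'   `judged_class` ([AV_ARTERY], [AV_VEIN] or [AV_TIE]).
#' @export
tally_segment <- function(partition, segment_id, predicted) {
  check_same_dim(partition$assignment, predicted, "partition and prediction")
  in_seg <- partition$assignment == segment_id
  total <- sum(in_seg)
  if (total == 0L)
    av_error("EmptySegment", sprintf("segment %d owns no vessel pixels", segment_id))
  new_segment_tally(segment_id,
                    total_pixels = total,
                    artery_pixels = sum(predicted[in_seg] == AV_ARTERY),
                    vein_pixels = sum(predicted[in_seg] == AV_VEIN))
}

#' @rdname tally_segment
#' @param total_pixels,artery_pixels,vein_pixels raw pixel counts for a
#'   segment; `new_segment_tally()` builds a tally directly from counts
#'   (as printed in a segment-judgment table) without a partition.
#' @export
new_segment_tally <- function(segment_id, total_pixels, artery_pixels, vein_pixels) {
  if (artery_pixels + vein_pixels > total_pixels)
    av_error("TallyError", "artery + vein counts exceed the segment's vessel pixels")
  t <- list(segment_id = segment_id,
            total_pixels = total_pixels,
            artery_pixels = artery_pixels,
            vein_pixels = vein_pixels,
            artery_fraction = artery_pixels / total_pixels,
            vein_fraction = vein_pixels / total_pixels)
  t$judged_class <- if (t$artery_fraction > t$vein_fraction) AV_ARTERY
                    else if (t$vein_fraction > t$artery_fraction) AV_VEIN
                    else AV_TIE
  structure(t, class = "segment_tally")
}

#' The multiloss judgment for one segment
#'
#' With segment-level losses `P_artery = 1 - artery_fraction` and
#' `P_vein = 1 - vein_fraction`, the judgment is the class attaining
#' `max(1 - P_artery, 1 - P_vein)` - i.e. the majority predicted class
#' among the segment's vessel pixels. Equal fractions give [AV_TIE].
#'
#' @param tally a `segment_tally`.
#' @return [AV_ARTERY], [AV_VEIN] or [AV_TIE].
#' @export
multiloss_judge <- function(tally) {
  one_minus_p_artery <- 1 - (1 - tally$artery_fraction)
  one_minus_p_vein <- 1 - (1 - tally$vein_fraction)
  if (one_minus_p_artery > one_minus_p_vein) AV_ARTERY
  else if (one_minus_p_vein > one_minus_p_artery) AV_VEIN
  else AV_TIE
}

#' Refine a pixel-wise classification segment by segment
#'
#' Applies the multiloss judgment to every segment of the partition: all
#' vessel pixels of a segment with a strict majority class are relabelled
#' to that class. Pixels outside the vessel mask are never touched. Tied
#' segments follow `tie_policy`; segments shorter than
#' `min_segment_length` skeleton pixels are left pixel-wise (too few
#' votes to trust a majority).
#'
#' @param predicted a [label_raster()] of pixel-wise predictions.
#' @param partition a `segment_partition` of the reference vessel mask.
#' @param tie_policy what a tied segment keeps: `"keep"` (default, the
#'   pixel-wise softmax prediction), `"artery"`, or `"vein"`.
#' @param min_segment_length minimum skeleton length for a segment to be
#'   judged (default 1).
#' @return The refined [label_raster()]. Refinement is idempotent and
#'   preserves the vessel mask: it only swaps artery/vein inside `V_j`.
#' @export
refine_labels <- function(predicted, partition,
                          tie_policy = c("keep", "artery", "vein"),
                          min_segment_length = 1L) {
  tie_policy <- match.arg(tie_policy)
  check_same_dim(partition$assignment, predicted, "partition and prediction")
  out <- unclass(predicted)
  for (s in partition$segments) {
    if (s$length < min_segment_length) next
    if (partition$n_vessel[s$id] == 0L) next
    tal <- tally_segment(partition, s$id, predicted)
    cls <- multiloss_judge(tal)
    if (cls == AV_TIE) {
      cls <- switch(tie_policy, keep = AV_TIE, artery = AV_ARTERY, vein = AV_VEIN)
      if (cls == AV_TIE) next
    }
    out[partition$assignment == s$id] <- cls
  }
  label_raster(out)
}

#' Matching search range between reference and predicted segments
#'
#' `R_j` is the minimum dilation radius of the reference segment's vessel
#' pixels `V_j` that achieves the maximum overlap with the predicted
#' vessel mask over radii up to `r_max` - the search range within which
#' the predicted counterpart segment `Vs'_j` is collected.
#'
#' @param ref_partition `segment_partition` of the reference mask.
#' @param pred_mask predicted [vessel_mask()].
#' @param segment_id reference segment id.
#' @param r_max maximum radius searched (default 10 px).
#' @return List with `segment_id`, `radius` (R_j), `overlap` (pixel count
#'   at that radius), and `matched` (logical matrix: the matched predicted
#'   pixel set `Vs'_j = dilate(V_j, R_j) & pred_mask`).
#' @export
matching_range <- function(ref_partition, pred_mask, segment_id, r_max = 10L) {
  if (r_max <= 0) av_error("RangeError", "r_max must be positive")
  check_same_dim(ref_partition$assignment, pred_mask, "partition and predicted mask")
  vj <- ref_partition$assignment == segment_id
  pm <- as.matrix(pred_mask); storage.mode(pm) <- "logical"
  overlaps <- integer(r_max + 1L)
  dil <- vj
  dilated <- list(dil)
  overlaps[1L] <- sum(dil & pm)
  for (r in seq_len(r_max)) {
    dil <- dilate_disc(vj, r)
    dilated[[r + 1L]] <- dil
    overlaps[r + 1L] <- sum(dil & pm)
  }
  r_best <- which.max(overlaps) - 1L   # first radius on the plateau
  list(segment_id = segment_id, radius = r_best,
       overlap = overlaps[r_best + 1L],
       matched = dilated[[r_best + 1L]] & pm)
}

## binary dilation by a disc of the given radius
dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::dilate(mask * 1, k)
  matrix(as.numeric(out) > 0, nrow(mask), ncol(mask))
}

#' Mismatch ratio between matched segment thicknesses
#'
#' `MisR = |TV'_j - TV_j| / TV_j`: the relative discrepancy between the
#' thickness of a reference segment and its matched predicted segment.
#' The absolute value penalizes thinner and thicker predictions
#' symmetrically.
#'
#' @param ref_thickness reference segment thickness `TV_j` (> 0).
#' @param matched_thickness matched predicted thickness `TV'_j`.
#' @return Non-negative scalar.
#' @export
mismatch_ratio <- function(ref_thickness, matched_thickness) {
  if (ref_thickness == 0)
    av_error("ZeroThickness", "reference thickness is zero")
  abs(matched_thickness - ref_thickness) / ref_thickness
}

#' Pixel weight matrix from per-segment mismatch ratios
#'
#' `w_p = 1 + MisR(Vs'_j, V_j)` for pixels inside a matched predicted
#' segment `Vs'_j`, and 1 everywhere else. A pixel covered by several
#' matched segments takes the largest weight.
#'
#' @param matched_segments named list (by segment id) of logical matrices
#'   marking each `Vs'_j`.
#' @param misr named numeric vector of mismatch ratios; names must be a
#'   subset of `names(matched_segments)`.
#' @param dim image dimensions `c(height, width)`.
#' @return Numeric matrix of weights, all `>= 1`.
#' @export
weight_map <- function(matched_segments, misr, dim) {
  if (!all(names(misr) %in% names(matched_segments)))
    av_error("WeightError", "misr has entries for unknown segments")
  W <- matrix(1, dim[1], dim[2])
  for (id in names(misr)) {
    m <- matched_segments[[id]]
    W[m] <- pmax(W[m], 1 + misr[[id]])
  }
  W
}

#' Weighted pixel-wise loss against a reference label
#'
#' Per pixel, `loss = (1 - p(true class)) * w_p`: the L1 deviation of the
#' predicted probability of the reference class from one, scaled by the
#' mismatch weight. A perfect one-hot prediction has zero loss; with all
#' weights 1 the total reduces to the unweighted deviation.
#'
#' @param predicted a [prob_raster()].
#' @param label reference [label_raster()].
#' @param weights weight matrix from [weight_map()] (default: all ones).
#' @return List with `per_pixel` (matrix) and `total` (its sum).
#' @export
weighted_loss <- function(predicted, label, weights = NULL) {
  check_same_dim(predicted, label, "prediction and label")
  if (is.null(weights)) weights <- matrix(1, nrow(label), ncol(label))
  check_same_dim(predicted, weights, "prediction and weights")
  h <- nrow(label); w <- ncol(label)
  plane <- as.integer(label)                 # 1 artery, 2 vein, 3 background
  p_true <- matrix(predicted[cbind(rep(seq_len(h), w),
                                   rep(seq_len(w), each = h),
                                   plane)], h, w)
  per_pixel <- (1 - p_true) * weights
  list(per_pixel = per_pixel, total = sum(per_pixel))
}

#' Segment-level loss report
#'
#' The full mismatch-weighted loss pipeline: for every reference segment,
#' find its matching range against the predicted vessel mask, collect the
#' matched predicted segment `Vs'_j`, compute its thickness over the
#' reference skeleton length and the mismatch ratio, assemble the weight
#' matrix, and evaluate the weighted loss of the predicted probabilities
#' against the reference label.
#'
#' @param ref_partition `segment_partition` of the reference mask.
#' @param ref_label reference [label_raster()].
#' @param predicted_probs predicted [prob_raster()].
#' @param threshold binarization threshold for the predicted mask.
#' @param r_max maximum matching radius.
#' @return List with `per_segment_misr` (named numeric), `matching_radius`
#'   (named numeric, R_j), `weights`, `per_pixel_loss`,
#'   `total_weighted_loss`.
#' @export
segment_loss_report <- function(ref_partition, ref_label, predicted_probs,
                                threshold = 0.5, r_max = 10L) {
  pred <- binarize(predicted_probs, threshold)
  ids <- vapply(ref_partition$segments, function(s) s$id, 0L)
  ids <- ids[ref_partition$n_vessel[ids] > 0]
  matched <- list(); misr <- numeric(0); radii <- numeric(0)
  for (id in ids) {
    mr <- matching_range(ref_partition, pred$mask, id, r_max = r_max)
    seg_len <- ref_partition$segments[[id]]$length
    t_matched <- sum(mr$matched) / seg_len
    key <- as.character(id)
    matched[[key]] <- mr$matched
    misr[key] <- mismatch_ratio(ref_partition$thickness[id], t_matched)
    radii[key] <- mr$radius
  }
  W <- weight_map(matched, misr, dim(ref_label))
  loss <- weighted_loss(predicted_probs, ref_label, W)
  list(per_segment_misr = misr, matching_radius = radii, weights = W,
       per_pixel_loss = loss$per_pixel, total_weighted_loss = loss$total)
}

#' Export segment tallies as a table
#'
#' One row per segment, mirroring the columns of a segment-judgment
#' table: id, vessel-pixel count, reference class (when a truth raster is
#' supplied), artery/vein counts and fractions, and the judged class.
#'
#' @param partition a `segment_partition`.
#' @param predicted pixel-wise [label_raster()].
#' @param truth optional reference [label_raster()]; adds a
#'   `reference_class` column (the majority truth class of the segment).
#' @return `data.frame`.
#' @export
tally_table <- function(partition, predicted, truth = NULL) {
  ids <- vapply(partition$segments, function(s) s$id, 0L)
  ids <- ids[partition$n_vessel[ids] > 0]
  rows <- lapply(ids, function(id) {
    tal <- tally_segment(partition, id, predicted)
    data.frame(segment_id = id,
               total_pixels = tal$total_pixels,
               artery_pixels = tal$artery_pixels,
               vein_pixels = tal$vein_pixels,
               artery_fraction = tal$artery_fraction,
               vein_fraction = tal$vein_fraction,
               judged_class = label_name(tal$judged_class))
  })
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    out$reference_class <- vapply(ids, function(id) {
      v <- truth[partition$assignment == id]
      label_name(majority_class(v))
    }, "")
    out <- out[, c("segment_id", "total_pixels", "reference_class",
                   "artery_pixels", "vein_pixels", "artery_fraction",
                   "vein_fraction", "judged_class")]
  }
  out
}

## majority vessel class of a vector of labels (tie -> AV_TIE)
majority_class <- function(v) {
  a <- sum(v == AV_ARTERY); b <- sum(v == AV_VEIN)
  if (a > b) AV_ARTERY else if (b > a) AV_VEIN else AV_TIE
}
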