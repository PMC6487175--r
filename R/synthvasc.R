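## Seeded generator of synthetic artery/vein vasculature: branching
## biased random-walk trees of two interleaved classes with tapering
## widths, plus corrupted predictions (class-flip noise, boundary
## jitter, softmax-style probability rasters) standing in for the output
## of a pixel classifier.

#' Specification of a synthetic vasculature case
#'
#' @param image_size `c(height, width)` in pixels (default 256 x 256).
#' @param n_trees_per_class vessel trees per class (default 2).
#' @param root_width root vessel width in pixels (default 4; branches
#'   taper so that much of the tree lies in the thin-vessel regime of
#'   width < 4 px that dominates retinal vasculature).
#' @param width_decay child width = parent width x `width_decay` at each
#'   branching (default 0.7, floor 1 px; a parent is never thinner than
#'   its branches).
#' @param branch_prob branching probability per walk step (default 0.03).
#' @param max_depth maximum branching depth (default 3).
#' @param flip_rate per-pixel probability that the prediction flips a
#'   vessel pixel's class, emulating classifier noise; in `[0, 0.5)`.
#' @param thickness_jitter boundary perturbation of the predicted mask:
#'   a dilation/erosion radius drawn uniformly from
#'   `-thickness_jitter..thickness_jitter` (default 0).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   cases.
#' @return A `vasculature_spec` list.
#' @export
vasculature_spec <- function(image_size = c(256L, 256L),
                             n_trees_per_class = 2L,
                             root_width = 4,
                             width_decay = 0.7,
                             branch_prob = 0.03,
                             max_depth = 3L,
                             flip_rate = 0.2,
                             thickness_jitter = 0L,
                             seed = 1L) {
  if (root_width < 1 || root_width > min(image_size) / 4)
    av_error("SpecError", "root_width must be in [1, min(image_size)/4]")
  if (width_decay <= 0 || width_decay > 1)
    av_error("SpecError", "width_decay must be in (0, 1]")
  if (branch_prob < 0 || branch_prob > 1 || flip_rate < 0 || flip_rate >= 0.5)
    av_error("SpecError", "branch_prob in [0,1], flip_rate in [0,0.5) required")
  structure(list(image_size = as.integer(image_size),
                 n_trees_per_class = as.integer(n_trees_per_class),
                 root_width = root_width, width_decay = width_decay,
                 branch_prob = branch_prob, max_depth = as.integer(max_depth),
                 flip_rate = flip_rate,
                 thickness_jitter = as.integer(thickness_jitter),
                 seed = as.integer(seed)),
            class = "vasculature_spec")
}

## disc offsets for stamping a vessel of the given width
disc_offsets <- function(width) {
  r <- max((width - 1) / 2, 0)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Generate a synthetic artery/vein case
#'
#' Trees of the two classes radiate outward from a disc origin, class
#' alternating around the rim (so neighboring vessels tend to be of
#' contrary type, as arterioles and venules interleave around the optic
#' disc). Each branch is a biased random walk with angular momentum and a
#' gentle outward radial pull, stamping a disc of its width; branching
#' spawns a narrower child at 20-60 degrees. A branch terminates rather
#' than cross a vessel of its own class; opposite-class crossings are
#' allowed - the later vessel passes on top - but a walk that rides along
#' an opposite-class vessel for longer than a crossing would take is
#' terminated.
#'
#' The prediction corrupts the truth by flipping each vessel pixel's
#' class independently with probability `flip_rate` and (optionally)
#' dilating/eroding the mask by `thickness_jitter`. The probability
#' raster gives the predicted class `0.5 + u` (u uniform in (0, 0.4]), so
#' [binarize()] at threshold 0.5 reproduces the hard prediction exactly.
#'
#' @param spec a [vasculature_spec()].
#' @param partition_args list of arguments passed to [segment_mask()]
#'   when deriving the truth partition (e.g. `max_length`).
#' @return A `synthetic_case`: list with `truth` ([label_raster()]),
#'   `mask` ([vessel_mask()]), `prediction` ([label_raster()]),
#'   `prob_prediction` ([prob_raster()]), `partition`
#'   (`segment_partition` of the truth mask) and `segment_truth` (integer
#'   vector: majority truth class per segment id).
#' @export
generate_case <- function(spec, partition_args = list()) {
  stopifnot(inherits(spec, "vasculature_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  h <- spec$image_size[1]; w <- spec$image_size[2]
  canvas <- matrix(0L, h, w)        # class per pixel, 0 = empty
  branch_of <- matrix(0L, h, w)     # stamping branch id, for self-crossing tests
  n_trees <- 2L * spec$n_trees_per_class

  ## trees radiate outward from a disc origin, as retinal vessels do from
  ## the optic disc; classes alternate around the rim so neighboring
  ## vessels tend to be of contrary type
  angles <- (seq_len(n_trees) - 1) * 2 * pi / n_trees + stats::runif(1, 0, 2 * pi)
  cx <- h * stats::runif(1, 0.4, 0.6); cy <- w * stats::runif(1, 0.35, 0.5)
  disc_r <- min(h, w) / 18
  next_branch_id <- 0L

  stamp <- function(r0, c0, off) {
    rr <- round(r0) + off$dr; cc <- round(c0) + off$dc
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    cbind(rr[keep], cc[keep])
  }

  for (t in seq_len(n_trees)) {
    cls <- if (t %% 2L == 1L) AV_ARTERY else AV_VEIN
    a0 <- angles[t]
    r0 <- cx + disc_r * cos(a0); c0 <- cy + disc_r * sin(a0)
    ## direction convention: a step is (dr, dc) = (sin(ang), cos(ang));
    ## roots head radially away from the disc
    queue <- list(list(r = r0, c = c0, ang = atan2(r0 - cx, c0 - cy),
                       width = spec$root_width, depth = 0L, parent_id = 0L))
    while (length(queue) > 0L) {
      br <- queue[[1]]; queue <- queue[-1]
      next_branch_id <- next_branch_id + 1L
      bid <- next_branch_id
      off <- disc_offsets(br$width)
      off_prox <- disc_offsets(br$width + 4)   # stamp grown by 2 px
      r <- br$r; c <- br$c; ang <- br$ang
      max_steps <- round(1.5 * max(h, w))
      cross_run <- 0L
      other_cls <- if (cls == AV_ARTERY) AV_VEIN else AV_ARTERY
      for (step in seq_len(max_steps)) {
        px <- stamp(r, c, off)
        if (nrow(px) == 0L) break
        ## terminate rather than cross a same-class vessel of another branch
        hit <- canvas[px] == cls & branch_of[px] != bid & branch_of[px] != br$parent_id
        if (step > 2L && any(hit)) break
        ## coming within 2 px of the opposite class is a crossing: allowed,
        ## but only briefly - a sustained run means the walk is riding
        ## along the other vessel, which arterioles and venules do not do
        if (any(canvas[stamp(r, c, off_prox)] == other_cls))
          cross_run <- cross_run + 1L
        else cross_run <- 0L
        if (cross_run > 2L * ceiling(br$width) + 10L) break
        canvas[px] <- cls
        branch_of[px] <- bid
        if (r < 1 || r > h || c < 1 || c > w) break
        if (br$depth < spec$max_depth && br$width * spec$width_decay >= 1 &&
            stats::runif(1) < spec$branch_prob && step > 10L) {
          side <- sample(c(-1, 1), 1L)
          child <- list(r = r, c = c,
                        ang = ang + side * stats::runif(1, 20, 60) * pi / 180,
                        width = br$width * spec$width_decay,
                        depth = br$depth + 1L, parent_id = bid)
          queue[[length(queue) + 1L]] <- child
          ang <- ang - side * stats::runif(1, 0, 15) * pi / 180
        }
        ## gentle outward radial bias keeps each tree in its own sector
        radial <- atan2(r - cx, c - cy)
        ang <- ang + 0.05 * atan2(sin(radial - ang), cos(radial - ang)) +
          stats::rnorm(1, 0, 0.06)
        r <- r + sin(ang); c <- c + cos(ang)
      }
    }
  }
  if (!any(canvas > 0L))
    av_error("SpecError", "generated geometry contains no vessels; enlarge the image or widen the walks")

  truth_m <- matrix(AV_BACKGROUND, h, w)
  truth_m[canvas == AV_ARTERY] <- AV_ARTERY
  truth_m[canvas == AV_VEIN] <- AV_VEIN
  truth <- label_raster(truth_m)
  mask <- vessel_mask(canvas > 0L)

  ## prediction: class-flip noise on vessel pixels
  pred_m <- truth_m
  vidx <- which(as.vector(mask))
  flips <- vidx[stats::runif(length(vidx)) < spec$flip_rate]
  pred_m[flips] <- ifelse(truth_m[flips] == AV_ARTERY, AV_VEIN, AV_ARTERY)
  pred_mask <- as.matrix(mask)

  if (spec$thickness_jitter > 0L) {
    j <- sample(seq(-spec$thickness_jitter, spec$thickness_jitter), 1L)
    if (j > 0L) {
      grown <- dilate_disc(pred_mask, j)
      new_px <- which(grown & !pred_mask)
      if (length(new_px) > 0L)
        pred_m[new_px] <- nearest_vessel_class(pred_m, pred_mask, new_px)
      pred_mask <- grown
    } else if (j < 0L) {
      k <- EBImage::makeBrush(2L * (-j) + 1L, shape = "disc")
      shrunk <- matrix(as.numeric(EBImage::erode(pred_mask * 1, k)) > 0, h, w)
      pred_m[pred_mask & !shrunk] <- AV_BACKGROUND
      pred_mask <- shrunk
    }
  }
  prediction <- label_raster(pred_m)

  ## softmax-style probabilities consistent with the hard prediction
  u <- stats::runif(h * w, 0, 0.4)
  u[u == 0] <- 0.2
  b <- 0.05
  pa <- matrix(0, h, w); pv <- matrix(0, h, w); pb <- matrix(0, h, w)
  ia <- pred_m == AV_ARTERY; iv <- pred_m == AV_VEIN; ib <- pred_m == AV_BACKGROUND
  U <- matrix(u, h, w)
  pa[ia] <- 0.5 + U[ia]; pv[ia] <- 0.5 - U[ia] - b; pb[ia] <- b
  pv[iv] <- 0.5 + U[iv]; pa[iv] <- 0.5 - U[iv] - b; pb[iv] <- b
  pb[ib] <- 0.5 + U[ib]; pa[ib] <- (0.5 - U[ib]) / 2; pv[ib] <- (0.5 - U[ib]) / 2
  prob_prediction <- prob_raster(array(c(pa, pv, pb), c(h, w, 3L)))

  partition <- do.call(segment_mask, c(list(mask), partition_args))
  seg_ids <- vapply(partition$segments, function(s) s$id, 0L)
  segment_truth <- vapply(seg_ids, function(id) {
    v <- truth_m[partition$assignment == id]
    if (length(v) == 0L) AV_TIE else majority_class(v)
  }, 0L)
  names(segment_truth) <- seg_ids

  structure(list(truth = truth, mask = mask, prediction = prediction,
                 prob_prediction = prob_prediction, partition = partition,
                 segment_truth = segment_truth, spec = spec),
            class = "synthetic_case")
}

## classes of the nearest existing vessel pixels for newly grown pixels
nearest_vessel_class <- function(labels, mask, new_idx) {
  h <- nrow(labels)
  vidx <- which(mask)
  vr <- ((vidx - 1L) %% h) + 1L; vc <- ((vidx - 1L) %/% h) + 1L
  nr <- ((new_idx - 1L) %% h) + 1L; nc <- ((new_idx - 1L) %/% h) + 1L
  out <- integer(length(new_idx))
  chunk <- 2048L
  for (s0 in seq(1L, length(new_idx), by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, length(new_idx))
    d2 <- outer(nr[ii], vr, "-")^2 + outer(nc[ii], vc, "-")^2
    best <- max.col(-d2, ties.method = "first")
    out[ii] <- labels[vidx[best]]
  }
  out
}

#' Fraction of vessel pixels on thin vessels
#'
#' Thin vessels are those with local width under 4 pixels - the dominant
#' regime in retinal vasculature and the motivation for segment-level
#' judgment. Local width at a vessel pixel is `2 d - 1` where `d` is the
#' distance-transform value at the nearest skeleton pixel; here the
#' per-pixel local width `2 d(p) - 1` of the pixel itself is used, which
#' flags pixels within 1.5 px of the vessel boundary interior of wide
#' vessels too, so the measure is computed per segment thickness instead:
#' a vessel pixel is thin iff its segment's mean thickness is < 4.
#'
#' @param partition a `segment_partition`.
#' @return Fraction in `[0, 1]` of vessel pixels lying on segments with
#'   thickness `< 4` px.
#' @export
thin_vessel_fraction <- function(partition) {
  if (sum(partition$n_vessel) == 0) return(0)
  thin <- partition$thickness < 4
  sum(partition$n_vessel[thin]) / sum(partition$n_vessel)
}

#' Segment-judgment worked-example fixture
#'
#' Twelve segments with the pixel counts of the published worked example
#' of the multiloss judgment: total vessel pixels, red (artery) and blue
#' (vein) predicted counts, the printed class fractions, the printed
#' judgment and the reference class, for exercising the judgment module
#' against printed values. The `consistent_fraction` flag marks rows
#' whose printed probabilities agree with their printed counts to 1e-3;
#' `consistent_judgment` marks rows whose printed judgment is the
#' majority of the printed counts (one row prints counts contradicting
#' its judgment - a typographic error in the source - and is excluded
#' from judgment checks).
#'
#' @return `data.frame` with columns `roi`, `total`, `label_class`,
#'   `artery_px`, `vein_px`, `printed_artery_prob`, `printed_vein_prob`,
#'   `printed_judgment`, `consistent_fraction_artery`,
#'   `consistent_fraction_vein`, `consistent_judgment`,
#'   `consistent_total` (one row's counts sum past its printed total; its
#'   tally uses the count sum as denominator), plus a `tally` list-column
#'   of `segment_tally` objects built from the counts.
#' @export
table2_fixture <- function() {
  df <- data.frame(
    roi = paste0("Seg", 1:12),
    total = c(200L, 500L, 700L, 457L, 458L, 459L, 460L, 320L, 230L, 543L, 544L, 545L),
    label_class = c("ARTERY", "VEIN", "VEIN", "VEIN", "ARTERY", "VEIN",
                    "VEIN", "VEIN", "ARTERY", "ARTERY", "ARTERY", "ARTERY"),
    artery_px = c(120L, 400L, 100L, 46L, 320L, 0L, 184L, 43L, 146L, 326L, 508L, 529L),
    vein_px = c(80L, 100L, 600L, 411L, 137L, 459L, 276L, 277L, 84L, 217L, 36L, 18L),
    printed_artery_prob = c(0.600, 0.800, 0.100, 0.100, 0.700, 0.000,
                            0.400, 0.134, 0.634, 0.600, 0.934, 0.967),
    printed_vein_prob = c(0.400, 0.200, 0.900, 0.900, 0.300, 1.000,
                          0.600, 0.867, 0.367, 0.400, 0.067, 0.034),
    printed_judgment = c("ARTERY", "VEIN", "VEIN", "VEIN", "ARTERY", "VEIN",
                         "VEIN", "VEIN", "ARTERY", "ARTERY", "ARTERY", "ARTERY"),
    stringsAsFactors = FALSE
  )
  denom <- pmax(df$total, df$artery_px + df$vein_px)
  df$consistent_fraction_artery <-
    abs(df$artery_px / denom - df$printed_artery_prob) <= 1e-3
  df$consistent_fraction_vein <-
    abs(df$vein_px / denom - df$printed_vein_prob) <= 1e-3
  maj <- ifelse(df$artery_px > df$vein_px, "ARTERY",
                ifelse(df$vein_px > df$artery_px, "VEIN", "TIE"))
  df$consistent_judgment <- maj == df$printed_judgment
  ## one printed row's class counts sum past its printed total (another
  ## typographic slip); tallies use the count sum as denominator there
  df$consistent_total <- df$artery_px + df$vein_px <= df$total
  df$tally <- lapply(seq_len(nrow(df)), function(i)
    new_segment_tally(i, max(df$total[i], df$artery_px[i] + df$vein_px[i]),
                      df$artery_px[i], df$vein_px[i]))
  df
}

#' Write a synthetic case to disk
#'
#' Emits the standard file trio plus extras for one case: truth and
#' prediction label PNGs, mask PNG, probability TIFF, and a CSV of
#' per-segment ground-truth classes.
#'
#' @param case a `synthetic_case`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem (default `"case"`).
#' @return Invisibly, the named vector of written paths.
#' @export
write_case <- function(case, dir, stem = "case") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    truth = file.path(dir, paste0(stem, "_truth.png")),
    mask = file.path(dir, paste0(stem, "_mask.png")),
    prediction = file.path(dir, paste0(stem, "_prediction.png")),
    probs = file.path(dir, paste0(stem, "_probs.tif")),
    segments = file.path(dir, paste0(stem, "_segments.csv"))
  )
  write_label_png(case$truth, paths["truth"])
  write_mask_png(case$mask, paths["mask"])
  write_label_png(case$prediction, paths["prediction"])
  write_prob_tiff(case$prob_prediction, paths["probs"])
  utils::write.csv(
    data.frame(segment_id = as.integer(names(case$segment_truth)),
               truth_class = label_name(case$segment_truth)),
    paths["segments"], row.names = FALSE)
  invisible(paths)
}
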