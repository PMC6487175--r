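# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately use naive enumeration, not the package's
# own code paths.

make_bar_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  vessel_mask(m)
}

random_label_raster <- function(h, w, seed, p_bg = 0.6) {
  withr::with_seed(seed, {
    label_raster(matrix(sample(c(AV_ARTERY, AV_VEIN, AV_BACKGROUND), h * w,
                               replace = TRUE,
                               prob = c((1 - p_bg) / 2, (1 - p_bg) / 2, p_bg)),
                        h, w))
  })
}

# blobby random mask from a few stamped discs
random_blob_mask <- function(h, w, seed, n_blobs = 4, r_max = 6) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(n_blobs)) {
      r0 <- sample(h, 1); c0 <- sample(w, 1); rad <- sample(2:r_max, 1)
      for (dr in -rad:rad) for (dc in -rad:rad)
        if (dr^2 + dc^2 <= rad^2) {
          rr <- r0 + dr; cc <- c0 + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) m[rr, cc] <- TRUE
        }
    }
    vessel_mask(m)
  })
}

# all-pairs nearest-skeleton-pixel assignment: the oracle for
# partition_vessel_pixels (skeleton pixels scanned in segment id / path
# order; first minimum wins)
brute_assignment <- function(mask, segments) {
  sk <- do.call(rbind, lapply(segments, function(s)
    cbind(s$pixels[, 1], s$pixels[, 2], s$id)))
  A <- matrix(0L, nrow(mask), ncol(mask))
  for (idx in which(as.matrix(mask))) {
    r <- ((idx - 1) %% nrow(mask)) + 1
    c <- ((idx - 1) %/% nrow(mask)) + 1
    d2 <- (sk[, 1] - r)^2 + (sk[, 2] - c)^2
    A[idx] <- sk[which.min(d2), 3]
  }
  A
}

# per-pixel counting oracle for tally_segment
brute_tally_counts <- function(assignment, segment_id, predicted) {
  a <- 0L; v <- 0L; tot <- 0L
  for (idx in which(assignment == segment_id)) {
    tot <- tot + 1L
    if (predicted[idx] == AV_ARTERY) a <- a + 1L
    if (predicted[idx] == AV_VEIN) v <- v + 1L
  }
  c(total = tot, artery = a, vein = v)
}

# exhaustive-distance oracle for the boundary F-score
brute_bf_score <- function(reference, predicted, tolerance) {
  boundary <- function(labels, cls) {
    M <- unclass(labels) == cls
    h <- nrow(M); w <- ncol(M)
    out <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!M[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && !M[ii, jj])
          out[i, j] <- TRUE
      }
    }
    out
  }
  match_frac <- function(from, to) {
    fp <- which(from, arr.ind = TRUE); tp <- which(to, arr.ind = TRUE)
    if (nrow(fp) == 0L) return(NA_real_)
    if (nrow(tp) == 0L) return(0)
    ok <- 0L
    for (i in seq_len(nrow(fp))) {
      d <- sqrt(min((tp[, 1] - fp[i, 1])^2 + (tp[, 2] - fp[i, 2])^2))
      if (d <= tolerance) ok <- ok + 1L
    }
    ok / nrow(fp)
  }
  scores <- c()
  for (cls in c(AV_ARTERY, AV_VEIN, AV_BACKGROUND)) {
    rb <- boundary(reference, cls); pb <- boundary(predicted, cls)
    if (!any(rb) && !any(pb)) next
    prec <- match_frac(pb, rb); rec <- match_frac(rb, pb)
    prec <- ifelse(is.na(prec), 0, prec); rec <- ifelse(is.na(rec), 0, rec)
    scores <- c(scores, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  mean(scores)
}

# 8-connected component labelling oracle (stack-based flood fill)
brute_cc8 <- function(mask) {
  M <- as.matrix(mask)
  lab <- matrix(0L, nrow(M), ncol(M))
  nxt <- 0L
  for (start in which(M & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack) > 0L) {
      idx <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[idx] != 0L) next
      lab[idx] <- nxt
      r <- ((idx - 1) %% nrow(M)) + 1; c <- ((idx - 1) %/% nrow(M)) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(M) && cc >= 1 && cc <= ncol(M) &&
            M[rr, cc] && lab[rr, cc] == 0L)
          stack <- c(stack, (cc - 1) * nrow(M) + rr)
      }
    }
  }
  lab
}

# uniform-probability raster whose argmax reproduces `labels` with margin
probs_from_labels <- function(labels, p_top = 0.8) {
  h <- nrow(labels); w <- ncol(labels)
  arr <- array((1 - p_top) / 2, c(h, w, 3))
  for (k in 1:3) {
    pl <- arr[, , k]
    pl[unclass(labels) == k] <- p_top
    arr[, , k] <- pl
  }
  prob_raster(arr)
}
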