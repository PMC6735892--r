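gaussian_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

dog_filter <- function(img, sigma) {
  # band-pass at the spot scale: difference of Gaussians, 1:1.6 sigma ratio
  EBImage::filter2(img, gaussian_kernel(sigma)) -
    EBImage::filter2(img, gaussian_kernel(1.6 * sigma))
}

local_maxima <- function(img) {
  h <- nrow(img); w <- ncol(img)
  res <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    shifted[ys, xs] <- img[ys - dy, xs - dx]
    res <- res & (img > shifted)
  }
  res
}

erode_labels <- function(labels, px) {
  if (px < 1) return(labels)
  bw <- labels > 0
  eroded <- EBImage::erode(bw, EBImage::makeBrush(2 * floor(px) + 1, "disc"))
  out <- labels
  out[!eroded] <- 0L
  out
}

#' Detect nuclear foci by band-pass filtering and local maxima
#'
#' Applies a difference-of-Gaussians band-pass at the expected spot scale,
#' then keeps local maxima whose filtered amplitude exceeds
#' `rel_threshold` times the per-nucleus robust background (1.4826 x MAD of
#' the filtered response inside the nucleus).  Because relative thresholding
#' is used, detections are invariant to rescaling the image by a positive
#' constant.  Maxima within `2 * spot_sigma` of the nucleus rim are
#' discarded (the band-pass responds to the nuclear boundary there), as are
#' maxima outside any nucleus.
#'
#' @param img single-channel matrix (max-project stacks first).
#' @param mask a [segment_nuclei()] result.
#' @param spot_sigma expected spot Gaussian sigma, px.
#' @param rel_threshold multiple of the per-nucleus robust background a peak
#'   must exceed; default 5.
#' @return a `foci_set` data frame: `cell_id`, `y`, `x`, `peak` (band-pass
#'   amplitude).
#' @export
detect_foci <- function(img, mask, spot_sigma = 1.5, rel_threshold = 5) {
  stopifnot(is.matrix(img), inherits(mask, "nucleus_mask"))
  dog <- dog_filter(img, spot_sigma)
  interior <- erode_labels(mask$labels, ceiling(2 * spot_sigma))
  cand <- which(local_maxima(dog) & interior > 0)
  out <- data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0),
                    peak = numeric(0))
  if (length(cand)) {
    labs <- interior[cand]
    # per-nucleus robust background: pixel noise estimated from horizontal
    # first differences of the raw channel (smooth spot structure cancels,
    # so the estimate stays noise-driven even in spot-dense nuclei), scaled
    # to the band-pass response by the DoG kernel's L2 norm
    k1 <- gaussian_kernel(spot_sigma); k2 <- gaussian_kernel(1.6 * spot_sigma)
    n1 <- nrow(k1); n2 <- nrow(k2); pad <- (n2 - n1) / 2
    kd <- -k2
    kd[pad + seq_len(n1), pad + seq_len(n1)] <-
      kd[pad + seq_len(n1), pad + seq_len(n1)] + k1
    kfac <- sqrt(sum(kd^2))
    dx <- img - cbind(img[, -1], img[, ncol(img)])
    bg <- vapply(seq_along(mask$area), function(l) {
      d <- dx[interior == l]
      if (!length(d)) return(Inf)
      max(kfac * median(abs(d)) / (0.6745 * sqrt(2)), 1e-9)
    }, 0)
    keep <- dog[cand] > rel_threshold * bg[labs]
    cand <- cand[keep]; labs <- labs[keep]
    out <- data.frame(cell_id = labs,
                      y = (cand - 1) %% nrow(img) + 1,
                      x = (cand - 1) %/% nrow(img) + 1,
                      peak = dog[cand])
    out <- out[order(out$cell_id, -out$peak), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("foci_set", "data.frame")
  out
}

#' Per-cell focus counts
#'
#' @param foci a `foci_set`.
#' @param n_cells total number of nuclei (cells without foci get 0).
#' @return integer vector of length `n_cells`.
#' @export
foci_counts <- function(foci, n_cells) {
  counts <- integer(n_cells)
  t <- table(factor(foci$cell_id, levels = seq_len(n_cells)))
  counts[] <- as.integer(t)
  counts
}

#' Object-based colocalization of two focus channels
#'
#' Greedy nearest-pair matching of channel-A and channel-B foci within each
#' cell: candidate pairs with centroid distance at most
#' `2 * overlap_radius` are matched in order of increasing distance (ties
#' broken by the smaller channel-A index), each focus used at most once.
#' Matched pairs at distance `<= overlap_radius` count as overlapping foci;
#' pairs in `(overlap_radius, 2 * overlap_radius]` as adjacent foci.  The
#' overlap count is symmetric in the two channels.
#'
#' @param a,b `foci_set` data frames from the same segmentation.
#' @param overlap_radius distance defining complete overlap, px.
#' @param n_cells number of nuclei.
#' @return data frame `cell_id`, `n_overlap`, `n_adjacent`.
#' @export
object_colocalization <- function(a, b, overlap_radius, n_cells) {
  stopifnot(inherits(a, "foci_set"), inherits(b, "foci_set"),
            overlap_radius > 0)
  n_ov <- integer(n_cells); n_ad <- integer(n_cells)
  for (cell in intersect(unique(a$cell_id), unique(b$cell_id))) {
    ai <- which(a$cell_id == cell); bi <- which(b$cell_id == cell)
    d <- outer(seq_along(ai), seq_along(bi), function(i, j)
      sqrt((a$y[ai[i]] - b$y[bi[j]])^2 + (a$x[ai[i]] - b$x[bi[j]])^2))
    pairs <- which(d <= 2 * overlap_radius, arr.ind = TRUE)
    if (!nrow(pairs)) next
    ord <- order(d[pairs], pairs[, 1])
    used_a <- logical(length(ai)); used_b <- logical(length(bi))
    for (idx in ord) {
      i <- pairs[idx, 1]; j <- pairs[idx, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      if (d[i, j] <= overlap_radius) n_ov[cell] <- n_ov[cell] + 1L
      else n_ad[cell] <- n_ad[cell] + 1L
    }
  }
  data.frame(cell_id = seq_len(n_cells), n_overlap = n_ov, n_adjacent = n_ad)
}
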