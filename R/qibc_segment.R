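#' Segment nuclei from a DAPI image
#'
#' Global Otsu threshold, hole filling and connected-component labelling
#' (via EBImage), followed by a size filter: components with area in
#' `[min_area, max_area]` become nuclei (relabelled 1..n); components below
#' `min_area` are retained separately as micronucleus candidates.
#'
#' @param dapi single-channel 2D numeric matrix (max-project stacks first).
#' @param min_area,max_area nucleus area bounds in pixels.
#' @return an object of class `nucleus_mask`: list with `labels` (integer
#'   label matrix), `area`, `centroid` (n x 2 matrix, rows are (y, x)) and
#'   `small` (same three fields for the sub-`min_area` candidates).
#' @export
segment_nuclei <- function(dapi, min_area = 100, max_area = Inf) {
  stopifnot(is.matrix(dapi), min_area >= 1)
  rng <- range(dapi)
  empty <- function() {
    warning("no objects found in DAPI image; returning empty mask")
    structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                   area = numeric(0),
                   centroid = matrix(numeric(0), 0, 2),
                   small = list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                                area = numeric(0),
                                centroid = matrix(numeric(0), 0, 2))),
              class = "nucleus_mask")
  }
  if (diff(rng) <= 0) return(empty())
  norm <- (dapi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- EBImage::fillHull(norm > thr)
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(empty())

  labv <- as.integer(lab)
  area <- tabulate(labv, nbins = nlab)
  idx <- which(labv > 0)
  yy <- (idx - 1) %% nrow(dapi) + 1
  xx <- (idx - 1) %/% nrow(dapi) + 1
  cy <- vapply(seq_len(nlab), function(l) mean(yy[labv[idx] == l]), 0)
  cx <- vapply(seq_len(nlab), function(l) mean(xx[labv[idx] == l]), 0)

  relabel <- function(keep) {
    map <- integer(nlab)
    map[keep] <- seq_along(keep)
    m <- matrix(0L, nrow(dapi), ncol(dapi))
    sel <- labv > 0 & map[pmax(labv, 1L)] > 0
    m[sel] <- map[labv[sel]]
    list(labels = m, area = area[keep],
         centroid = cbind(y = cy[keep], x = cx[keep]))
  }
  keep_n <- which(area >= min_area & area <= max_area)
  keep_s <- which(area < min_area)
  big <- relabel(keep_n)
  small <- relabel(keep_s)
  structure(list(labels = big$labels, area = big$area,
                 centroid = big$centroid, small = small),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat("nucleus_mask:", length(x$area), "nuclei,",
      length(x$small$area), "sub-threshold candidate object(s)\n")
  invisible(x)
}

#' Per-cell intensity features from segmented nuclei
#'
#' Computes the QIBC feature vector of each nucleus: integrated DAPI
#' intensity (DNA content proxy), mean EdU intensity (replication proxy) and
#' optionally mean Cyclin A intensity.
#'
#' @param mask a [segment_nuclei()] result.
#' @param dapi,edu matrices matching the mask.
#' @param cyclinA optional Cyclin A matrix.
#' @return a `cell_records` data frame: `cell_id`, `y`, `x`, `area`,
#'   `dapi_integrated`, `edu_mean`, `cyclinA_mean` (NA when not supplied),
#'   `stage` (NA until gated).
#' @export
qibc_cell_records <- function(mask, dapi, edu, cyclinA = NULL) {
  stopifnot(inherits(mask, "nucleus_mask"))
  n <- length(mask$area)
  labv <- as.integer(mask$labels)
  sum_by <- function(img) {
    v <- rep(0, n)
    s <- tapply(as.numeric(img)[labv > 0], labv[labv > 0], sum)
    v[as.integer(names(s))] <- s
    v
  }
  dapi_int <- sum_by(dapi)
  edu_mean <- sum_by(edu) / pmax(mask$area, 1)
  cyc_mean <- if (is.null(cyclinA)) rep(NA_real_, n)
              else sum_by(cyclinA) / pmax(mask$area, 1)
  out <- data.frame(cell_id = seq_len(n),
                    y = mask$centroid[, 1], x = mask$centroid[, 2],
                    area = mask$area,
                    dapi_integrated = dapi_int, edu_mean = edu_mean,
                    cyclinA_mean = cyc_mean,
                    stage = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Count micronuclei near segmented nuclei
#'
#' Sub-threshold DAPI objects (area at most `max_mn_area`) whose centroid
#' lies within `search_radius` of a nucleus boundary are counted as
#' micronuclei of the nearest nucleus.  Boundary distance is approximated as
#' centroid distance minus the nucleus equivalent-disk radius, which is
#' exact for the disk-shaped nuclei the generator produces.
#'
#' @param mask a [segment_nuclei()] result.
#' @param max_mn_area maximum micronucleus area, px.
#' @param search_radius maximum boundary distance, px.
#' @return data frame `cell_id`, `micronuclei_count` (one row per nucleus).
#' @export
detect_micronuclei <- function(mask, max_mn_area = 60, search_radius = 15) {
  stopifnot(inherits(mask, "nucleus_mask"))
  n <- length(mask$area)
  counts <- integer(n)
  cand <- which(mask$small$area > 0 & mask$small$area <= max_mn_area)
  if (n > 0 && length(cand)) {
    eq_r <- sqrt(mask$area / pi)
    for (i in cand) {
      d <- sqrt((mask$centroid[, 1] - mask$small$centroid[i, 1])^2 +
                (mask$centroid[, 2] - mask$small$centroid[i, 2])^2) - eq_r
      j <- which.min(d)
      if (d[j] <= search_radius) counts[j] <- counts[j] + 1L
    }
  }
  data.frame(cell_id = seq_len(n), micronuclei_count = counts)
}
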