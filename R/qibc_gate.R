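split_bimodal <- function(x, what) {
  # two-component threshold on log intensities: Gaussian mixture, with a
  # two-means fallback when the mixture fit degenerates
  lx <- log10(pmax(x, 1e-12))
  thr <- tryCatch({
    fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    lo <- which.min(mu); hi <- which.max(mu)
    cl <- fit$classification
    if (length(unique(cl)) < 2) stop("degenerate mixture")
    (max(lx[cl == lo]) + min(lx[cl == hi])) / 2
  }, error = function(e) {
    km <- kmeans(lx, centers = sort(quantile(lx, c(0.25, 0.75))))
    mean(km$centers)
  })
  if (!is.finite(thr)) stop("could not locate a ", what, " threshold")
  10^thr
}

dapi_modes <- function(dapi) {
  # 2N and 4N modes among EdU-negative cells, via 2-means on DNA content
  km <- kmeans(dapi, centers = sort(quantile(dapi, c(0.25, 0.75))))
  m <- sort(vapply(1:2, function(k) median(dapi[km$cluster == k]), 0))
  if (m[2] / m[1] < 1.25)
    stop("DAPI distribution of EdU-negative cells looks unimodal; ",
         "supply manual thresholds via the 'thresholds' argument")
  m
}

#' Assign cell-cycle stages from DAPI/EdU (and optionally Cyclin A) profiles
#'
#' Standard QIBC gating: cells are first split into EdU-positive
#' (replicating) and EdU-negative by a two-component intensity model on log
#' EdU.  The 2N and 4N DAPI modes are located on the EdU-negative cells;
#' EdU-negative cells near the 2N mode are G1 and near the 4N mode are G2.
#' EdU-positive cells are divided into early/mid/late S by terciles of the
#' DAPI span between the two modes.  When `cyclinA_gate = TRUE`,
#' EdU-negative cells are instead split by Cyclin A: Cyclin A-negative cells
#' are selected as G1 and Cyclin A-positive as G2 (the gate used when
#' scoring G1-specific structures such as 53BP1 nuclear bodies).
#'
#' @param records a `cell_records` data frame ([qibc_cell_records()]); at
#'   least ~50 cells are recommended for stable mode detection.
#' @param cyclinA_gate use Cyclin A to define G1 among EdU-negative cells.
#' @param thresholds optional manual gates: list with any of `edu` (EdU
#'   positivity cut), `dapi_2n`, `dapi_4n` (mode positions), `cyclinA`.
#' @return `records` with `stage` filled in (every cell gets exactly one
#'   stage) plus attributes `gates` (the thresholds used).
#' @export
gate_cell_cycle <- function(records, cyclinA_gate = FALSE, thresholds = NULL) {
  stopifnot(inherits(records, "cell_records"))
  if (nrow(records) < 2) stop("need at least 2 cells to gate")
  edu_thr <- thresholds$edu %||% split_bimodal(records$edu_mean, "EdU")
  edu_pos <- records$edu_mean > edu_thr
  if (!any(!edu_pos)) stop("no EdU-negative cells; cannot locate DAPI modes")

  # DAPI modes are needed to place S-phase terciles, and to split G1/G2
  # unless the Cyclin A gate takes over the EdU-negative split
  need_modes <- any(edu_pos) || !cyclinA_gate
  if (need_modes) {
    if (is.null(thresholds$dapi_2n) || is.null(thresholds$dapi_4n)) {
      m <- dapi_modes(records$dapi_integrated[!edu_pos])
    } else m <- c(thresholds$dapi_2n, thresholds$dapi_4n)
    mid <- sqrt(m[1] * m[2])            # geometric midpoint between modes
    b1 <- m[1] + (m[2] - m[1]) / 3
    b2 <- m[1] + 2 * (m[2] - m[1]) / 3
  } else {
    m <- c(NA_real_, NA_real_); mid <- b1 <- b2 <- NA_real_
  }

  stage <- character(nrow(records))
  d <- records$dapi_integrated
  if (cyclinA_gate) {
    if (all(is.na(records$cyclinA_mean)))
      stop("cyclinA_gate requested but no Cyclin A measurements present")
    cyc_thr <- thresholds$cyclinA %||%
      split_bimodal(records$cyclinA_mean, "Cyclin A")
    stage[!edu_pos] <- ifelse(records$cyclinA_mean[!edu_pos] <= cyc_thr,
                              "G1", "G2")
  } else {
    stage[!edu_pos] <- ifelse(d[!edu_pos] <= mid, "G1", "G2")
  }
  stage[edu_pos & d <= b1] <- "earlyS"
  stage[edu_pos & d > b1 & d <= b2] <- "midS"
  stage[edu_pos & d > b2] <- "lateS"

  records$stage <- stage
  attr(records, "gates") <- list(edu = edu_thr, dapi_2n = m[1], dapi_4n = m[2],
                                 s_terciles = c(b1, b2))
  records
}
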