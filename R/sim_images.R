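STAGES <- c("G1", "earlyS", "midS", "lateS", "G2")

# DNA-content position of each stage between the 2N (0) and 4N (1) modes;
# S-phase stages are interpolated.
STAGE_DNA_FRAC <- c(G1 = 0, earlyS = 0.25, midS = 0.5, lateS = 0.75, G2 = 1)

#' Parameters for the synthetic QIBC image generator
#'
#' Emulates a max-projected high-content imaging field: non-overlapping
#' disk-shaped nuclei whose integrated DAPI intensity reflects DNA content
#' (2N in G1, 4N in G2, interpolated through S phase), EdU incorporation high
#' only in S-phase cells, and nuclear foci rendered as isotropic Gaussian
#' spots in two marker channels (A and B).  A controlled fraction of B foci
#' is planted exactly at an A focus to produce known colocalization.
#' Geometry is deliberately minimal (disks, isotropic spots) so that ground
#' truth is analytic.
#'
#' @param n_cells number of nuclei to place.
#' @param stage_mix named proportions over `G1, earlyS, midS, lateS, G2`
#'   (must sum to 1).
#' @param dapi_2n_mean,dapi_4n_mean mean integrated DAPI intensity (intensity
#'   x px) of 2N and 4N nuclei; `dapi_4n_mean` must exceed `dapi_2n_mean`.
#' @param dapi_cv,edu_cv per-cell lognormal coefficient of variation of the
#'   DAPI and EdU levels.
#' @param edu_pos_mean,edu_neg_mean mean within-nucleus EdU pixel intensity
#'   of replicating and non-replicating cells.
#' @param foci_rate_per_stage named vector, mean foci per cell per channel
#'   for each stage (Poisson).
#' @param coloc_fraction probability that a channel-B focus is planted at a
#'   channel-A focus of the same cell.
#' @param spot_sigma_px Gaussian sigma of rendered foci, in pixels.
#' @param spot_amplitude peak intensity added by one focus.
#' @param noise_sd additive Gaussian pixel noise (all channels).
#' @param image_shape integer `c(rows, cols)` of the field.
#' @param nucleus_radius_px nucleus disk radius in pixels.
#' @param cyclinA_pos_mean,cyclinA_neg_mean mean within-nucleus Cyclin A
#'   intensity for S/G2 versus G1 cells (Cyclin A marks S and G2; G1 cells
#'   are Cyclin A-negative).
#' @param micronucleus_prob probability that a cell carries one small
#'   satellite DAPI body (micronucleus) near its nucleus.
#' @param seed integer seed.
#' @return an object of class `image_sim_params`.
#' @seealso [gen_foci_images()]
#' @export
image_sim_params <- function(n_cells = 60,
                             stage_mix = c(G1 = 0.30, earlyS = 0.15,
                                           midS = 0.15, lateS = 0.15,
                                           G2 = 0.25),
                             dapi_2n_mean = 5000, dapi_4n_mean = 10000,
                             dapi_cv = 0.05,
                             edu_pos_mean = 2.0, edu_neg_mean = 0.2,
                             edu_cv = 0.10,
                             foci_rate_per_stage = c(G1 = 1, earlyS = 2,
                                                     midS = 3, lateS = 5,
                                                     G2 = 4),
                             coloc_fraction = 0.2,
                             spot_sigma_px = 1.5,
                             spot_amplitude = 3,
                             noise_sd = 0.05,
                             image_shape = c(512L, 512L),
                             nucleus_radius_px = 18,
                             cyclinA_pos_mean = 1.5, cyclinA_neg_mean = 0.15,
                             micronucleus_prob = 0,
                             seed = 1L) {
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  if (!is_count(p$n_cells)) stop("n_cells must be a non-negative integer")
  if (length(p$stage_mix) != 5L || !setequal(names(p$stage_mix), STAGES))
    stop("stage_mix must be named over ", paste(STAGES, collapse = ", "))
  if (abs(sum(p$stage_mix) - 1) > 1e-8) stop("stage_mix must sum to 1")
  if (any(p$stage_mix < 0)) stop("stage_mix proportions must be >= 0")
  if (p$dapi_4n_mean <= p$dapi_2n_mean)
    stop("dapi_4n_mean must exceed dapi_2n_mean")
  if (!setequal(names(p$foci_rate_per_stage), STAGES) ||
      any(p$foci_rate_per_stage < 0))
    stop("foci_rate_per_stage must be a non-negative rate per stage")
  if (!is_prob(p$coloc_fraction)) stop("coloc_fraction must lie in [0, 1]")
  if (!is_prob(p$micronucleus_prob)) stop("micronucleus_prob must lie in [0, 1]")
  if (p$noise_sd < 0 || p$spot_sigma_px <= 0 || p$nucleus_radius_px < 3)
    stop("invalid noise/spot/radius parameter")
  p$image_shape <- as.integer(image_shape)
  structure(p, class = "image_sim_params")
}

add_gaussian_spot <- function(img, y, x, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma)
  ys <- max(1, round(y) - half):min(h, round(y) + half)
  xs <- max(1, round(x) - half):min(w, round(x) + half)
  d2 <- outer((ys - y)^2, (xs - x)^2, `+`)
  img[ys, xs] <- img[ys, xs] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

paint_disk <- function(img, y, x, r, value) {
  h <- nrow(img); w <- ncol(img)
  ys <- max(1, floor(y - r)):min(h, ceiling(y + r))
  xs <- max(1, floor(x - r)):min(w, ceiling(x + r))
  inside <- outer((ys - y)^2, (xs - x)^2, `+`) <= r^2
  block <- img[ys, xs, drop = FALSE]
  block[inside] <- block[inside] + value
  img[ys, xs] <- block
  img
}

#' Generate a synthetic QIBC imaging field with ground truth
#'
#' Draws one multi-channel field from the model in [image_sim_params()]:
#' DAPI, EdU and Cyclin A channels plus two focus channels (A and B).
#' Nuclei are non-overlapping disks; foci are planted uniformly inside the
#' nucleus at least `3 * spot_sigma_px` from its rim so every spot lies
#' fully within its parent nucleus.
#'
#' @param params an [image_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{images}{named list of numeric matrices: `dapi`, `edu`,
#'       `cyclinA`, `chanA`, `chanB`.}
#'     \item{truth}{list with `cells` (per-cell: `cell_id`, `y`, `x`,
#'       `radius`, `stage`, `dapi_total`, `edu_mean`, `n_foci_a`/`n_foci_b`
#'       planting events, `n_spots_a`/`n_spots_b` distinct resolvable spots
#'       after fusing foci closer than two spot sigmas, `n_micronuclei`) and
#'       `foci` (per-focus: `cell_id`, `channel`, `y`, `x`,
#'       `colocalized`).}
#'   }
#' @export
gen_foci_images <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(params$seed)
  h <- params$image_shape[1]; w <- params$image_shape[2]
  r <- params$nucleus_radius_px
  margin <- r + 6
  if (2 * margin >= min(h, w)) stop("image_shape too small for nucleus radius")

  # non-overlapping placement by rejection sampling, bounded retries
  centers <- matrix(NA_real_, params$n_cells, 2)
  tries <- 0L; max_tries <- 200L * max(1L, params$n_cells)
  i <- 1L
  while (i <= params$n_cells) {
    if (tries >= max_tries)
      stop("could not place ", params$n_cells,
           " non-overlapping nuclei in the given image_shape")
    tries <- tries + 1L
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    if (i == 1L ||
        all((centers[seq_len(i - 1L), 1] - cand[1])^2 +
            (centers[seq_len(i - 1L), 2] - cand[2])^2 > (2 * r + 4)^2)) {
      centers[i, ] <- cand
      i <- i + 1L
    }
  }

  n <- params$n_cells
  stage <- if (n) sample(STAGES, n, replace = TRUE, prob = params$stage_mix[STAGES])
           else character(0)
  frac <- STAGE_DNA_FRAC[stage]
  dapi_total <- (params$dapi_2n_mean +
                 frac * (params$dapi_4n_mean - params$dapi_2n_mean)) *
    exp(rnorm(n, 0, params$dapi_cv))
  s_phase <- stage %in% c("earlyS", "midS", "lateS")
  edu_mean <- ifelse(s_phase, params$edu_pos_mean, params$edu_neg_mean) *
    exp(rnorm(n, 0, params$edu_cv))
  cyc_mean <- ifelse(stage == "G1", params$cyclinA_neg_mean,
                     params$cyclinA_pos_mean) * exp(rnorm(n, 0, params$edu_cv))

  dapi <- matrix(0, h, w); edu <- matrix(0, h, w)
  cyc <- matrix(0, h, w); chanA <- matrix(0, h, w); chanB <- matrix(0, h, w)
  disk_area <- sum(outer((seq(-ceiling(r), ceiling(r)))^2,
                         (seq(-ceiling(r), ceiling(r)))^2, `+`) <= r^2)

  foci <- list(); mn_count <- integer(n)
  n_a <- integer(n); n_b <- integer(n)
  rate <- params$foci_rate_per_stage
  r_inner <- max(1, r - 3 * params$spot_sigma_px)

  rand_in_disk <- function(cy, cx, rad) {
    repeat {
      dy <- runif(1, -rad, rad); dx <- runif(1, -rad, rad)
      if (dy^2 + dx^2 <= rad^2) return(c(cy + dy, cx + dx))
    }
  }

  for (i in seq_len(n)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    dapi <- paint_disk(dapi, cy, cx, r, dapi_total[i] / disk_area)
    edu <- paint_disk(edu, cy, cx, r, edu_mean[i])
    cyc <- paint_disk(cyc, cy, cx, r, cyc_mean[i])

    n_a[i] <- rpois(1, rate[[stage[i]]])
    a_pos <- matrix(NA_real_, n_a[i], 2)
    for (j in seq_len(n_a[i])) {
      a_pos[j, ] <- rand_in_disk(cy, cx, r_inner)
      chanA <- add_gaussian_spot(chanA, a_pos[j, 1], a_pos[j, 2],
                                 params$spot_amplitude, params$spot_sigma_px)
      foci[[length(foci) + 1L]] <-
        data.frame(cell_id = i, channel = "A", y = a_pos[j, 1],
                   x = a_pos[j, 2], colocalized = NA)
    }
    n_b[i] <- rpois(1, rate[[stage[i]]])
    for (j in seq_len(n_b[i])) {
      coloc <- n_a[i] > 0 && runif(1) < params$coloc_fraction
      pos <- if (coloc) a_pos[sample.int(n_a[i], 1), ]
             else rand_in_disk(cy, cx, r_inner)
      chanB <- add_gaussian_spot(chanB, pos[1], pos[2],
                                 params$spot_amplitude, params$spot_sigma_px)
      foci[[length(foci) + 1L]] <-
        data.frame(cell_id = i, channel = "B", y = pos[1], x = pos[2],
                   colocalized = coloc)
    }
    if (runif(1) < params$micronucleus_prob) {
      ang <- runif(1, 0, 2 * pi); dist <- r + runif(1, 5, 10)
      my <- min(h - 4, max(4, cy + dist * sin(ang)))
      mx <- min(w - 4, max(4, cx + dist * cos(ang)))
      dapi <- paint_disk(dapi, my, mx, 2.5, dapi_total[i] / disk_area)
      mn_count[i] <- mn_count[i] + 1L
    }
  }

  if (params$noise_sd > 0) {
    addn <- function(m) {
      m[] <- pmax(0, m + rnorm(h * w, 0, params$noise_sd))
      m
    }
    dapi <- addn(dapi); edu <- addn(edu); cyc <- addn(cyc)
    chanA <- addn(chanA); chanB <- addn(chanB)
  }

  foci_df <- if (length(foci)) do.call(rbind, foci) else
    data.frame(cell_id = integer(0), channel = character(0),
               y = numeric(0), x = numeric(0), colocalized = logical(0))
  # distinct resolvable spots: planted foci closer than ~2 sigma fuse into a
  # single intensity maximum, so the image contains fewer distinct spots
  # than planting events; both are reported as ground truth
  n_resolved <- function(ch) {
    vapply(seq_len(n), function(i) {
      d <- foci_df[foci_df$cell_id == i & foci_df$channel == ch, , drop = FALSE]
      if (nrow(d) < 2) return(nrow(d))
      cl <- stats::cutree(stats::hclust(stats::dist(d[, c("y", "x")]),
                                        method = "single"),
                          h = 2 * params$spot_sigma_px)
      length(unique(cl))
    }, 0L)
  }
  list(images = list(dapi = dapi, edu = edu, cyclinA = cyc,
                     chanA = chanA, chanB = chanB),
       truth = list(
         cells = data.frame(cell_id = seq_len(n), y = centers[, 1],
                            x = centers[, 2], radius = r, stage = stage,
                            dapi_total = dapi_total, edu_mean = edu_mean,
                            n_foci_a = n_a, n_foci_b = n_b,
                            n_spots_a = n_resolved("A"),
                            n_spots_b = n_resolved("B"),
                            n_micronuclei = mn_count,
                            stringsAsFactors = FALSE),
         foci = foci_df))
}

# arbitrary intensity units are stored as value / TIFF_SCALE so that the
# [0, 1] float TIFF convention holds; the power-of-two scale makes the
# round trip exact in 32-bit floats
TIFF_SCALE <- 2^16

#' Write simulated channels as TIFF files
#'
#' One 32-bit float TIFF per channel.  Intensities are divided by a fixed
#' power-of-two scale to fit the `[0, 1]` float TIFF convention;
#' [read_channel_tiff()] restores them exactly.
#'
#' @param images named list of matrices (as returned by [gen_foci_images()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of file paths, invisibly.
#' @export
write_channel_tiffs <- function(images, dir, prefix = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(images), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(images[[ch]] / TIFF_SCALE, p, bits.per.sample = 32L)
    p
  }, character(1))
  invisible(paths)
}

#' Read a channel TIFF written by [write_channel_tiffs()]
#'
#' @param path TIFF file.
#' @return numeric matrix in the original intensity units.
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * TIFF_SCALE
}
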