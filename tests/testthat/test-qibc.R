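make_records <- function(df) {
  df$cell_id <- seq_len(nrow(df))
  df$y <- 0; df$x <- 0; df$area <- 1000
  if (is.null(df$cyclinA_mean)) df$cyclinA_mean <- NA_real_
  df$stage <- NA_character_
  class(df) <- c("cell_records", "data.frame")
  df
}

# Monte-Carlo oracle: recall achievable with the generator's own intensity
# model and ideal (true-parameter) gates; depends only on the stated
# separations and CVs, not on the package's gating code
oracle_stage_recall <- function(dapi_2n = 5000, dapi_4n = 10000,
                                dapi_cv = 0.05, n = 20000, seed = 99) {
  set.seed(seed)
  stages <- c("G1", "earlyS", "midS", "lateS", "G2")
  frac <- c(0, 0.25, 0.5, 0.75, 1)
  truth <- sample(stages, n, replace = TRUE)
  dapi <- (dapi_2n + frac[match(truth, stages)] * (dapi_4n - dapi_2n)) *
    exp(rnorm(n, 0, dapi_cv))
  s <- truth %in% c("earlyS", "midS", "lateS")  # EdU split assumed perfect
  b1 <- dapi_2n + (dapi_4n - dapi_2n) / 3
  b2 <- dapi_2n + 2 * (dapi_4n - dapi_2n) / 3
  mid <- sqrt(dapi_2n * dapi_4n)
  pred <- ifelse(!s, ifelse(dapi <= mid, "G1", "G2"),
                 ifelse(dapi <= b1, "earlyS", ifelse(dapi <= b2, "midS",
                                                     "lateS")))
  vapply(stages, function(st) mean(pred[truth == st] == st), 0)
}

test_that("segmentation separates disjoint disks and rejects blank images", {
  img <- disk_image(c(128, 128), 40, 40, 15) +
    disk_image(c(128, 128), 90, 90, 12)
  m <- segment_nuclei(img, min_area = 100)
  expect_equal(length(m$area), 2)
  expect_equal(sort(m$area), sort(c(sum(disk_image(c(128,128),40,40,15) > 0),
                                    sum(disk_image(c(128,128),90,90,12) > 0))),
               tolerance = 0.05)
  expect_warning(m0 <- segment_nuclei(matrix(0, 32, 32)), "empty mask")
  expect_equal(length(m0$area), 0)
})

test_that("segmentation recovers the planted nucleus count on generator output", {
  p <- image_sim_params(n_cells = 50, seed = 23)
  sim <- gen_foci_images(p)
  m <- segment_nuclei(sim$images$dapi, min_area = 150)
  expect_equal(length(m$area), 50)
})

test_that("gating on a clean two-point DAPI distribution splits G1/G2 perfectly", {
  rec <- make_records(data.frame(
    dapi_integrated = rep(c(5000, 10000), each = 40) * exp(rnorm(80, 0, 0.01)),
    edu_mean = rep(0.2, 80)))
  # all EdU-negative: supply a manual EdU gate above every value
  out <- gate_cell_cycle(rec, thresholds = list(edu = 1))
  expect_equal(out$stage, rep(c("G1", "G2"), each = 40))
})

test_that("per-stage gating recall beats the Monte-Carlo oracle bound", {
  set.seed(31)
  n <- 500
  stages <- c("G1", "earlyS", "midS", "lateS", "G2")
  truth <- sample(stages, n, replace = TRUE)
  frac <- c(0, 0.25, 0.5, 0.75, 1)[match(truth, stages)]
  s <- truth %in% c("earlyS", "midS", "lateS")
  rec <- make_records(data.frame(
    dapi_integrated = (5000 + frac * 5000) * exp(rnorm(n, 0, 0.05)),
    edu_mean = ifelse(s, 2.0, 0.2) * exp(rnorm(n, 0, 0.10))))
  out <- gate_cell_cycle(rec)
  oracle <- oracle_stage_recall()
  for (st in stages) {
    got <- mean(out$stage[truth == st] == st)
    n_st <- sum(truth == st)
    bound <- oracle[[st]] - 3 * sqrt(oracle[[st]] * (1 - oracle[[st]]) / n_st) - 0.05
    expect_gte(got, bound)
  }
  # stage-wise DAPI medians are ordered G1 < S stages < G2
  med <- tapply(rec$dapi_integrated, out$stage, median)
  expect_true(med[["G1"]] < med[["earlyS"]])
  expect_true(med[["earlyS"]] <= med[["midS"]])
  expect_true(med[["midS"]] <= med[["lateS"]])
  expect_true(med[["lateS"]] < med[["G2"]])
})

test_that("Cyclin A gate defines G1 as Cyclin A-negative among EdU-negative cells", {
  set.seed(5)
  n <- 120
  cyc_neg <- rep(c(TRUE, FALSE), each = n / 2)
  rec <- make_records(data.frame(
    dapi_integrated = rep(7000, n) * exp(rnorm(n, 0, 0.05)),  # uninformative
    edu_mean = rep(0.2, n),
    cyclinA_mean = ifelse(cyc_neg, 0.15, 1.5) * exp(rnorm(n, 0, 0.1))))
  out <- gate_cell_cycle(rec, cyclinA_gate = TRUE, thresholds = list(edu = 1))
  expect_equal(out$stage, ifelse(cyc_neg, "G1", "G2"))
  expect_error(gate_cell_cycle(make_records(data.frame(
    dapi_integrated = c(1, 2), edu_mean = c(1, 2))), cyclinA_gate = TRUE,
    thresholds = list(edu = 10)), "Cyclin A")
})

test_that("unimodal DAPI raises a gating error pointing at manual thresholds", {
  rec <- make_records(data.frame(
    dapi_integrated = 5000 * exp(rnorm(100, 0, 0.02)),
    edu_mean = rep(c(0.2, 2), 50)))
  expect_error(gate_cell_cycle(rec), "manual thresholds")
})

test_that("noiseless planted spots are each detected at their centroid", {
  spots <- rbind(c(40, 40), c(52, 44), c(44, 56))
  img <- disk_image(c(96, 96), 48, 48, 20, base = 0, spots = spots,
                    spot_amp = 3, noise_sd = 0)
  dapi <- disk_image(c(96, 96), 48, 48, 20, base = 10)
  m <- segment_nuclei(dapi, min_area = 100)
  f <- detect_foci(img, m, spot_sigma = 1.5, rel_threshold = 5)
  expect_equal(nrow(f), 3)
  for (i in seq_len(3)) {
    d <- sqrt((f$y - spots[i, 1])^2 + (f$x - spots[i, 2])^2)
    expect_lte(min(d), 1)
  }
})

test_that("spots below the relative threshold are not detected; detection is scale-invariant", {
  set.seed(11)
  spots <- rbind(c(40, 40), c(56, 52))
  img <- disk_image(c(96, 96), 48, 48, 20, base = 0, spots = spots,
                    spot_amp = 3, noise_sd = 0.05)
  weak <- disk_image(c(96, 96), 48, 48, 20, base = 0,
                     spots = rbind(c(48, 60)), spot_amp = 0.02, noise_sd = 0)
  img2 <- img + weak
  dapi <- disk_image(c(96, 96), 48, 48, 20, base = 10)
  m <- segment_nuclei(dapi, min_area = 100)
  f <- detect_foci(img2, m, spot_sigma = 1.5, rel_threshold = 5)
  expect_equal(nrow(f), 2)   # the 0.02-amplitude spot is sub-threshold
  f_scaled <- detect_foci(img2 * 37, m, spot_sigma = 1.5, rel_threshold = 5)
  expect_equal(nrow(f_scaled), nrow(f))
  expect_equal(f_scaled[, c("y", "x")], f[, c("y", "x")])
})

test_that("per-stage detected focus means track the planted Poisson means", {
  p <- image_sim_params(n_cells = 80, seed = 37, image_shape = c(640L, 640L))
  sim <- gen_foci_images(p)
  m <- segment_nuclei(sim$images$dapi, min_area = 150)
  f <- detect_foci(sim$images$chanA, m, p$spot_sigma_px, 5)
  counts <- foci_counts(f, length(m$area))
  # match detected nuclei to truth cells by centroid
  tr <- sim$truth$cells
  idx <- vapply(seq_along(m$area), function(i)
    which.min((tr$y - m$centroid[i, 1])^2 + (tr$x - m$centroid[i, 2])^2), 0L)
  for (st in unique(tr$stage[idx])) {
    sel <- tr$stage[idx] == st
    lambda <- p$foci_rate_per_stage[[st]]
    if (sum(sel) < 5) next
    se <- sqrt(lambda / sum(sel))
    expect_lt(abs(mean(counts[sel]) - lambda), max(3 * se, 0.5))
  }
})

test_that("object colocalization classifies overlap and adjacency by distance", {
  mk <- function(pos, cell = 1L) {
    d <- data.frame(cell_id = cell, y = pos[, 1], x = pos[, 2],
                    peak = 1)
    class(d) <- c("foci_set", "data.frame")
    d
  }
  a <- mk(rbind(c(10, 10), c(30, 30)))
  # identical sets: all overlap, none adjacent
  oc <- object_colocalization(a, a, overlap_radius = 3, n_cells = 1)
  expect_equal(oc$n_overlap, 2)
  expect_equal(oc$n_adjacent, 0)
  # distance 1.5 * radius: adjacent
  b <- mk(rbind(c(10, 14.5)))
  oc2 <- object_colocalization(a, b, overlap_radius = 3, n_cells = 1)
  expect_equal(oc2$n_overlap, 0)
  expect_equal(oc2$n_adjacent, 1)
  # beyond 2 * radius: nothing
  c3 <- mk(rbind(c(10, 17)))
  oc3 <- object_colocalization(a, c3, overlap_radius = 3, n_cells = 1)
  expect_equal(oc3$n_overlap + oc3$n_adjacent, 0)
  # symmetry of the overlap count
  set.seed(3)
  pa <- cbind(runif(12, 1, 60), runif(12, 1, 60))
  pb <- cbind(runif(9, 1, 60), runif(9, 1, 60))
  ab <- object_colocalization(mk(pa), mk(pb), 3, 1)
  ba <- object_colocalization(mk(pb), mk(pa), 3, 1)
  expect_equal(ab$n_overlap, ba$n_overlap)
})

test_that("micronuclei are assigned to the nearest nucleus within the search radius", {
  dapi <- disk_image(c(128, 128), 50, 50, 18, base = 10) +
    disk_image(c(128, 128), 50, 78, 4, base = 10)      # satellite nearby
  m <- segment_nuclei(dapi, min_area = 200)
  expect_equal(length(m$area), 1)
  mn <- detect_micronuclei(m, max_mn_area = 80, search_radius = 15)
  expect_equal(mn$micronuclei_count, 1)
  # satellite beyond the search radius is not counted
  far <- disk_image(c(128, 128), 40, 40, 14, base = 10) +
    disk_image(c(128, 128), 110, 110, 4, base = 10)
  m2 <- segment_nuclei(far, min_area = 200)
  mn2 <- detect_micronuclei(m2, max_mn_area = 80, search_radius = 15)
  expect_equal(mn2$micronuclei_count, 0)
})

test_that("planted micronucleus fraction is recovered within a binomial interval", {
  p <- image_sim_params(n_cells = 60, seed = 41, micronucleus_prob = 0.3,
                        image_shape = c(640L, 640L))
  sim <- gen_foci_images(p)
  m <- segment_nuclei(sim$images$dapi, min_area = 150)
  mn <- detect_micronuclei(m, max_mn_area = 80, search_radius = 15)
  frac <- mean(mn$micronuclei_count >= 1)
  planted <- mean(sim$truth$cells$n_micronuclei >= 1)
  ci <- wilson_ci(sum(sim$truth$cells$n_micronuclei >= 1), 60)
  expect_gte(frac, ci[["lower"]] - 0.05)
  expect_lte(frac, ci[["upper"]] + 0.05)
  expect_equal(frac, planted, tolerance = 0.15)
})
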