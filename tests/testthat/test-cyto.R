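test_that("cytogenetics generator matches forced settings and is deterministic", {
  p <- cyto_sim_params(n_spreads_per_group = 30,
                       break_rate = c(a = 0, b = 3),
                       midas_pos_prob = c(a = 0.5, b = 1),
                       locus_break_prob = c(a = 0.1, b = 0.1),
                       n_loci = 50, seed = 3)
  sim <- gen_cyto_counts(p)
  expect_true(all(sim$breaks$breaks_total[sim$breaks$group == "a"] == 0))
  bb <- sim$breaks[sim$breaks$group == "b", ]
  expect_equal(bb$breaks_edu_pos, bb$breaks_total)  # midas prob 1
  expect_identical(gen_cyto_counts(p), sim)
  expect_equal(nrow(sim$breaks), 60)
  expect_equal(rowSums(sim$locus[, c("broken", "intact")]), rep(50, 2))
})

test_that("group summaries reproduce hand-computed mean/SD/SEM", {
  tab <- data.frame(spread_id = paste0("s", 1:5),
                    group = c("g1", "g1", "g1", "g2", "g2"),
                    breaks_total = c(2, 2, 2, 0, 4),
                    breaks_edu_pos = c(1, 1, 1, 0, 2))
  class(tab) <- c("break_table", "data.frame")
  s <- group_summary(tab)
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(0, sqrt(8)))
  expect_equal(s$sem, c(0, 2))
})

test_that("generator group means satisfy the CLT bound", {
  p <- cyto_sim_params(n_spreads_per_group = 400,
                       break_rate = c(x = 2.5, y = 6),
                       midas_pos_prob = c(x = 0.6, y = 0.6),
                       locus_break_prob = c(x = 0.1, y = 0.1), seed = 8)
  s <- group_summary(gen_cyto_counts(p)$breaks)
  expect_lt(abs(s$mean[s$group == "x"] - 2.5), 3 * sqrt(2.5 / 400))
  expect_lt(abs(s$mean[s$group == "y"] - 6), 3 * sqrt(6 / 400))
})

test_that("unpaired t matches closed form and conventions", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_message(r <- unpaired_t(c(2, 2, 2), c(2, 2, 2)), "p = 1")
  expect_equal(r$p, 1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- unpaired_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.001)
  # closed form for the pooled test on these numbers: t = -10/sqrt(2/3)
  pooled <- unpaired_t(c(1, 2, 3), c(11, 12, 13), welch = FALSE)
  expect_equal(pooled$t, -10 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(pooled$df, 4)
})

test_that("unpaired t is invariant to a common affine transform", {
  set.seed(2)
  a <- rnorm(15); b <- rnorm(12, 0.8)
  r1 <- unpaired_t(a, b)
  r2 <- unpaired_t(3 * a + 7, 3 * b + 7)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("t-test type-I error is calibrated at alpha = 0.05", {
  set.seed(1234)
  rej <- mean(replicate(2000, unpaired_t(rnorm(40), rnorm(40))$p <= 0.05))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("chi-square on equal proportions is exactly zero, and matches the Pearson formula", {
  tab <- data.frame(group = c("a", "b"), broken = c(10, 10),
                    intact = c(90, 90))
  class(tab) <- c("locus_contingency", "data.frame")
  r <- chisq_independence(tab)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # unequal table against the hand-evaluated Pearson sum
  m <- rbind(c(20, 80), c(5, 95))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  chi_hand <- sum((m - expected)^2 / expected)
  r2 <- chisq_independence(m)
  expect_equal(r2$chi2, chi_hand, tolerance = 1e-12)
  expect_equal(r2$df, 1)
})

test_that("chi-square on equal generating probabilities is rarely significant", {
  sig <- vapply(1:200, function(s) {
    p <- cyto_sim_params(n_spreads_per_group = 1,
                         break_rate = c(a = 1, b = 1),
                         midas_pos_prob = c(a = 0.5, b = 0.5),
                         locus_break_prob = c(a = 0.12, b = 0.12),
                         n_loci = 150, seed = s)
    chisq_independence(gen_cyto_counts(p)$locus)$p <= 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("MiDAS proportions use the Wilson interval", {
  tab <- data.frame(spread_id = paste0("s", 1:4),
                    group = c("g0", "g0", "g1", "g1"),
                    breaks_total = c(5, 5, 4, 4),
                    breaks_edu_pos = c(0, 0, 4, 4))
  class(tab) <- c("break_table", "data.frame")
  m <- midas_proportions(tab)
  # 0 of 10: Wilson 95% CI approx [0, 0.278]
  g0 <- m[m$group == "g0", ]
  expect_equal(g0$frac_edu_pos, 0)
  expect_equal(g0$ci_upper, 0.278, tolerance = 0.01)
  # all EdU-positive: fraction 1, upper limit 1
  g1 <- m[m$group == "g1", ]
  expect_equal(g1$frac_edu_pos, 1)
  expect_equal(g1$ci_upper, 1)
  # cross-check against prop.test's uncorrected (Wilson score) interval
  pt <- prop.test(0, 10, correct = FALSE)
  expect_equal(unname(wilson_ci(0, 10)[c("lower", "upper")]),
               as.numeric(pt$conf.int), tolerance = 1e-10)
})

test_that("MiDAS estimate covers the generating probability at large n", {
  p <- cyto_sim_params(n_spreads_per_group = 300,
                       break_rate = c(g = 4),
                       midas_pos_prob = c(g = 0.6),
                       locus_break_prob = c(g = 0.1), seed = 12)
  m <- midas_proportions(gen_cyto_counts(p)$breaks)
  expect_gte(0.6, m$ci_lower - 0.02)
  expect_lte(0.6, m$ci_upper + 0.02)
})

test_that("summaries are invariant to row order and p-values lie in (0,1]", {
  p <- cyto_sim_params(seed = 5)
  sim <- gen_cyto_counts(p)
  perm <- sim$breaks[sample(nrow(sim$breaks)), ]
  class(perm) <- c("break_table", "data.frame")
  expect_equal(group_summary(perm), group_summary(sim$breaks))
  r <- chisq_independence(sim$locus)
  expect_gt(r$p, 0)
  expect_lte(r$p, 1)
})
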