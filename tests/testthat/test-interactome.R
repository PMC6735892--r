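test_that("proteinGroups dialect parsing handles flags, sentinels and variants", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c(
    paste("Protein IDs", "Gene names", "Razor + unique peptides",
          "Potential contaminant", "Reverse",
          "Ratio H/M e1", "Ratio H/M normalized e1", "Ratio H/M e2",
          sep = "\t"),
    paste("P1", "AAA", "4", "", "", "2.0", "3.0", "NaN", sep = "\t"),
    paste("CON__P2", "KRT1", "10", "+", "", "1.1", "1.2", "0", sep = "\t"),
    paste("REV__P3", "BBB", "2", "", "+", "0.5", "0.6", "1.9", sep = "\t")),
    tf)
  design <- experiment_design(
    data.frame(id = c("e1", "e2"), has_hm = TRUE, has_hl = FALSE))
  tab <- read_protein_groups(tf, design)
  expect_equal(nrow(tab), 3)
  # normalized column preferred over the raw one
  expect_equal(tab$ratio_hm.e1, c(3.0, 1.2, 0.6))
  # "NaN" and 0 are missing
  expect_true(is.na(tab$ratio_hm.e2[1]))
  expect_true(is.na(tab$ratio_hm.e2[2]))
  expect_equal(tab$is_contaminant, c(FALSE, TRUE, FALSE))
  expect_equal(tab$is_decoy, c(FALSE, FALSE, TRUE))
  # a missing declared experiment is a format error naming the column
  bad <- experiment_design(
    data.frame(id = "e9", has_hm = TRUE, has_hl = FALSE))
  expect_error(read_protein_groups(tf, bad), "Ratio H/M e9")
})

test_that("identification filter keeps multi-peptide non-contaminant groups", {
  tab <- toy_table(hm = matrix(2, 4, 3),
                   peptide_count = c(1L, 2L, 5L, 2L),
                   contaminant = c(FALSE, FALSE, TRUE, FALSE),
                   decoy = c(FALSE, FALSE, FALSE, TRUE))
  kept <- filter_identifications(tab)
  expect_equal(kept$protein_ids, "P002")
  # identity on a clean table
  clean <- toy_table(hm = matrix(2, 3, 3), peptide_count = rep(2L, 3))
  expect_equal(filter_identifications(clean)$protein_ids, clean$protein_ids)
})

test_that("majority rule matches its stated examples and edge cases", {
  expect_equal(majority_pass(c(1.6, 1.4, 1.7), 1.5),
               list(n_quantified = 3L, n_passing = 2L, passes = TRUE))
  # exactly half fails "more than half"
  expect_equal(majority_pass(c(1.6, 1.2), 1.5)$passes, FALSE)
  expect_equal(majority_pass(c(NA, NA), 1.5)$passes, FALSE)
  expect_equal(majority_pass(c(1.5), 1.5)$passes, TRUE)  # >= threshold
})

test_that("majority rule equals exhaustive enumeration over all <=4-experiment patterns", {
  # each experiment is missing, failing (1.2) or passing (1.6): 3^4 patterns
  states <- c(NA, 1.2, 1.6)
  for (n_exp in 1:4) {
    grid <- do.call(expand.grid, rep(list(states), n_exp))
    for (i in seq_len(nrow(grid))) {
      ratios <- as.numeric(grid[i, ])
      expect_identical(majority_pass(ratios, 1.5)[c("n_quantified", "passes")],
                       oracle_majority(ratios, 1.5)[c("n_quantified", "passes")],
                       info = paste(ratios, collapse = ","))
    }
  }
})

test_that("two-tier classification applies both rules and the stated ordering", {
  hm <- rbind(c(8, 8, 8),        # bait: both tiers, ranked first
              c(2, 2, NA),       # tier 1 only (H/L fails)
              c(1.2, 1.1, 1.6),  # identified only
              c(2, 2, 2))        # excluded (decoy)
  hl <- rbind(c(8, 8), c(1.1, 1.0), c(2, 2), c(2, 2))
  tab <- toy_table(hm, hl, decoy = c(FALSE, FALSE, FALSE, TRUE),
                   genes = c("BAIT", "T1", "ID", "DEC"))
  calls <- classify_interactors(tab)
  expect_s3_class(calls, "interactor_calls")
  expect_equal(as.character(calls$tier[calls$gene_names == "BAIT"]),
               "aph_induced")
  expect_equal(as.character(calls$tier[calls$gene_names == "T1"]),
               "potential_interactor")
  expect_equal(as.character(calls$tier[calls$gene_names == "ID"]),
               "identified")
  expect_equal(as.character(calls$tier[calls$gene_names == "DEC"]),
               "excluded")
  expect_equal(calls$gene_names[1], "BAIT")   # highest median log2 H/M first
  expect_false(calls$passed_id_filter[calls$gene_names == "DEC"])
})

test_that("ties in the ranking break lexicographically by gene name", {
  hm <- matrix(2, 3, 3)
  tab <- toy_table(hm, genes = c("ZZZ", "AAA", "MMM"))
  calls <- classify_interactors(tab)
  expect_equal(calls$gene_names, c("AAA", "MMM", "ZZZ"))
  expect_equal(top_n_calls(calls, 0, tier = "potential_interactor")$gene_names,
               character(0))
  expect_equal(
    top_n_calls(calls, 99, tier = "potential_interactor")$gene_names,
    c("AAA", "MMM", "ZZZ"))
  expect_equal(top_n_calls(calls, 2, tier = "potential_interactor")$gene_names,
               c("AAA", "MMM"))
})

test_that("tier membership is nested and invariant to row permutation", {
  sim <- gen_protein_groups(proteomics_sim_params(n_background = 150,
                                                  n_interactors = 40,
                                                  n_aph_responsive = 15,
                                                  seed = 8))
  calls <- classify_interactors(sim$table)
  tr <- as.character(calls$tier)
  # nesting by construction of the factor levels
  expect_true(all(tr[tr == "aph_induced"] != "excluded"))
  cs <- cascade_summary(calls)
  expect_lte(cs[["aph_induced"]], cs[["potential_interactor"]])
  expect_lte(cs[["potential_interactor"]], cs[["identified"]])
  # permuted rows give the same calls
  perm <- sim$table[sample(nrow(sim$table)), , drop = FALSE]
  attr(perm, "design") <- attr(sim$table, "design")
  class(perm) <- class(sim$table)
  calls2 <- classify_interactors(perm)
  expect_equal(calls2$protein_ids, calls$protein_ids)
  expect_equal(calls2$tier, calls$tier)
})

test_that("raising the fold threshold never grows any tier", {
  sim <- gen_protein_groups(proteomics_sim_params(n_background = 150,
                                                  n_interactors = 40,
                                                  n_aph_responsive = 15,
                                                  seed = 9))
  sizes <- sapply(c(1.2, 1.5, 2, 3), function(thr) {
    d <- attr(sim$table, "design"); d$fold_threshold <- thr
    cascade_summary(classify_interactors(sim$table, d))
  })
  expect_true(all(diff(sizes["potential_interactor", ]) <= 0))
  expect_true(all(diff(sizes["aph_induced", ]) <= 0))
})

test_that("deleting a passing ratio never converts a failing protein into a passing one", {
  sim <- gen_protein_groups(proteomics_sim_params(n_background = 60,
                                                  n_interactors = 20,
                                                  n_aph_responsive = 8,
                                                  missing_prob = 0.1,
                                                  seed = 10))
  calls <- classify_interactors(sim$table)
  base_pass <- setNames(calls$tier %in% c("potential_interactor", "aph_induced"),
                        calls$protein_ids)
  tab <- sim$table
  hm <- grep("^ratio_hm", names(tab), value = TRUE)
  set.seed(1)
  for (rep in 1:30) {
    i <- sample(nrow(tab), 1); j <- sample(hm, 1)
    v <- tab[[j]][i]
    if (is.na(v) || v < 1.5) next   # only delete passing ratios
    mod <- tab; mod[[j]][i] <- NA
    attr(mod, "design") <- attr(tab, "design"); class(mod) <- class(tab)
    mcalls <- classify_interactors(mod)
    mpass <- setNames(mcalls$tier %in% c("potential_interactor", "aph_induced"),
                      mcalls$protein_ids)
    pid <- tab$protein_ids[i]
    if (!base_pass[pid]) expect_false(mpass[pid])
  }
})

test_that("design/table mismatch is a configuration error", {
  tab <- toy_table(hm = matrix(2, 2, 2))
  other <- toy_design(n_hm = 4, n_hl = 0)
  expect_error(classify_interactors(tab, other), "missing column")
})
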