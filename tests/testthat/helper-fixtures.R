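# Shared builders for small in-code fixtures.

toy_design <- function(n_hm = 3, n_hl = 2, fold = 1.5) {
  ids <- sprintf("e%d", seq_len(n_hm))
  experiment_design(
    data.frame(id = ids, has_hm = TRUE,
               has_hl = seq_len(n_hm) > (n_hm - n_hl)),
    fold_threshold = fold)
}

# hand-built protein_group_table; hm/hl are matrices (rows = proteins)
toy_table <- function(hm, hl = NULL, peptide_count = NULL,
                      contaminant = NULL, decoy = NULL, genes = NULL,
                      design = NULL) {
  hm <- as.matrix(hm)
  n <- nrow(hm)
  n_hl <- if (is.null(hl)) 0 else ncol(as.matrix(hl))
  design <- design %||% toy_design(ncol(hm), n_hl)
  tab <- data.frame(stringsAsFactors = FALSE,
    protein_ids = sprintf("P%03d", seq_len(n)),
    gene_names = genes %||% sprintf("G%03d", seq_len(n)),
    peptide_count = peptide_count %||% rep(3L, n),
    is_contaminant = contaminant %||% rep(FALSE, n),
    is_decoy = decoy %||% rep(FALSE, n))
  hm_ids <- design$experiments$id[design$experiments$has_hm]
  for (j in seq_len(ncol(hm))) tab[[paste0("ratio_hm.", hm_ids[j])]] <- hm[, j]
  if (n_hl > 0) {
    hl <- as.matrix(hl)
    hl_ids <- design$experiments$id[design$experiments$has_hl]
    for (j in seq_len(ncol(hl))) tab[[paste0("ratio_hl.", hl_ids[j])]] <- hl[, j]
  }
  attr(tab, "design") <- design
  class(tab) <- c("protein_group_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one synthetic disk image with optional Gaussian spots
disk_image <- function(shape = c(96, 96), cy = 48, cx = 48, r = 18,
                       base = 10, spots = NULL, spot_amp = 3,
                       spot_sigma = 1.5, noise_sd = 0) {
  img <- matrix(0, shape[1], shape[2])
  yy <- row(img); xx <- col(img)
  img[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- base
  if (!is.null(spots)) {
    for (i in seq_len(nrow(spots))) {
      d2 <- (yy - spots[i, 1])^2 + (xx - spots[i, 2])^2
      img <- img + spot_amp * exp(-d2 / (2 * spot_sigma^2))
    }
  }
  if (noise_sd > 0) img[] <- pmax(0, img + rnorm(length(img), 0, noise_sd))
  img
}

# brute-force majority rule over an explicit ratio vector
oracle_majority <- function(ratios, threshold) {
  q <- ratios[!is.na(ratios)]
  list(n_quantified = length(q), n_passing = sum(q >= threshold),
       passes = length(q) >= 1 && sum(q >= threshold) * 2 > length(q))
}

# brute-force hypergeometric upper tail by enumerating all draws
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # treat items 1..K as successes
  mean(hits >= k)
}
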