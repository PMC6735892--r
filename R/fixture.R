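#' Synthetic protein-group table matching the published filtering margins
#'
#' Builds, by construction, a protein-group table whose filtering cascade
#' margins equal those of the original screen: 894 protein groups of which
#' 229 are single-peptide identifications, leaving 665 multi-peptide groups;
#' 226 of those clear the 1.5-fold bait-versus-IgG majority rule and 45 of
#' the 226 additionally clear the stress-versus-untreated (H/L) rule.  Which
#' experiments are quantified, and the exact ratio values, are randomized
#' under the seed, but every row's pass/fail pattern is constrained so the
#' margins hold exactly.  The bait and its constitutive partner are planted
#' as the most enriched stress-induced calls.
#'
#' @param seed integer seed.
#' @param n_total,n_single_peptide,n_tier1,n_tier2 cascade margins; defaults
#'   are the published ones (894 / 229 / 226 / 45).
#' @param fold_threshold enrichment threshold, default 1.5.
#' @return list with `table` (a `protein_group_table` under the three-run
#'   [default_design()]) and `truth` (per-row intended tier).
#' @export
simulate_cascade_fixture <- function(seed = 1L, n_total = 894L,
                                     n_single_peptide = 229L,
                                     n_tier1 = 226L, n_tier2 = 45L,
                                     fold_threshold = 1.5) {
  stopifnot(n_single_peptide < n_total,
            n_tier1 <= n_total - n_single_peptide, n_tier2 <= n_tier1)
  set.seed(seed)
  design <- default_design(fold_threshold)
  n_multi <- n_total - n_single_peptide
  tiers <- c(rep("aph_induced", n_tier2),
             rep("potential_interactor", n_tier1 - n_tier2),
             rep("identified", n_multi - n_tier1),
             rep("excluded", n_single_peptide))
  tiers <- sample(tiers)

  bait_genes <- c("FANCD2", "FANCI", "ATRX", "BLM", "BRCA1")
  genes <- sprintf("GENE%04d", seq_len(n_total))
  aph_rows <- which(tiers == "aph_induced")
  genes[aph_rows[seq_along(bait_genes)]] <- bait_genes

  thr <- fold_threshold
  pass_val <- function(k) thr * 2^runif(k, 0.2, 2.0)
  fail_val <- function(k) thr * 2^runif(k, -1.5, -0.05)

  fill_channel <- function(n_exp, want_pass) {
    # quantified pattern with the majority-rule outcome forced
    vals <- rep(NA_real_, n_exp)
    q <- which(runif(n_exp) < 0.85)
    if (want_pass && !length(q)) q <- sample.int(n_exp, 1)
    nq <- length(q)
    if (!nq) return(vals)
    pick1 <- function(v) v[sample.int(length(v), 1)]
    np <- if (want_pass) pick1(seq(floor(nq / 2) + 1, nq))
          else pick1(seq(0, floor(nq / 2)))
    pass_idx <- if (np) q[sample.int(nq, np)] else integer(0)
    vals[pass_idx] <- pass_val(length(pass_idx))
    vals[setdiff(q, pass_idx)] <- fail_val(nq - np)
    vals
  }

  n_hm <- sum(design$experiments$has_hm)
  n_hl <- sum(design$experiments$has_hl)
  hm <- matrix(NA_real_, n_total, n_hm)
  hl <- matrix(NA_real_, n_total, n_hl)
  for (i in seq_len(n_total)) {
    t1 <- tiers[i] %in% c("potential_interactor", "aph_induced")
    hm[i, ] <- fill_channel(n_hm, t1)
    hl[i, ] <- fill_channel(n_hl, tiers[i] == "aph_induced")
  }
  # bait and partner: strongly enriched everywhere, ranked first
  hm[aph_rows[1], ] <- 9; hl[aph_rows[1], ] <- 9
  hm[aph_rows[2], ] <- 8; hl[aph_rows[2], ] <- 8

  tab <- data.frame(stringsAsFactors = FALSE,
    protein_ids = sprintf("P%05d", seq_len(n_total)),
    gene_names = genes,
    peptide_count = ifelse(tiers == "excluded", 1L, 2L + rpois(n_total, 5)),
    is_contaminant = FALSE, is_decoy = FALSE)
  hm_ids <- design$experiments$id[design$experiments$has_hm]
  hl_ids <- design$experiments$id[design$experiments$has_hl]
  for (j in seq_len(n_hm)) tab[[paste0("ratio_hm.", hm_ids[j])]] <- hm[, j]
  for (j in seq_len(n_hl)) tab[[paste0("ratio_hl.", hl_ids[j])]] <- hl[, j]
  attr(tab, "design") <- design
  class(tab) <- c("protein_group_table", "data.frame")
  list(table = tab,
       truth = data.frame(protein_ids = tab$protein_ids, gene_names = genes,
                          tier = tiers, stringsAsFactors = FALSE))
}

#' Synthetic gene-to-term annotations enriched in a target gene set
#'
#' Builds a small annotation table in which DNA-repair-like terms
#' preferentially cover the supplied target genes, plus uninformative random
#' terms, for exercising [hypergeom_enrichment()] on data with known signal.
#'
#' @param universe all gene symbols.
#' @param target genes the informative terms should favour.
#' @param seed integer seed.
#' @return annotation data frame (`term_id`, `term_name`, `gene`).
#' @export
synth_annotations <- function(universe, target, seed = 1L) {
  set.seed(seed)
  universe <- unique(toupper(universe)); target <- unique(toupper(target))
  pick <- function(pool, frac) pool[runif(length(pool)) < frac]
  mk <- function(id, name, genes) {
    if (!length(genes)) return(NULL)
    data.frame(term_id = id, term_name = name, gene = genes,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    mk("T:DNA_REPAIR", "DNA repair",
       unique(c(pick(target, 0.6), pick(universe, 0.05)))),
    mk("T:CHROM_ORG", "chromosome organization",
       unique(c(pick(target, 0.4), pick(universe, 0.08)))),
    mk("T:REPLICATION", "DNA replication",
       unique(c(pick(target, 0.3), pick(universe, 0.05)))))
  for (k in 1:4)
    out <- rbind(out, mk(sprintf("T:RAND%d", k), sprintf("random term %d", k),
                         pick(universe, 0.10)))
  out
}

#' Synthetic functional-association edge table
#'
#' Dense high-confidence edges among the target genes, sparse low-confidence
#' edges elsewhere, for exercising [build_network()].
#'
#' @param universe all gene symbols.
#' @param target genes forming the dense module.
#' @param seed integer seed.
#' @return edge data frame (`geneA`, `geneB`, `score`).
#' @export
synth_edges <- function(universe, target, seed = 1L) {
  set.seed(seed)
  universe <- unique(toupper(universe)); target <- unique(toupper(target))
  edges <- list()
  if (length(target) >= 2) {
    pairs <- t(utils::combn(target, 2))
    keep <- runif(nrow(pairs)) < 0.12
    if (any(keep))
      edges[[1]] <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                               score = round(runif(sum(keep), 0.4, 0.99), 3),
                               stringsAsFactors = FALSE)
  }
  other <- setdiff(universe, target)
  if (length(other) >= 2) {
    m <- min(200L, length(other))
    a <- sample(other, m, replace = TRUE); b <- sample(other, m, replace = TRUE)
    ok <- a != b
    edges[[2]] <- data.frame(geneA = a[ok], geneB = b[ok],
                             score = round(runif(sum(ok), 0.05, 0.6), 3),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  out[!duplicated(out[, 1:2]), , drop = FALSE]
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates and writes every file the end-to-end pipeline consumes:
#' a protein-group table at the published cascade margins, annotation and
#' edge tables, vehicle- and stress-condition imaging fields (five channels
#' each, 32-bit TIFF), metaphase break and locus-breakage tables, truth
#' labels, and a ready-to-run YAML configuration.
#'
#' @param dir output directory (created).
#' @param seed master seed; per-modality seeds are derived with
#'   [derive_seed()].
#' @param n_cells nuclei per imaging field.
#' @param image_shape imaging field size, px.
#' @return path to the written `config.yaml`, invisibly.
#' @export
make_fixture <- function(dir, seed = 1L, n_cells = 25,
                         image_shape = c(320L, 320L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- simulate_cascade_fixture(seed = derive_seed(seed, 1))
  pg_path <- file.path(dir, "proteinGroups.txt")
  write_protein_groups(fx$table, pg_path)
  write.table(fx$truth, file.path(dir, "truth_proteins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  target <- fx$truth$gene_names[fx$truth$tier %in%
                                  c("potential_interactor", "aph_induced")]
  ann <- synth_annotations(fx$truth$gene_names, target,
                           seed = derive_seed(seed, 2))
  write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  edges <- synth_edges(fx$truth$gene_names, target,
                       seed = derive_seed(seed, 3))
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  conds <- list(
    vehicle = image_sim_params(n_cells = n_cells, image_shape = image_shape,
                               seed = derive_seed(seed, 4)),
    aph = image_sim_params(n_cells = n_cells, image_shape = image_shape,
                           foci_rate_per_stage = c(G1 = 2, earlyS = 4,
                                                   midS = 6, lateS = 10,
                                                   G2 = 8),
                           coloc_fraction = 0.4,
                           micronucleus_prob = 0.15,
                           seed = derive_seed(seed, 5)))
  img_dir <- file.path(dir, "images")
  truth_cells <- list()
  for (cond in names(conds)) {
    sim <- gen_foci_images(conds[[cond]])
    write_channel_tiffs(sim$images, img_dir, prefix = cond)
    tc <- sim$truth$cells; tc$condition <- cond
    truth_cells[[cond]] <- tc
  }
  write.table(do.call(rbind, truth_cells), file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cyto <- gen_cyto_counts(cyto_sim_params(seed = derive_seed(seed, 6)))
  utils::write.csv(cyto$breaks, file.path(dir, "breaks.csv"),
                   row.names = FALSE)
  utils::write.csv(cyto$locus, file.path(dir, "locus.csv"), row.names = FALSE)
  write.table(cyto$truth, file.path(dir, "truth_cyto.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  design <- attr(fx$table, "design")
  cfg <- list(
    seed = as.integer(seed),
    outdir = file.path(dir, "out"),
    design = list(
      fold_threshold = design$fold_threshold,
      experiments = lapply(seq_len(nrow(design$experiments)),
                           function(i) as.list(design$experiments[i, ]))))
  cfg$paths <- list(protein_groups = pg_path,
                    annotations = file.path(dir, "annotations.tsv"),
                    edges = file.path(dir, "edges.tsv"),
                    images_dir = img_dir,
                    breaks = file.path(dir, "breaks.csv"),
                    locus = file.path(dir, "locus.csv"))
  cfg$imaging <- list(conditions = names(conds),
                      spot_sigma = conds$vehicle$spot_sigma_px,
                      min_area = 150, n_rand = 200)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
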