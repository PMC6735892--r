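#' Parameters for the synthetic ChIP-MS protein-group generator
#'
#' Encodes the statistical structure the downstream filtering cascade
#' assumes: a background population whose log2 bait/IgG (H/M) ratios are
#' centred at zero, a set of spiked interactors centred at a stated log2
#' effect, and a subset of those interactors additionally enriched on the
#' H/L channel (stress-treated versus untreated cells).  Ratio noise is
#' log-normal (Normal on the log2 scale) and each per-experiment ratio is
#' independently missing completely at random.
#'
#' @param n_background number of background (non-interacting) protein groups.
#' @param n_interactors number of true bait-associated protein groups.
#' @param n_aph_responsive number of interactors also recruited under
#'   replication stress (must not exceed `n_interactors`).
#' @param log2_effect_bait_vs_igg mean log2(H/M) of interactors; default 1.5.
#' @param log2_effect_aph_vs_untreated mean log2(H/L) of stress-responsive
#'   interactors; default 1.5.
#' @param ratio_noise_sd standard deviation of log2 ratios; default 0.3.
#' @param n_experiments_hm,n_experiments_hl number of experiments carrying the
#'   H/M and H/L channels.  The first `n_experiments_hm - n_experiments_hl`
#'   experiments are H/M-only (the "pilot"-like runs); requires
#'   `n_experiments_hl <= n_experiments_hm`.
#' @param missing_prob probability that any one per-experiment ratio is
#'   unquantified.
#' @param single_peptide_frac fraction of rows supported by a single peptide
#'   (these fail the identification filter).
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical tables.
#' @return an object of class `proteomics_sim_params`.
#' @seealso [gen_protein_groups()]
#' @export
proteomics_sim_params <- function(n_background = 600,
                                  n_interactors = 80,
                                  n_aph_responsive = 20,
                                  log2_effect_bait_vs_igg = 1.5,
                                  log2_effect_aph_vs_untreated = 1.5,
                                  ratio_noise_sd = 0.3,
                                  n_experiments_hm = 3,
                                  n_experiments_hl = 2,
                                  missing_prob = 0.2,
                                  single_peptide_frac = 0.25,
                                  seed = 1L) {
  p <- list(n_background = n_background, n_interactors = n_interactors,
            n_aph_responsive = n_aph_responsive,
            log2_effect_bait_vs_igg = log2_effect_bait_vs_igg,
            log2_effect_aph_vs_untreated = log2_effect_aph_vs_untreated,
            ratio_noise_sd = ratio_noise_sd,
            n_experiments_hm = n_experiments_hm,
            n_experiments_hl = n_experiments_hl,
            missing_prob = missing_prob,
            single_peptide_frac = single_peptide_frac,
            seed = as.integer(seed))
  if (!is_count(p$n_background) || !is_count(p$n_interactors) ||
      !is_count(p$n_aph_responsive))
    stop("population sizes must be non-negative integers")
  if (p$n_aph_responsive > p$n_interactors)
    stop("n_aph_responsive must not exceed n_interactors")
  if (!is_prob(p$missing_prob) || !is_prob(p$single_peptide_frac))
    stop("missing_prob and single_peptide_frac must lie in [0, 1]")
  if (!is_count(p$n_experiments_hm) || !is_count(p$n_experiments_hl) ||
      p$n_experiments_hm < 1 || p$n_experiments_hl > p$n_experiments_hm)
    stop("need 1 <= n_experiments_hl <= n_experiments_hm (hl <= hm)")
  if (p$ratio_noise_sd < 0) stop("ratio_noise_sd must be >= 0")
  structure(p, class = "proteomics_sim_params")
}

sim_design <- function(params, fold_threshold = 1.5) {
  n_hm <- params$n_experiments_hm
  n_hl <- params$n_experiments_hl
  ids <- sprintf("exp%d", seq_len(n_hm))
  experiment_design(
    data.frame(id = ids, has_hm = TRUE,
               has_hl = seq_len(n_hm) > (n_hm - n_hl)),
    fold_threshold = fold_threshold)
}

#' Generate a synthetic SILAC protein-group table with ground truth
#'
#' Draws one protein-group quantification table from the model described in
#' [proteomics_sim_params()].  Background rows have log2(H/M) ~
#' Normal(0, sd); interactors Normal(effect, sd).  On the H/L channel,
#' stress-responsive interactors are Normal(effect_hl, sd) and everything
#' else Normal(0, sd).  Each per-experiment ratio is independently missing
#' with `missing_prob`; a `single_peptide_frac` fraction of rows receive a
#' peptide count of 1 (all classes equally affected).
#'
#' @param params a [proteomics_sim_params()] object.
#' @return a list with elements
#'   \describe{
#'     \item{table}{a `protein_group_table`: data frame with columns
#'       `protein_ids`, `gene_names`, `peptide_count`, `is_contaminant`,
#'       `is_decoy` and one `ratio_hm.<exp>` / `ratio_hl.<exp>` column per
#'       channel, with the generating `experiment_design` attached as
#'       attribute `design`.}
#'     \item{truth}{data frame with `protein_ids`, `gene_names` and `class`
#'       (one of `background`, `interactor`, `aph_responsive`), one row per
#'       generated protein group.}
#'   }
#' @examples
#' sim <- gen_protein_groups(proteomics_sim_params(n_background = 50,
#'                                                 n_interactors = 10,
#'                                                 n_aph_responsive = 4,
#'                                                 seed = 7))
#' table(sim$truth$class)
#' @export
gen_protein_groups <- function(params) {
  stopifnot(inherits(params, "proteomics_sim_params"))
  set.seed(params$seed)
  n <- params$n_background + params$n_interactors
  cls <- c(rep("background", params$n_background),
           rep("interactor", params$n_interactors - params$n_aph_responsive),
           rep("aph_responsive", params$n_aph_responsive))
  design <- sim_design(params)
  ids <- sprintf("P%05d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(n))

  tab <- data.frame(protein_ids = ids, gene_names = genes,
                    peptide_count = NA_integer_,
                    is_contaminant = FALSE, is_decoy = FALSE,
                    stringsAsFactors = FALSE)
  n_single <- round(params$single_peptide_frac * n)
  single <- rep(FALSE, n)
  if (n_single > 0) single[sample.int(n, n_single)] <- TRUE
  tab$peptide_count <- ifelse(single, 1L, 2L + rpois(n, 4))

  mu_hm <- ifelse(cls == "background", 0, params$log2_effect_bait_vs_igg)
  mu_hl <- ifelse(cls == "aph_responsive",
                  params$log2_effect_aph_vs_untreated, 0)
  sdr <- params$ratio_noise_sd
  for (e in design$experiments$id) {
    r <- 2^rnorm(n, mu_hm, sdr)
    r[runif(n) < params$missing_prob] <- NA_real_
    tab[[paste0("ratio_hm.", e)]] <- r
  }
  for (e in design$experiments$id[design$experiments$has_hl]) {
    r <- 2^rnorm(n, mu_hl, sdr)
    r[runif(n) < params$missing_prob] <- NA_real_
    tab[[paste0("ratio_hl.", e)]] <- r
  }
  attr(tab, "design") <- design
  class(tab) <- c("protein_group_table", "data.frame")
  list(table = tab,
       truth = data.frame(protein_ids = ids, gene_names = genes, class = cls,
                          stringsAsFactors = FALSE))
}

#' Write a protein-group table in the MaxQuant proteinGroups.txt dialect
#'
#' Emits the tab-delimited column layout consumed by
#' [read_protein_groups()]: "Protein IDs", "Gene names",
#' "Razor + unique peptides", "Potential contaminant", "Reverse" and one
#' "Ratio H/M normalized <exp>" / "Ratio H/L normalized <exp>" column per
#' channel.  Missing ratios are written as "NaN", matching MaxQuant output.
#'
#' @param table a `protein_group_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  stopifnot(inherits(table, "protein_group_table"))
  design <- attr(table, "design")
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = table$protein_ids,
    `Gene names` = table$gene_names,
    `Razor + unique peptides` = table$peptide_count,
    `Potential contaminant` = ifelse(table$is_contaminant, "+", ""),
    `Reverse` = ifelse(table$is_decoy, "+", ""))
  for (e in design$experiments$id[design$experiments$has_hm])
    out[[paste("Ratio H/M normalized", e)]] <- table[[paste0("ratio_hm.", e)]]
  for (e in design$experiments$id[design$experiments$has_hl])
    out[[paste("Ratio H/L normalized", e)]] <- table[[paste0("ratio_hl.", e)]]
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "NaN", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
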