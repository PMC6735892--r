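#' Read a MaxQuant-style proteinGroups.txt table
#'
#' Parses the tab-delimited protein-group dialect: one row per protein group
#' with identification metadata and per-experiment SILAC ratio columns.
#' Ratio columns are matched case-insensitively against the patterns
#' `"Ratio H/M <exp>"` and `"Ratio H/L <exp>"`; when both a raw and a
#' `"... normalized <exp>"` variant exist, the normalized column is used
#' (MaxQuant's normalized ratios correct for channel loading).  Contaminant
#' and decoy rows are recognized either by `"+"` flags in the
#' "Potential contaminant" / "Reverse" columns or by `CON__` / `REV__`
#' accession prefixes.  Unparseable ratio cells and the sentinels `"NaN"`,
#' empty string and `0` become missing values.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param design an [experiment_design()] declaring the expected experiments
#'   and channels.
#' @return a `protein_group_table` (row count equal to the file's data rows)
#'   with the design attached as attribute `design`.
#' @export
read_protein_groups <- function(path, design) {
  stopifnot(inherits(design, "experiment_design"))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2 || nrow(raw) == 0)
    stop("protein-group file has no header or no data rows: ", path)
  norm_name <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  cols <- norm_name(names(raw))

  find_col <- function(candidates) {
    hit <- match(norm_name(candidates), cols)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }
  ratio_col <- function(channel, exp_id) {
    # normalized variant preferred over raw
    find_col(c(sprintf("ratio %s normalized %s", channel, exp_id),
               sprintf("ratio %s %s", channel, exp_id)))
  }
  parse_ratio <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    v[!is.finite(v) | v <= 0] <- NA_real_
    v
  }

  id_col <- find_col(c("protein ids", "majority protein ids"))
  if (is.na(id_col)) stop("no 'Protein IDs' column found in ", path)
  gene_col <- find_col(c("gene names"))
  pep_col <- find_col(c("razor + unique peptides", "peptides"))
  con_col <- find_col(c("potential contaminant", "contaminant"))
  rev_col <- find_col(c("reverse"))

  ids <- raw[[id_col]]
  tab <- data.frame(stringsAsFactors = FALSE,
    protein_ids = ids,
    gene_names = if (!is.na(gene_col)) raw[[gene_col]] else "",
    peptide_count = if (!is.na(pep_col))
      pmax(1L, suppressWarnings(as.integer(raw[[pep_col]]))) else 1L,
    is_contaminant = grepl("(^|;)CON__", ids) |
      (!is.na(con_col) & raw[[con_col]] == "+"),
    is_decoy = grepl("(^|;)REV__", ids) |
      (!is.na(rev_col) & raw[[rev_col]] == "+"))
  tab$peptide_count[is.na(tab$peptide_count)] <- 1L

  for (i in seq_len(nrow(design$experiments))) {
    e <- design$experiments[i, ]
    if (e$has_hm) {
      j <- ratio_col("h/m", e$id)
      if (is.na(j))
        stop(sprintf("no 'Ratio H/M %s' column found in %s", e$id, path))
      tab[[paste0("ratio_hm.", e$id)]] <- parse_ratio(raw[[j]])
    }
    if (e$has_hl) {
      j <- ratio_col("h/l", e$id)
      if (is.na(j))
        stop(sprintf("no 'Ratio H/L %s' column found in %s", e$id, path))
      tab[[paste0("ratio_hl.", e$id)]] <- parse_ratio(raw[[j]])
    }
  }
  attr(tab, "design") <- design
  class(tab) <- c("protein_group_table", "data.frame")
  tab
}

#' Identification filter: multi-peptide, non-contaminant, non-decoy groups
#'
#' Retains protein groups identified with at least two peptides that are
#' neither common contaminants nor decoy (reversed-database) hits.  Row
#' order is preserved; an empty result is allowed.
#'
#' @param table a `protein_group_table`.
#' @return the filtered `protein_group_table`.
#' @export
filter_identifications <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  keep <- table$peptide_count >= 2 & !table$is_contaminant & !table$is_decoy
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- attr(table, "design")
  class(out) <- class(table)
  out
}

#' Majority enrichment rule over the experiments in which a protein was quantified
#'
#' A protein passes when it is enriched at least `threshold`-fold in strictly
#' more than half of the experiments in which the ratio was quantified
#' (missing ratios do not count toward the denominator).  One passing
#' experiment out of one passes; one out of two — exactly half — fails.  A
#' protein with no quantified ratio never passes.
#'
#' @param ratios numeric vector of per-experiment fold changes, `NA` for
#'   unquantified experiments.
#' @param threshold fold-change threshold (> 1); the comparison is
#'   `ratio >= threshold`.
#' @return list with `n_quantified`, `n_passing` and logical `passes`.
#' @examples
#' majority_pass(c(1.6, 1.4, 1.7), 1.5)  # 2 of 3 -> passes
#' majority_pass(c(1.6, 1.2), 1.5)       # 1 of 2 -> fails
#' @export
majority_pass <- function(ratios, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 1)
  ratios <- as.numeric(ratios)
  n_quantified <- sum(!is.na(ratios))
  n_passing <- sum(ratios >= threshold, na.rm = TRUE)
  list(n_quantified = n_quantified, n_passing = n_passing,
       passes = n_quantified >= 1L && n_passing > n_quantified / 2)
}

#' Two-tier classification of candidate fragile-site interactors
#'
#' Applies the filtering cascade to a protein-group table.  Rows failing the
#' identification filter (single peptide, contaminant or decoy) are tier
#' `excluded`.  Remaining rows are tier `identified`; those enriched at
#' least `fold_threshold`-fold over the IgG control (H/M channel) in a
#' majority of quantified experiments are promoted to `potential_interactor`;
#' those additionally enriched on the H/L channel (stress-treated versus
#' untreated cells, evaluated only over experiments carrying an H/L channel)
#' become `aph_induced`.
#'
#' @param table a `protein_group_table` (filtering is applied internally;
#'   pre-filtered input is also accepted).
#' @param design an [experiment_design()]; defaults to the design attached to
#'   `table`.  Its experiments must match the table's ratio columns.
#' @return an `interactor_calls` data frame, one row per input protein group,
#'   sorted by `median_log2_hm` decreasing with ties broken by gene name
#'   (rows without a quantified H/M ratio sort last).  Columns:
#'   `protein_ids`, `gene_names`, `passed_id_filter`, `n_quantified_hm`,
#'   `n_passing_hm`, `n_quantified_hl`, `n_passing_hl`, `median_log2_hm`,
#'   `median_log2_hl`, `tier`.
#' @export
classify_interactors <- function(table, design = attr(table, "design")) {
  stopifnot(inherits(table, "protein_group_table"),
            inherits(design, "experiment_design"))
  hm <- hm_cols(design); hl <- hl_cols(design)
  missing_cols <- setdiff(c(hm, hl), names(table))
  if (length(missing_cols))
    stop("design does not match table: missing column(s) ",
         paste(missing_cols, collapse = ", "))

  n <- nrow(table)
  hm_mat <- as.matrix(table[, hm, drop = FALSE])
  hl_mat <- if (length(hl)) as.matrix(table[, hl, drop = FALSE]) else
    matrix(NA_real_, n, 0)

  passed <- table$peptide_count >= 2 & !table$is_contaminant & !table$is_decoy
  thr <- design$fold_threshold

  row_majority <- function(mat) {
    nq <- rowSums(!is.na(mat))
    np <- rowSums(mat >= thr, na.rm = TRUE)
    list(nq = nq, np = np, pass = nq >= 1L & np > nq / 2)
  }
  m_hm <- row_majority(hm_mat)
  m_hl <- row_majority(hl_mat)
  med <- function(mat) apply(mat, 1, function(r)
    if (all(is.na(r))) NA_real_ else median(log2(r), na.rm = TRUE))

  tier <- rep("excluded", n)
  tier[passed] <- "identified"
  tier[passed & m_hm$pass] <- "potential_interactor"
  tier[passed & m_hm$pass & m_hl$pass] <- "aph_induced"

  calls <- data.frame(stringsAsFactors = FALSE,
    protein_ids = table$protein_ids,
    gene_names = table$gene_names,
    passed_id_filter = passed,
    n_quantified_hm = m_hm$nq, n_passing_hm = m_hm$np,
    n_quantified_hl = m_hl$nq, n_passing_hl = m_hl$np,
    median_log2_hm = if (n) med(hm_mat) else numeric(0),
    median_log2_hl = if (n && ncol(hl_mat)) med(hl_mat) else rep(NA_real_, n),
    tier = factor(tier, levels = c("excluded", "identified",
                                   "potential_interactor", "aph_induced")))
  ord <- order(-xtfrm(calls$median_log2_hm), calls$gene_names,
               na.last = TRUE)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("interactor_calls", "data.frame")
  calls
}

#' Top-ranked calls of a tier
#'
#' Returns the first `n` calls of the requested tier under the ranking used
#' by [classify_interactors()] (median log2 H/M decreasing, gene-name
#' tie-break).  Requesting more calls than exist returns all of them.
#'
#' @param calls an `interactor_calls` data frame.
#' @param n number of calls to return.
#' @param tier which tier to rank, default `"aph_induced"`.
#' @return the subset of `calls`.
#' @export
top_n_calls <- function(calls, n, tier = "aph_induced") {
  stopifnot(inherits(calls, "interactor_calls"), is_count(n))
  sub <- calls[calls$tier == tier, , drop = FALSE]
  out <- head(sub, n)
  rownames(out) <- NULL
  out
}

#' Write interactor calls as tab-delimited text
#'
#' @param calls an `interactor_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactor_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tier sizes of a classified table
#'
#' Convenience summary of the filtering cascade: how many protein groups
#' survived identification filtering and how many fall in each enrichment
#' tier (tiers are nested: stress-induced calls are also potential
#' interactors, which are also identified).
#'
#' @param calls an `interactor_calls` data frame.
#' @return named integer vector with `total`, `identified` (passed the
#'   identification filter), `potential_interactor` and `aph_induced`
#'   (cumulative tier memberships).
#' @export
cascade_summary <- function(calls) {
  stopifnot(inherits(calls, "interactor_calls"))
  tr <- as.character(calls$tier)
  c(total = nrow(calls),
    identified = sum(tr != "excluded"),
    potential_interactor = sum(tr %in% c("potential_interactor", "aph_induced")),
    aph_induced = sum(tr == "aph_induced"))
}
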