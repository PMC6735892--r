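#' Read gene-to-term annotations
#'
#' Accepts either a two/three-column tab-delimited file (`gene`, `term_id`
#' and optionally `term_name`) or a GMT file (`term_id`, description, then
#' member genes).  Gene symbols are uppercased.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gmt"`; `"auto"` picks GMT for `.gmt` files.
#' @return data frame with columns `term_id`, `term_name`, `gene` (long
#'   format, one row per gene-term pair).
#' @export
read_term_annotations <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    recs <- lapply(strsplit(lines, "\t"), function(f) {
      if (length(f) < 3) return(NULL)
      data.frame(term_id = f[1], term_name = f[2],
                 gene = toupper(f[-(1:2)]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE)
    nm <- tolower(names(raw))
    gene_col <- which(nm %in% c("gene", "genes", "symbol"))[1]
    term_col <- which(nm %in% c("term", "term_id", "go", "go_id"))[1]
    if (is.na(gene_col) || is.na(term_col))
      stop("annotation file needs 'gene' and 'term_id' columns: ", path)
    name_col <- which(nm %in% c("term_name", "name", "description"))[1]
    out <- data.frame(term_id = raw[[term_col]],
                      term_name = if (!is.na(name_col)) raw[[name_col]]
                                  else raw[[term_col]],
                      gene = toupper(raw[[gene_col]]), stringsAsFactors = FALSE)
  }
  unique(out)
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each annotation term, tests whether the selected gene set contains
#' more term members than expected by chance when drawing `n` genes from a
#' universe of `N`, of which `K` carry the term: the p-value is the
#' upper-tail hypergeometric probability `P[X >= k]`.  Terms are intersected
#' with the universe before testing; terms left with no universe gene are
#' skipped.  q-values are Benjamini-Hochberg across all tested terms.
#'
#' @param selection character vector of selected gene symbols (must be a
#'   subset of `universe`).
#' @param universe character vector of background gene symbols.
#' @param terms annotation data frame as from [read_term_annotations()]
#'   (columns `term_id`, `term_name`, `gene`).
#' @param alpha significance level used only to flag `significant` in the
#'   output; default 0.05.
#' @return data frame sorted by p-value ascending with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `fold_enrichment`, `p_value`,
#'   `q_value`, `significant`.
#' @examples
#' terms <- data.frame(term_id = "T1", term_name = "toy",
#'                     gene = c("A", "B", "C"))
#' hypergeom_enrichment(c("A", "B"), LETTERS[1:10], terms)
#' @export
hypergeom_enrichment <- function(selection, universe, terms, alpha = 0.05) {
  selection <- unique(toupper(selection))
  universe <- unique(toupper(universe))
  bad <- setdiff(selection, universe)
  if (length(bad))
    stop("selection genes absent from universe: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "gene") %in% names(terms)))
  terms$gene <- toupper(terms$gene)
  N <- length(universe)
  n <- length(selection)
  by_term <- split(terms$gene, terms$term_id)
  term_names <- tapply(terms$term_name, terms$term_id, `[`, 1)

  res <- lapply(names(by_term), function(tid) {
    members <- intersect(unique(by_term[[tid]]), universe)
    K <- length(members)
    if (K == 0) {
      message("term ", tid, " has no gene in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(members, selection))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_name = unname(term_names[tid]),
               k = k, K = K, n = n, N = N,
               fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(res)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value <= alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
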