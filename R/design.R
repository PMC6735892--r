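#' Describe the SILAC experiment layout
#'
#' A triple-SILAC ChIP-MS design is a set of MS runs ("experiments"), each
#' contributing a heavy/medium ratio (bait pull-down in stressed cells versus
#' IgG control) and optionally a heavy/light ratio (stressed, synchronized
#' bait pull-down versus untreated asynchronous cells).  A pilot run that was
#' searched together with the main replicates typically contributes the H/M
#' channel only.
#'
#' @param experiments data frame with columns `id` (character, unique),
#'   `has_hm` and `has_hl` (logical): which ratio channels each run carries.
#' @param fold_threshold minimum fold change called "enriched"; must exceed 1.
#'   Default 1.5.
#' @return an object of class `experiment_design`.
#' @examples
#' experiment_design(data.frame(
#'   id = c("pilot", "rep1", "rep2"),
#'   has_hm = TRUE, has_hl = c(FALSE, TRUE, TRUE)))
#' @export
experiment_design <- function(experiments, fold_threshold = 1.5) {
  stopifnot(is.data.frame(experiments),
            all(c("id", "has_hm", "has_hl") %in% names(experiments)))
  experiments$id <- as.character(experiments$id)
  if (anyDuplicated(experiments$id))
    stop("duplicate experiment ids: ",
         paste(unique(experiments$id[duplicated(experiments$id)]), collapse = ", "))
  if (!any(experiments$has_hm))
    stop("design must contain at least one experiment with an H/M channel")
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      fold_threshold <= 1)
    stop("fold_threshold must be a single number > 1")
  structure(list(experiments = experiments[, c("id", "has_hm", "has_hl")],
                 fold_threshold = fold_threshold),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("SILAC experiment design:", nrow(x$experiments), "experiment(s),",
      sum(x$experiments$has_hm), "with H/M,",
      sum(x$experiments$has_hl), "with H/L; fold threshold",
      x$fold_threshold, "\n")
  invisible(x)
}

#' Default three-run design: pilot (H/M only) plus two full replicates
#'
#' @param fold_threshold enrichment threshold, default 1.5.
#' @return an `experiment_design`.
#' @export
default_design <- function(fold_threshold = 1.5) {
  experiment_design(
    data.frame(id = c("pilot", "rep1", "rep2"),
               has_hm = c(TRUE, TRUE, TRUE),
               has_hl = c(FALSE, TRUE, TRUE)),
    fold_threshold = fold_threshold)
}

hm_cols <- function(design) {
  ids <- design$experiments$id[design$experiments$has_hm]
  if (length(ids)) paste0("ratio_hm.", ids) else character(0)
}
hl_cols <- function(design) {
  ids <- design$experiments$id[design$experiments$has_hl]
  if (length(ids)) paste0("ratio_hl.", ids) else character(0)
}
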