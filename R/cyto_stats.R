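#' Per-condition summary of metaphase break counts
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error
#' of the mean of gaps+breaks per spread, per condition.  Empty groups are
#' dropped with a message.
#'
#' @param table a `break_table`.
#' @return data frame `group`, `n`, `mean`, `sd`, `sem`, ordered by group.
#' @export
group_summary <- function(table) {
  stopifnot(inherits(table, "break_table"))
  groups <- sort(unique(table$group))
  rows <- lapply(groups, function(g) {
    x <- table$breaks_total[table$group == g]
    x <- x[!is.na(x)]
    if (!length(x)) {
      message("group ", g, " has no scored spreads; excluded")
      return(NULL)
    }
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0,
               sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test; Welch's unequal-variance form by default,
#' with `welch = FALSE` for the classical pooled-variance test.  When both
#' groups are constant with equal means the test statistic is undefined and
#' the conventional `t = 0, p = 1` is returned with a message.
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @param welch use the Welch correction (default `TRUE`).
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t <- function(groupA, groupB, welch = TRUE) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      message("both groups constant with equal means; returning p = 1")
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    }
    return(list(t = Inf * sign(mean(groupA) - mean(groupB)),
                df = length(groupA) + length(groupB) - 2, p = 0))
  }
  fit <- t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Pearson chi-square test of fragile-locus breakage across conditions
#'
#' Tests independence of breakage status and condition on a 2 x k table of
#' broken/intact counts, without continuity correction by default (a flag
#' enables Yates' correction for 2 x 2 tables).  A message recommends an
#' exact test when any expected count falls below 1, but the chi-square
#' result is still returned.
#'
#' @param tab a `locus_contingency` (columns `group`, `broken`, `intact`)
#'   or a k x 2 count matrix.
#' @param correct apply the continuity correction (default `FALSE`).
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_independence <- function(tab, correct = FALSE) {
  if (inherits(tab, "locus_contingency") || is.data.frame(tab)) {
    m <- as.matrix(tab[, c("broken", "intact")])
    rownames(m) <- tab$group
  } else m <- as.matrix(tab)
  stopifnot(is.numeric(m), ncol(m) == 2, nrow(m) >= 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1))
    message("expected count below 1; consider an exact test")
  if (all(abs(m[, 1] / rowSums(m) - sum(m[, 1]) / sum(m)) < 1e-12))
    return(list(chi2 = 0, df = (nrow(m) - 1) * (ncol(m) - 1), p = 1))
  fit <- suppressWarnings(chisq.test(m, correct = correct))
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Fraction of EdU-positive (MiDAS) breaks per condition
#'
#' Pools breaks within each condition and reports the fraction that are
#' EdU-positive with a Wilson 95% confidence interval.  Conditions with no
#' breaks (or no EdU scoring) are reported as missing.
#'
#' @param table a `break_table` with `breaks_edu_pos` scored.
#' @param conf confidence level, default 0.95.
#' @return data frame `group`, `n_breaks`, `n_edu_pos`, `frac_edu_pos`,
#'   `ci_lower`, `ci_upper`.
#' @export
midas_proportions <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "break_table"))
  groups <- sort(unique(table$group))
  rows <- lapply(groups, function(g) {
    sub <- table[table$group == g & !is.na(table$breaks_edu_pos), , drop = FALSE]
    n <- sum(sub$breaks_total); x <- sum(sub$breaks_edu_pos)
    if (n == 0)
      return(data.frame(group = g, n_breaks = 0L, n_edu_pos = 0L,
                        frac_edu_pos = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, stringsAsFactors = FALSE))
    ci <- wilson_ci(x, n, conf)
    data.frame(group = g, n_breaks = n, n_edu_pos = x,
               frac_edu_pos = unname(ci["estimate"]),
               ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
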