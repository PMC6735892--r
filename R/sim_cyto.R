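#' Parameters for the synthetic cytogenetics generator
#'
#' Emulates scored metaphase-spread data: per-spread gap+break counts are
#' Poisson with a condition-specific mean, each break is EdU-positive
#' (mitotic DNA synthesis, MiDAS) with a condition-specific probability, and
#' a fragile locus is broken on each scored chromosome with a
#' condition-specific Bernoulli probability.
#'
#' @param n_spreads_per_group number of metaphase spreads scored per
#'   condition.
#' @param break_rate named vector, mean gaps+breaks per spread per condition
#'   (Poisson mean).
#' @param midas_pos_prob named vector (same conditions), probability that a
#'   break incorporates EdU.
#' @param locus_break_prob named vector (same conditions), probability that
#'   a scored fragile locus is broken.
#' @param n_loci number of fragile loci scored per condition.
#' @param seed integer seed.
#' @return an object of class `cyto_sim_params`.
#' @export
cyto_sim_params <- function(n_spreads_per_group = 40,
                            break_rate = c(ctrl_dmso = 1, ctrl_aph = 3,
                                           kd_dmso = 2, kd_aph = 6),
                            midas_pos_prob = c(ctrl_dmso = 0.2,
                                               ctrl_aph = 0.45,
                                               kd_dmso = 0.3, kd_aph = 0.6),
                            locus_break_prob = c(ctrl_dmso = 0.02,
                                                 ctrl_aph = 0.08,
                                                 kd_dmso = 0.04,
                                                 kd_aph = 0.20),
                            n_loci = 120, seed = 1L) {
  p <- list(n_spreads_per_group = n_spreads_per_group,
            break_rate = break_rate, midas_pos_prob = midas_pos_prob,
            locus_break_prob = locus_break_prob, n_loci = n_loci,
            seed = as.integer(seed))
  if (!is_count(p$n_spreads_per_group) || !is_count(p$n_loci))
    stop("n_spreads_per_group and n_loci must be non-negative integers")
  groups <- names(p$break_rate)
  if (is.null(groups) || !setequal(groups, names(p$midas_pos_prob)) ||
      !setequal(groups, names(p$locus_break_prob)))
    stop("break_rate, midas_pos_prob and locus_break_prob must share group names")
  if (any(p$break_rate < 0)) stop("break rates must be >= 0")
  if (any(p$midas_pos_prob < 0 | p$midas_pos_prob > 1) ||
      any(p$locus_break_prob < 0 | p$locus_break_prob > 1))
    stop("probabilities must lie in [0, 1]")
  structure(p, class = "cyto_sim_params")
}

#' Generate synthetic metaphase break counts and locus-breakage tables
#'
#' @param params a [cyto_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{breaks}{`break_table` data frame: `spread_id`, `group`,
#'       `breaks_total`, `breaks_edu_pos`.}
#'     \item{locus}{`locus_contingency` data frame: `group`, `broken`,
#'       `intact`.}
#'     \item{truth}{the generating rates per group.}
#'   }
#' @export
gen_cyto_counts <- function(params) {
  stopifnot(inherits(params, "cyto_sim_params"))
  set.seed(params$seed)
  groups <- names(params$break_rate)
  n <- params$n_spreads_per_group

  breaks <- do.call(rbind, lapply(groups, function(g) {
    tot <- rpois(n, params$break_rate[[g]])
    data.frame(spread_id = sprintf("%s_s%03d", g, seq_len(n)), group = g,
               breaks_total = tot,
               breaks_edu_pos = rbinom(n, tot, params$midas_pos_prob[[g]]),
               stringsAsFactors = FALSE)
  }))
  locus <- do.call(rbind, lapply(groups, function(g) {
    broken <- rbinom(1, params$n_loci, params$locus_break_prob[[g]])
    data.frame(group = g, broken = broken,
               intact = params$n_loci - broken, stringsAsFactors = FALSE)
  }))
  class(breaks) <- c("break_table", "data.frame")
  class(locus) <- c("locus_contingency", "data.frame")
  list(breaks = breaks, locus = locus,
       truth = data.frame(group = groups,
                          break_rate = unname(params$break_rate[groups]),
                          midas_pos_prob = unname(params$midas_pos_prob[groups]),
                          locus_break_prob =
                            unname(params$locus_break_prob[groups]),
                          stringsAsFactors = FALSE))
}

#' Read a per-spread break-count table from CSV
#'
#' Expected columns: `spread_id`, `group`, `breaks_total` and optionally
#' `breaks_edu_pos`.
#'
#' @param path CSV file.
#' @return a `break_table` data frame.
#' @export
read_break_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spread_id", "group", "breaks_total")
  if (!all(need %in% names(tab)))
    stop("break table needs columns: ", paste(need, collapse = ", "))
  if (!"breaks_edu_pos" %in% names(tab)) tab$breaks_edu_pos <- NA_integer_
  bad <- !is.na(tab$breaks_edu_pos) & tab$breaks_edu_pos > tab$breaks_total
  if (any(bad)) stop("breaks_edu_pos exceeds breaks_total in ", sum(bad), " row(s)")
  class(tab) <- c("break_table", "data.frame")
  tab
}

#' Read a per-condition locus-breakage contingency table from CSV
#'
#' Expected columns: `group`, `broken`, `intact`.
#'
#' @param path CSV file.
#' @return a `locus_contingency` data frame.
#' @export
read_locus_contingency <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "broken", "intact") %in% names(tab)))
    stop("locus table needs columns: group, broken, intact")
  if (any(tab$broken + tab$intact <= 0))
    stop("each group needs a positive number of scored loci")
  class(tab) <- c("locus_contingency", "data.frame")
  tab
}
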