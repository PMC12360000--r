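# Family-level proportion tests and the 2x2 contingency utilities used for
# the cohort-level comparisons.

#' Family-level proportion test of epigenetic effects
#'
#' One-sample chi-square goodness-of-fit of a family's (effect, no-effect)
#' copy counts against the cohort-wide effect proportion. Families below the
#' eligibility gates (minimum copies in the genome; minimum copies with an
#' effect) are excluded. When an expected cell drops below 1 the test
#' switches to an exact binomial test and the row is flagged.
#'
#' @param n_copies Number of analyzed copies in the family.
#' @param n_effect Number of those copies with the epigenetic effect.
#' @param global_proportion Cohort-wide proportion of copies with the
#'   effect, computed from the analyzed cohort (never hard-coded).
#' @param config A [teepi_config()] supplying the eligibility gates.
#' @return One-row data frame: `n_copies`, `n_effect`, `expected_proportion`,
#'   `statistic` (chi-square, `NA` for the exact fallback), `p`, `direction`
#'   (`over` / `under` / `ns` / `excluded`), `exact` (logical flag).
#' @export
family_proportion_test <- function(n_copies, n_effect, global_proportion,
                                   config = teepi_config()) {
  row <- function(stat, p, dirn, exact = FALSE) {
    data.frame(n_copies = n_copies, n_effect = n_effect,
               expected_proportion = global_proportion, statistic = stat,
               p = p, direction = dirn, exact = exact,
               stringsAsFactors = FALSE)
  }
  if (n_copies < config$min_copies_family ||
      n_effect < config$min_effect_copies_family) {
    return(row(NA_real_, NA_real_, "excluded"))
  }
  expected <- n_copies * c(global_proportion, 1 - global_proportion)
  obs_prop <- n_effect / n_copies
  dirn <- if (obs_prop > global_proportion) "over"
          else if (obs_prop < global_proportion) "under" else "ns"
  if (any(expected < 1)) {
    bt <- stats::binom.test(n_effect, n_copies, p = global_proportion)
    p <- bt$p.value
    if (p >= 0.05) dirn <- "ns"
    return(row(NA_real_, p, dirn, exact = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(
    c(n_effect, n_copies - n_effect),
    p = c(global_proportion, 1 - global_proportion)))
  if (ct$p.value >= 0.05) dirn <- "ns"
  row(unname(ct$statistic), ct$p.value, dirn)
}

#' Family proportion tests across a cohort of effect calls
#'
#' Computes the global effect proportion from the calls themselves, then
#' tests every family. TEs with class `excluded` are dropped from both
#' numerator and denominator.
#'
#' @param te_families Data frame: `te_id`, `family`.
#' @param has_effect Logical vector parallel to `te_families`: does this
#'   copy show the effect being tested.
#' @param config A [teepi_config()].
#' @return Data frame with one row per family (columns of
#'   [family_proportion_test()] plus `family` and a BH-adjusted p column).
#' @export
family_tests_all <- function(te_families, has_effect,
                             config = teepi_config()) {
  stopifnot(nrow(te_families) == length(has_effect))
  global_p <- mean(has_effect)
  fams <- split(seq_len(nrow(te_families)), te_families$family)
  rows <- lapply(names(fams), function(f) {
    i <- fams[[f]]
    cbind(data.frame(family = f, stringsAsFactors = FALSE),
          family_proportion_test(length(i), sum(has_effect[i]), global_p,
                                 config))
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' 2x2 contingency test
#'
#' Chi-square test of independence with Yates continuity correction
#' (df = 1), or two-sided Fisher's exact test under the standard convention
#' (sum of hypergeometric probabilities not exceeding the observed table's).
#' The odds ratio is the sample cross-product `ad/bc` (0 and `Inf`
#' sentinels allowed).
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param method `"chi2_yates"` (default) or `"fisher"`.
#' @return One-row data frame: `statistic` (`NA` for Fisher), `p`,
#'   `odds_ratio`, `method`.
#' @export
contingency_2x2 <- function(table, method = c("chi2_yates", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(table) == 0) && any(colSums(table) == 0)) {
    stop("degenerate table: empty margin", call. = FALSE)
  }
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  if (method == "chi2_yates") {
    ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
    data.frame(statistic = unname(ct$statistic), p = ct$p.value,
               odds_ratio = or, method = method, stringsAsFactors = FALSE)
  } else {
    ft <- stats::fisher.test(table, alternative = "two.sided")
    data.frame(statistic = NA_real_, p = ft$p.value, odds_ratio = or,
               method = method, stringsAsFactors = FALSE)
  }
}
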