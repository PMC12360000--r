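# Core statistics: per-window rank-sum tests between TE(+) and TE(-)
# genomes, percentage enrichment/depletion in the innermost +/-1 kb,
# spread extent of consecutive significant windows, per-pair classification
# and the consensus rule across strain pairs.

# Two-sided Wilcoxon rank-sum p-value and location direction.
# Follows the classical decision rule: exact distribution (pwilcox) for
# tie-free samples below 50 per group, otherwise normal approximation with
# tie correction and continuity correction. Returns c(p, sign) where sign
# is +1 when x tends higher than y, -1 lower, 0 no shift.
.ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U of x
  ties <- length(unique(r)) != nx + ny
  mu <- nx * ny / 2
  if (!ties && nx < 50 && ny < 50) {
    p <- if (W > mu) {
      stats::pwilcox(W - 1, nx, ny, lower.tail = FALSE)
    } else {
      stats::pwilcox(W, nx, ny)
    }
    p <- min(2 * p, 1)
  } else {
    z <- W - mu
    nties <- table(r)
    sigma <- sqrt((nx * ny / 12) *
                    ((nx + ny + 1) -
                       sum(nties^3 - nties) / ((nx + ny) * (nx + ny - 1))))
    if (sigma == 0) return(c(1, 0))
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
  }
  c(p, sign(W - mu))
}

#' Rank-sum test between homologous windows of two genomes
#'
#' Two-sided Wilcoxon rank-sum test on the replicate-averaged bin values of
#' one window in a TE(+) genome versus the homologous window in a TE(-)
#' genome. Direction is assigned post hoc from the rank shift when the test
#' is significant at `alpha`, and is `"none"` otherwise.
#'
#' @param x_bins,y_bins Bin values (TE(+) and TE(-) respectively); `NA`s are
#'   dropped.
#' @param alpha Significance level.
#' @param min_bins Minimum non-missing bins required in each vector; below
#'   it the test is missing (`p_value = NA`), which feeds the consensus NA
#'   rule.
#' @return A list: `p_value`, `direction` (`higher`/`lower`/`none`/`NA`),
#'   `n_pos`, `n_neg`.
#' @export
window_test <- function(x_bins, y_bins, alpha = 0.05, min_bins = 50L) {
  x <- x_bins[!is.na(x_bins)]
  y <- y_bins[!is.na(y_bins)]
  if (length(x) < min_bins || length(y) < min_bins) {
    return(list(p_value = NA_real_, direction = NA_character_,
                n_pos = length(x), n_neg = length(y)))
  }
  rs <- .ranksum(x, y)
  dir <- if (rs[1] < alpha && rs[2] != 0) {
    if (rs[2] > 0) "higher" else "lower"
  } else "none"
  list(p_value = rs[1], direction = dir, n_pos = length(x),
       n_neg = length(y))
}

#' Percentage change of median enrichment in the innermost windows
#'
#' `P = 100 * (median+ - median-) / median-` where the medians are taken,
#' by default, over the pooled bins of the two innermost (+/-1 kb) windows
#' of each genome; the denominator is always the TE(-) genome.
#'
#' @param prof_pos,prof_neg `window_profile` objects for the TE(+) and
#'   TE(-) genomes.
#' @param pool_sides If `TRUE` (default) pool left and right innermost
#'   windows before taking medians; otherwise compute P per side and
#'   average.
#' @return Signed percentage, or `NA` when the TE(-) median is 0 (the call
#'   is then excluded) or no bins are usable.
#' @export
percent_change <- function(prof_pos, prof_neg, pool_sides = TRUE) {
  pc <- function(xp, xn) {
    mp <- stats::median(xp, na.rm = TRUE)
    mn <- stats::median(xn, na.rm = TRUE)
    if (!is.finite(mp) || !is.finite(mn) || mn == 0) return(NA_real_)
    100 * (mp - mn) / mn
  }
  if (pool_sides) {
    pc(c(prof_pos$left[, 1L], prof_pos$right[, 1L]),
       c(prof_neg$left[, 1L], prof_neg$right[, 1L]))
  } else {
    mean(c(pc(prof_pos$left[, 1L], prof_neg$left[, 1L]),
           pc(prof_pos$right[, 1L], prof_neg$right[, 1L])))
  }
}

#' Per-window tests for one TE(+)/TE(-) genome pair
#'
#' @param prof_pos,prof_neg `window_profile` objects with identical
#'   geometry.
#' @param config A [teepi_config()].
#' @return Data frame: `side`, `window`, `p_value`, `direction`.
#' @export
pair_window_tests <- function(prof_pos, prof_neg, config = teepi_config()) {
  nw <- prof_pos$n_windows
  one_side <- function(side) {
    mp <- prof_pos[[side]]; mn <- prof_neg[[side]]
    p <- numeric(nw); d <- character(nw)
    for (i in seq_len(nw)) {
      wt <- window_test(mp[, i], mn[, i], config$alpha,
                        config$min_bins_per_window)
      p[i] <- wt$p_value; d[i] <- if (is.na(wt$p_value)) NA_character_
                                  else wt$direction
    }
    data.frame(side = side, window = seq_len(nw), p_value = p,
               direction = d, stringsAsFactors = FALSE)
  }
  rbind(one_side("left"), one_side("right"))
}

#' Spread extent from per-window tests
#'
#' Per side, the run length of windows from window 1 outward that are all
#' significant with the given direction; the spread is the minimum of the
#' two sides (the window closer to the TE, the conservative choice when the
#' sides disagree). A missing test breaks the run.
#'
#' @param tests Result of [pair_window_tests()].
#' @param direction `"higher"` or `"lower"`: the direction whose run is
#'   measured.
#' @return Integer spread in windows (= kb at the default 1 kb window).
#' @export
spread_extent <- function(tests, direction) {
  run <- function(side) {
    d <- tests$direction[tests$side == side][order(
      tests$window[tests$side == side])]
    ok <- !is.na(d) & d == direction
    if (!ok[1L]) return(0L)
    which.min(c(ok, FALSE)) - 1L
  }
  min(run("left"), run("right"))
}

#' Classify one TE(+)/TE(-) genome pair
#'
#' Enrichment (depletion) requires window 1 significantly higher (lower) on
#' both sides; the spread is then the consecutive run, minimized across
#' sides. Contradictory directions between the sides at window 1, a missing
#' window-1 test on either side, or an undefined percentage (TE(-) median
#' 0) yield `NA`.
#'
#' @param prof_pos,prof_neg `window_profile` objects for the pair.
#' @param config A [teepi_config()].
#' @return One-row data frame: `class` (`enrichment`/`depletion`/`none`/
#'   `NA`), `percentage`, `spread`, `direction`.
#' @export
classify_pair <- function(prof_pos, prof_neg, config = teepi_config()) {
  out <- function(class, P = NA_real_, S = NA_integer_,
                  direction = NA_character_) {
    data.frame(class = class, percentage = P, spread = S,
               direction = direction, stringsAsFactors = FALSE)
  }
  wt <- function(side, i) {
    window_test(prof_pos[[side]][, i], prof_neg[[side]][, i], config$alpha,
                config$min_bins_per_window)$direction
  }
  d1 <- c(left = wt("left", 1L), right = wt("right", 1L))
  if (anyNA(d1)) return(out(NA_character_))
  if (d1[["left"]] == "none" || d1[["right"]] == "none") {
    return(out("none", S = 0L, direction = "none"))
  }
  if (d1[["left"]] != d1[["right"]]) return(out(NA_character_))
  dirn <- d1[["left"]]
  # consecutive significant run from window 1 outward, evaluated lazily;
  # identical to spread_extent() on the full test table
  run <- function(side) {
    k <- 1L
    while (k < prof_pos$n_windows) {
      d <- wt(side, k + 1L)
      if (is.na(d) || d != dirn) break
      k <- k + 1L
    }
    k
  }
  S <- min(run("left"), run("right"))
  P <- percent_change(prof_pos, prof_neg, config$pool_percentage_sides)
  if (is.na(P)) return(out(NA_character_))
  class <- if (dirn == "higher") "enrichment" else "depletion"
  # class and sign(P) must agree; a rank-shift with opposing median change
  # is uninterpretable and treated as missing
  if ((class == "enrichment" && P <= 0) || (class == "depletion" && P >= 0)) {
    return(out(NA_character_))
  }
  out(class, P, as.integer(S), dirn)
}

#' Consensus call across all TE(+) x TE(-) strain pairs
#'
#' The TE-level class is the modal pair-level class when at most one pair
#' deviates from it (whether by a different class or by missing data);
#' otherwise the TE is excluded. When the mode ties between an effect class
#' and `none`, the effect class wins (the single allowed deviation being the
#' no-effect pair); a tie between enrichment and depletion is contradictory
#' and excludes the TE. Reported percentage and spread are means over the
#' concordant pairs.
#'
#' @param pair_calls Data frame of [classify_pair()] rows (one per pair).
#' @return One-row data frame: `class` (`enrichment`/`depletion`/`none`/
#'   `excluded`), `percentage`, `spread`, `n_pairs`, `n_valid`.
#' @export
consensus_call <- function(pair_calls) {
  n <- nrow(pair_calls)
  cls <- pair_calls$class
  valid <- !is.na(cls)
  out <- function(class, P = NA_real_, S = NA_real_) {
    data.frame(class = class, percentage = P, spread = S, n_pairs = n,
               n_valid = sum(valid), stringsAsFactors = FALSE)
  }
  if (!any(valid)) return(out("excluded"))
  counts <- table(cls[valid])
  maxc <- max(counts)
  cands <- names(counts)[counts == maxc]
  if (length(cands) > 1L) {
    if (all(c("enrichment", "depletion") %in% cands)) {
      return(out("excluded"))
    }
    cands <- setdiff(cands, "none")   # effect class wins a tie with none
  }
  modal <- cands[1L]
  deviants <- n - counts[[modal]]
  if (deviants > 1L) return(out("excluded"))
  conc <- valid & cls == modal
  if (modal == "none") return(out("none", S = 0))
  out(modal, P = mean(pair_calls$percentage[conc]),
      S = mean(pair_calls$spread[conc]))
}

#' Combine per-mark calls into a per-body-part class
#'
#' Both marks affected in the same direction is `bivalent`; opposite
#' directions is `mix`; a single affected mark gives `<mark>-only`; no
#' affected mark gives `none`.
#'
#' @param effect_calls Data frame with columns `te_id`, `body_part`, `mark`,
#'   `class`.
#' @return Data frame: `te_id`, `body_part`, `combined_class`.
#' @export
combine_marks <- function(effect_calls) {
  key <- interaction(effect_calls$te_id, effect_calls$body_part, drop = TRUE)
  rows <- lapply(split(effect_calls, key), function(d) {
    eff <- d[d$class %in% c("enrichment", "depletion"), , drop = FALSE]
    combined <- if (nrow(eff) == 0L) {
      "none"
    } else if (nrow(eff) == 1L) {
      paste0(eff$mark, "-only")
    } else if (length(unique(eff$class)) == 1L) {
      "bivalent"
    } else {
      "mix"
    }
    data.frame(te_id = d$te_id[1L], body_part = d$body_part[1L],
               combined_class = combined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call epigenetic effects for every TE across a cohort
#'
#' For each (TE, body part, mark): builds replicate-averaged window profiles
#' anchored at the TE span in carrier strains and at the insertion junction
#' in non-carrier strains, classifies every carrier x non-carrier pair, and
#' applies the consensus rule. Junctions come from the cohort's recorded
#' truth (`anchors = "truth"`) or from [project_breakpoints()] output
#' (`anchors = breakpoints` data frame; TEs lacking a unique call in a
#' strain contribute NA pairs).
#'
#' @param cohort A `teepi_cohort`.
#' @param tracks List of replicate [signal_track()]s covering the conditions
#'   to call.
#' @param config A [teepi_config()].
#' @param anchors `"truth"` or a data frame from [project_breakpoints()].
#' @return A list: `effect_calls` (per TE x body part x mark, with
#'   `combined_class` merged in) and `pair_calls` (per strain pair).
#' @export
call_all_effects <- function(cohort, tracks, config = teepi_config(),
                             anchors = "truth") {
  pres <- attr(cohort$tes, "presence")
  meta <- data.frame(
    strain = vapply(tracks, `[[`, character(1), "strain"),
    body_part = vapply(tracks, `[[`, character(1), "body_part"),
    mark = vapply(tracks, `[[`, character(1), "mark"),
    stringsAsFactors = FALSE
  )
  conds <- unique(meta[, c("body_part", "mark")])
  junctions <- if (identical(anchors, "truth")) {
    cohort$junctions
  } else {
    j <- anchors[anchors$status == "unique",
                 c("te_id", "target_strain", "position")]
    names(j) <- c("te_id", "strain", "position")
    j
  }
  pair_rows <- list(); call_rows <- list(); pk <- 0L; ck <- 0L
  for (ci in seq_len(nrow(conds))) {
    bp <- conds$body_part[ci]; mk <- conds$mark[ci]
    sel <- which(meta$body_part == bp & meta$mark == mk)
    by_strain <- split(sel, meta$strain[sel])
    avg <- lapply(by_strain, function(ix)
      average_replicates(tracks[ix], config$replicate_agg))
    for (ti in seq_len(nrow(cohort$tes))) {
      te <- cohort$tes$te_id[ti]
      carriers <- colnames(pres)[pres[ti, ] == "carrier"]
      noncarr <- colnames(pres)[pres[ti, ] == "non-carrier"]
      carriers <- intersect(carriers, names(avg))
      noncarr <- intersect(noncarr, names(avg))
      prof_pos <- lapply(carriers, function(s) {
        iv <- cohort$carrier_intervals
        iv <- iv[iv$te_id == te & iv$strain == s, ]
        build_window_profile(avg[[s]], cohort$chrom, iv$start, iv$end,
                             config, te_id = te)
      })
      names(prof_pos) <- carriers
      prof_neg <- lapply(noncarr, function(s) {
        j <- junctions[junctions$te_id == te & junctions$strain == s, ]
        if (nrow(j) == 0L) return(NULL)
        build_window_profile(avg[[s]], cohort$chrom, j$position[1L],
                             j$position[1L], config, te_id = te)
      })
      names(prof_neg) <- noncarr
      pc <- list(); q <- 0L
      for (sp in carriers) for (sn in noncarr) {
        q <- q + 1L
        cl <- if (is.null(prof_neg[[sn]])) {
          data.frame(class = NA_character_, percentage = NA_real_,
                     spread = NA_integer_, direction = NA_character_,
                     stringsAsFactors = FALSE)
        } else {
          classify_pair(prof_pos[[sp]], prof_neg[[sn]], config)
        }
        pc[[q]] <- cbind(data.frame(te_id = te, body_part = bp, mark = mk,
                                    carrier = sp, non_carrier = sn,
                                    stringsAsFactors = FALSE), cl)
      }
      pc <- do.call(rbind, pc)
      pk <- pk + 1L
      pair_rows[[pk]] <- pc
      ck <- ck + 1L
      call_rows[[ck]] <- cbind(
        data.frame(te_id = te, body_part = bp, mark = mk,
                   stringsAsFactors = FALSE),
        consensus_call(pc))
    }
  }
  effect_calls <- do.call(rbind, call_rows)
  rownames(effect_calls) <- NULL
  combined <- combine_marks(effect_calls)
  effect_calls <- merge(effect_calls, combined,
                        by = c("te_id", "body_part"), sort = FALSE)
  effect_calls <- effect_calls[order(effect_calls$te_id,
                                     effect_calls$body_part,
                                     effect_calls$mark), ]
  rownames(effect_calls) <- NULL
  pair_calls <- do.call(rbind, pair_rows)
  rownames(pair_calls) <- NULL
  list(effect_calls = effect_calls, pair_calls = pair_calls)
}
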