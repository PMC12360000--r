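# Expression linkage: TMM normalization, TE-to-gene assignment using the
# called spread, and the carrier vs non-carrier z-score statistic.

#' TMM normalization factors
#'
#' Trimmed mean of M-values. The reference sample is the one whose
#' library-size-scaled upper quartile is closest to the mean upper quartile.
#' For each sample, genes with zero counts in the sample or the reference
#' are dropped pairwise, the most extreme `trim_M` fraction of log2 ratios
#' (M) and `trim_A` fraction of average abundances (A) are trimmed, and the
#' factor is 2 to the inverse-variance-weighted mean of the remaining M
#' values (delta-method binomial weights). Factors are rescaled so their
#' geometric mean is 1: depth differences are carried by library sizes, not
#' factors.
#'
#' @param counts Non-negative count matrix, genes x samples (>= 2 samples).
#' @param trim_M Fraction of M values trimmed from each tail (default 0.30).
#' @param trim_A Fraction of A values trimmed from each tail (default 0.05).
#' @param do_weighting Use inverse asymptotic-variance weights
#'   (default `TRUE`).
#' @return Numeric vector of per-sample factors, geometric mean 1.
#' @export
compute_tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                                do_weighting = TRUE) {
  x <- as.matrix(counts)
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample with all-zero counts", call. = FALSE)
  uq <- apply(x, 2L, stats::quantile, probs = 0.75) / lib
  ref_col <- which.min(abs(uq - mean(uq)))
  ref <- x[, ref_col]
  nR <- lib[ref_col]
  one <- function(obs, nO) {
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(logR); rA <- rank(absE)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f <- if (do_weighting) {
      sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    } else {
      mean(logR[keep], na.rm = TRUE)
    }
    if (is.na(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(x)), function(j) one(x[, j], lib[j]), numeric(1))
  f / exp(mean(log(f)))
}

#' TMM-normalized counts per million
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Normalization factors from [compute_tmm_factors()]
#'   (computed if missing).
#' @return Matrix of normalized abundances (counts per million of the
#'   TMM-scaled library).
#' @export
cpm_tmm <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- compute_tmm_factors(counts)
  lib <- colSums(counts) * factors
  sweep(counts, 2L, lib / 1e6, "/")
}

#' Position of a TE relative to a gene model
#'
#' @param te_start,te_end TE interval (0-based half-open).
#' @param gene_feats Feature rows for one gene (as from
#'   [read_gene_annotations()]): a `gene` row plus optional `CDS`,
#'   `five_prime_UTR`, `three_prime_UTR` rows.
#' @return One of `upstream`, `downstream`, `5'UTR`, `3'UTR`, `CDS`,
#'   `intron`; when the TE lies inside the gene but the model has no
#'   sub-features, `gene_body` is returned with attribute
#'   `distance_only = TRUE`.
#' @export
classify_position <- function(te_start, te_end, gene_feats) {
  g <- gene_feats[gene_feats$feature == "gene", ][1L, ]
  overlaps <- function(s, e) te_start < e && te_end > s
  if (overlaps(g$start, g$end)) {
    sub <- gene_feats[gene_feats$feature != "gene", , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(structure("gene_body", distance_only = TRUE))
    }
    for (feat in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
      rows <- sub[sub$feature == feat, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        if (overlaps(rows$start[r], rows$end[r])) {
          return(switch(feat, CDS = "CDS", five_prime_UTR = "5'UTR",
                        three_prime_UTR = "3'UTR"))
        }
      }
    }
    return("intron")
  }
  # outside the gene: orient by strand
  before <- te_end <= g$start
  if (g$strand == "-") before <- !before
  if (before) "upstream" else "downstream"
}

#' Link TEs with epigenetic effects to nearby genes
#'
#' A gene is linked to a TE when its body overlaps the TE or lies within
#' the called spread (in kb) of the TE's edges. The positional category of
#' the TE relative to the gene model is recorded.
#'
#' @param effect_calls Data frame from [call_all_effects()]; only rows with
#'   `class` in enrichment/depletion and `spread >= 1` produce links.
#' @param tes TE annotation data frame (`te_id`, `chrom`, `start`, `end`) in
#'   the same coordinate system as `genes`.
#' @param genes Gene feature table ([read_gene_annotations()] schema).
#' @return Data frame: `te_id`, `gene_id`, `body_part`, `mark`, `class`,
#'   `spread`, `positional_category`, `distance_bp`.
#' @export
link_te_genes <- function(effect_calls, tes, genes) {
  eff <- effect_calls[effect_calls$class %in% c("enrichment", "depletion") &
                        !is.na(effect_calls$spread) &
                        effect_calls$spread >= 1, , drop = FALSE]
  gene_rows <- genes[genes$feature == "gene", , drop = FALSE]
  by_gene <- split(genes, genes$gene_id)
  out <- list(); k <- 0L
  for (r in seq_len(nrow(eff))) {
    ti <- match(eff$te_id[r], tes$te_id)
    if (is.na(ti)) next
    s <- tes$start[ti]; e <- tes$end[ti]
    reach <- eff$spread[r] * 1000
    near <- gene_rows$chrom == tes$chrom[ti] &
      gene_rows$start < e + reach & gene_rows$end > s - reach
    for (gi in which(near)) {
      gid <- gene_rows$gene_id[gi]
      d <- max(0, max(gene_rows$start[gi], s) - min(gene_rows$end[gi], e))
      dist <- if (gene_rows$start[gi] < e && gene_rows$end[gi] > s) 0L
              else as.integer(max(gene_rows$start[gi] - e,
                                  s - gene_rows$end[gi]))
      k <- k + 1L
      out[[k]] <- data.frame(
        te_id = eff$te_id[r], gene_id = gid, body_part = eff$body_part[r],
        mark = eff$mark[r], class = eff$class[r], spread = eff$spread[r],
        positional_category = as.character(
          classify_position(s, e, by_gene[[gid]])),
        distance_bp = dist, stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    return(data.frame(te_id = character(), gene_id = character(),
                      body_part = character(), mark = character(),
                      class = character(), spread = double(),
                      positional_category = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Link a cohort's affected TEs to genes in carrier coordinates
#'
#' For each TE the linking runs in its first carrier strain's coordinate
#' system (TE interval from the carrier annotation, gene models projected
#' into that strain), so a TE inserted in an intron is classified as
#' intronic rather than overlapping the features its insertion displaced.
#'
#' @param cohort A `teepi_cohort`.
#' @param effect_calls Data frame from [call_all_effects()].
#' @return As [link_te_genes()].
#' @export
link_cohort_genes <- function(cohort, effect_calls) {
  pres <- attr(cohort$tes, "presence")
  first_carrier <- apply(pres, 1L, function(p)
    colnames(pres)[which(p == "carrier")[1L]])
  out <- lapply(unique(first_carrier), function(s) {
    ids <- cohort$tes$te_id[first_carrier == s]
    iv <- cohort$carrier_intervals
    iv <- iv[iv$strain == s & iv$te_id %in% ids, , drop = FALSE]
    tes_s <- cohort$tes[match(iv$te_id, cohort$tes$te_id), , drop = FALSE]
    tes_s$start <- iv$start; tes_s$end <- iv$end
    link_te_genes(effect_calls[effect_calls$te_id %in% ids, , drop = FALSE],
                  tes_s, genes_for_strain(cohort, s))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$te_id, res$gene_id, res$body_part, res$mark), , drop = FALSE]
}

#' Expression z-score between carrier and non-carrier groups
#'
#' `z = (mean+ - mean-) / sqrt(SE+^2 + SE-^2)` with `SE = sd / sqrt(n)` per
#' group. Zero variance in both groups yields 0 when the means are equal
#' and a signed infinite sentinel otherwise.
#'
#' @param x_pos,x_neg Normalized expression values for the carrier and
#'   non-carrier samples (>= 2 each).
#' @return The z statistic.
#' @export
zscore_expression <- function(x_pos, x_neg) {
  x_pos <- x_pos[!is.na(x_pos)]; x_neg <- x_neg[!is.na(x_neg)]
  if (length(x_pos) < 2L || length(x_neg) < 2L) return(NA_real_)
  se2 <- stats::var(x_pos) / length(x_pos) +
    stats::var(x_neg) / length(x_neg)
  dm <- mean(x_pos) - mean(x_neg)
  if (se2 == 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sqrt(se2)
}

#' z-scores for a set of TE-gene links
#'
#' For each link, compares TMM-normalized expression of the gene between
#' all carrier-strain and all non-carrier-strain samples of the link's body
#' part. Genes below the expressed-abundance floor in that body part are
#' dropped.
#'
#' @param links Data frame from [link_te_genes()].
#' @param norm_expr Normalized expression matrix from [cpm_tmm()].
#' @param samples Sample metadata (as from [read_counts()]).
#' @param presence Character presence matrix te_id x strain.
#' @param config A [teepi_config()]. `pool_replicates = FALSE` averages
#'   replicates per strain before comparing strain means.
#' @return `links` with `z`, `significant`, `direction` (`up`/`down`/
#'   `none`) columns appended; unexpressed or unmeasurable links are
#'   dropped.
#' @export
te_gene_zscores <- function(links, norm_expr, samples, presence,
                            config = teepi_config()) {
  if (nrow(links) == 0L) {
    links$z <- double(); links$significant <- logical()
    links$direction <- character()
    return(links)
  }
  z <- rep(NA_real_, nrow(links))
  keep <- rep(TRUE, nrow(links))
  for (r in seq_len(nrow(links))) {
    gid <- links$gene_id[r]; bp <- links$body_part[r]
    te <- links$te_id[r]
    if (!gid %in% rownames(norm_expr) || !te %in% rownames(presence)) {
      keep[r] <- FALSE; next
    }
    in_bp <- samples$body_part == bp
    vals <- norm_expr[gid, samples$sample[in_bp]]
    if (mean(vals) < config$expressed_min_cpm) { keep[r] <- FALSE; next }
    carr <- colnames(presence)[presence[te, ] == "carrier"]
    ncar <- colnames(presence)[presence[te, ] == "non-carrier"]
    grp <- function(strs) {
      sel <- in_bp & samples$strain %in% strs
      v <- norm_expr[gid, samples$sample[sel]]
      if (config$pool_replicates) return(v)
      tapply(v, samples$strain[sel], mean)
    }
    z[r] <- zscore_expression(grp(carr), grp(ncar))
  }
  links <- links[keep, , drop = FALSE]
  links$z <- z[keep]
  links$significant <- !is.na(links$z) & abs(links$z) >= config$z_threshold
  links$direction <- ifelse(!links$significant, "none",
                            ifelse(links$z < 0, "down", "up"))
  rownames(links) <- NULL
  links
}

#' Quadrant counts of effect class versus expression direction
#'
#' Tabulates significant TE-gene links by (mark, effect class, expression
#' direction), the summary used to relate repressive/active mark changes to
#' down/upregulation.
#'
#' @param links Data frame from [te_gene_zscores()].
#' @return Data frame: `mark`, `class`, `direction`, `n`.
#' @export
quadrant_counts <- function(links) {
  sig <- links[links$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(mark = character(), class = character(),
                      direction = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(n = seq_len(nrow(sig))),
    by = list(mark = sig$mark, class = sig$class, direction = sig$direction),
    FUN = length)
  agg[order(agg$mark, agg$class, agg$direction), , drop = FALSE]
}
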