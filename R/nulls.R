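# Permutation null models: positionally matched random TE sets, TE-free
# control regions, and the shared empirical p-value rule.

#' Empirical permutation p-value with add-one correction
#'
#' `p = (1 + #\{null >= observed\}) / (N + 1)`, so p is never 0 and lies in
#' `[1/(N+1), 1]`.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @return A one-row data frame: `observed`, `n_null`, `count_ge`, `p`.
#' @export
permutation_pvalue <- function(observed, null) {
  count_ge <- sum(null >= observed)
  data.frame(observed = observed, n_null = length(null),
             count_ge = count_ge, p = (1 + count_ge) / (length(null) + 1))
}

#' Genomic category of a region relative to the nearest gene
#'
#' Applies [classify_position()] against the closest gene model; regions
#' with no gene within `max_dist` are `intergenic`.
#'
#' @param start,end Region interval (0-based half-open).
#' @param genes Gene feature table.
#' @param max_dist Maximum distance to a gene for a positional category
#'   (default 20 kb).
#' @return A category string.
#' @export
region_category <- function(start, end, genes, max_dist = 20000) {
  g <- genes[genes$feature == "gene", , drop = FALSE]
  if (nrow(g) == 0L) return("intergenic")
  d <- pmax(0, pmax(g$start - end, start - g$end))
  i <- which.min(d)
  if (d[i] > max_dist) return("intergenic")
  as.character(classify_position(start, end,
                                 genes[genes$gene_id == g$gene_id[i], ,
                                       drop = FALSE]))
}

#' Sample TE-free control regions matched to focal TEs
#'
#' Draws, for each focal TE, a uniformly random region of the same length on
#' the same chromosome that has no annotated TE within 1 kb and falls in the
#' same positional category relative to genes. Categories that cannot be
#' matched within `max_tries` draws are reported as shortfall, never
#' silently truncated.
#'
#' @param focal_tes TE rows (subset of `tes`) to control for.
#' @param tes All TE annotations (clearance is checked against these).
#' @param genes Gene feature table.
#' @param chrom_length Length of the chromosome sampled from.
#' @param seed Integer seed (same seed, same sample).
#' @param max_tries Rejection-sampling attempts per region (default 200).
#' @return Data frame: `region_id`, `matched_te_id`, `chrom`, `start`,
#'   `end`, `category`. A `shortfall` attribute lists unmatched TEs with
#'   their categories.
#' @export
sample_te_free_regions <- function(focal_tes, tes, genes, chrom_length,
                                   seed = 1L, max_tries = 200L) {
  set.seed(seed)
  clear <- function(s, e, chrom) {
    sel <- tes$chrom == chrom & tes$start < e + 1000 & tes$end > s - 1000
    !any(sel)
  }
  out <- list(); short <- list(); k <- 0L
  for (r in seq_len(nrow(focal_tes))) {
    len <- focal_tes$end[r] - focal_tes$start[r]
    chrom <- focal_tes$chrom[r]
    want <- region_category(focal_tes$start[r], focal_tes$end[r], genes)
    found <- FALSE
    if (chrom_length - len < 1) {
      short[[length(short) + 1L]] <- data.frame(
        te_id = focal_tes$te_id[r], category = want,
        stringsAsFactors = FALSE)
      next
    }
    for (try in seq_len(max_tries)) {
      s <- sample.int(chrom_length - len, 1L) - 1L
      e <- s + len
      if (!clear(s, e, chrom)) next
      if (region_category(s, e, genes) != want) next
      k <- k + 1L
      out[[k]] <- data.frame(
        region_id = sprintf("tefree%04d", k),
        matched_te_id = focal_tes$te_id[r], chrom = chrom,
        start = s, end = e, category = want, stringsAsFactors = FALSE)
      found <- TRUE
      break
    }
    if (!found) {
      short[[length(short) + 1L]] <- data.frame(
        te_id = focal_tes$te_id[r], category = want,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (k) do.call(rbind, out) else
    data.frame(region_id = character(), matched_te_id = character(),
               chrom = character(), start = integer(), end = integer(),
               category = character(), stringsAsFactors = FALSE)
  attr(res, "shortfall") <- if (length(short)) do.call(rbind, short) else
    data.frame(te_id = character(), category = character(),
               stringsAsFactors = FALSE)
  res
}

#' Positional permutation test for expression effects of focal TEs
#'
#' Compares an expression statistic over the links of a focal TE set (TEs
#' with epigenetic effects) to the same statistic over random TE sets of
#' equal size drawn from all TEs with links, matched by positional category
#' (each null draw reproduces the focal set's category histogram exactly;
#' sampling is without replacement within a draw).
#'
#' @param links Data frame with at least `te_id`, `positional_category`,
#'   `z` (one or more links per TE).
#' @param focal_te_ids TE ids forming the focal set.
#' @param n_perm Number of null draws (default 1000).
#' @param seed Integer seed.
#' @param statistic `"prop_down"` (default): proportion of links with
#'   `z <= -z_threshold`; `"mean_z"`: negative mean z (larger = stronger
#'   downregulation); or a function of a z vector where larger means a
#'   stronger effect.
#' @param z_threshold Threshold for `"prop_down"`.
#' @return A one-row data frame as [permutation_pvalue()], plus a `null`
#'   attribute holding the null distribution for audit.
#' @export
positional_permutation_test <- function(links, focal_te_ids, n_perm = 1000L,
                                        seed = 1L,
                                        statistic = "prop_down",
                                        z_threshold = 1.96) {
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else if (statistic == "prop_down") {
    function(z) mean(z <= -z_threshold, na.rm = TRUE)
  } else if (statistic == "mean_z") {
    function(z) -mean(z, na.rm = TRUE)
  } else {
    stop("unknown statistic: ", statistic, call. = FALSE)
  }
  if (length(focal_te_ids) == 0L) stop("empty focal set", call. = FALSE)
  te_cat <- unique(links[, c("te_id", "positional_category")])
  te_cat <- te_cat[!duplicated(te_cat$te_id), ]
  lost <- setdiff(focal_te_ids, te_cat$te_id)
  if (length(lost)) {
    stop("focal TE(s) absent from the link table: ",
         paste(utils::head(lost, 3), collapse = ", "), call. = FALSE)
  }
  focal_cat <- te_cat$positional_category[te_cat$te_id %in% focal_te_ids]
  by_cat <- split(te_cat$te_id, te_cat$positional_category)
  need <- table(focal_cat)
  for (cat in names(need)) {
    if (length(by_cat[[cat]]) < need[[cat]]) {
      stop("cannot match category '", cat, "': ", need[[cat]],
           " needed, ", length(by_cat[[cat]]), " available", call. = FALSE)
    }
  }
  z_by_te <- split(links$z, links$te_id)
  observed <- stat_fun(unlist(z_by_te[
    intersect(names(z_by_te), focal_te_ids)], use.names = FALSE))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    ids <- unlist(lapply(names(need), function(cat) {
      pool <- by_cat[[cat]]
      pool[sample.int(length(pool), need[[cat]])]
    }), use.names = FALSE)
    stat_fun(unlist(z_by_te[intersect(names(z_by_te), ids)],
                    use.names = FALSE))
  }, numeric(1))
  res <- permutation_pvalue(observed, null)
  res$seed <- seed
  attr(res, "null") <- null
  res
}

#' Enrichment calls for control regions with the window machinery
#'
#' Applies the same profile/test/consensus chain used for TEs to arbitrary
#' regions: for each region and strain, the strain is treated as the
#' "carrier" and compared against every other strain; a region is enriched
#' in a strain when the consensus class is enrichment.
#'
#' @param cohort A `teepi_cohort` (regions are given in ancestral
#'   coordinates and projected per strain).
#' @param tracks Replicate signal tracks for one (body part, mark)
#'   condition.
#' @param regions Data frame with `region_id`, `chrom`, `start`, `end`.
#' @param config A [teepi_config()].
#' @return Data frame: `region_id`, `strain`, `class`, `percentage`,
#'   `spread`.
#' @export
call_region_enrichment <- function(cohort, tracks, regions,
                                   config = teepi_config()) {
  meta_strain <- vapply(tracks, `[[`, character(1), "strain")
  avg <- lapply(split(seq_along(tracks), meta_strain), function(ix)
    average_replicates(tracks[ix], config$replicate_agg))
  strains <- names(avg)
  out <- list(); k <- 0L
  for (r in seq_len(nrow(regions))) {
    profs <- lapply(strains, function(s) {
      se <- project_position(cohort, s,
                             c(regions$start[r], regions$end[r]))
      build_window_profile(avg[[s]], regions$chrom[r], se[1L], se[2L],
                           config, te_id = regions$region_id[r])
    })
    names(profs) <- strains
    for (s in strains) {
      pc <- do.call(rbind, lapply(setdiff(strains, s), function(o)
        classify_pair(profs[[s]], profs[[o]], config)))
      cc <- consensus_call(pc)
      k <- k + 1L
      out[[k]] <- data.frame(region_id = regions$region_id[r], strain = s,
                             class = cc$class, percentage = cc$percentage,
                             spread = cc$spread, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Permutation test of expression effects near TE-free regions
#'
#' Compares the number of differentially expressed genes observed near
#' TE-associated regions to a null built by repeatedly sampling equal-size
#' sets of mark-enriched TE-free regions and counting their DE genes.
#'
#' @param te_de_count Observed DE gene count for the TE-associated set.
#' @param tefree_de Logical vector: for every candidate TE-free region,
#'   whether its associated gene is differentially expressed.
#' @param set_size Number of TE-free regions per null draw (defaults to the
#'   TE-associated set size, i.e. `te_de_count`'s denominator must match).
#' @param n_perm Number of draws (default 1000).
#' @param seed Integer seed.
#' @return As [permutation_pvalue()] with the null attached; if no TE-free
#'   regions are available the result is flagged degenerate.
#' @export
tefree_expression_permutation <- function(te_de_count, tefree_de, set_size,
                                          n_perm = 1000L, seed = 1L) {
  if (length(tefree_de) == 0L) {
    res <- data.frame(observed = te_de_count, n_null = 0L, count_ge = NA,
                      p = NA_real_, seed = seed)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  if (set_size > length(tefree_de)) {
    stop("set_size exceeds the number of TE-free regions", call. = FALSE)
  }
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b)
    sum(tefree_de[sample.int(length(tefree_de), set_size)]),
    numeric(1))
  res <- permutation_pvalue(te_de_count, null)
  res$seed <- seed
  attr(res, "null") <- null
  res
}
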