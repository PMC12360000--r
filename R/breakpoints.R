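# Breakpoint projection: locate each polymorphic TE's insertion junction in
# the genomes that lack it, from the placements of its +/-flank_bp flanking
# sequences. Real data flows in as PAF alignments; for synthetic genomes a
# built-in exact-substring mapper removes the need for an external aligner.

#' Extract TE flanking sequences from a carrier genome
#'
#' @param genome_seq Carrier genome sequence (single character string,
#'   0-based coordinates).
#' @param start,end TE interval in the carrier genome (0-based half-open).
#' @param flank_bp Flank length (default 500).
#' @return A list with `up`, `down`, `concat` character sequences and a
#'   logical `truncated` flag set when the TE lies closer than `flank_bp` to
#'   a contig end (the flank is shortened, with a warning).
#' @export
extract_flanks <- function(genome_seq, start, end, flank_bp = 500L) {
  L <- nchar(genome_seq)
  stopifnot(start >= 0, end > start, end <= L)
  up_from <- max(0L, start - flank_bp)
  down_to <- min(L, end + flank_bp)
  truncated <- (start - flank_bp < 0L) || (end + flank_bp > L)
  if (truncated) {
    warning("TE within ", flank_bp, " bp of a contig end: flank truncated",
            call. = FALSE)
  }
  up <- substr(genome_seq, up_from + 1L, start)
  down <- substr(genome_seq, end + 1L, down_to)
  list(up = up, down = down, concat = paste0(up, down),
       truncated = truncated)
}

#' Map flank sequences into a target genome by exact matching
#'
#' Finds all exact occurrences of the upstream, downstream and concatenated
#' flank in the target sequence. When the concatenation has no contiguous
#' exact match but the two flanks each place uniquely on the same chromosome
#' in order, a spanning placement is synthesized for the concatenated query
#' (as a spliced aligner would report), so junction indels are adjudicated by
#' the gap rule in [call_breakpoint()] rather than failing outright.
#'
#' @param flanks Result of [extract_flanks()].
#' @param target Target genome sequence: character string or a
#'   `Biostrings::DNAString` (pre-convert when mapping many TEs into the
#'   same genome).
#' @param target_name Chromosome/contig name reported in the records.
#' @param te_id TE identifier used to form query names (`<te_id>|up` etc.).
#' @return Alignment records in the schema of [read_alignments_paf()].
#' @export
map_flanks_exact <- function(flanks, target, target_name = "chr",
                             te_id = "te") {
  subj <- if (inherits(target, "DNAString")) target
          else Biostrings::DNAString(target)
  tlen <- length(subj)
  hits <- function(q) {
    if (nchar(q) == 0L) return(integer())
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(q),
                                               subj)) - 1L
  }
  rec <- function(role, q, tstart) {
    n <- nchar(q)
    if (length(tstart) == 0L) return(NULL)
    data.frame(query = paste0(te_id, "|", role), qlen = n, qstart = 0L,
               qend = n, strand = "+", target = target_name, tlen = tlen,
               tstart = as.integer(tstart), tend = as.integer(tstart) + n,
               nmatch = n, alen = n, mapq = 60L, primary = TRUE,
               stringsAsFactors = FALSE)
  }
  up_at <- hits(flanks$up)
  down_at <- hits(flanks$down)
  cat_at <- hits(flanks$concat)
  out <- list(rec("up", flanks$up, up_at),
              rec("down", flanks$down, down_at))
  if (length(cat_at)) {
    out <- c(out, list(rec("concat", flanks$concat, cat_at)))
  } else if (length(up_at) == 1L && length(down_at) == 1L &&
             down_at + nchar(flanks$down) > up_at) {
    n <- nchar(flanks$concat)
    out <- c(out, list(data.frame(
      query = paste0(te_id, "|concat"), qlen = n, qstart = 0L, qend = n,
      strand = "+", target = target_name, tlen = tlen,
      tstart = as.integer(up_at), tend = as.integer(down_at) +
        nchar(flanks$down), nmatch = n, alen = n, mapq = 60L,
      primary = TRUE, stringsAsFactors = FALSE)))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(read_alignments_paf(textConnection(character()))[0, ])
  }
  do.call(rbind, out)
}

#' Call a TE breakpoint in a target genome from flank alignments
#'
#' A breakpoint is `unique` when each of the three queries (upstream,
#' downstream, concatenated flank) has exactly one accepted placement, the
#' up/down placements lie on the same chromosome and strand in the correct
#' order, and the signed gap (> 0) or overlap (< 0) between the upstream end
#' and downstream start does not exceed `tolerance_bp` in absolute value.
#' The called position is the midpoint of the junction interval, rounded
#' toward the upstream side.
#'
#' Accepted placements are primary alignments with mapping quality at least
#' `min_mapq` covering at least `min_flank_coverage` of the query.
#'
#' @param alns Alignment records for one TE (schema of
#'   [read_alignments_paf()]); query names must end in `|up`, `|down`,
#'   `|concat`.
#' @param tolerance_bp Maximum |gap/overlap| in bp (default 50).
#' @param min_mapq,min_flank_coverage Acceptance thresholds for a placement.
#' @return A one-row data frame: `status` (unique / ambiguous / unmapped /
#'   inconsistent), `chrom`, `position` (0-based junction, `NA` unless
#'   unique), `gap_bp`.
#' @export
call_breakpoint <- function(alns, tolerance_bp = 50L, min_mapq = 30L,
                            min_flank_coverage = 0.8) {
  res <- function(status, chrom = NA_character_, position = NA_integer_,
                  gap = NA_integer_) {
    data.frame(status = status, chrom = chrom, position = position,
               gap_bp = gap, stringsAsFactors = FALSE)
  }
  role <- sub(".*\\|", "", alns$query)
  acc <- alns$primary & alns$mapq >= min_mapq &
    (alns$qend - alns$qstart) / alns$qlen >= min_flank_coverage
  pick <- function(r) alns[role == r & acc, , drop = FALSE]
  up <- pick("up"); down <- pick("down"); concat <- pick("concat")
  ns <- c(nrow(up), nrow(down), nrow(concat))
  if (any(ns > 1L)) return(res("ambiguous"))
  if (any(ns == 0L)) return(res("unmapped"))
  if (up$target != down$target || up$strand != down$strand ||
      concat$target != up$target) {
    return(res("inconsistent"))
  }
  if (up$strand == "+") {
    gap <- down$tstart - up$tend
    junction <- c(up$tend, down$tstart)
  } else {
    gap <- up$tstart - down$tend
    junction <- c(down$tend, up$tstart)
  }
  if (abs(gap) > tolerance_bp) return(res("inconsistent", gap = gap))
  pos <- as.integer(floor((junction[1L] + junction[2L]) / 2))
  res("unique", chrom = up$target, position = pos, gap = as.integer(gap))
}

#' Project all polymorphic TE breakpoints across a cohort
#'
#' For each TE, flanks are extracted from the first carrier strain's genome
#' and mapped into every non-carrier strain with the exact-substring mapper;
#' [call_breakpoint()] adjudicates each placement set.
#'
#' @param cohort A `teepi_cohort` generated with sequences.
#' @param config A [teepi_config()].
#' @return Data frame: `te_id`, `source_strain`, `target_strain`, `status`,
#'   `chrom`, `position`, `gap_bp`.
#' @export
project_breakpoints <- function(cohort, config = teepi_config()) {
  if (is.null(cohort$genomes)) {
    stop("cohort was generated without sequences", call. = FALSE)
  }
  pres <- attr(cohort$tes, "presence")
  targets <- lapply(cohort$genomes, Biostrings::DNAString)
  out <- vector("list", nrow(cohort$tes) * ncol(pres))
  k <- 0L
  for (i in seq_len(nrow(cohort$tes))) {
    te <- cohort$tes$te_id[i]
    carriers <- colnames(pres)[pres[i, ] == "carrier"]
    noncarriers <- colnames(pres)[pres[i, ] == "non-carrier"]
    if (!length(carriers) || !length(noncarriers)) next
    src <- carriers[1L]
    ci <- cohort$carrier_intervals
    ci <- ci[ci$te_id == te & ci$strain == src, ]
    fl <- extract_flanks(cohort$genomes[[src]], ci$start, ci$end,
                         config$flank_bp)
    for (s in noncarriers) {
      alns <- map_flanks_exact(fl, targets[[s]], cohort$chrom, te)
      bc <- call_breakpoint(alns, config$breakpoint_tolerance_bp,
                            config$min_mapq, config$min_flank_coverage)
      k <- k + 1L
      out[[k]] <- cbind(data.frame(te_id = te, source_strain = src,
                                   target_strain = s,
                                   stringsAsFactors = FALSE), bc)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
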