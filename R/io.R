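# File formats. All coordinates are 0-based half-open (BED convention)
# internally; GFF3 input is converted on read.

#' Construct a signal track
#'
#' A signal track holds binned fold-enrichment values for one strain, body
#' part, histone mark and replicate. Bin `i` (1-based vector index) covers
#' `[(i-1)*bin_bp, i*bin_bp)` on its chromosome; bins with no data are `NA`,
#' never 0, so assembly gaps cannot masquerade as depletion.
#'
#' @param bins Named list mapping chromosome to a numeric vector of bin
#'   values (`NA` = missing).
#' @param bin_bp Bin width in bp.
#' @param strain,body_part,mark,replicate Track metadata.
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(bins, bin_bp = 10L, strain = NA_character_,
                         body_part = NA_character_, mark = NA_character_,
                         replicate = NA_integer_) {
  stopifnot(is.list(bins), !is.null(names(bins)), bin_bp > 0)
  for (v in bins) {
    if (any(v < 0, na.rm = TRUE)) {
      stop("signal bins must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(strain = strain, body_part = body_part, mark = mark,
         replicate = as.integer(replicate), bin_bp = as.integer(bin_bp),
         bins = bins),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s / %s / %s / rep %s; %d bp bins on %d chrom(s)\n",
              x$strain, x$body_part, x$mark, x$replicate, x$bin_bp,
              length(x$bins)))
  invisible(x)
}

#' Read TE annotations and a presence/absence matrix
#'
#' Reads a BED6+ file of TE insertions (columns: chrom, start, end, te_id,
#' score, strand, family, order, and optionally length_class and
#' population_frequency) together with a TSV presence matrix (rows = te_id,
#' columns = strains, entries in carrier / non-carrier / unknown).
#'
#' @param path BED6+ file of TE insertions.
#' @param presence_path TSV presence matrix (first column `te_id`).
#' @return A data frame with one row per TE (columns `te_id`, `family`,
#'   `order`, `chrom`, `start`, `end`, `strand`, `length_class`,
#'   `population_frequency`) plus a `presence` attribute: a character matrix
#'   te_id x strain.
#' @export
read_te_annotations <- function(path, presence_path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    tes <- data.frame(te_id = character(), family = character(),
                      order = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), length_class = character(),
                      population_frequency = double(),
                      stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 8L)) {
      stop("malformed TE BED line ", which(nf < 8L)[1L],
           ": expected >= 8 tab-separated fields", call. = FALSE)
    }
    grab <- function(i) vapply(fields, `[[`, character(1), i)
    start <- suppressWarnings(as.integer(grab(2)))
    end <- suppressWarnings(as.integer(grab(3)))
    if (anyNA(start) || anyNA(end)) {
      stop("malformed TE BED line ",
           which(is.na(start) | is.na(end))[1L],
           ": non-integer coordinates", call. = FALSE)
    }
    tes <- data.frame(
      te_id = grab(4), family = grab(7), order = grab(8),
      chrom = grab(1), start = start, end = end, strand = grab(6),
      length_class = if (all(nf >= 9L)) grab(9) else NA_character_,
      population_frequency = if (all(nf >= 10L))
        as.numeric(grab(10)) else NA_real_,
      stringsAsFactors = FALSE
    )
    bad <- which(!(tes$start >= 0L & tes$end > tes$start))
    if (length(bad)) {
      stop("malformed TE BED line ", bad[1L],
           ": need 0 <= start < end", call. = FALSE)
    }
    if (anyDuplicated(tes$te_id)) {
      stop("duplicate te_id in ", path, call. = FALSE)
    }
  }
  pres <- utils::read.table(presence_path, header = TRUE, sep = "\t",
                            row.names = 1L, check.names = FALSE,
                            stringsAsFactors = FALSE)
  pres <- as.matrix(pres)
  missing_in_bed <- setdiff(rownames(pres), tes$te_id)
  if (length(missing_in_bed)) {
    stop("te_id in presence matrix missing from BED: ",
         paste(utils::head(missing_in_bed, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_state <- setdiff(unique(as.vector(pres)),
                       c("carrier", "non-carrier", "unknown"))
  if (length(bad_state)) {
    stop("invalid presence state(s): ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  pres <- pres[match(tes$te_id, rownames(pres)), , drop = FALSE]
  rownames(pres) <- tes$te_id
  attr(tes, "presence") <- pres
  tes
}

#' Write TE annotations and presence matrix
#'
#' Inverse of [read_te_annotations()].
#'
#' @param tes TE data frame with `presence` attribute.
#' @param path,presence_path Output paths.
#' @export
write_te_annotations <- function(tes, path, presence_path) {
  bed <- data.frame(tes$chrom, tes$start, tes$end, tes$te_id, 0L, tes$strand,
                    tes$family, tes$order, tes$length_class,
                    tes$population_frequency)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pres <- attr(tes, "presence")
  utils::write.table(
    data.frame(te_id = rownames(pres), pres, check.names = FALSE),
    presence_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}

#' Read a bedGraph file into a binned signal track
#'
#' Each output bin's value is the coverage-weighted mean of the bedGraph
#' intervals overlapping it; bins with no overlapping interval are missing
#' (`NA`), not zero.
#'
#' @param path bedGraph file (chrom, start, end, value; no header required,
#'   `track`/`#` lines are skipped).
#' @param bin_bp Bin width in bp (default 10).
#' @param strain,body_part,mark,replicate Metadata attached to the track.
#' @return A [signal_track()].
#' @export
read_signal_track <- function(path, bin_bp = 10L, strain = NA_character_,
                              body_part = NA_character_, mark = NA_character_,
                              replicate = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (length(lines) == 0L) {
    return(signal_track(structure(list(), names = character()), bin_bp,
                        strain, body_part, mark, replicate))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("malformed bedGraph line ", which(lengths(fields) < 4L)[1L],
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  value <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  if (any(value < 0)) stop("negative signal value in bedGraph", call. = FALSE)
  bins <- list()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    bins[[ch]] <- .bin_intervals(start[i], end[i], value[i], bin_bp)
  }
  signal_track(bins, bin_bp, strain, body_part, mark, replicate)
}

# Coverage-weighted binning of non-overlapping intervals on one chromosome.
.bin_intervals <- function(start, end, value, bin_bp) {
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- value[o]
  if (any(start[-1] < end[-length(end)])) {
    stop("overlapping bedGraph intervals", call. = FALSE)
  }
  nbin <- ceiling(max(end) / bin_bp)
  first_bin <- floor(start / bin_bp)          # 0-based bin index
  last_bin <- floor((end - 1) / bin_bp)
  nper <- last_bin - first_bin + 1
  row <- rep.int(seq_along(start), nper)
  bin <- first_bin[row] + (sequence(nper) - 1)
  ov <- pmin(end[row], (bin + 1) * bin_bp) - pmax(start[row], bin * bin_bp)
  idx <- as.integer(bin + 1)
  ws <- numeric(nbin)                          # sum of value * overlap
  cov <- numeric(nbin)                         # covered bp per bin
  wst <- rowsum(ov * value[row], idx)
  covt <- rowsum(ov, idx)
  at <- as.integer(rownames(wst))
  ws[at] <- wst[, 1L]
  cov[at] <- covt[, 1L]
  out <- rep(NA_real_, nbin)
  has <- cov > 0
  out[has] <- ws[has] / cov[has]
  out
}

#' Write a signal track as bedGraph
#'
#' Adjacent bins are not merged; missing bins produce no line. Inverse of
#' [read_signal_track()] at the same bin width.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @export
write_signal_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- track$bin_bp
  for (ch in names(track$bins)) {
    v <- track$bins[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, (keep - 1L) * b, keep * b,
                       v[keep]), con)
  }
  invisible(NULL)
}

#' Read alignment records in PAF format
#'
#' Parses the 12 mandatory PAF columns plus the `tp:A:` tag (primary vs
#' secondary) when present.
#'
#' @param path PAF file.
#' @return A data frame with columns `query`, `qlen`, `qstart`, `qend`,
#'   `strand`, `target`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`,
#'   `primary`, ordered and grouped by query name.
#' @export
read_alignments_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), target = character(),
                      tlen = integer(), tstart = integer(), tend = integer(),
                      nmatch = integer(), alen = integer(), mapq = integer(),
                      primary = logical(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop("PAF parse error at line ", which(lengths(fields) < 12L)[1L],
         ": fewer than 12 fields", call. = FALSE)
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  primary <- vapply(fields, function(f) {
    tp <- grep("^tp:A:", f, value = TRUE)
    if (length(tp) == 0L) TRUE else substring(tp[1L], 6L, 6L) == "P"
  }, logical(1))
  out <- data.frame(
    query = grab(1), qlen = as.integer(grab(2)),
    qstart = as.integer(grab(3)), qend = as.integer(grab(4)),
    strand = grab(5), target = grab(6), tlen = as.integer(grab(7)),
    tstart = as.integer(grab(8)), tend = as.integer(grab(9)),
    nmatch = as.integer(grab(10)), alen = as.integer(grab(11)),
    mapq = as.integer(grab(12)), primary = primary,
    stringsAsFactors = FALSE
  )
  out[order(match(out$query, unique(out$query))), , drop = FALSE]
}

#' Read a gene count matrix with sample metadata in the header
#'
#' Sample columns must be named `strain_bodypart_replicate` (e.g.
#' `AKA_head_1`); metadata are parsed from these tokens.
#'
#' @param path TSV with first column `gene_id`.
#' @return A list with `counts` (integer matrix gene x sample) and `samples`
#'   (data frame: `sample`, `strain`, `body_part`, `replicate`).
#' @export
read_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1L]])) {
    stop("duplicate gene id in ", path, call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1L]]
  samples <- parse_sample_names(colnames(m))
  list(counts = m, samples = samples)
}

#' Parse `strain_bodypart_replicate` sample tokens
#'
#' @param x Character vector of sample names.
#' @return Data frame with `sample`, `strain`, `body_part`, `replicate`.
#' @export
parse_sample_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("sample name not in strain_bodypart_replicate form: ",
         x[which(lengths(parts) < 3L)[1L]], call. = FALSE)
  }
  n <- lengths(parts)
  data.frame(
    sample = x,
    strain = vapply(seq_along(parts), function(i)
      paste(parts[[i]][seq_len(n[i] - 2L)], collapse = "_"), character(1)),
    body_part = vapply(seq_along(parts), function(i)
      parts[[i]][n[i] - 1L], character(1)),
    replicate = as.integer(vapply(seq_along(parts), function(i)
      parts[[i]][n[i]], character(1))),
    stringsAsFactors = FALSE
  )
}

#' Write a count matrix
#' @param counts Integer matrix gene x sample.
#' @param path Output TSV path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(
    data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}

#' Read gene annotations from GFF3
#'
#' Retains `gene`, `CDS`, `five_prime_UTR`, `three_prime_UTR` and `exon`
#' features; 1-based closed GFF coordinates are converted to the package's
#' 0-based half-open convention on read.
#'
#' @param path GFF3 file. Feature attributes must carry `ID=` (genes) or
#'   `Parent=` (sub-features).
#' @return Data frame: `gene_id`, `feature`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keep_feats <- c("gene", "CDS", "five_prime_UTR", "three_prime_UTR", "exon")
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), feature = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) {
    stop("malformed GFF3 line ", which(lengths(fields) < 9L)[1L],
         call. = FALSE)
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  feature <- grab(3)
  sel <- feature %in% keep_feats
  attr9 <- grab(9)[sel]
  id <- sub(".*ID=([^;]+).*", "\\1", attr9)
  parent <- ifelse(grepl("Parent=", attr9),
                   sub(".*Parent=([^;]+).*", "\\1", attr9), NA_character_)
  gene_id <- ifelse(feature[sel] == "gene", id, parent)
  data.frame(
    gene_id = gene_id,
    feature = feature[sel],
    chrom = grab(1)[sel],
    start = as.integer(grab(4)[sel]) - 1L,   # to 0-based half-open
    end = as.integer(grab(5)[sel]),
    strand = grab(7)[sel],
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations as GFF3
#'
#' Inverse of [read_gene_annotations()]; converts back to 1-based closed
#' coordinates.
#'
#' @param genes Data frame as returned by [read_gene_annotations()].
#' @param path Output path.
#' @export
write_gene_annotations <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attr9 <- ifelse(genes$feature == "gene",
                  paste0("ID=", genes$gene_id),
                  paste0("ID=", genes$gene_id, ":", genes$feature, ":",
                         seq_len(nrow(genes)), ";Parent=", genes$gene_id))
  writeLines(sprintf("%s\tteepi\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     genes$chrom, genes$feature, genes$start + 1L, genes$end,
                     genes$strand, attr9), con)
  invisible(NULL)
}

#' Write a result table as TSV
#'
#' Columns are written in their current (deterministic) order with a header;
#' [read_results()] round-trips the table.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(NULL)
}

#' Read a result table written by [write_results()]
#' @param path TSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
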