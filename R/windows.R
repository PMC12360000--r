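# Window profiles: binned fold-enrichment in n non-overlapping windows of
# window_bp on each side of an anchor. In a carrier genome the anchor is the
# TE span (windows measured outward from its outer edges, the TE body
# excluded); in a non-carrier genome it is the projected breakpoint, so the
# two genomes' windows cover homologous flank sequence.

#' Average replicate signal tracks into a single track
#'
#' Combines replicate tracks bin-by-bin with the mean (or median), ignoring
#' missing bins; a bin missing in every replicate stays missing.
#'
#' @param tracks List of [signal_track()] objects with identical bin width
#'   and chromosomes.
#' @param agg `"mean"` (default) or `"median"`.
#' @return A single [signal_track()] with `replicate = NA`.
#' @export
average_replicates <- function(tracks, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  stopifnot(length(tracks) >= 1L)
  if (length(unique(vapply(tracks, `[[`, integer(1), "bin_bp"))) != 1L) {
    stop("replicate tracks disagree on bin width", call. = FALSE)
  }
  t1 <- tracks[[1L]]
  bins <- lapply(names(t1$bins), function(ch) {
    vs <- lapply(tracks, function(t) t$bins[[ch]])
    n <- max(lengths(vs))
    m <- vapply(vs, function(v) c(v, rep(NA_real_, n - length(v))),
                numeric(n))
    if (!is.matrix(m)) m <- matrix(m, nrow = n)
    out <- if (agg == "mean") rowMeans(m, na.rm = TRUE)
           else apply(m, 1L, stats::median, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  })
  names(bins) <- names(t1$bins)
  signal_track(bins, t1$bin_bp, strain = t1$strain, body_part = t1$body_part,
               mark = t1$mark, replicate = NA_integer_)
}

#' Build a two-sided window profile around an anchor
#'
#' @param track A replicate-averaged [signal_track()], or a list of replicate
#'   tracks (averaged internally with `config$replicate_agg`).
#' @param chrom Chromosome of the anchor.
#' @param anchor_start,anchor_end Anchor interval, 0-based half-open: the TE
#'   span in a carrier, or `start == end ==` breakpoint in a non-carrier.
#' @param config A [teepi_config()].
#' @param te_id Optional TE id carried in the result.
#' @return An object of class `"window_profile"`: matrices `left` and
#'   `right` of dimension (bins per window) x `n_windows_per_side`; column
#'   `i` is window `i` (1 = innermost), rows ordered by increasing genomic
#'   coordinate; bins beyond the contig are `NA`.
#' @export
build_window_profile <- function(track, chrom, anchor_start, anchor_end,
                                 config = teepi_config(), te_id = NA) {
  if (!inherits(track, "signal_track")) {
    track <- average_replicates(track, config$replicate_agg)
  }
  stopifnot(anchor_end >= anchor_start)
  v <- track$bins[[chrom]]
  if (is.null(v)) stop("chromosome ", chrom, " absent from track",
                       call. = FALSE)
  b <- track$bin_bp
  W <- config$window_bp
  nw <- config$n_windows_per_side
  nb <- W %/% b
  fetch <- function(start_offsets) {
    # start_offsets: genomic start of each bin; NA outside [0, len)
    idx <- floor(start_offsets / b) + 1L
    out <- rep(NA_real_, length(idx))
    ok <- idx >= 1L & idx <= length(v)
    out[ok] <- v[idx[ok]]
    out
  }
  side <- function(anchor, dirn) {
    m <- matrix(NA_real_, nb, nw)
    for (i in seq_len(nw)) {
      ws <- if (dirn < 0) anchor - i * W else anchor + (i - 1L) * W
      m[, i] <- fetch(ws + (seq_len(nb) - 1L) * b)
    }
    m
  }
  structure(list(
    te_id = te_id, strain = track$strain, body_part = track$body_part,
    mark = track$mark, chrom = chrom, anchor_start = anchor_start,
    anchor_end = anchor_end, window_bp = W, bin_bp = b,
    n_windows = nw,
    left = side(anchor_start, -1L),
    right = side(anchor_end, +1L)
  ), class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf(
    "window_profile %s (%s): %d x %d bp windows per side around %s:%d-%d\n",
    x$te_id, x$strain, x$n_windows, x$window_bp, x$chrom, x$anchor_start,
    x$anchor_end))
  invisible(x)
}

#' Fraction of missing bins per window
#' @param profile A `window_profile`.
#' @return List with `left` and `right` vectors of length `n_windows`.
#' @export
window_missingness <- function(profile) {
  list(left = colMeans(is.na(profile$left)),
       right = colMeans(is.na(profile$right)))
}

#' Compute a cohort metaprofile with LOESS smoothing
#'
#' For every bin offset in `[-n*W, +n*W)` relative to the anchor, takes the
#' median signal across the contributing profiles (TEs with a missing value
#' at that offset are dropped for that offset only), then fits a degree-1
#' LOESS (tricube weights) with span `config$loess_span` over the offsets.
#'
#' @param profiles Non-empty list of `window_profile` objects with identical
#'   geometry.
#' @param config A [teepi_config()].
#' @return Data frame: `offset_bp` (bin start relative to the anchor),
#'   `median`, `smoothed`, `n` (contributing TEs).
#' @export
compute_metaprofile <- function(profiles, config = teepi_config()) {
  if (length(profiles) == 0L) stop("empty profile group", call. = FALSE)
  p1 <- profiles[[1L]]
  nb <- nrow(p1$left)
  nw <- p1$n_windows
  b <- p1$bin_bp
  flat <- vapply(profiles, function(p) {
    stopifnot(p$n_windows == nw, nrow(p$left) == nb)
    # left: windows nw..1 left-to-right in genome order, then right 1..nw
    c(as.vector(p$left[, nw:1, drop = FALSE]), as.vector(p$right))
  }, numeric(2L * nb * nw))
  if (!is.matrix(flat)) flat <- matrix(flat, ncol = length(profiles))
  offset <- c(-(nw * nb):-1L, 0L:(nw * nb - 1L)) * b
  med <- apply(flat, 1L, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  n_contrib <- rowSums(!is.na(flat))
  ok <- !is.na(med)
  sm <- rep(NA_real_, length(med))
  if (sum(ok) >= 10L) {
    fit <- stats::loess(med[ok] ~ offset[ok], span = config$loess_span,
                        degree = 1, family = "gaussian")
    sm[ok] <- stats::predict(fit)
  } else {
    sm[ok] <- med[ok]
  }
  data.frame(offset_bp = offset, median = med, smoothed = sm, n = n_contrib)
}
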