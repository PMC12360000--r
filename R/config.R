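#' Pipeline configuration
#'
#' Collects the scalar parameters used throughout the pipeline: flank size for
#' breakpoint projection, window geometry for the ChIP profiles, significance
#' thresholds, permutation sampling depth, and family-test eligibility gates.
#'
#' @param flank_bp Length in bp of the upstream/downstream flanks extracted
#'   around each TE for breakpoint projection (default 500).
#' @param breakpoint_tolerance_bp Maximum absolute gap/overlap in bp allowed
#'   between the projected upstream and downstream flanks (default 50).
#' @param window_bp Width of one profile window in bp (default 1000).
#' @param n_windows_per_side Number of non-overlapping windows on each side of
#'   a TE (default 20, i.e. profiles reach 20 kb out).
#' @param bin_bp Signal bin width in bp; must divide `window_bp` (default 10).
#' @param alpha Per-window significance level for the rank-sum tests
#'   (default 0.05). No multiple-testing correction is applied across windows.
#' @param z_threshold Absolute z-score above which a TE-gene expression link is
#'   called significant (default 1.96).
#' @param n_permutations Number of null draws for the permutation tests
#'   (default 1000).
#' @param loess_span LOESS span (fraction of offsets) for metaprofile
#'   smoothing (default 0.10).
#' @param min_copies_family Minimum genome-wide copy number for a family to
#'   enter the family proportion test (default 20).
#' @param min_effect_copies_family Minimum number of copies with an epigenetic
#'   effect for a family to enter the test (default 8).
#' @param min_bins_per_window Minimum non-missing bins required in a window
#'   (in both genomes) for the window test to be computed (default 50 of the
#'   100 bins in a 1 kb window at 10 bp resolution).
#' @param min_mapq Minimum mapping quality for a flank placement to be
#'   accepted during breakpoint calling (default 30).
#' @param min_flank_coverage Minimum fraction of the flank covered by an
#'   accepted placement (default 0.8).
#' @param replicate_agg How replicate tracks are combined per bin: `"mean"`
#'   (default) or `"median"`.
#' @param pool_percentage_sides If `TRUE` (default) the percentage change
#'   pools the bins of both innermost windows before taking medians; otherwise
#'   it is computed per side and averaged.
#' @param expressed_min_cpm Minimum mean normalized abundance (counts per
#'   million) for a gene to count as expressed in a body part (default 1).
#' @param pool_replicates If `TRUE` (default) the z-score groups pool all
#'   replicates of all carrier (resp. non-carrier) strains; if `FALSE`
#'   replicates are first averaged per strain.
#' @param rng_seed Integer seed used by seeded operations when no explicit
#'   seed is passed (default 1).
#'
#' @return A validated list of class `"teepi_config"`.
#' @examples
#' cfg <- teepi_config(alpha = 0.01)
#' cfg$alpha
#' @export
teepi_config <- function(flank_bp = 500L,
                         breakpoint_tolerance_bp = 50L,
                         window_bp = 1000L,
                         n_windows_per_side = 20L,
                         bin_bp = 10L,
                         alpha = 0.05,
                         z_threshold = 1.96,
                         n_permutations = 1000L,
                         loess_span = 0.10,
                         min_copies_family = 20L,
                         min_effect_copies_family = 8L,
                         min_bins_per_window = 50L,
                         min_mapq = 30L,
                         min_flank_coverage = 0.8,
                         replicate_agg = c("mean", "median"),
                         pool_percentage_sides = TRUE,
                         expressed_min_cpm = 1,
                         pool_replicates = TRUE,
                         rng_seed = 1L) {
  replicate_agg <- match.arg(replicate_agg)
  cfg <- list(
    flank_bp = as.integer(flank_bp),
    breakpoint_tolerance_bp = as.integer(breakpoint_tolerance_bp),
    window_bp = as.integer(window_bp),
    n_windows_per_side = as.integer(n_windows_per_side),
    bin_bp = as.integer(bin_bp),
    alpha = alpha,
    z_threshold = z_threshold,
    n_permutations = as.integer(n_permutations),
    loess_span = loess_span,
    min_copies_family = as.integer(min_copies_family),
    min_effect_copies_family = as.integer(min_effect_copies_family),
    min_bins_per_window = as.integer(min_bins_per_window),
    min_mapq = as.integer(min_mapq),
    min_flank_coverage = min_flank_coverage,
    replicate_agg = replicate_agg,
    pool_percentage_sides = isTRUE(pool_percentage_sides),
    expressed_min_cpm = expressed_min_cpm,
    pool_replicates = isTRUE(pool_replicates),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "teepi_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg A `teepi_config` list.
#' @return `cfg`, invisibly unchanged, or an error describing the violated
#'   constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "teepi_config"))
  pos <- c("flank_bp", "breakpoint_tolerance_bp", "window_bp",
           "n_windows_per_side", "bin_bp", "n_permutations",
           "min_copies_family", "min_effect_copies_family",
           "min_bins_per_window")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive integer", call. = FALSE)
    }
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("config field 'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (!(cfg$loess_span > 0 && cfg$loess_span <= 1)) {
    stop("config field 'loess_span' must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$window_bp %% cfg$bin_bp != 0L) {
    stop("'bin_bp' must divide 'window_bp'", call. = FALSE)
  }
  if (cfg$z_threshold <= 0) {
    stop("config field 'z_threshold' must be positive", call. = FALSE)
  }
  if (!(cfg$min_flank_coverage > 0 && cfg$min_flank_coverage <= 1)) {
    stop("config field 'min_flank_coverage' must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file whose keys are `teepi_config()` arguments.
#' @return A validated `teepi_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(teepi_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(teepi_config, vals)
}
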