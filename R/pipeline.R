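# End-to-end orchestration on a synthetic cohort: every stage writes its
# result table to the output directory so each step of the chain is
# auditable and restartable.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort from `spec`, simulates signal and expression, projects
#' breakpoints (optionally), calls per-TE epigenetic effects, links affected
#' TEs to genes, computes expression z-scores, runs the positional
#' permutation test, family proportion tests, and writes all result tables,
#' a Table-1-style summary (class x body part x mark with mean percentage
#' and spread), quadrant counts, and a run manifest.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created).
#' @param config A [teepi_config()].
#' @param use_breakpoints If `TRUE` (default), non-carrier anchors come from
#'   [project_breakpoints()] on the generated genomes; if `FALSE`, from the
#'   generator's recorded junctions (faster; no sequences materialized).
#' @param body_parts,marks Conditions to simulate and call (default: all in
#'   `spec`).
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `breakpoints`, `effects`, `links`, `permutation`, `family_tests`,
#'   `summary`, `quadrants`, `manifest`).
#' @export
run_pipeline <- function(spec, out_dir, config = teepi_config(),
                         use_breakpoints = TRUE,
                         body_parts = spec$body_parts, marks = spec$marks) {
  validate_config(config)
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("generate_cohort",
                  generate_cohort(spec, with_sequences = use_breakpoints))
  tracks <- stage("simulate_signal",
                  simulate_signal(cohort, body_parts, marks))
  expr <- stage("simulate_expression", simulate_expression(cohort))

  bps <- NULL
  anchors <- "truth"
  if (use_breakpoints) {
    bps <- stage("breakpoints", project_breakpoints(cohort, config))
    write_results(bps, file.path(out_dir, "breakpoints.tsv"))
    anchors <- bps
  }

  eff <- stage("effect_calling",
               call_all_effects(cohort, tracks, config, anchors))
  write_results(eff$effect_calls, file.path(out_dir, "effect_calls.tsv"))
  write_results(eff$pair_calls, file.path(out_dir, "pair_calls.tsv"))

  links <- stage("expression_link", {
    factors <- compute_tmm_factors(expr$counts)
    norm <- cpm_tmm(expr$counts, factors)
    l <- link_cohort_genes(cohort, eff$effect_calls)
    te_gene_zscores(l, norm, expr$samples, attr(cohort$tes, "presence"),
                    config)
  })
  write_results(links, file.path(out_dir, "te_gene_links.tsv"))

  perm <- NULL
  if (nrow(links) > 0L) {
    focal <- unique(links$te_id[links$class == "enrichment" &
                                  links$mark == "H3K9me3"])
    if (length(focal) >= 2L &&
        length(unique(links$te_id)) > length(focal)) {
      perm <- stage("positional_permutation", tryCatch(
        positional_permutation_test(links, focal, config$n_permutations,
                                    seed = config$rng_seed,
                                    z_threshold = config$z_threshold),
        error = function(e) NULL))
      if (!is.null(perm)) {
        write_results(perm, file.path(out_dir, "positional_permutation.tsv"))
      }
    }
  }

  fam <- stage("family_stats", {
    per_te <- unique(eff$effect_calls[
      eff$effect_calls$class != "excluded", c("te_id"), drop = FALSE])
    has_eff <- vapply(per_te$te_id, function(t) {
      any(eff$effect_calls$te_id == t &
            eff$effect_calls$class %in% c("enrichment", "depletion"))
    }, logical(1))
    per_te$family <- cohort$tes$family[match(per_te$te_id,
                                             cohort$tes$te_id)]
    family_tests_all(per_te, has_eff, config)
  })
  write_results(fam, file.path(out_dir, "family_tests.tsv"))

  summary_tab <- stage("summary", {
    e <- eff$effect_calls
    e <- e[e$class %in% c("enrichment", "depletion"), , drop = FALSE]
    if (nrow(e)) {
      agg <- stats::aggregate(
        cbind(percentage, spread) ~ class + mark + body_part, data = e,
        FUN = mean)
      agg$n <- stats::aggregate(te_id ~ class + mark + body_part, data = e,
                                FUN = length)$te_id
      agg
    } else {
      data.frame(class = character(), mark = character(),
                 body_part = character(), percentage = double(),
                 spread = double(), n = integer())
    }
  })
  write_results(summary_tab, file.path(out_dir, "summary.tsv"))
  quad <- quadrant_counts(links)
  write_results(quad, file.path(out_dir, "quadrant_counts.tsv"))

  manifest <- list(
    spec = unclass(spec),
    config = unclass(config),
    seed = spec$seed,
    outputs = as.list(tools::md5sum(list.files(out_dir, "\\.tsv$",
                                               full.names = TRUE))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, breakpoints = bps, effects = eff,
                 links = links, permutation = perm, family_tests = fam,
                 summary = summary_tab, quadrants = quad,
                 manifest = manifest))
}
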