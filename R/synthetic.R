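# Synthetic multi-strain cohort with planted, recorded epigenetic effects.
# The generator mirrors the study design this package targets: 5 strains,
# 3 body parts (head, gut, ovary), 2 histone marks (H3K9me3, H3K27ac),
# 3 ChIP replicates, polymorphic TE insertions with boxcar enrichment or
# depletion kernels of known percentage and spread, and negative-binomial
# expression counts with TE-linked shifts.

#' Specify a synthetic cohort
#'
#' Defaults encode the emulated study design (5 strains x 3 body parts x
#' 2 marks x 3 replicates) and planted-effect magnitudes that sit inside the
#' ranges reported for natural TE insertions: +50% enrichment / -40%
#' depletion over a 3 kb spread, multiplicative lognormal signal noise with
#' sdlog 0.2, and negative-binomial counts with dispersion 0.1.
#'
#' @param n_strains Number of strains (>= 2; default 5).
#' @param n_te Number of polymorphic TE insertions (default 200).
#' @param body_parts Character vector of body parts (default head, gut,
#'   ovary).
#' @param marks Character vector of histone marks (default H3K9me3,
#'   H3K27ac).
#' @param replicates ChIP/RNA replicates per sample (>= 2; default 3).
#' @param effect_prob Named probabilities `c(enrichment=, depletion=)` that a
#'   given (TE, body part, mark) combination receives a planted effect;
#'   the remainder is "none".
#' @param pct_enrich,pct_deplete Planted signed percentage change in the
#'   innermost +/-1 kb for enrichment and depletion effects. `pct_deplete`
#'   must be > -100 (signal cannot go negative).
#' @param spread_kb Planted spread of the boxcar effect kernel, in kb
#'   (integer 1..20).
#' @param signal_sdlog Lognormal sdlog of the multiplicative signal noise
#'   around a baseline fold-enrichment of 1.0 (0 = noise-free).
#' @param expr_mean_log,expr_sd_log Lognormal parameters of per-gene baseline
#'   expression means.
#' @param nb_dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @param depth_sdlog Lognormal sdlog of per-sample sequencing-depth factors.
#' @param linked_lfc Magnitude of the planted log2 fold change for genes
#'   linked to TEs with effects; sign follows the mark (repressive H3K9me3
#'   enrichment lowers expression, active H3K27ac enrichment raises it, and
#'   depletions invert the sign).
#' @param gene_prob Probability that a TE has a nearby gene.
#' @param intron_prob Given a nearby gene, probability the TE sits inside the
#'   gene's intron rather than adjacent to the gene.
#' @param n_bg_genes Number of background genes placed far (> 20 kb) from all
#'   TEs (default `round(n_te / 2)`).
#' @param isolated If `TRUE` (default) TEs are spaced >= twice the full
#'   profile width apart so their windows never overlap.
#' @param chrom Chromosome name for the single synthetic chromosome.
#' @param chrom_length Ancestral chromosome length in bp; `NULL` (default)
#'   sizes it from `n_te` and the required spacing.
#' @param seed Integer seed; the whole cohort (sequences, truth, signal,
#'   counts) is a deterministic function of these parameters and the seed.
#'
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_strains = 5L,
                        n_te = 200L,
                        body_parts = c("head", "gut", "ovary"),
                        marks = c("H3K9me3", "H3K27ac"),
                        replicates = 3L,
                        effect_prob = c(enrichment = 0.35, depletion = 0.15),
                        pct_enrich = 50,
                        pct_deplete = -40,
                        spread_kb = 3L,
                        signal_sdlog = 0.2,
                        expr_mean_log = log(100),
                        expr_sd_log = 1,
                        nb_dispersion = 0.1,
                        depth_sdlog = 0.3,
                        linked_lfc = 1,
                        gene_prob = 0.7,
                        intron_prob = 0.3,
                        n_bg_genes = NULL,
                        isolated = TRUE,
                        chrom = "2L",
                        chrom_length = NULL,
                        seed = 1L) {
  if (n_strains < 2L) stop("n_strains must be >= 2", call. = FALSE)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (pct_deplete <= -100) {
    stop("pct_deplete must be > -100 (signal cannot become negative)",
         call. = FALSE)
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  stopifnot(all(c("enrichment", "depletion") %in% names(effect_prob)),
            sum(effect_prob) <= 1, all(effect_prob >= 0),
            spread_kb >= 1L, spread_kb <= 20L, signal_sdlog >= 0)
  if (is.null(n_bg_genes)) n_bg_genes <- max(2L, round(n_te / 2))
  spec <- list(
    n_strains = as.integer(n_strains), n_te = as.integer(n_te),
    body_parts = body_parts, marks = marks,
    replicates = as.integer(replicates),
    effect_prob = effect_prob, pct_enrich = pct_enrich,
    pct_deplete = pct_deplete, spread_kb = as.integer(spread_kb),
    signal_sdlog = signal_sdlog, expr_mean_log = expr_mean_log,
    expr_sd_log = expr_sd_log, nb_dispersion = nb_dispersion,
    depth_sdlog = depth_sdlog, linked_lfc = linked_lfc,
    gene_prob = gene_prob, intron_prob = intron_prob,
    n_bg_genes = as.integer(n_bg_genes), isolated = isTRUE(isolated),
    chrom = chrom, chrom_length = chrom_length, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic per-purpose RNG substream seed, kept below 2^31.
.sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + as.integer(k)
}

#' Generate a synthetic multi-strain cohort with planted truth
#'
#' Builds an ancestral chromosome, plants polymorphic TE insertions from a
#' small synthetic family library, assigns each strain a carrier /
#' non-carrier state per TE, derives every strain's genome coordinates
#' (carrier TE intervals; exact insertion junctions in non-carriers), places
#' gene models near a subset of TEs plus background genes far from any TE,
#' and records the planted epigenetic truth per (TE, body part, mark).
#'
#' @param spec A [cohort_spec()].
#' @param with_sequences If `TRUE` (default) strain genome sequences are
#'   materialized (needed for breakpoint projection); coordinates and truth
#'   are generated either way.
#' @return A list of class `"teepi_cohort"`: `spec`, `chrom`, `tes` (with
#'   `presence` attribute), `carrier_intervals`, `junctions`, `genes`
#'   (ancestral feature table), `genomes` (named character vector or `NULL`),
#'   `strain_lengths`, and `truth` (`te_effects`, `gene_effects`).
#' @export
generate_cohort <- function(spec, with_sequences = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(.sub_seed(spec$seed, 1L))
  strains <- sprintf("S%02d", seq_len(spec$n_strains))
  profile_bp <- 20000L                       # 20 x 1 kb per side
  max_te_len <- 5000L
  spacing <- if (spec$isolated) 2L * profile_bp + max_te_len + 5000L
             else max_te_len + 4000L
  margin <- profile_bp + 5000L
  need <- 2L * margin + spec$n_te * spacing
  L <- if (is.null(spec$chrom_length)) need else as.integer(spec$chrom_length)
  if (L < need) {
    stop("chrom_length ", L, " too small: need >= ", need,
         " bp to host ", spec$n_te, " TEs at the required spacing",
         call. = FALSE)
  }

  # TE family library: random sequences are >= ~25% divergent pairwise by
  # construction, so flanks map unambiguously except where repeats are
  # planted on purpose.
  fam_names <- c("rover", "jumper", "hopper", "skipper", "drifter", "glider")
  fam_order <- c("LTR", "LTR", "LINE", "LINE", "DNA", "other")
  fam_len <- c(5000L, 4000L, 3000L, 2500L, 1500L, 1000L)
  fam_seq <- vapply(fam_len, .rand_dna, character(1))

  # junction positions in ancestral coordinates, 10 bp aligned
  jitter <- sample.int(floor((spacing - max_te_len - 2000L) / 10), spec$n_te,
                       replace = TRUE) * 10L
  anc_pos <- margin + (seq_len(spec$n_te) - 1L) * spacing + jitter
  fam_idx <- sample.int(length(fam_names), spec$n_te, replace = TRUE)
  full_length <- stats::runif(spec$n_te) < 0.5
  frag_len <- pmax(300L, as.integer(
    floor(stats::runif(spec$n_te, 300, fam_len[fam_idx]) / 10) * 10L))
  te_len <- as.integer(ifelse(full_length, fam_len[fam_idx], frag_len))
  te_seq <- vapply(seq_len(spec$n_te), function(i) {
    if (full_length[i]) fam_seq[fam_idx[i]]
    else substr(fam_seq[fam_idx[i]], 1L, te_len[i])
  }, character(1))

  # presence: redraw until polymorphic (>=1 carrier, >=1 non-carrier)
  presence <- matrix("non-carrier", spec$n_te, spec$n_strains,
                     dimnames = list(sprintf("te%03d", seq_len(spec$n_te)),
                                     strains))
  for (i in seq_len(spec$n_te)) {
    repeat {
      carr <- stats::runif(spec$n_strains) < 0.5
      if (any(carr) && !all(carr)) break
    }
    presence[i, carr] <- "carrier"
  }
  te_id <- rownames(presence)

  tes <- data.frame(
    te_id = te_id, family = fam_names[fam_idx], order = fam_order[fam_idx],
    chrom = spec$chrom, start = anc_pos, end = anc_pos + te_len,
    strand = "+",
    length_class = ifelse(full_length, "full-length", "fragment"),
    population_frequency = rowMeans(presence == "carrier"),
    stringsAsFactors = FALSE
  )
  attr(tes, "presence") <- presence

  # per-strain coordinates: every ancestral position x maps to
  # x + sum(lengths of carried TEs inserted at positions <= x)
  carrier_intervals <- do.call(rbind, lapply(strains, function(s) {
    carr <- presence[, s] == "carrier"
    if (!any(carr)) return(NULL)
    shift <- cumsum(ifelse(carr, te_len, 0L)) - ifelse(carr, te_len, 0L)
    data.frame(te_id = te_id[carr], strain = s, chrom = spec$chrom,
               start = anc_pos[carr] + shift[carr],
               end = anc_pos[carr] + shift[carr] + te_len[carr],
               stringsAsFactors = FALSE)
  }))
  junctions <- do.call(rbind, lapply(strains, function(s) {
    carr <- presence[, s] == "carrier"
    if (all(carr)) return(NULL)
    shift <- cumsum(ifelse(carr, te_len, 0L)) - ifelse(carr, te_len, 0L)
    nc <- !carr
    data.frame(te_id = te_id[nc], strain = s, chrom = spec$chrom,
               position = anc_pos[nc] + shift[nc], stringsAsFactors = FALSE)
  }))

  genes <- .place_genes(spec, anc_pos, te_len, te_id)

  truth_te <- .plant_te_effects(spec, te_id)
  truth_gene <- .plant_gene_effects(spec, truth_te, genes$link)

  genomes <- NULL
  strain_lengths <- stats::setNames(
    L + vapply(strains, function(s)
      sum(te_len[presence[, s] == "carrier"]), integer(1)), strains)
  if (with_sequences) {
    anc <- .rand_dna(L)
    genomes <- vapply(strains, function(s) {
      carr <- which(presence[, s] == "carrier")
      if (!length(carr)) return(anc)
      pieces <- character(2L * length(carr) + 1L)
      prev <- 0L
      for (k in seq_along(carr)) {
        i <- carr[k]
        pieces[2L * k - 1L] <- substr(anc, prev + 1L, anc_pos[i])
        pieces[2L * k] <- te_seq[i]
        prev <- anc_pos[i]
      }
      pieces[2L * length(carr) + 1L] <- substr(anc, prev + 1L, L)
      paste(pieces, collapse = "")
    }, character(1))
  }

  structure(list(
    spec = spec, chrom = spec$chrom, strains = strains, tes = tes,
    carrier_intervals = carrier_intervals, junctions = junctions,
    genes = genes$features, gene_link = genes$link,
    genomes = genomes, strain_lengths = strain_lengths,
    ancestral_length = L,
    truth = list(te_effects = truth_te, gene_effects = truth_gene)
  ), class = "teepi_cohort")
}

# Gene models in ancestral coordinates. Structure per gene (plus strand):
# 5'UTR 200 | CDS 600 | intron 400 | CDS 600 | 3'UTR 200 (2 kb total).
.place_genes <- function(spec, anc_pos, te_len, te_id) {
  glen <- c(utr5 = 200L, cds1 = 600L, intron = 400L, cds2 = 600L,
            utr3 = 200L)
  total <- sum(glen)
  rows <- list(); links <- list(); g <- 0L
  mk_gene <- function(gid, gstart, strand) {
    bounds <- gstart + cumsum(c(0L, glen))
    feats <- if (strand == "+") {
      c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR")
    } else {
      c("three_prime_UTR", "CDS", "intron", "CDS", "five_prime_UTR")
    }
    data.frame(
      gene_id = gid,
      feature = c("gene", feats),
      chrom = spec$chrom,
      start = c(gstart, bounds[-length(bounds)]),
      end = c(gstart + total, bounds[-1L]),
      strand = strand, stringsAsFactors = FALSE
    )
  }
  has_gene <- stats::runif(spec$n_te) < spec$gene_prob
  in_intron <- stats::runif(spec$n_te) < spec$intron_prob
  for (i in seq_len(spec$n_te)) {
    if (!has_gene[i]) next
    g <- g + 1L
    gid <- sprintf("g%04d", g)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    if (in_intron[i]) {
      # junction lands mid-intron: gene starts so the TE insertion point
      # falls 200 bp into the intron
      gstart <- anc_pos[i] - (glen[["utr5"]] + glen[["cds1"]] + 200L)
      mode <- "intron"
    } else {
      d <- 200L + sample.int(180L, 1L) * 10L   # 0.2-2 kb from the TE edge
      gstart <- anc_pos[i] + te_len[i] + d
      mode <- "flank"
    }
    rows[[g]] <- mk_gene(gid, as.integer(gstart), strand)
    links[[g]] <- data.frame(gene_id = gid, te_id = te_id[i], mode = mode,
                             stringsAsFactors = FALSE)
  }
  # background genes in the inter-TE deserts, > 20 kb from every junction
  bg_at <- anc_pos[seq_len(min(spec$n_bg_genes, spec$n_te))] +
    te_len[seq_len(min(spec$n_bg_genes, spec$n_te))] + 22000L
  for (k in seq_along(bg_at)) {
    g <- g + 1L
    gid <- sprintf("g%04d", g)
    rows[[g]] <- mk_gene(gid, as.integer(bg_at[k]),
                         if (stats::runif(1) < 0.5) "+" else "-")
    links[[g]] <- data.frame(gene_id = gid, te_id = NA_character_,
                             mode = "background", stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, rows), link = do.call(rbind, links))
}

.plant_te_effects <- function(spec, te_id) {
  grid <- expand.grid(te_id = te_id, body_part = spec$body_parts,
                      mark = spec$marks, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  u <- stats::runif(nrow(grid))
  pe <- spec$effect_prob[["enrichment"]]
  pd <- spec$effect_prob[["depletion"]]
  grid$effect <- ifelse(u < pe, "enrichment",
                        ifelse(u < pe + pd, "depletion", "none"))
  grid$percentage <- ifelse(grid$effect == "enrichment", spec$pct_enrich,
                            ifelse(grid$effect == "depletion",
                                   spec$pct_deplete, 0))
  grid$spread_kb <- ifelse(grid$effect == "none", 0L, spec$spread_kb)
  grid
}

# Planted expression shift: sign follows the mark's biology; effects from
# several (mark) conditions on the same TE add on the log2 scale.
.plant_gene_effects <- function(spec, truth_te, link) {
  link <- link[!is.na(link$te_id), , drop = FALSE]
  if (nrow(link) == 0L) {
    return(data.frame(gene_id = character(), te_id = character(),
                      body_part = character(), log2fc = double(),
                      stringsAsFactors = FALSE))
  }
  eff <- truth_te[truth_te$effect != "none", , drop = FALSE]
  m <- merge(link[, c("gene_id", "te_id")], eff, by = "te_id")
  if (nrow(m) == 0L) {
    return(data.frame(gene_id = character(), te_id = character(),
                      body_part = character(), log2fc = double(),
                      stringsAsFactors = FALSE))
  }
  sign_of <- function(mark, effect) {
    s <- ifelse(mark == "H3K9me3", -1, 1)     # repressive vs active mark
    ifelse(effect == "enrichment", s, -s)
  }
  m$log2fc <- sign_of(m$mark, m$effect) * spec$linked_lfc
  agg <- stats::aggregate(log2fc ~ gene_id + te_id + body_part, data = m,
                          FUN = sum)
  agg[order(agg$gene_id, agg$body_part), , drop = FALSE]
}

#' Simulate replicate ChIP signal tracks for a cohort
#'
#' Baseline bins are lognormal around a fold-enrichment of 1.0
#' (`exp(rnorm(., 0, signal_sdlog))`). For each carrier strain of a TE with a
#' planted effect, bins within `spread_kb` of the TE span (and the span
#' itself) are multiplied by `1 + percentage/100` with a hard-edged boxcar
#' kernel; non-carrier strains receive baseline only. Replicates are i.i.d.
#' draws; every track is a deterministic function of the cohort seed and its
#' (strain, body part, mark, replicate) index.
#'
#' @param cohort A `teepi_cohort`.
#' @param body_parts,marks Subsets of the cohort's conditions to simulate
#'   (default: all).
#' @param bin_bp Signal bin width (default 10).
#' @return A list of [signal_track()] objects.
#' @export
simulate_signal <- function(cohort, body_parts = cohort$spec$body_parts,
                            marks = cohort$spec$marks, bin_bp = 10L) {
  spec <- cohort$spec
  if (spec$pct_deplete <= -100 || spec$pct_enrich <= -100) {
    stop("planted percentage <= -100 would produce negative signal",
         call. = FALSE)
  }
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      strain = cohort$strains, mark = marks,
                      body_part = body_parts, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  # global track index (stable across subsetting) for seed derivation
  full <- expand.grid(replicate = seq_len(spec$replicates),
                      strain = cohort$strains, mark = spec$marks,
                      body_part = spec$body_parts, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$strain, d$body_part, d$mark, d$replicate)
  kidx <- match(key(grid), key(full))
  truth <- cohort$truth$te_effects
  pres <- attr(cohort$tes, "presence")
  lapply(seq_len(nrow(grid)), function(r) {
    s <- grid$strain[r]; bp <- grid$body_part[r]; mk <- grid$mark[r]
    set.seed(.sub_seed(spec$seed, 100L + kidx[r]))
    nbin <- ceiling(cohort$strain_lengths[[s]] / bin_bp)
    v <- if (spec$signal_sdlog > 0) {
      exp(stats::rnorm(nbin, 0, spec$signal_sdlog))
    } else rep(1, nbin)
    eff <- truth[truth$body_part == bp & truth$mark == mk &
                   truth$effect != "none", , drop = FALSE]
    if (nrow(eff)) {
      ci <- cohort$carrier_intervals
      ci <- ci[ci$strain == s & ci$te_id %in% eff$te_id, , drop = FALSE]
      if (nrow(ci)) {
        m <- match(ci$te_id, eff$te_id)
        for (j in seq_len(nrow(ci))) {
          spread <- eff$spread_kb[m[j]] * 1000L
          mult <- 1 + eff$percentage[m[j]] / 100
          lo <- max(0L, ci$start[j] - spread)
          hi <- min(nbin * bin_bp, ci$end[j] + spread)
          b0 <- floor(lo / bin_bp) + 1L
          b1 <- ceiling(hi / bin_bp)
          v[b0:b1] <- v[b0:b1] * mult
        }
      }
    }
    bins <- stats::setNames(list(v), cohort$chrom)
    signal_track(bins, bin_bp, strain = s, body_part = bp, mark = mk,
                 replicate = grid$replicate[r])
  })
}

#' Simulate an expression count matrix for a cohort
#'
#' Counts are negative binomial with gene-specific lognormal baseline means,
#' per-sample depth factors, and planted log2 fold changes applied to
#' carrier-strain samples of TE-linked genes in the affected body part.
#'
#' @param cohort A `teepi_cohort`.
#' @return A list with `counts` (integer matrix gene x sample) and `samples`
#'   (metadata data frame as in [read_counts()]).
#' @export
simulate_expression <- function(cohort) {
  spec <- cohort$spec
  if (spec$nb_dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  set.seed(.sub_seed(spec$seed, 2L))
  genes <- unique(cohort$genes$gene_id)
  samples <- expand.grid(replicate = seq_len(spec$replicates),
                         body_part = spec$body_parts,
                         strain = cohort$strains, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "body_part", "replicate")]
  samples$sample <- sprintf("%s_%s_%d", samples$strain, samples$body_part,
                            samples$replicate)
  mu_g <- stats::setNames(
    exp(stats::rnorm(length(genes), spec$expr_mean_log, spec$expr_sd_log)),
    genes)
  depth <- exp(stats::rnorm(nrow(samples), 0, spec$depth_sdlog))
  pres <- attr(cohort$tes, "presence")
  ge <- cohort$truth$gene_effects
  lfc <- matrix(0, length(genes), nrow(samples),
                dimnames = list(genes, samples$sample))
  if (nrow(ge)) {
    for (j in seq_len(nrow(ge))) {
      carr <- colnames(pres)[pres[ge$te_id[j], ] == "carrier"]
      cols <- samples$strain %in% carr & samples$body_part == ge$body_part[j]
      lfc[ge$gene_id[j], cols] <- lfc[ge$gene_id[j], cols] + ge$log2fc[j]
    }
  }
  mu <- outer(mu_g, depth) * 2^lfc
  counts <- matrix(0L, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample))
  if (spec$nb_dispersion == 0) {
    counts[] <- stats::rpois(length(mu), mu)
  } else {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / spec$nb_dispersion)
  }
  list(counts = counts, samples = samples)
}

#' Write cohort fixtures to disk
#'
#' Emits strain genomes (FASTA), TE annotations (BED6+ in ancestral
#' coordinates) with the presence matrix (TSV), gene models (GFF3, ancestral
#' coordinates), optional signal tracks (bedGraph) and counts (TSV), and the
#' planted truth (JSON). Identical cohort + seed yields byte-identical files.
#'
#' @param cohort A `teepi_cohort`.
#' @param dir Output directory (created if needed).
#' @param tracks Optional list of signal tracks from [simulate_signal()].
#' @param expression Optional result of [simulate_expression()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, tracks = NULL, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$genomes)) {
    for (s in names(cohort$genomes)) {
      dna <- Biostrings::DNAStringSet(cohort$genomes[[s]])
      names(dna) <- cohort$chrom
      Biostrings::writeXStringSet(dna, file.path(dir, paste0(s, ".fa")))
    }
  }
  write_te_annotations(cohort$tes, file.path(dir, "tes.bed"),
                       file.path(dir, "presence.tsv"))
  write_gene_annotations(cohort$genes, file.path(dir, "genes.gff3"))
  if (!is.null(tracks)) {
    td <- file.path(dir, "tracks")
    dir.create(td, showWarnings = FALSE)
    for (tr in tracks) {
      write_signal_track(tr, file.path(td, sprintf(
        "%s_%s_%s_%d.bedGraph", tr$strain, tr$body_part, tr$mark,
        tr$replicate)))
    }
  }
  if (!is.null(expression)) {
    write_counts(expression$counts, file.path(dir, "counts.tsv"))
  }
  jsonlite::write_json(
    list(te_effects = cohort$truth$te_effects,
         gene_effects = cohort$truth$gene_effects),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' Project gene annotations into one strain's coordinates
#'
#' Every ancestral position shifts right by the total length of that
#' strain's TE insertions at or before it, so features spanning an insertion
#' point grow by the TE length (e.g. an intron hosting the TE).
#'
#' @param cohort A `teepi_cohort`.
#' @param strain Strain name.
#' @return The gene feature table in the strain's coordinates.
#' @export
genes_for_strain <- function(cohort, strain) {
  g <- cohort$genes
  g$start <- as.integer(project_position(cohort, strain, g$start))
  g$end <- as.integer(project_position(cohort, strain, g$end))
  g
}

#' Project ancestral positions into one strain's coordinates
#'
#' @param cohort A `teepi_cohort`.
#' @param strain Strain name.
#' @param x Numeric vector of ancestral positions.
#' @return `x` shifted by the total length of the strain's TE insertions at
#'   or before each position.
#' @export
project_position <- function(cohort, strain, x) {
  pres <- attr(cohort$tes, "presence")
  carr <- pres[, strain] == "carrier"
  if (!any(carr)) return(x)
  pos <- cohort$tes$start[carr]
  len <- (cohort$tes$end - cohort$tes$start)[carr]
  x + vapply(x, function(xx) sum(len[pos <= xx]), numeric(1))
}
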