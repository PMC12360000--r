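test_that("cohort generation is deterministic and every TE is polymorphic", {
  spec <- cohort_spec(n_te = 8, seed = 21, body_parts = "gut",
                      marks = "H3K9me3")
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$tes, co2$tes)
  expect_identical(co1$genomes, co2$genomes)
  expect_identical(co1$truth, co2$truth)

  pm <- attr(co1$tes, "presence")
  expect_true(all(rowSums(pm == "carrier") >= 1))
  expect_true(all(rowSums(pm == "non-carrier") >= 1))

  # one truth row per TE x condition; spread 0 iff no effect
  tt <- co1$truth$te_effects
  expect_equal(nrow(tt), 8L)
  expect_equal(anyDuplicated(tt$te_id), 0L)
  expect_identical(tt$spread_kb == 0L, tt$effect == "none")
  expect_true(all(sign(tt$percentage[tt$effect == "enrichment"]) == 1))
  expect_true(all(sign(tt$percentage[tt$effect == "depletion"]) == -1))
})

test_that("undersized chromosome is rejected with a sizing error", {
  spec <- cohort_spec(n_te = 10, seed = 1, chrom_length = 100000)
  expect_error(generate_cohort(spec, with_sequences = FALSE), "too small")
})

test_that("carrier genomes contain the TE, non-carriers the contiguous junction", {
  fix <- small_cohort()
  co <- fix$cohort
  pm <- attr(co$tes, "presence")
  i <- 1L
  te <- co$tes$te_id[i]
  carrier <- colnames(pm)[which(pm[i, ] == "carrier")[1]]
  noncarr <- colnames(pm)[which(pm[i, ] == "non-carrier")[1]]
  iv <- co$carrier_intervals
  iv <- iv[iv$te_id == te & iv$strain == carrier, ]
  j <- co$junctions
  j <- j[j$te_id == te & j$strain == noncarr, ]
  # 30 bp on each side of the junction must be contiguous in the non-carrier
  # and flank the TE span in the carrier
  up <- substr(co$genomes[[carrier]], iv$start - 29, iv$start)
  down <- substr(co$genomes[[carrier]], iv$end + 1, iv$end + 30)
  junction_seq <- substr(co$genomes[[noncarr]], j$position - 29,
                         j$position + 30)
  expect_identical(junction_seq, paste0(up, down))
})

test_that("noise-free planted +100% doubles the innermost flank signal exactly", {
  fix <- noise_free_cohort()
  co <- fix$cohort
  tt <- co$truth$te_effects
  eff <- tt[tt$effect == "enrichment", ]
  expect_gt(nrow(eff), 0)
  pm <- attr(co$tes, "presence")
  meta <- data.frame(strain = sapply(fix$tracks, `[[`, "strain"),
                     rep = sapply(fix$tracks, `[[`, "replicate"))
  for (r in seq_len(nrow(eff))) {
    i <- match(eff$te_id[r], co$tes$te_id)
    carrier <- colnames(pm)[which(pm[i, ] == "carrier")[1]]
    noncarr <- colnames(pm)[which(pm[i, ] == "non-carrier")[1]]
    iv <- co$carrier_intervals
    iv <- iv[iv$te_id == eff$te_id[r] & iv$strain == carrier, ]
    j <- co$junctions
    j <- j[j$te_id == eff$te_id[r] & j$strain == noncarr, ]
    trc <- fix$tracks[[which(meta$strain == carrier & meta$rep == 1)]]
    trn <- fix$tracks[[which(meta$strain == noncarr & meta$rep == 1)]]
    # innermost 1 kb window downstream of the TE end / junction
    vc <- trc$bins[[co$chrom]][(iv$end / 10 + 1):(iv$end / 10 + 100)]
    vn <- trn$bins[[co$chrom]][(j$position / 10 + 1):(j$position / 10 + 100)]
    expect_equal(median(vc), 2 * median(vn))
  }
})

test_that("measured innermost percentage tracks the planted value", {
  spec <- cohort_spec(n_te = 60, seed = 5, body_parts = "gut",
                      marks = "H3K9me3", signal_sdlog = 0.2,
                      effect_prob = c(enrichment = 1, depletion = 0),
                      pct_enrich = 50)
  co <- generate_cohort(spec, with_sequences = FALSE)
  tracks <- simulate_signal(co)
  meta_s <- sapply(tracks, `[[`, "strain")
  avg <- lapply(split(seq_along(tracks), meta_s),
                function(ix) average_replicates(tracks[ix]))
  pm <- attr(co$tes, "presence")
  meas <- sapply(seq_len(nrow(co$tes)), function(i) {
    carrier <- colnames(pm)[which(pm[i, ] == "carrier")[1]]
    noncarr <- colnames(pm)[which(pm[i, ] == "non-carrier")[1]]
    iv <- co$carrier_intervals
    iv <- iv[iv$te_id == co$tes$te_id[i] & iv$strain == carrier, ]
    j <- co$junctions
    j <- j[j$te_id == co$tes$te_id[i] & j$strain == noncarr, ]
    cfg <- teepi_config()
    pp <- build_window_profile(avg[[carrier]], co$chrom, iv$start, iv$end,
                               cfg)
    pn <- build_window_profile(avg[[noncarr]], co$chrom, j$position,
                               j$position, cfg)
    percent_change(pp, pn)
  })
  expect_lt(abs(mean(meas) - 50), 10)
})

test_that("expression counts honor dimensions and the planted fold change", {
  fix <- small_cohort()
  ex <- fix$expr
  spec <- fix$spec
  n_genes <- length(unique(fix$cohort$genes$gene_id))
  expect_equal(dim(ex$counts),
               c(n_genes, spec$n_strains * length(spec$body_parts) *
                   spec$replicates))
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == round(ex$counts)))

  # near-Poisson limit: planted log2FC = -2 gives a carrier/non-carrier
  # mean ratio of ~1/4
  spec0 <- cohort_spec(n_te = 10, seed = 13, body_parts = "gut",
                       marks = "H3K9me3", nb_dispersion = 0,
                       depth_sdlog = 0, linked_lfc = 2, gene_prob = 1,
                       effect_prob = c(enrichment = 1, depletion = 0))
  co0 <- generate_cohort(spec0, with_sequences = FALSE)
  ex0 <- simulate_expression(co0)
  ge <- co0$truth$gene_effects
  down <- ge[ge$log2fc == -2, ]
  expect_gt(nrow(down), 0)
  pm <- attr(co0$tes, "presence")
  ratios <- sapply(seq_len(nrow(down)), function(r) {
    carr <- colnames(pm)[pm[down$te_id[r], ] == "carrier"]
    sel_c <- ex0$samples$strain %in% carr
    mean(ex0$counts[down$gene_id[r], sel_c]) /
      mean(ex0$counts[down$gene_id[r], !sel_c])
  })
  expect_lt(abs(mean(ratios) - 0.25), 0.08)
})

test_that("cohort fixtures are written deterministically", {
  spec <- cohort_spec(n_te = 4, seed = 31, body_parts = "gut",
                      marks = "H3K9me3")
  co <- generate_cohort(spec)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(co, d1, tracks = simulate_signal(co)[1:2])
  write_cohort(generate_cohort(spec), d2,
               tracks = simulate_signal(co)[1:2])
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
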