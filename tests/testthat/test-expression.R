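test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(4)
  base <- rnbinom(200, mu = 100, size = 10) + 1L
  m <- cbind(a = base, b = base, c = base)
  expect_equal(compute_tmm_factors(m), rep(1, 3), tolerance = 1e-12)

  # pure depth difference is carried by library size, not the factor
  m2 <- cbind(a = base, b = 2L * base)
  expect_equal(compute_tmm_factors(m2), rep(1, 2), tolerance = 1e-12)

  expect_error(compute_tmm_factors(cbind(a = base, b = 0L * base)),
               "all-zero")
  expect_error(compute_tmm_factors(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("TMM factors match the independent edgeR reference within 1e-8", {
  set.seed(77)
  for (rep in 1:3) {
    counts <- matrix(rnbinom(50 * 6, mu = exp(rnorm(50, log(80), 1)),
                             size = 5), nrow = 50)
    counts[sample(length(counts), 10)] <- 0L
    colnames(counts) <- paste0("s", 1:6)
    got <- compute_tmm_factors(counts)
    ref <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_lt(max(abs(got - ref)), 1e-8)
  }
  # geometric mean is exactly 1
  counts <- matrix(rnbinom(300, mu = 50, size = 3), nrow = 50)
  expect_equal(exp(mean(log(compute_tmm_factors(counts)))), 1,
               tolerance = 1e-12)
})

test_that("z-score follows its definition, scale invariance, antisymmetry", {
  expect_equal(zscore_expression(c(5, 5, 5), c(5, 5, 5)), 0)
  # mean+ 10, SE+ 0.6; mean- 8, SE- 0.8 -> z = 2 / sqrt(0.36 + 0.64) = 2
  xp <- c(9.4, 10.6); xn <- c(7.2, 8.8)
  expect_equal(zscore_expression(xp, xn), 2)
  expect_equal(zscore_expression(10 * xp, 10 * xn),
               zscore_expression(xp, xn))
  expect_equal(zscore_expression(xn, xp), -zscore_expression(xp, xn))
  # zero variance with unequal means: signed infinite sentinel
  expect_identical(zscore_expression(c(2, 2, 2), c(1, 1, 1)), Inf)
  expect_identical(zscore_expression(c(1, 1), c(3, 3)), -Inf)
})

test_that("null z-scores are symmetric about zero", {
  set.seed(31)
  n_genes <- 10000L
  z <- vapply(seq_len(n_genes), function(i)
    zscore_expression(rnorm(6, 10, 2), rnorm(9, 10, 2)), numeric(1))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(median(z)), 0.05)
})

test_that("genes are linked within the called spread and categorized", {
  genes <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    feature = c("gene", "CDS", "gene", "CDS", "gene"),
    chrom = "2L",
    start = c(12500L, 12600L, 13500L, 13600L, 50000L),
    end = c(13300L, 13200L, 14300L, 14200L, 51000L),
    strand = "+", stringsAsFactors = FALSE)
  tes <- data.frame(te_id = "te1", chrom = "2L", start = 9000L,
                    end = 10000L, stringsAsFactors = FALSE)
  eff <- data.frame(te_id = "te1", body_part = "gut", mark = "H3K9me3",
                    class = "enrichment", spread = 3, stringsAsFactors = FALSE)
  links <- link_te_genes(eff, tes, genes)
  # gA starts 2.5 kb away (linked), gB 3.5 kb away (not), gC far (not);
  # the TE sits 5' of the plus-strand gene, i.e. upstream
  expect_equal(links$gene_id, "gA")
  expect_equal(links$positional_category, "upstream")
  expect_equal(links$distance_bp, 2500L)

  # spread 0 or class none produce no links
  eff0 <- eff; eff0$spread <- 0
  expect_equal(nrow(link_te_genes(eff0, tes, genes)), 0L)

  # a TE inside the gene body but outside CDS/UTRs is intronic
  tes_in <- data.frame(te_id = "te2", chrom = "2L", start = 13250L,
                       end = 13280L, stringsAsFactors = FALSE)
  eff_in <- eff; eff_in$te_id <- "te2"
  links_in <- link_te_genes(eff_in, tes_in, genes)
  expect_true("intron" %in%
                links_in$positional_category[links_in$gene_id == "gA"])
})

test_that("strand orients upstream/downstream categories", {
  gene_m <- data.frame(gene_id = "gM", feature = "gene", chrom = "2L",
                       start = 20000L, end = 22000L, strand = "-",
                       stringsAsFactors = FALSE)
  # TE to the left of a minus-strand gene is downstream of it
  expect_equal(classify_position(18000L, 18500L, gene_m), "downstream")
  expect_equal(classify_position(23000L, 23500L, gene_m), "upstream")
  gene_p <- gene_m; gene_p$strand <- "+"
  expect_equal(classify_position(18000L, 18500L, gene_p), "upstream")
})

test_that("cohort z-scores separate planted shifts from background", {
  fix <- small_cohort()
  eff <- call_all_effects(fix$cohort, fix$tracks, teepi_config())
  links <- link_cohort_genes(fix$cohort, eff$effect_calls)
  norm <- cpm_tmm(fix$expr$counts)
  lz <- te_gene_zscores(links, norm, fix$expr$samples,
                        attr(fix$cohort$tes, "presence"))
  ge <- fix$cohort$truth$gene_effects
  m <- merge(lz, ge, by = c("gene_id", "te_id", "body_part"))
  expect_gt(nrow(m), 0)
  # planted direction and z sign agree for significant links
  sig <- m[m$significant, ]
  expect_true(all(sign(sig$z) == sign(sig$log2fc)))
  q <- quadrant_counts(lz)
  if (nrow(q)) {
    expect_true(all(q$n >= 1))
    expect_true(all(q$direction %in% c("up", "down")))
  }
})
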