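test_that("empirical p honors the add-one rule exactly", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(permutation_pvalue(10, null)$p, 1 / 6)
  expect_equal(permutation_pvalue(0, null)$p, 1)
  expect_equal(permutation_pvalue(3, null)$p, (1 + 3) / 6)
  # observed above every one of N = 1000 draws -> 1/1001
  expect_equal(permutation_pvalue(2, rep(1, 1000))$p, 1 / 1001)
  # observed equal to every draw -> 1
  expect_equal(permutation_pvalue(1, rep(1, 1000))$p, 1)
})

test_that("TE-free regions respect clearance, matching, and determinism", {
  fix <- small_cohort()
  co <- fix$cohort
  focal <- co$tes[1:6, ]
  reg <- sample_te_free_regions(focal, co$tes, co$genes,
                                co$ancestral_length, seed = 5)
  expect_gt(nrow(reg), 0)
  # >= 1 kb clearance from every TE, asserted directly
  for (r in seq_len(nrow(reg))) {
    d_ok <- co$tes$start >= reg$end[r] + 1000 |
      co$tes$end <= reg$start[r] - 1000
    expect_true(all(d_ok))
    expect_equal(reg$end[r] - reg$start[r],
                 focal$end[match(reg$matched_te_id[r], focal$te_id)] -
                   focal$start[match(reg$matched_te_id[r], focal$te_id)])
    expect_equal(reg$category[r],
                 region_category(reg$start[r], reg$end[r], co$genes))
  }
  reg2 <- sample_te_free_regions(focal, co$tes, co$genes,
                                 co$ancestral_length, seed = 5)
  expect_identical(reg, reg2)
  # matched + shortfall account for every focal TE
  expect_equal(nrow(reg) + nrow(attr(reg, "shortfall")), nrow(focal))
})

test_that("a fully TE-tiled genome yields shortfall, not silent truncation", {
  tes <- data.frame(te_id = "teX", chrom = "2L", start = 0L, end = 50000L,
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = character(), feature = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  reg <- sample_te_free_regions(tes, tes, genes, 50000L, seed = 1,
                                max_tries = 20)
  expect_equal(nrow(reg), 0L)
  expect_equal(attr(reg, "shortfall")$te_id, "teX")
})

test_that("positional permutation matches categories and is reproducible", {
  set.seed(6)
  links <- data.frame(
    te_id = sprintf("te%03d", 1:120),
    positional_category = sample(c("intron", "upstream", "downstream"),
                                 120, TRUE),
    z = rnorm(120), stringsAsFactors = FALSE)
  focal <- links$te_id[1:25]
  r1 <- positional_permutation_test(links, focal, n_perm = 200, seed = 9)
  r2 <- positional_permutation_test(links, focal, n_perm = 200, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$p, (1 + r1$count_ge) / 201)
  expect_true(r1$p >= 1 / 201 && r1$p <= 1)

  # focal TEs must be present in the link table
  expect_error(positional_permutation_test(links, c(focal, "te_missing"),
                                           10, 1),
               "te_missing")
  expect_error(positional_permutation_test(links, character(0), 10, 1),
               "empty focal")
})

test_that("category histogram of each null draw equals the focal histogram", {
  set.seed(16)
  links <- data.frame(
    te_id = sprintf("te%03d", 1:90),
    positional_category = rep(c("intron", "upstream", "CDS"), each = 30),
    z = rnorm(90), stringsAsFactors = FALSE)
  focal <- c(links$te_id[1:10], links$te_id[31:35], links$te_id[61:62])
  # statistic that records the category histogram of the drawn set by
  # encoding counts in decimals; constant iff histograms always match
  hist_stat <- local({
    cat_of <- setNames(links$positional_category, links$te_id)
    zs <- setNames(links$z, links$te_id)
    function(z) {
      ids <- names(zs)[match(round(z, 10), round(zs, 10))]
      h <- table(factor(cat_of[ids], levels = c("intron", "upstream",
                                                "CDS")))
      h[[1]] * 1e4 + h[[2]] * 1e2 + h[[3]]
    }
  })
  r <- positional_permutation_test(links, focal, n_perm = 50, seed = 2,
                                   statistic = hist_stat)
  expect_true(all(attr(r, "null") == r$observed))
})

test_that("planted downregulation is detected against matched nulls", {
  set.seed(41)
  n <- 150
  links <- data.frame(
    te_id = sprintf("te%03d", 1:n),
    positional_category = sample(c("intron", "upstream"), n, TRUE),
    z = rnorm(n), stringsAsFactors = FALSE)
  focal <- links$te_id[1:30]
  links$z[1:30] <- links$z[1:30] - 3      # strongly downregulated focal set
  r <- positional_permutation_test(links, focal, n_perm = 500, seed = 3)
  expect_lt(r$p, 0.05)
})

test_that("TE-free expression permutation flags degenerate input and detects excess", {
  # zero DE genes anywhere -> p = 1
  r0 <- tefree_expression_permutation(0, rep(FALSE, 40), set_size = 10,
                                      n_perm = 200, seed = 1)
  expect_equal(r0$p, 1)
  # TE-associated count far above the TE-free rate
  set.seed(2)
  r1 <- tefree_expression_permutation(9, runif(60) < 0.1, set_size = 10,
                                      n_perm = 500, seed = 4)
  expect_lt(r1$p, 0.05)
  # determinism
  r2 <- tefree_expression_permutation(9, runif(60) < 0.1, set_size = 10,
                                      n_perm = 500, seed = 4)
  expect_equal(r1$p, r2$p)
  # no candidate regions
  rd <- tefree_expression_permutation(3, logical(0), set_size = 5)
  expect_true(is.na(rd$p))
  expect_true(isTRUE(attr(rd, "degenerate")))
  expect_error(tefree_expression_permutation(1, rep(TRUE, 3), set_size = 5),
               "exceeds")
})

test_that("region enrichment via the window machinery finds strain-specific signal", {
  fix <- noise_free_cohort()
  co <- fix$cohort
  # regions at planted-effect TEs: the carrier strains stand out; control
  # regions far from TEs show nothing
  tt <- co$truth$te_effects
  eff_te <- tt$te_id[tt$effect == "enrichment"][1]
  i <- match(eff_te, co$tes$te_id)
  # region just upstream of the junction, inside the planted 3 kb spread
  regions <- data.frame(
    region_id = c("at_te", "control"),
    chrom = co$chrom,
    start = c(co$tes$start[i] - 2000L, co$tes$start[i] - 30000L),
    end = c(co$tes$start[i] - 1000L, co$tes$start[i] - 29000L),
    stringsAsFactors = FALSE)
  pm <- attr(co$tes, "presence")
  carriers <- colnames(pm)[pm[i, ] == "carrier"]
  noncarr <- colnames(pm)[pm[i, ] == "non-carrier"]
  # one carrier against the non-carrier strains only, so every pair for the
  # carrier is a true with/without comparison
  keep <- c(carriers[1], noncarr)
  tracks_sub <- Filter(function(t) t$strain %in% keep, fix$tracks)
  calls <- call_region_enrichment(co, tracks_sub, regions, teepi_config())
  at_te <- calls[calls$region_id == "at_te", ]
  expect_equal(at_te$class[at_te$strain == carriers[1]], "enrichment")
  ctrl <- calls[calls$region_id == "control", ]
  expect_false(any(ctrl$class %in% c("enrichment", "depletion")))
})
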