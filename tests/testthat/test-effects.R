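test_that("window rank-sum test handles identity, separation, and missingness", {
  x <- seq(1, 2, length.out = 100)
  same <- window_test(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  # complete separation at n = 100 per group
  sep <- window_test(x + 10, x)
  expect_lt(sep$p_value, 1e-30)
  expect_equal(sep$direction, "higher")
  expect_equal(window_test(x, x + 10)$direction, "lower")

  # below the minimum usable bins the test is missing
  x40 <- c(x[1:40], rep(NA, 60))
  miss <- window_test(x40, x, min_bins = 50L)
  expect_true(is.na(miss$p_value))
  expect_true(is.na(miss$direction))
  expect_equal(miss$n_pos, 40L)
})

test_that("rank-sum p-values match wilcox.test across regimes", {
  set.seed(14)
  for (n in c(8, 30, 100)) {
    for (shift in c(0, 0.3)) {
      x <- rnorm(n) + shift
      y <- rnorm(n)
      got <- window_test(x, y, min_bins = 5L)$p_value
      ref <- suppressWarnings(wilcox.test(x, y))$p.value
      expect_equal(got, ref, tolerance = 1e-12,
                   label = paste("n", n, "shift", shift))
    }
  }
  # tied data exercise the tie-corrected normal approximation
  x <- rep(1:5, each = 12); y <- rep(c(1, 2, 2, 3, 6), each = 12)
  expect_equal(window_test(x, y, min_bins = 5L)$p_value,
               suppressWarnings(wilcox.test(x, y))$p.value,
               tolerance = 1e-12)
})

test_that("exact rank-sum matches brute-force enumeration for small groups", {
  set.seed(23)
  for (rep in 1:20) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    got <- window_test(x, y, min_bins = 2L)$p_value
    expect_equal(got, ranksum_enum_p(x, y), tolerance = 1e-12,
                 label = paste("nx", nx, "ny", ny, "rep", rep))
  }
})

test_that("percentage change follows its definition and degenerates safely", {
  p2 <- flat_profile(2); p1 <- flat_profile(1)
  expect_equal(percent_change(p2, p1), 100)
  p075 <- flat_profile(0.75)
  expect_equal(percent_change(p075, p1), -25)
  p0 <- flat_profile(0)
  expect_true(is.na(percent_change(p1, p0)))
  # pooled and per-side agree for symmetric profiles
  expect_equal(percent_change(p2, p1, pool_sides = FALSE), 100)
})

test_that("spread takes the conservative minimum of consecutive runs", {
  mk_tests <- function(left, right) {
    rbind(data.frame(side = "left", window = seq_along(left),
                     p_value = ifelse(left == "ns", 0.5, 0.01),
                     direction = ifelse(left == "ns", "none", left)),
          data.frame(side = "right", window = seq_along(right),
                     p_value = ifelse(right == "ns", 0.5, 0.01),
                     direction = ifelse(right == "ns", "none", right)))
  }
  h <- "higher"
  expect_equal(spread_extent(mk_tests(c(h, h, h, "ns", h),
                                      c(h, h, "ns", h, h)), h), 2L)
  expect_equal(spread_extent(mk_tests(rep(h, 20), rep(h, 20)), h), 20L)
  expect_equal(spread_extent(mk_tests(c(h, h), c("ns", h)), h), 0L)
  # a missing window breaks the run
  tt <- mk_tests(c(h, h, h), c(h, h, h))
  tt$direction[tt$side == "left" & tt$window == 2] <- NA
  expect_equal(spread_extent(tt, h), 1L)
})

test_that("pair classification recovers planted shifts and flags contradictions", {
  sp <- shifted_profile(1.5, k = 3)
  cl <- classify_pair(sp$pos, sp$neg, sp$config)
  expect_equal(cl$class, "enrichment")
  expect_equal(cl$spread, 3L)
  expect_lt(abs(cl$percentage - 50), 15)

  # equivalent lazy evaluation and the full-table route agree
  tests <- pair_window_tests(sp$pos, sp$neg, sp$config)
  expect_equal(spread_extent(tests, "higher"), 3L)

  dep <- classify_pair(sp$neg, sp$pos, sp$config)
  expect_equal(dep$class, "depletion")
  expect_lt(dep$percentage, 0)

  # no shift: none with spread 0
  null <- shifted_profile(1, k = 0, seed = 7)
  cl0 <- classify_pair(null$pos, null$neg, null$config)
  expect_true(cl0$class %in% c("none", NA_character_))

  # contradictory window-1 directions between the sides yield NA
  sp2 <- shifted_profile(1.5, k = 3)
  contra_pos <- sp2$pos
  contra_pos$left[, 1] <- sp2$neg$left[, 1] / 1.5    # left now lower
  clc <- classify_pair(contra_pos, sp2$neg, sp2$config)
  expect_true(is.na(clc$class))
})

test_that("swapping carrier and non-carrier flips class and sign of P", {
  for (seed in c(1, 2, 3)) {
    sp <- shifted_profile(1.6, k = 2, seed = seed)
    fwd <- classify_pair(sp$pos, sp$neg, sp$config)
    rev <- classify_pair(sp$neg, sp$pos, sp$config)
    expect_equal(fwd$class, "enrichment")
    expect_equal(rev$class, "depletion")
    expect_true(fwd$percentage > 0 && rev$percentage < 0)
  }
})

test_that("consensus allows one deviating pair and rejects contradiction", {
  mk <- function(classes, P = 50, S = 3) {
    data.frame(class = classes,
               percentage = ifelse(is.na(classes), NA,
                                   ifelse(classes == "depletion", -P, P)),
               spread = ifelse(is.na(classes), NA, S),
               direction = NA_character_, stringsAsFactors = FALSE)
  }
  e4 <- consensus_call(mk(rep("enrichment", 4)))
  expect_equal(e4$class, "enrichment")
  expect_equal(e4$percentage, 50)
  expect_equal(e4$spread, 3)

  expect_equal(consensus_call(mk(c(rep("enrichment", 3), "none")))$class,
               "enrichment")
  expect_equal(consensus_call(mk(c(rep("enrichment", 3), NA)))$class,
               "enrichment")
  expect_equal(consensus_call(mk(c("enrichment", "enrichment",
                                   "depletion", "depletion")))$class,
               "excluded")
  expect_equal(consensus_call(mk(c(rep("enrichment", 2), "none",
                                   NA)))$class, "excluded")
  expect_equal(consensus_call(mk(rep(NA_character_, 3)))$class, "excluded")
  # an effect class wins a 1-1 tie with none
  expect_equal(consensus_call(mk(c("enrichment", "none")))$class,
               "enrichment")
  none3 <- consensus_call(mk(c("none", "none", "none")))
  expect_equal(none3$class, "none")
  expect_equal(none3$spread, 0)
  # P and S are averaged over concordant pairs only
  pc <- mk(c("enrichment", "enrichment", "none"))
  pc$percentage[1:2] <- c(40, 60); pc$spread[1:2] <- c(2, 4)
  cc <- consensus_call(pc)
  expect_equal(cc$percentage, 50)
  expect_equal(cc$spread, 3)
})

test_that("mark combination distinguishes bivalent, mix, and single-mark TEs", {
  ec <- data.frame(
    te_id = rep(c("t1", "t2", "t3", "t4"), each = 2),
    body_part = "gut",
    mark = rep(c("H3K9me3", "H3K27ac"), 4),
    class = c("enrichment", "enrichment",   # bivalent
              "enrichment", "depletion",    # mix
              "enrichment", "none",         # K9-only
              "none", "excluded"),          # none
    stringsAsFactors = FALSE)
  cm <- combine_marks(ec)
  got <- setNames(cm$combined_class, cm$te_id)
  expect_equal(unname(got[c("t1", "t2", "t3", "t4")]),
               c("bivalent", "mix", "H3K9me3-only", "none"))
})

test_that("cohort-level calls recover the planted truth on the small cohort", {
  fix <- small_cohort()
  eff <- call_all_effects(fix$cohort, fix$tracks, teepi_config())
  cmp <- merge(eff$effect_calls, fix$cohort$truth$te_effects,
               by = c("te_id", "body_part", "mark"))
  expect_equal(nrow(cmp), 12L)
  planted <- cmp$effect != "none"
  expect_true(all(cmp$class[planted] == cmp$effect[planted]))
  expect_true(all(cmp$class[!planted] == "none"))
  # recovered magnitudes near the planted +50 / -40 / 3 kb
  eff_rows <- cmp[planted, ]
  expect_lt(max(abs(eff_rows$percentage.x - eff_rows$percentage.y)), 20)
  expect_true(all(abs(eff_rows$spread - eff_rows$spread_kb) <= 1))
})
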