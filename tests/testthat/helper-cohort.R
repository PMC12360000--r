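# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# 12-TE single-condition cohort with planted effects, sequences included
small_cohort <- function() {
  cached("small_cohort", {
    spec <- cohort_spec(n_te = 12, seed = 7, body_parts = "gut",
                       marks = "H3K9me3", intron_prob = 0.4)
    co <- generate_cohort(spec)
    list(spec = spec, cohort = co,
         tracks = simulate_signal(co),
         expr = simulate_expression(co))
  })
}

# noise-free cohort: planted +100% over 3 kb, sdlog 0
noise_free_cohort <- function() {
  cached("noise_free_cohort", {
    spec <- cohort_spec(n_te = 6, seed = 3, body_parts = "gut",
                        marks = "H3K9me3", signal_sdlog = 0,
                        pct_enrich = 100,
                        effect_prob = c(enrichment = 0.6, depletion = 0))
    co <- generate_cohort(spec, with_sequences = FALSE)
    list(spec = spec, cohort = co, tracks = simulate_signal(co))
  })
}

# flat profile pair: every bin = value (+ optional deterministic jitter so
# rank tests have untied data)
flat_profile <- function(value, nw = 20L, nb = 100L, jitter = 0) {
  v <- value + jitter * sin(seq_len(nb * nw * 2 + nb))
  tr <- signal_track(list(chr = v), bin_bp = 10L, strain = "X")
  cfg <- teepi_config(n_windows_per_side = nw)
  build_window_profile(tr, "chr", nw * nb * 10L, nw * nb * 10L, cfg)
}

# profile whose innermost k windows (both sides) are shifted by `mult`
# relative to a baseline jittered profile
shifted_profile <- function(mult, k, base = 1, nw = 20L, nb = 100L,
                            seed = 42L) {
  set.seed(seed)
  n <- nb * nw * 2L + nb
  v <- base * exp(rnorm(n, 0, 0.2))
  anchor <- nw * nb * 10L
  tr0 <- signal_track(list(chr = v), bin_bp = 10L, strain = "neg")
  vs <- v
  lo <- anchor / 10 - k * nb
  hi <- anchor / 10 + nb + k * nb
  vs[(lo + 1):hi] <- vs[(lo + 1):hi] * mult
  trs <- signal_track(list(chr = vs), bin_bp = 10L, strain = "pos")
  cfg <- teepi_config(n_windows_per_side = nw)
  list(pos = build_window_profile(trs, "chr", anchor, anchor + nb * 10L,
                                  cfg),
       neg = build_window_profile(tr0, "chr", anchor, anchor + nb * 10L,
                                  cfg),
       config = cfg)
}

# exact two-sided rank-sum p by enumeration of all group assignments
# (independent oracle; tie-free data only)
ranksum_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- colSums(matrix(r[combos], nrow = nx))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
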