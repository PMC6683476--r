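test_that("windows tile transcripts per the stated geometry", {
  w <- window_counts(numeric(150), numeric(150), window = 50L, step = 25L)
  expect_equal(w$start, c(0L, 25L, 50L, 75L, 100L))
  expect_equal(w$end, c(50L, 75L, 100L, 125L, 150L))
  expect_true(all(w$ip == 0) && all(w$input == 0))

  # short transcript: one full-length window
  w2 <- window_counts(numeric(30), numeric(30))
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0L, 30L))

  # non-multiple length still covers [0, len)
  w3 <- window_counts(numeric(160), numeric(160))
  expect_equal(max(w3$end), 160L)

  # sums agree with brute-force slice sums
  set.seed(2)
  x <- rpois(137, 3); y <- rpois(137, 3)
  w4 <- window_counts(x, y)
  for (i in seq_len(nrow(w4))) {
    expect_equal(w4$ip[i], sum(x[(w4$start[i] + 1):w4$end[i]]))
    expect_equal(w4$input[i], sum(y[(w4$start[i] + 1):w4$end[i]]))
  }
})

test_that("window test matches the hypergeometric tail and its contracts", {
  # symmetric counts, equal depths: enrichment 1, p >= 0.5
  t0 <- test_window(50, 50, 1e6, 1e6)
  expect_equal(t0$enrichment, 1)
  expect_gte(t0$p_value, 0.5)

  # strong enrichment: brute-force tail sum oracle
  brute <- sum(dhyper(200:210, m = 210, n = 2e6 - 210, k = 1e6))
  t1 <- test_window(200, 10, 1e6, 1e6)
  expect_equal(t1$p_value, brute, tolerance = 1e-12)
  expect_lt(t1$p_value, 1e-6)

  # zero IP: depleted, p near 1
  t2 <- test_window(0, 20, 1e6, 1e6)
  expect_lt(t2$enrichment, 1)
  expect_gt(t2$p_value, 0.99)
})

test_that("p-value is monotone decreasing in the IP count", {
  set.seed(4)
  for (r in 1:20) {
    input <- sample(0:200, 1)
    ip <- sort(sample(0:400, 10))
    p <- test_window(ip, input, 5e5, 5e5)$p_value
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("planted sites are recovered as single peaks with close summits", {
  cfg <- small_config(fraction_methylated = 0.2)
  sim <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(sim, "A", 1L)
  peaks <- call_peaks(cnt$ip, cnt$input)
  truth <- sim$truth$sites
  hits <- 0L
  for (k in seq_len(nrow(truth))) {
    p <- peaks[peaks$transcript_id == truth$transcript_id[k] &
                 peaks$start <= truth$position[k] &
                 peaks$end > truth$position[k], , drop = FALSE]
    if (nrow(p) == 1L && abs(p$summit - truth$position[k]) <= 50) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / nrow(truth), 0.9)
  # no transcript carries more than one called peak here (single sites)
  expect_lte(max(table(peaks$transcript_id)), 1L)
})

test_that("two sites 400 nt apart yield two separate peaks", {
  # one long transcript, two planted windows, deterministic counts
  len <- 1200L
  input <- rep(30, len)
  ip <- rep(30, len)
  for (s in c(300L, 700L)) ip[(s - 50L):(s + 49L)] <- 200
  ips <- coverage_set(list(tx = ip), library_size = 1e6)
  ins <- coverage_set(list(tx = input), library_size = 1e6)
  peaks <- call_peaks(ips, ins)
  expect_equal(nrow(peaks), 2L)
  expect_true(all(abs(sort(peaks$summit) - c(300, 700)) <= 60))
})

test_that("consensus equals the stated intersection rules", {
  mk <- function(start, end, p = 1e-6, summit = NULL) {
    data.frame(transcript_id = "t", start = start, end = end,
               summit = if (is.null(summit)) (start + end) %/% 2 else summit,
               enrichment = 5, p_value = p, q_value = p)
  }
  # identical peaks in all three replicates
  cons <- consensus_peaks(list(mk(100, 200), mk(100, 200), mk(100, 200)))
  expect_equal(c(cons$start, cons$end), c(100L, 200L))

  # staggered peaks: intersection [180, 200)
  cons2 <- consensus_peaks(list(mk(100, 200), mk(150, 250), mk(180, 300)))
  expect_equal(c(cons2$start, cons2$end), c(180L, 200L))

  # absent from one replicate: no consensus
  none <- consensus_peaks(list(mk(100, 200), mk(100, 200),
                               mk(500, 600)))
  expect_equal(nrow(none), 0L)

  # summit taken from the smallest-p supporting peak
  cons3 <- consensus_peaks(list(mk(100, 200, p = 1e-3, summit = 120),
                                mk(120, 260, p = 1e-9, summit = 190),
                                mk(90, 210, p = 1e-6, summit = 150)))
  expect_equal(cons3$summit, 190L)
})

test_that("consensus matches the brute-force all-triples oracle on fuzz", {
  set.seed(77)
  for (r in 1:120) {
    sets <- lapply(1:3, function(k) {
      n <- sample(1:4, 1)
      start <- sample(0:300, n)
      cbind(start, start + sample(10:120, n, replace = TRUE))
    })
    peak_sets <- lapply(sets, function(m)
      data.frame(transcript_id = "t", start = m[, 1L], end = m[, 2L],
                 summit = m[, 1L], enrichment = 2, p_value = 1e-4,
                 q_value = 1e-4))
    got <- consensus_peaks(peak_sets)
    want <- oracle_consensus(sets)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, unname(want[, 1L]))
      expect_equal(got$end, unname(want[, 2L]))
    }
  }
})

test_that("consensus is invariant to replicate order", {
  set.seed(8)
  sets <- lapply(1:3, function(k) {
    start <- sample(0:200, 3)
    data.frame(transcript_id = "t", start = start,
               end = start + sample(20:80, 3, replace = TRUE),
               summit = start + 5L, enrichment = 2,
               p_value = runif(3, 1e-8, 1e-3), q_value = 1e-3)
  })
  a <- consensus_peaks(sets)
  b <- consensus_peaks(rev(sets))
  expect_equal(a[, c("start", "end", "summit")],
               b[, c("start", "end", "summit")])
})

test_that("replicate correlation behaves at the extremes and under noise", {
  cv <- coverage_set(list(t = as.numeric(rpois(500, 10))))
  r <- replicate_correlation(list(cv, cv))
  expect_equal(r[1, 2], 1)

  anti <- coverage_set(list(t = rev(cv$tracks$t) +
                              max(cv$tracks$t) - cv$tracks$t))
  # anti-correlated toy vectors
  x <- coverage_set(list(t = c(rep(0, 100), rep(20, 100))))
  y <- coverage_set(list(t = c(rep(20, 100), rep(0, 100))))
  expect_lt(replicate_correlation(list(x, y))[1, 2], 0)

  # independent replicates of identical expectations at 30x coverage
  # (no biological dispersion, so the two draws share their means)
  cfg <- small_config(dispersion = 0)
  sim <- simulate_transcriptome(cfg)
  c1 <- simulate_counts(sim, "A", 1L)
  c2 <- simulate_counts(sim, "A", 2L)
  expect_gt(replicate_correlation(list(c1$input, c2$input))[1, 2], 0.9)
})
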