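test_that("FPKM arithmetic is exact and scale-invariant", {
  expect_equal(fpkm(100, 2000, 1e7), 5)
  expect_equal(fpkm(0, 2000, 1e7), 0)
  expect_equal(fpkm(100, 2000, 1e7), fpkm(200, 2000, 2e7))
  # exact rational arithmetic on integers
  expect_identical(fpkm(3L, 1500L, 2e6), 3 / (1.5 * 2))
})

test_that("differential expression respects its criteria and detects shifts", {
  # identical replicate sets: nothing significant
  m <- matrix(c(10, 12, 11, 10, 12, 11), nrow = 1)
  de0 <- differential_expression(m[, 1:3, drop = FALSE],
                                 m[, 4:6, drop = FALSE])
  expect_false(any(de0$significant))

  # planted 4x shift at 3 replicates, CV 10%
  set.seed(61)
  base <- runif(40, 5, 50)
  fa <- sapply(1:3, function(r) base * rnorm(40, 1, 0.1))
  fb <- fa * ifelse(seq_len(40) <= 10, 4, 1) *
    matrix(rnorm(120, 1, 0.1), nrow = 40) / matrix(rnorm(120, 1, 0.1),
                                                   nrow = 40)
  de <- differential_expression(fa, fb)
  expect_gte(mean(de$significant[1:10]), 0.8)
  expect_true(all(de$direction[de$significant][
    seq_len(sum(de$significant[1:10]))] == "up"))

  # fold change exactly 1.5 passes the inclusive threshold
  a <- matrix(c(10, 10, 10), nrow = 1)
  b <- matrix(c(15.25, 15.25, 15.25), nrow = 1)  # (15.25+.5)/(10+.5) = 1.5
  de15 <- differential_expression(a, b)
  expect_equal(de15$fold_change, 1.5)
  expect_true(de15$significant)   # zero-variance unequal means -> p = 0
})

test_that("differential m6A follows its formula; p from hypergeometric oracle", {
  peaks <- data.frame(transcript_id = "t", start = 0L, end = 10L)
  mk <- function(ip_counts, in_counts, n_ip, n_in) list(list(
    ip = coverage_set(list(t = ip_counts), library_size = n_ip),
    input = coverage_set(list(t = in_counts), library_size = n_in)))
  # identical counts in both conditions: FC 1, not significant
  ca <- mk(c(rep(2, 10)), c(rep(2, 10)), 1e4, 1e4)
  d0 <- differential_m6a(peaks, ca, ca)
  expect_equal(d0$fold_change, 1)
  expect_false(d0$significant)

  # worked example: [[IP_A=20, in_A=20], [IP_B=120, in_B=20]], equal
  # library sizes; enrichment_B/enrichment_A = 120.5/20.5
  ca <- mk(c(20, rep(0, 9)), c(20, rep(0, 9)), 1e4, 1e4)
  cb <- mk(c(120, rep(0, 9)), c(20, rep(0, 9)), 1e4, 1e4)
  d1 <- differential_m6a(peaks, ca, cb)
  expect_equal(d1$fold_change, 120.5 / 20.5, tolerance = 1e-12)
  # two-sided Fisher oracle by brute-force enumeration of the 2x2 family
  oracle_fisher2 <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(support, c1, n - c1, r1)
    sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
  }
  expect_equal(d1$p_value, oracle_fisher2(20, 20, 120, 20),
               tolerance = 1e-9)
  expect_true(d1$significant)
  expect_equal(d1$direction, "up")

  # swapping condition labels inverts FC and preserves p
  d2 <- differential_m6a(peaks, cb, ca)
  expect_equal(d2$fold_change, 1 / d1$fold_change, tolerance = 1e-12)
  expect_equal(d2$p_value, d1$p_value, tolerance = 1e-12)
  expect_equal(d2$direction, "down")
})

test_that("planted methylation fold changes are detected with correct sign", {
  cfg <- simulation_config(n_transcripts = 250, seed = 71,
                           fraction_methylated = 0.2, diff_fraction = 0.5,
                           hyper_fraction = 1, diff_m6a_fc = 3)
  sim <- simulate_transcriptome(cfg)
  counts <- simulate_replicates(sim, conditions = c("A", "B"))
  peaks_a <- consensus_peaks(lapply(counts$A, function(r)
    call_peaks(r$ip, r$input)))
  peaks_b <- consensus_peaks(lapply(counts$B, function(r)
    call_peaks(r$ip, r$input)))
  regions <- meripr:::merge_peak_sets(peaks_a, peaks_b)
  dm <- differential_m6a(regions, counts$A, counts$B)
  truth <- sim$truth$sites
  up_tx <- truth$transcript_id[truth$direction == "up"]
  det <- dm[dm$significant, ]
  sens <- mean(up_tx %in% det$transcript_id[det$direction == "up"])
  expect_gte(sens, 0.8)
  # every significant call on a differential transcript has the
  # planted direction
  called_up <- det$transcript_id[det$direction == "up"]
  expect_true(all(!called_up %in%
                    truth$transcript_id[truth$direction == "down"]))
})

test_that("quadrant cross-tabulation matches a hand-counted toy set", {
  dm <- data.frame(transcript_id = c("a", "b", "c", "d", "e", "e", "f"),
                   start = 0L, end = 10L,
                   fold_change = c(2, 3, 0.4, 2.5, 2, 0.3, 1.1),
                   p_value = c(1e-4, 1e-5, 1e-3, 1e-2, 1e-6, 1e-2, 0.5),
                   significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                   FALSE),
                   direction = c("up", "up", "down", "up", "up", "down",
                                 "unchanged"))
  de <- data.frame(transcript_id = c("a", "b", "c", "d", "e", "f"),
                   direction = c("down", "down", "up", "unchanged",
                                 "up", "down"))
  q <- quadrants(dm, de)
  # e has two peaks; the smaller-p (up) one represents it
  want <- matrix(c(1L, 2L, 1L,   # m6a up: expr up(e), down(a,b), unch(d)
                   1L, 0L, 0L),  # m6a down: expr up(c)
                 nrow = 2, byrow = TRUE,
                 dimnames = dimnames(q$table))
  expect_equal(q$table, want)
  # marginals equal the number of represented transcripts
  expect_equal(sum(q$table), 5L)

  # empty input: all-zero table
  q0 <- quadrants(dm[dm$significant == FALSE & dm$transcript_id == "zz", ],
                  de)
  expect_true(all(q0$table == 0L))
})

test_that("Fig-4-like regime shows the planted negative association", {
  cfg <- simulation_config(n_transcripts = 300, seed = 81,
                           fraction_methylated = 0.15)
  rep <- run_pipeline(cfg)
  st <- association_sign_test(rep$quadrants)
  expect_gt(st$n_negative, st$n_positive)
  expect_lt(st$p_value, 0.05)
})
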