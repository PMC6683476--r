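test_that("worked five-segment partition example", {
  # 5'UTR 200 / CDS 900 (stop triplet [1097,1100)) / 3'UTR 300
  m <- transcript_model("t", "g", "c", "+", rbind(c(0L, 1400L)),
                        200L, 1100L)
  part <- partition_transcript(m)
  iv <- part$intervals
  get <- function(seg) unname(unlist(
    iv[iv$segment == seg, c("start", "end")]))
  expect_equal(get("stop_codon"), c(1047L, 1147L))
  expect_equal(get("tss"), c(0L, 100L))
  expect_equal(get("utr5"), c(100L, 200L))
  expect_equal(get("cds"), c(200L, 1047L))
  expect_equal(get("utr3"), c(1147L, 1400L))
})

test_that("short 5'UTR folds entirely into the TSS segment", {
  m <- transcript_model("t", "g", "c", "+", rbind(c(0L, 1000L)),
                        40L, 640L)
  part <- partition_transcript(m)
  expect_equal(unname(part$nt["tss"]), 40)
  expect_equal(unname(part$nt["utr5"]), 0)
})

test_that("partition covers every base exactly once on random transcripts", {
  set.seed(99)
  for (i in 1:60) {
    m <- random_model(sprintf("p%02d", i))
    part <- partition_transcript(m)
    iv <- part$intervals[order(part$intervals$start), ]
    # contiguous, gapless, within bounds
    expect_equal(iv$start[1L], 0L)
    expect_equal(iv$end[nrow(iv)], m$length_t)
    if (nrow(iv) > 1L) expect_equal(iv$start[-1L], iv$end[-nrow(iv)])
    # labels equal brute-force per-base rule application
    expect_equal(segment_of(m, 0:(m$length_t - 1L)),
                 oracle_segment_labels(m))
    expect_equal(sum(part$nt), m$length_t)
  }
})

test_that("non-coding transcripts are rejected from segment math", {
  m <- transcript_model("nc", "g", "c", "+", rbind(c(0L, 500L)))
  expect_error(partition_transcript(m), "non-coding")
})

test_that("summit assignment conserves counts and applies precedence", {
  m <- transcript_model("t", "g", "c", "+", rbind(c(0L, 1400L)),
                        200L, 1100L)
  models <- structure(list(t = m), class = "transcript_models")
  peaks <- data.frame(transcript_id = "t",
                      summit = c(0L, 150L, 500L, 1060L, 1300L))
  asg <- assign_summits(peaks, models)
  expect_equal(as.character(asg$labels$segment),
               c("tss", "utr5", "cds", "stop_codon", "utr3"))
  # position 1060 sits inside CDS coordinates but in the stop window
  expect_equal(sum(asg$counts), nrow(peaks))
  expect_equal(sum(asg$fractions), 1)
})

test_that("relative enrichment: identity under uniformity, toy arithmetic", {
  # all summits in a stop window occupying 5% of nucleotides
  sf <- c(tss = 0, utr5 = 0, cds = 0, stop_codon = 1, utr3 = 0)
  nf <- c(tss = 0.1, utr5 = 0.1, cds = 0.55, stop_codon = 0.05, utr3 = 0.2)
  expect_equal(unname(relative_enrichment(sf, nf)["stop_codon"]), 20)

  # hand computation on a 3-transcript toy set
  models <- structure(list(
    a = transcript_model("a", "g", "c", "+", rbind(c(0L, 1400L)),
                         200L, 1100L),
    b = transcript_model("b", "g", "c", "+", rbind(c(0L, 900L)),
                         100L, 700L),
    nc = transcript_model("nc", "g", "c", "+", rbind(c(0L, 500L)))),
    class = "transcript_models")
  nf2 <- segment_nt_fractions(models)   # non-coding excluded
  # by hand: a contributes 100/100/847/100/253, b 100/0/547/100/153
  hand <- c(tss = 200, utr5 = 100, cds = 1394, stop_codon = 200,
            utr3 = 406) / 2300
  expect_equal(nf2, hand[names(nf2)])

  summits <- data.frame(transcript_id = c("a", "a", "b"),
                        summit = c(1100L, 50L, 650L))
  asg <- assign_summits(summits, models)
  re <- relative_enrichment(asg$fractions, nf2)
  expect_equal(unname(re["stop_codon"]),
               (2 / 3) / unname(hand["stop_codon"]))
  expect_equal(unname(re["tss"]), (1 / 3) / unname(hand["tss"]))
})

test_that("relative enrichment is invariant to duplicating transcripts", {
  set.seed(21)
  models <- lapply(1:10, function(i) random_model(sprintf("d%02d", i)))
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  class(models) <- "transcript_models"
  doubled <- models
  for (m in models) {
    m2 <- m; m2$transcript_id <- paste0(m$transcript_id, "_copy")
    doubled[[m2$transcript_id]] <- m2
  }
  class(doubled) <- "transcript_models"
  expect_equal(segment_nt_fractions(models), segment_nt_fractions(doubled))
})

test_that("metagene profile is a density with correctly placed mass", {
  m <- transcript_model("t", "g", "c", "+", rbind(c(0L, 1400L)),
                        200L, 1100L)
  models <- structure(list(t = m), class = "transcript_models")
  # all summits at the CDS midpoint -> one central CDS bin
  mid <- (200L + 1097L) %/% 2L
  prof <- metagene(data.frame(transcript_id = "t",
                              summit = rep(mid, 10L)), models)
  expect_equal(sum(prof$density), 1)
  expect_equal(sum(prof$density > 0), 1L)
  expect_equal(prof$segment[which(prof$density > 0)], "cds")

  # uniform summits fill bins roughly evenly within each segment
  set.seed(31)
  pos <- sample(0:1399, 8000, replace = TRUE)
  prof2 <- metagene(data.frame(transcript_id = "t", summit = pos), models)
  expect_equal(sum(prof2$density), 1)
  cds_bins <- prof2$density[prof2$segment == "cds"]
  expect_lt(max(cds_bins) / min(cds_bins), 2)
})

test_that("peak-count distribution and peaks-per-expressed arithmetic", {
  pk <- data.frame(transcript_id = c("a", "b", "b", "c", "c", "c",
                                     rep("d", 5)))
  res <- peaks_per_transcript(pk)
  expect_equal(unname(res$fractions),
               c(1, 1, 1, 1) / 4)
  expect_equal(res$mean, 11 / 4)
  expect_equal(sum(res$fractions), 1)

  only_ones <- peaks_per_transcript(
    data.frame(transcript_id = letters[1:10]))
  expect_equal(unname(only_ones$fractions["1"]), 1)

  expr <- data.frame(transcript_id = letters[1:10],
                     fpkm = c(rep(5, 8), 0.2, 0.1))
  expect_equal(peaks_per_expressed(data.frame(transcript_id = letters[1:4]),
                                   expr), 0.5)
  none <- data.frame(transcript_id = "a", fpkm = 0)
  expect_error(peaks_per_expressed(pk, none), "FPKM floor")
})
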