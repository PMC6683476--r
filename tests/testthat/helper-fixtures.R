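# Shared fixtures: tiny transcript models and a brute-force per-base
# coordinate oracle used across test files.

# Single-exon plus-strand mRNA: exon [1000, 2500), CDS at transcript
# offsets [200, 1100).
single_plus <- function() {
  transcript_model("txp", "gp", "chr1", "+",
                   rbind(c(1000L, 2500L)), 200L, 1100L)
}

single_minus <- function() {
  transcript_model("txm", "gm", "chr1", "-",
                   rbind(c(1000L, 2500L)), 200L, 1100L)
}

# Brute-force per-base genomic -> transcript mapping, independent of
# the implementation: enumerate exonic bases in transcript order.
oracle_tx_offsets <- function(model) {
  ex <- model$exons
  bases <- unlist(lapply(seq_len(nrow(ex)),
                         function(i) seq.int(ex[i, 1L], ex[i, 2L] - 1L)))
  if (model$strand == "-") bases <- rev(bases)
  stats::setNames(seq_along(bases) - 1L, bases)   # genomic base -> offset
}

random_model <- function(id = "tx", min_len = 200L) {
  utr5 <- sample(1:250, 1)
  cds <- 3L * sample(2:400, 1)
  utr3 <- sample(1:300, 1)
  len <- utr5 + cds + utr3
  nex <- sample(1:3, 1)
  strand <- sample(c("+", "-"), 1)
  if (nex == 1L) {
    exons <- rbind(c(50L, 50L + len))
  } else {
    brks <- sort(sample(seq_len(len - 1L), nex - 1L))
    sizes <- diff(c(0L, brks, len))
    starts <- 50L + cumsum(c(0L, head(sizes, -1) + 100L))
    exons <- cbind(starts, starts + sizes)
  }
  transcript_model(id, paste0("g_", id), "chrR", strand, exons,
                   utr5, utr5 + cds)
}

# Brute-force five-segment labeling of every base, applying the stated
# rules position by position.
oracle_segment_labels <- function(model, stop_window = 100L,
                                  tss_window = 100L) {
  len <- model$length_t
  cs <- model$cds_start_t; ce <- model$cds_end_t
  c0 <- ce - 3L
  half <- stop_window %/% 2L
  vapply(0:(len - 1L), function(p) {
    if (p >= max(0L, c0 - half) && p < min(len, c0 + half)) return("stop_codon")
    if (p < min(tss_window, cs)) return("tss")
    if (p < cs) return("utr5")
    if (p < ce) return("cds")
    "utr3"
  }, character(1))
}

# Brute-force all-tuples interval intersection oracle for consensus
# peaks: every combination of one interval per replicate, non-empty
# intersections pooled and merged into maximal intervals.
oracle_consensus <- function(interval_sets) {
  grids <- expand.grid(lapply(interval_sets, function(m) seq_len(nrow(m))))
  pieces <- list()
  for (r in seq_len(nrow(grids))) {
    lo <- max(vapply(seq_along(interval_sets), function(k)
      interval_sets[[k]][grids[r, k], 1L], numeric(1)))
    hi <- min(vapply(seq_along(interval_sets), function(k)
      interval_sets[[k]][grids[r, k], 2L], numeric(1)))
    if (hi > lo) pieces[[length(pieces) + 1L]] <- c(lo, hi)
  }
  if (!length(pieces)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else out <- rbind(out, m[i, ])
  }
  out
}

small_config <- function(...) {
  simulation_config(n_transcripts = 60, seed = 42, ...)
}
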