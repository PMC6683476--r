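# Transcript-topology analysis: five-segment anatomy, summit
# assignment, transcriptome-normalized enrichment, metagene profiles,
# and per-transcript peak statistics.
#
# The five segments are TSS, 5'UTR, CDS, stop codon, and 3'UTR. The
# stop-codon segment is the 100-nt window centred on the stop codon
# (anchored at the first base of the stop triplet) and takes precedence
# over the segments it overlaps; the TSS segment is the first
# min(100, 5'UTR length) nt, mirroring the stop-window convention.

#' Partition a coding transcript into the five segments
#'
#' @param model A coding [transcript_model()].
#' @param stop_window Width (nt) of the stop-codon window, centred on
#'   the first base of the stop triplet and truncated at transcript
#'   ends.
#' @param tss_window Width (nt) of the TSS segment (truncated to the
#'   5'UTR length).
#' @return list with `intervals` (data.frame `segment`, `start`, `end`;
#'   half-open, possibly several rows per segment) and `nt` (named
#'   vector of per-segment nucleotide counts). The intervals partition
#'   `[0, length_t)` exactly.
#' @export
partition_transcript <- function(model, stop_window = 100L,
                                 tss_window = 100L) {
  if (!model$coding)
    stop("transcript '", model$transcript_id,
         "' is non-coding; segment partition is defined for mRNAs only")
  len <- model$length_t
  cs <- model$cds_start_t
  ce <- model$cds_end_t
  stop_first <- ce - 3L                       # first base of stop triplet
  half <- stop_window %/% 2L
  stop_iv <- c(max(0L, stop_first - half), min(len, stop_first + half))

  raw <- list(tss = c(0L, min(tss_window, cs)),
              utr5 = c(min(tss_window, cs), cs),
              cds = c(cs, ce),
              utr3 = c(ce, len))
  subtract <- function(iv, cut) {
    pieces <- list(c(iv[1L], min(iv[2L], cut[1L])),
                   c(max(iv[1L], cut[2L]), iv[2L]))
    Filter(function(p) p[2L] > p[1L], pieces)
  }
  rows <- list(data.frame(segment = "stop_codon",
                          start = stop_iv[1L], end = stop_iv[2L]))
  for (seg in names(raw)) {
    for (p in subtract(raw[[seg]], stop_iv))
      rows[[length(rows) + 1L]] <- data.frame(segment = seg,
                                              start = p[1L], end = p[2L])
  }
  iv <- do.call(rbind, rows)
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  nt <- vapply(segment_name_levels, function(s)
    sum(iv$end[iv$segment == s] - iv$start[iv$segment == s]), numeric(1))
  list(intervals = iv, nt = nt)
}

#' Segment label of transcript positions
#'
#' @param model A coding [transcript_model()].
#' @param pos Vector of transcript offsets.
#' @inheritParams partition_transcript
#' @return Character vector of segment labels.
#' @export
segment_of <- function(model, pos, stop_window = 100L, tss_window = 100L) {
  part <- partition_transcript(model, stop_window, tss_window)
  iv <- part$intervals
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(iv))) {
    hit <- pos >= iv$start[i] & pos < iv$end[i]
    out[hit] <- iv$segment[i]
  }
  out
}

#' Segment nucleotide fractions over a transcript set
#'
#' The relative fraction each segment occupies in the transcriptome,
#' used as the normalizer for [relative_enrichment()].
#'
#' @param models `transcript_models`; non-coding entries are skipped.
#' @inheritParams partition_transcript
#' @return Named numeric vector summing to 1.
#' @export
segment_nt_fractions <- function(models, stop_window = 100L,
                                 tss_window = 100L) {
  coding <- Filter(function(m) m$coding, models)
  nt <- Reduce(`+`, lapply(coding, function(m)
    partition_transcript(m, stop_window, tss_window)$nt))
  nt / sum(nt)
}

#' Assign peak summits to transcript segments
#'
#' Each summit falls in exactly one segment (the stop-codon window
#' taking precedence over the regions it overlaps).
#'
#' @param peaks data.frame with `transcript_id` and `summit` columns.
#' @param models `transcript_models`.
#' @inheritParams partition_transcript
#' @return list with `labels` (input peaks plus a `segment` column),
#'   `counts` and `fractions` (named by segment; fractions sum to 1).
#' @export
assign_summits <- function(peaks, models, stop_window = 100L,
                           tss_window = 100L) {
  seg <- character(nrow(peaks))
  for (tx in unique(peaks$transcript_id)) {
    m <- models[[tx]]
    if (is.null(m)) stop("peak on unknown transcript '", tx, "'")
    sel <- peaks$transcript_id == tx
    seg[sel] <- segment_of(m, peaks$summit[sel], stop_window, tss_window)
  }
  peaks$segment <- factor(seg, levels = segment_name_levels)
  counts <- table(peaks$segment)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  fr <- if (sum(counts) > 0) counts / sum(counts) else counts
  list(labels = peaks, counts = counts, fractions = fr)
}

#' Segment-normalized relative enrichment
#'
#' Divides each segment's share of peak summits by the share of
#' transcriptome nucleotides that segment occupies; 1 means summits
#' land there no more often than expected from segment size alone.
#'
#' @param summit_fractions Named fractions from [assign_summits()].
#' @param nt_fractions Named fractions from [segment_nt_fractions()]
#'   over the same transcript set.
#' @return Named numeric vector of enrichment ratios.
#' @export
relative_enrichment <- function(summit_fractions, nt_fractions) {
  stopifnot(abs(sum(nt_fractions) - 1) < 1e-8)
  segs <- names(nt_fractions)
  summit_fractions[segs] / nt_fractions[segs]
}

#' Metagene profile of peak summits
#'
#' Each summit's position is rescaled to a fractional position within
#' its transcript region, using three rescaled regions: 5'UTR (TSS
#' included), CDS, and 3'UTR (the stop window split at the first stop
#' base). Bin masses are normalized to sum to 1.
#'
#' @param peaks data.frame with `transcript_id` and `summit`.
#' @param models `transcript_models`.
#' @param bins Integer vector of bin counts for (5'UTR, CDS, 3'UTR);
#'   the defaults are proportional to typical segment lengths.
#' @return list of class `metagene_profile` with `density` (one value
#'   per bin, summing to 1), `segment` (bin region labels), `x`
#'   (plotting coordinate on a 0-3 axis), and `n_summits`.
#' @export
metagene <- function(peaks, models, bins = c(30L, 100L, 30L)) {
  assign_bin <- function(m, pos) {
    c3 <- m$cds_end_t - 3L
    b <- c(0L, m$cds_start_t, c3, m$length_t)
    if (pos < b[2L]) {
      k <- 1L; frac <- (pos - b[1L]) / max(1L, b[2L] - b[1L])
    } else if (pos < b[3L]) {
      k <- 2L; frac <- (pos - b[2L]) / max(1L, b[3L] - b[2L])
    } else {
      k <- 3L; frac <- (pos - b[3L]) / max(1L, b[4L] - b[3L])
    }
    offset <- c(0L, cumsum(bins))[k]
    offset + min(bins[k] - 1L, floor(frac * bins[k])) + 1L
  }
  counts <- numeric(sum(bins))
  n <- 0L
  for (i in seq_len(nrow(peaks))) {
    m <- models[[peaks$transcript_id[i]]]
    if (is.null(m) || !m$coding) next
    j <- assign_bin(m, peaks$summit[i])
    counts[j] <- counts[j] + 1
    n <- n + 1L
  }
  segment <- rep(c("utr5", "cds", "utr3"), times = bins)
  x <- unlist(lapply(seq_along(bins), function(k)
    (k - 1) + (seq_len(bins[k]) - 0.5) / bins[k]))
  dens <- if (n > 0) counts / n else counts
  structure(list(density = dens, segment = segment, x = x, n_summits = n),
            class = "metagene_profile")
}

#' Plot a metagene profile
#'
#' @param x A `metagene_profile`.
#' @param ... Passed to [plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  plot(x$x, x$density, type = "l", xaxt = "n",
       xlab = "", ylab = "summit density", ...)
  graphics::axis(1, at = c(0.5, 1.5, 2.5),
                 labels = c("5'UTR", "CDS", "3'UTR"), tick = FALSE)
  graphics::abline(v = c(1, 2), lty = 2, col = "grey50")
  invisible(x)
}

#' Peak-count distribution over methylated transcripts
#'
#' @param peaks Consensus-peak data.frame.
#' @return list with `fractions` over `{1, 2, 3, >3}` peaks (summing to
#'   1 across m6A-containing transcripts), `counts`, and `mean` peaks
#'   per methylated transcript.
#' @export
peaks_per_transcript <- function(peaks) {
  if (nrow(peaks) == 0L)
    return(list(fractions = stats::setNames(numeric(4),
                                            c("1", "2", "3", ">3")),
                counts = stats::setNames(numeric(4), c("1", "2", "3", ">3")),
                mean = NaN))
  k <- table(peaks$transcript_id)
  cls <- cut(as.numeric(k), breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
             labels = c("1", "2", "3", ">3"))
  counts <- table(cls)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  list(fractions = counts / sum(counts), counts = counts,
       mean = mean(as.numeric(k)))
}

#' Peaks per actively expressed transcript
#'
#' @param peaks Consensus-peak data.frame.
#' @param expression data.frame with `transcript_id` (or `gene_id`) and
#'   `fpkm` columns.
#' @param fpkm_min Expression floor defining "actively expressed".
#' @return Total consensus peaks divided by the number of expressed
#'   transcripts.
#' @export
peaks_per_expressed <- function(peaks, expression, fpkm_min = 1) {
  n_expr <- sum(expression$fpkm >= fpkm_min)
  if (n_expr == 0L) stop("no transcripts at or above the FPKM floor")
  nrow(peaks) / n_expr
}
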