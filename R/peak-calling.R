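# IP-vs-input peak detection in transcript space.
#
# Sliding windows are tested with a one-sided Fisher exact test of the
# window's IP and input fragment counts against the two library sizes,
# BH-adjusted jointly over every window of every transcript
# (transcriptome-wide FDR), merged into peaks, and intersected across
# replicates into consensus peaks. This is a defined, testable
# replacement for genome-scale peak callers, whose local-background
# machinery is aimed at ChIP DNA rather than transcript-space RNA
# coverage.

#' Tile a transcript with sliding windows
#'
#' @param ip,input [coverage_set()]-style tracks for one transcript
#'   (numeric vectors of equal length), or `NULL` input for windowing
#'   only.
#' @param window Window width (nt); default 50, about half the ~100-nt
#'   fragment size.
#' @param step Stride (nt); default 25.
#' @return data.frame with `start`, `end`, `ip`, `input` summed counts
#'   per window. Windows tile `[0, length)`; a transcript shorter than
#'   `window` gets a single full-length window.
#' @export
window_counts <- function(ip, input = NULL, window = 50L, step = 25L) {
  len <- length(ip)
  if (!is.null(input) && length(input) != len)
    stop("IP and input tracks differ in length")
  starts <- window_starts(len, window, step)
  ends <- pmin(starts + window, len)
  data.frame(start = starts, end = ends,
             ip = window_sums(ip, starts, ends),
             input = if (is.null(input)) NA_real_
                     else window_sums(input, starts, ends))
}

window_starts <- function(len, window, step) {
  if (len <= window) return(0L)
  nwin <- ceiling((len - window) / step) + 1L
  as.integer(seq(0L, by = step, length.out = nwin))
}

window_sums <- function(x, starts, ends) {
  cs <- c(0, cumsum(x))
  cs[ends + 1L] - cs[starts + 1L]
}

#' Test one window for IP enrichment
#'
#' Enrichment is the pseudocounted depth-normalized ratio
#' `((ip + 0.5)/N_IP) / ((input + 0.5)/N_in)`; the p-value is a
#' one-sided Fisher exact test (hypergeometric upper tail) on the 2x2
#' table `[[ip, N_IP - ip], [input, N_in - input]]`, alternative: IP
#' enriched. Vectorized over windows.
#'
#' @param ip,input Window fragment counts.
#' @param n_ip,n_in Library sizes.
#' @return data.frame with `enrichment` and `p_value`.
#' @export
test_window <- function(ip, input, n_ip, n_in) {
  stopifnot(n_ip > 0, n_in > 0, all(ip >= 0), all(input >= 0))
  enr <- ((ip + 0.5) / n_ip) / ((input + 0.5) / n_in)
  p <- stats::phyper(ip - 1, m = ip + input,
                     n = n_ip + n_in - ip - input, k = n_ip,
                     lower.tail = FALSE)
  data.frame(enrichment = enr, p_value = pmin(1, p))
}

#' Test every window of every transcript
#'
#' The window-level table underlying [call_peaks()]: sliding windows
#' over all transcripts, [test_window()] per window, and BH adjustment
#' computed jointly across the whole transcriptome.
#'
#' @inheritParams call_peaks
#' @return data.frame with `transcript_id`, `start`, `end`, `ip`,
#'   `input`, `enrichment`, `p_value`, `q_value`.
#' @export
transcriptome_window_tests <- function(ip, input, window = 50L,
                                       step = 25L) {
  stopifnot(inherits(ip, "coverage_set"), inherits(input, "coverage_set"),
            identical(names(ip$tracks), names(input$tracks)))
  wins <- lapply(names(ip$tracks), function(tx) {
    w <- window_counts(ip$tracks[[tx]], input$tracks[[tx]], window, step)
    w$transcript_id <- tx
    w
  })
  wins <- do.call(rbind, wins)
  tst <- test_window(wins$ip, wins$input, ip$library_size,
                     input$library_size)
  wins$enrichment <- tst$enrichment
  wins$p_value <- tst$p_value
  wins$q_value <- stats::p.adjust(wins$p_value, method = "BH")
  wins
}

#' Call m6A peaks on a coverage set
#'
#' Every transcript is tiled with sliding windows, each window tested
#' with [test_window()], and BH adjustment applied jointly over all
#' windows of all transcripts. Significant windows (`q < alpha_fdr`)
#' that overlap or lie within `merge_gap` nt of each other are merged
#' into peaks. A peak's p-value is its minimum window p; its q-value is
#' that window's BH value; its summit is the position of maximum
#' pseudocounted per-nucleotide normalized enrichment (ties broken
#' 5'-most).
#'
#' @param ip,input [coverage_set()]s over the same transcripts.
#' @param alpha_fdr FDR threshold (default 0.05).
#' @param window,step Window geometry, see [window_counts()].
#' @param merge_gap Maximum gap (nt) bridged when merging significant
#'   windows; defaults to `step`.
#' @return data.frame of peaks: `transcript_id`, `start`, `end`,
#'   `summit`, `enrichment`, `p_value`, `q_value`.
#' @export
call_peaks <- function(ip, input, alpha_fdr = 0.05, window = 50L,
                       step = 25L, merge_gap = step) {
  n_ip <- ip$library_size
  n_in <- input$library_size
  wins <- transcriptome_window_tests(ip, input, window, step)

  sig <- wins[wins$q_value < alpha_fdr, , drop = FALSE]
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), summit = integer(),
                      enrichment = numeric(), p_value = numeric(),
                      q_value = numeric())
  if (nrow(sig) == 0L) return(empty)

  peaks <- lapply(split(sig, sig$transcript_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    # group by chained adjacency: start new group when the gap to the
    # running right edge exceeds merge_gap
    edge <- d$end[1L]; grp <- integer(nrow(d)); grp[1L] <- 1L
    for (i in seq_len(nrow(d))[-1L]) {
      grp[i] <- grp[i - 1L] + as.integer(d$start[i] > edge + merge_gap)
      edge <- max(edge, d$end[i])
    }
    do.call(rbind, lapply(split(d, grp), function(g) {
      best <- which.min(g$p_value)
      data.frame(transcript_id = g$transcript_id[1L],
                 start = min(g$start), end = max(g$end),
                 summit = NA_integer_, enrichment = NA_real_,
                 p_value = g$p_value[best], q_value = g$q_value[best])
    }))
  })
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL

  # summit and peak-level enrichment from per-nucleotide tracks
  for (i in seq_len(nrow(peaks))) {
    tx <- peaks$transcript_id[i]
    idx <- (peaks$start[i] + 1L):peaks$end[i]
    iv <- ip$tracks[[tx]][idx]
    nv <- input$tracks[[tx]][idx]
    ratio <- ((iv + 0.5) / n_ip) / ((nv + 0.5) / n_in)
    peaks$summit[i] <- peaks$start[i] + which.max(ratio) - 1L
    peaks$enrichment[i] <- ((sum(iv) + 0.5) / n_ip) /
      ((sum(nv) + 0.5) / n_in)
  }
  peaks[order(peaks$transcript_id, peaks$start), , drop = FALSE]
}

#' Replicate-consensus peaks
#'
#' Only regions supported by at least `min_replicates` replicate peak
#' sets are retained: a consensus peak is a maximal interval covered by
#' one or more peaks from each required replicate, i.e. the
#' intersection of the supporting peaks. Its summit is taken from the
#' supporting replicate peak with the smallest p-value (ties: the
#' 5'-most summit).
#'
#' @param peak_sets List of peak data.frames as returned by
#'   [call_peaks()], one per replicate.
#' @param min_replicates Required support; defaults to all replicates,
#'   matching the rule that only peaks called in every biological
#'   replicate count as confident.
#' @return data.frame of consensus peaks: `transcript_id`, `start`,
#'   `end`, `summit`, `n_replicates`, `p_value` (minimum supporting
#'   peak p).
#' @export
consensus_peaks <- function(peak_sets, min_replicates = length(peak_sets)) {
  if (length(peak_sets) < 2L) stop("need at least two replicate peak sets")
  txs <- sort(unique(unlist(lapply(peak_sets, function(p) p$transcript_id))))
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), summit = integer(),
                      n_replicates = integer(), p_value = numeric())
  out <- list()
  for (tx in txs) {
    reps <- lapply(peak_sets, function(p)
      p[p$transcript_id == tx, , drop = FALSE])
    covs <- lapply(reps, function(p) {
      if (nrow(p) == 0L) return(NULL)
      IRanges::coverage(IRanges::reduce(
        IRanges::IRanges(p$start + 1L, p$end)))
    })
    present <- !vapply(covs, is.null, logical(1))
    if (sum(present) < min_replicates) next
    maxlen <- max(vapply(covs[present], length, integer(1)))
    depth <- Reduce(`+`, lapply(covs[present], function(cv) {
      v <- as.integer(cv)
      c(pmin(v, 1L), integer(maxlen - length(v)))
    }))
    r <- rle(depth >= min_replicates)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    iv <- cbind(start = starts[r$values], end = ends[r$values])
    allp <- do.call(rbind, reps)
    for (j in seq_len(nrow(iv))) {
      sup <- allp[allp$start < iv[j, "end"] & allp$end > iv[j, "start"], ,
                  drop = FALSE]
      sup <- sup[order(sup$p_value, sup$summit), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, start = iv[j, "start"], end = iv[j, "end"],
        summit = sup$summit[1L],
        n_replicates = sum(vapply(seq_along(reps), function(k) {
          p <- reps[[k]]
          any(p$start < iv[j, "end"] & p$end > iv[j, "start"])
        }, logical(1))),
        p_value = sup$p_value[1L])
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation between replicate libraries
#'
#' Correlates log2-transformed windowed fragment counts (pseudocount 1)
#' between every pair of replicates.
#'
#' @param sets List of [coverage_set()]s (e.g. the IP library of each
#'   replicate).
#' @param window,step Window geometry.
#' @return Symmetric matrix of Pearson r.
#' @export
replicate_correlation <- function(sets, window = 50L, step = 25L) {
  mat <- vapply(sets, function(cv) {
    unlist(lapply(names(cv$tracks), function(tx)
      window_counts(cv$tracks[[tx]], NULL, window, step)$ip))
  }, numeric(sum(vapply(sets[[1L]]$tracks, function(v)
    length(window_starts(length(v), window, step)), integer(1)))))
  stats::cor(log2(mat + 1))
}

#' Convert peaks to a BED6 data.frame
#'
#' Name is `transcript:rank` (rank by position within transcript);
#' score is `-10 log10(q)` capped at 1000.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @return BED6-style data.frame writable with [write_bed()].
#' @export
peaks_to_bed <- function(peaks) {
  rank <- stats::ave(peaks$start, peaks$transcript_id,
                     FUN = function(x) rank(x, ties.method = "first"))
  q <- if ("q_value" %in% names(peaks)) peaks$q_value else peaks$p_value
  data.frame(transcript_id = peaks$transcript_id, start = peaks$start,
             end = peaks$end,
             name = sprintf("%s:%d", peaks$transcript_id, as.integer(rank)),
             score = round(pmin(1000, -10 * log10(pmax(q, 1e-100)))),
             strand = "+")
}
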