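# Differential expression and differential m6A, and their
# integration into the m6A-vs-expression quadrant table.
#
# Expression is quantified as FPKM from the input libraries (the input
# fraction doubles as RNA-seq). Differential expression uses a Welch
# t-test on log2(FPKM + 1) across replicates - a deliberately simple,
# replicate-aware stand-in for assembly-based differential pipelines.
# Differential methylation compares each consensus peak's IP/input
# enrichment between conditions with a two-sided Fisher exact test on
# replicate-summed counts. Both calls use the fold change >= 1.5 and
# P < 0.05 rule.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `FPKM = count / ((length/1e3) * (mapped/1e6))`. Exact rational
#' arithmetic on integer inputs; invariant to scaling count and library
#' size together.
#'
#' @param fragment_count Fragments assigned to the transcript.
#' @param exonic_length_nt Exonic length (nt).
#' @param mapped_fragments Total mapped fragments in the library.
#' @return FPKM value(s).
#' @export
fpkm <- function(fragment_count, exonic_length_nt, mapped_fragments) {
  stopifnot(all(exonic_length_nt > 0), all(mapped_fragments > 0))
  fragment_count / ((exonic_length_nt / 1e3) * (mapped_fragments / 1e6))
}

#' FPKM table from input coverage sets
#'
#' @param input_sets List of input [coverage_set()]s, one per
#'   replicate.
#' @param models `transcript_models`.
#' @return data.frame with `transcript_id`, `length_t`, and one
#'   `fpkm_rep<i>` column per replicate plus `fpkm` (the replicate
#'   mean).
#' @export
expression_table <- function(input_sets, models) {
  ids <- names(models)
  len <- vapply(models, `[[`, integer(1), "length_t")
  out <- data.frame(transcript_id = ids, length_t = len,
                    stringsAsFactors = FALSE)
  for (r in seq_along(input_sets)) {
    cv <- input_sets[[r]]
    cnt <- vapply(ids, function(tx) sum(cv$tracks[[tx]]), numeric(1))
    out[[sprintf("fpkm_rep%d", r)]] <- fpkm(cnt, len, cv$library_size)
  }
  reps <- grep("^fpkm_rep", names(out))
  out$fpkm <- rowMeans(out[, reps, drop = FALSE])
  rownames(out) <- NULL
  out
}

welch_log_t <- function(a, b) {
  la <- log2(a + 1); lb <- log2(b + 1)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  tryCatch(stats::t.test(lb, la, var.equal = FALSE)$p.value,
           error = function(e) 1)
}

#' Differential expression between two conditions
#'
#' Two-sided Welch t-test on log2(FPKM + 1) across replicates, BH
#' adjustment across genes, fold change pseudocounted with 0.5. A gene
#' is significant when both `p_value < alpha` and
#' `max(FC, 1/FC) >= fc_min` (1.5 counts: the threshold is inclusive).
#'
#' @param fpkm_a,fpkm_b Matrices or data.frames of FPKM (rows =
#'   transcripts, columns = replicates), identical row order, with
#'   rownames or a shared `transcript_id` attribute taken from
#'   `fpkm_a`.
#' @param transcript_id Optional explicit transcript identifiers.
#' @param fc_min,alpha Thresholds (defaults 1.5, 0.05).
#' @return data.frame with per-gene mean FPKMs, `fold_change` (B/A),
#'   `p_value`, `q_value`, `significant`, `direction`
#'   (up/down/unchanged in B relative to A).
#' @export
differential_expression <- function(fpkm_a, fpkm_b, transcript_id = NULL,
                                    fc_min = 1.5, alpha = 0.05) {
  fpkm_a <- as.matrix(fpkm_a); fpkm_b <- as.matrix(fpkm_b)
  stopifnot(nrow(fpkm_a) == nrow(fpkm_b))
  if (is.null(transcript_id))
    transcript_id <- rownames(fpkm_a) %||% as.character(seq_len(nrow(fpkm_a)))
  mean_a <- rowMeans(fpkm_a); mean_b <- rowMeans(fpkm_b)
  fc <- (mean_b + 0.5) / (mean_a + 0.5)
  p <- vapply(seq_len(nrow(fpkm_a)), function(i)
    welch_log_t(fpkm_a[i, ], fpkm_b[i, ]), numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  sig <- p < alpha & pmax(fc, 1 / fc) >= fc_min
  data.frame(transcript_id = transcript_id, mean_fpkm_a = mean_a,
             mean_fpkm_b = mean_b, fold_change = fc, p_value = p,
             q_value = q, significant = sig,
             direction = ifelse(!sig, "unchanged",
                                ifelse(fc > 1, "up", "down")),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sum_peak_counts <- function(peaks, rep_list, which = c("ip", "input")) {
  which <- match.arg(which)
  counts <- numeric(nrow(peaks))
  lib <- 0
  for (rep in rep_list) {
    cv <- rep[[which]]
    lib <- lib + cv$library_size
    for (i in seq_len(nrow(peaks))) {
      v <- cv$tracks[[peaks$transcript_id[i]]]
      counts[i] <- counts[i] + sum(v[(peaks$start[i] + 1L):peaks$end[i]])
    }
  }
  list(counts = counts, library_size = lib)
}

#' Differential m6A between two conditions
#'
#' Per consensus peak, IP and input fragment counts are summed over
#' replicates within each condition. Enrichment per condition is
#' `((IP + 0.5)/N_IP) / ((input + 0.5)/N_in)`; the fold change is
#' enrichment(B)/enrichment(A); the p-value is a two-sided Fisher
#' exact test on the 2x2 count table `[[IP_A, in_A], [IP_B, in_B]]`.
#' Significance: `p_value < alpha` and `max(FC, 1/FC) >= fc_min`.
#'
#' @param peaks Consensus-peak data.frame (`transcript_id`, `start`,
#'   `end`).
#' @param counts_a,counts_b Lists over replicates, each element with
#'   `ip` and `input` [coverage_set()]s (as returned by
#'   [simulate_counts()] / [load_dataset()]).
#' @param fc_min,alpha Thresholds (defaults 1.5, 0.05).
#' @return data.frame of per-peak enrichments, `fold_change`,
#'   `p_value`, `significant`, `direction` (up = higher m6A in B).
#' @export
differential_m6a <- function(peaks, counts_a, counts_b, fc_min = 1.5,
                             alpha = 0.05) {
  ip_a <- sum_peak_counts(peaks, counts_a, "ip")
  in_a <- sum_peak_counts(peaks, counts_a, "input")
  ip_b <- sum_peak_counts(peaks, counts_b, "ip")
  in_b <- sum_peak_counts(peaks, counts_b, "input")
  enr_a <- ((ip_a$counts + 0.5) / ip_a$library_size) /
    ((in_a$counts + 0.5) / in_a$library_size)
  enr_b <- ((ip_b$counts + 0.5) / ip_b$library_size) /
    ((in_b$counts + 0.5) / in_b$library_size)
  fc <- enr_b / enr_a
  p <- vapply(seq_len(nrow(peaks)), function(i)
    stats::fisher.test(matrix(round(c(ip_a$counts[i], in_a$counts[i],
                                      ip_b$counts[i], in_b$counts[i])),
                              nrow = 2, byrow = TRUE))$p.value,
    numeric(1))
  sig <- p < alpha & pmax(fc, 1 / fc) >= fc_min
  out <- peaks[, c("transcript_id", "start", "end")]
  out$enrichment_a <- enr_a
  out$enrichment_b <- enr_b
  out$fold_change <- fc
  out$p_value <- p
  out$significant <- sig
  out$direction <- ifelse(!sig, "unchanged", ifelse(fc > 1, "up", "down"))
  rownames(out) <- NULL
  out
}

#' m6A-vs-expression quadrant table
#'
#' Cross-tabulates transcripts with significant m6A change (up/down)
#' against their expression stratum (up/down/unchanged). Transcripts
#' with several peaks are represented by the most significant one
#' (smallest p; ties broken by largest |log fold change|).
#'
#' @param diff_m6a Output of [differential_m6a()].
#' @param diff_expr Output of [differential_expression()].
#' @return list with `table` (2 x 3 matrix, rows m6A up/down, columns
#'   expression up/down/unchanged) and `transcripts` (the per-
#'   transcript merged calls).
#' @export
quadrants <- function(diff_m6a, diff_expr) {
  tab <- matrix(0L, nrow = 2, ncol = 3,
                dimnames = list(m6a = c("up", "down"),
                                expression = c("up", "down", "unchanged")))
  sig <- diff_m6a[diff_m6a$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(table = tab, transcripts = data.frame()))
  ord <- order(sig$p_value, -abs(log(sig$fold_change)))
  sig <- sig[ord, , drop = FALSE]
  sig <- sig[!duplicated(sig$transcript_id), , drop = FALSE]
  ed <- diff_expr$direction[match(sig$transcript_id,
                                  diff_expr$transcript_id)]
  ed[is.na(ed)] <- "unchanged"
  for (i in seq_len(nrow(sig)))
    tab[sig$direction[i], ed[i]] <- tab[sig$direction[i], ed[i]] + 1L
  merged <- data.frame(transcript_id = sig$transcript_id,
                       m6a_direction = sig$direction,
                       m6a_fold_change = sig$fold_change,
                       m6a_p = sig$p_value,
                       expression_direction = ed,
                       stringsAsFactors = FALSE)
  list(table = tab, transcripts = merged)
}

#' Sign test for negative m6A-expression association
#'
#' Among transcripts with both a significant m6A change and a
#' significant expression change, counts concordant-negative pairs
#' (m6A up with expression down, or m6A down with expression up) and
#' tests whether they form the majority (one-sided binomial test).
#'
#' @param quad Output of [quadrants()].
#' @return list with `n_negative`, `n_positive`, `p_value`.
#' @export
association_sign_test <- function(quad) {
  tr <- quad$transcripts
  tr <- tr[tr$expression_direction != "unchanged", , drop = FALSE]
  neg <- sum((tr$m6a_direction == "up" & tr$expression_direction == "down") |
               (tr$m6a_direction == "down" & tr$expression_direction == "up"))
  pos <- nrow(tr) - neg
  p <- if (nrow(tr) == 0L) 1
  else stats::binom.test(neg, neg + pos, alternative = "greater")$p.value
  list(n_negative = neg, n_positive = pos, p_value = p)
}
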