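# End-to-end orchestration: simulate (or load) -> peak calling ->
# consensus -> topology -> motif -> differential m6A / expression ->
# quadrants, as one seeded, reproducible run with a machine-readable
# report.

#' Run the full m6A methylome analysis pipeline
#'
#' Stages: simulate both conditions (or load a dataset emitted by
#' [emit_dataset()]), call peaks per replicate, intersect into
#' consensus peaks per condition, characterize topology and motifs on
#' condition A, quantify expression from the input libraries, call
#' differential m6A and differential expression between conditions,
#' and cross-tabulate the quadrants. Deterministic given the
#' configuration seed; any stage failure aborts with a stage-named
#' error.
#'
#' @param config A [simulation_config()] (thresholds below are
#'   separate arguments).
#' @param data_dir Optional directory from [emit_dataset()]; when
#'   given, inputs are loaded from disk instead of simulated in
#'   memory (the directory must contain both conditions).
#' @param out_dir Optional output directory for the JSON report and
#'   stage TSVs.
#' @param alpha_fdr Peak-level FDR threshold (default 0.05).
#' @param fc_min,alpha Differential thresholds (defaults 1.5, 0.05).
#' @param window,step Peak-calling window geometry.
#' @return list of class `merip_report`: per-stage results and a
#'   `summary` of per-stage counts.
#' @export
run_pipeline <- function(config = simulation_config(), data_dir = NULL,
                         out_dir = NULL, alpha_fdr = 0.05, fc_min = 1.5,
                         alpha = 0.05, window = 50L, step = 25L) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, fc_min >= 1, alpha > 0, alpha < 1)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  dat <- stage("input", {
    if (is.null(data_dir)) {
      sim <- simulate_transcriptome(config)
      counts <- simulate_replicates(sim, conditions = c("A", "B"))
      c(sim, list(counts = counts))
    } else {
      load_dataset(data_dir)
    }
  })
  cfg <- dat$config %||% config

  peaks <- stage("callpeaks", lapply(dat$counts, function(reps)
    lapply(reps, function(r)
      call_peaks(r$ip, r$input, alpha_fdr = alpha_fdr, window = window,
                 step = step))))
  cons <- stage("consensus", lapply(peaks, consensus_peaks))

  topo <- stage("topology", {
    nt_frac <- segment_nt_fractions(dat$models)
    asg <- assign_summits(cons$A, dat$models)
    list(nt_fractions = nt_frac, assignment = asg,
         relative_enrichment = relative_enrichment(asg$fractions, nt_frac),
         metagene = metagene(cons$A, dat$models),
         peaks_per_transcript = peaks_per_transcript(cons$A))
  })

  motif <- stage("motif", {
    sets <- build_sequence_sets(cons$A, dat$sequences)
    list(ranking = utils::head(kmer_enrichment(sets$target,
                                               sets$background), 20L),
         n_target = length(sets$target),
         n_background = length(sets$background))
  })

  expr <- stage("expression", {
    list(A = expression_table(lapply(dat$counts$A, `[[`, "input"),
                              dat$models),
         B = expression_table(lapply(dat$counts$B, `[[`, "input"),
                              dat$models))
  })

  diffs <- stage("differential", {
    test_regions <- merge_peak_sets(cons$A, cons$B)
    dm <- differential_m6a(test_regions, dat$counts$A, dat$counts$B,
                           fc_min = fc_min, alpha = alpha)
    reps <- grep("^fpkm_rep", names(expr$A))
    de <- differential_expression(expr$A[, reps], expr$B[, reps],
                                  transcript_id = expr$A$transcript_id,
                                  fc_min = fc_min, alpha = alpha)
    list(m6a = dm, expression = de)
  })

  quad <- stage("quadrants", quadrants(diffs$m6a, diffs$expression))

  report <- structure(list(
    config = unclass(cfg), peaks = peaks, consensus = cons,
    topology = topo, motif = motif, expression = expr,
    differential = diffs, quadrants = quad,
    summary = list(
      version = as.character(utils::packageVersion("meripr")),
      n_transcripts = length(dat$models),
      n_peaks = lapply(peaks, function(x) vapply(x, nrow, integer(1))),
      n_consensus = vapply(cons, nrow, integer(1)),
      segment_fractions = as.list(topo$assignment$fractions),
      relative_enrichment = as.list(topo$relative_enrichment),
      top_kmer = motif$ranking$kmer[1L],
      n_differential_m6a = sum(diffs$m6a$significant),
      n_differential_expression = sum(diffs$expression$significant),
      quadrant_table = as.list(as.data.frame(as.table(quad$table))$Freq))),
    class = "merip_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report$summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_bed(peaks_to_bed(cons$A), file.path(out_dir, "consensus_A.bed"))
    write_bed(peaks_to_bed(cons$B), file.path(out_dir, "consensus_B.bed"))
    utils::write.table(diffs$m6a, file.path(out_dir, "differential_m6a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diffs$expression,
                       file.path(out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

# Union of two peak sets: overlapping intervals on the same transcript
# merged, so differential testing covers regions methylated in either
# condition.
merge_peak_sets <- function(a, b) {
  all <- rbind(a[, c("transcript_id", "start", "end")],
               b[, c("transcript_id", "start", "end")])
  if (nrow(all) == 0L) return(all)
  out <- lapply(split(all, all$transcript_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(transcript_id = d$transcript_id[1L],
               start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hash of a pipeline report
#'
#' MD5 of the canonical JSON serialization of the report summary; two
#' runs with identical configuration and seed produce identical
#' hashes.
#'
#' @param report A `merip_report`.
#' @return Character MD5 digest.
#' @export
report_hash <- function(report) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(report$summary, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' @export
print.merip_report <- function(x, ...) {
  s <- x$summary
  cat("merip pipeline report\n")
  cat(sprintf("  transcripts: %d\n", s$n_transcripts))
  cat(sprintf("  consensus peaks: A=%d B=%d\n",
              s$n_consensus[["A"]], s$n_consensus[["B"]]))
  cat(sprintf("  stop-codon summit fraction (A): %.3f\n",
              s$segment_fractions$stop_codon))
  cat(sprintf("  top k-mer: %s\n", s$top_kmer))
  cat(sprintf("  differential m6A peaks: %d; differential genes: %d\n",
              s$n_differential_m6a, s$n_differential_expression))
  invisible(x)
}
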