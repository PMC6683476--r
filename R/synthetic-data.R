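# Synthetic MeRIP-seq data with known ground truth.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: a multi-transcript mRNA transcriptome, methylation
# sites concentrated in the 100-nt stop-codon window and 3'UTR, a
# UGUAYY motif embedded at planted sites, IP enrichment over input
# proportional to stoichiometry, negative-binomial count noise, three
# replicates per condition, and two conditions with planted
# differential methylation coupled (negatively, by default) to
# expression.

#' Simulation configuration
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_range,cds_range,utr3_range Length ranges (nt) sampled
#'   uniformly; CDS lengths are rounded to multiples of 3 (stop codon
#'   included) and floored at 6.
#' @param fraction_methylated Fraction of transcripts carrying one
#'   planted m6A site.
#' @param segment_weights Probability weights over the five segments
#'   used to place sites; default concentrates mass on the stop-codon
#'   window and 3'UTR, the canonical plant m6A topology.
#' @param enrichment_factor IP-over-input fold enrichment at a fully
#'   methylated site (must exceed 1).
#' @param stoichiometry Methylation stoichiometry per planted site in
#'   (0, 1]; the realized IP boost is
#'   `1 + (enrichment_factor - 1) * stoichiometry`.
#' @param motif_fraction Fraction of planted sites with a UGUAYY
#'   instance (IUPAC Y = C/U) embedded centred on the site.
#' @param mean_coverage Mean input fragment count per nucleotide for a
#'   transcript of average abundance.
#' @param dispersion Negative-binomial dispersion of replicate-level
#'   biological noise (variance of the per-transcript rate multiplier);
#'   0 gives Poisson counts.
#' @param n_replicates Biological replicates per condition.
#' @param fragment_length Fragment footprint (nt) over which a site
#'   boosts IP coverage; fixed at 100 to match ~100-nt RNA
#'   fragmentation.
#' @param diff_fraction Fraction of methylated transcripts whose
#'   stoichiometry differs between conditions A and B.
#' @param diff_m6a_fc Planted fold change of IP/input enrichment at
#'   differential sites (on the measurable enrichment scale).
#' @param hyper_fraction Fraction of differential sites hypermethylated
#'   in condition B (the rest are hypomethylated).
#' @param expr_fc Fold change of abundance planted on differential
#'   transcripts.
#' @param coupling Sign of the m6A-expression coupling: -1 (default)
#'   plants *lower* expression where m6A goes up, +1 the reverse, 0
#'   decouples expression from methylation.
#' @param abundance_sdlog Log-sd of the lognormal relative-abundance
#'   distribution.
#' @param ip_depth_ratio Target IP library depth as a multiple of the
#'   input depth.
#' @param seed Integer seed; all replicate/condition streams are
#'   derived from it by fixed offsets.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_transcripts = 500,
                              utr5_range = c(50, 300),
                              cds_range = c(300, 1500),
                              utr3_range = c(100, 500),
                              fraction_methylated = 0.1,
                              segment_weights = c(tss = 0.02, utr5 = 0.03,
                                                  cds = 0.15,
                                                  stop_codon = 0.50,
                                                  utr3 = 0.30),
                              enrichment_factor = 8,
                              stoichiometry = 0.8,
                              motif_fraction = 0.6,
                              mean_coverage = 30,
                              dispersion = 0.05,
                              n_replicates = 3,
                              fragment_length = 100,
                              diff_fraction = 0.5,
                              diff_m6a_fc = 3,
                              hyper_fraction = 0.8,
                              expr_fc = 3,
                              coupling = -1,
                              abundance_sdlog = 0.5,
                              ip_depth_ratio = 1,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$enrichment_factor > 1,
            cfg$fraction_methylated >= 0, cfg$fraction_methylated <= 1,
            cfg$motif_fraction >= 0, cfg$motif_fraction <= 1,
            cfg$diff_fraction >= 0, cfg$diff_fraction <= 1,
            cfg$hyper_fraction >= 0, cfg$hyper_fraction <= 1,
            cfg$stoichiometry > 0, cfg$stoichiometry <= 1,
            cfg$dispersion >= 0, cfg$n_replicates >= 1,
            utr5_range[1] >= 1, cds_range[1] >= 6, utr3_range[1] >= 1)
  names(cfg$segment_weights) <- c("tss", "utr5", "cds", "stop_codon", "utr3")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-stream seed below 2^31, derived from the master
# seed by fixed offsets so any condition/replicate pair is
# independently reproducible.
substream_seed <- function(seed, condition, replicate) {
  ci <- match(condition, c("A", "B"))
  as.integer((as.numeric(seed) * 97L + ci * 1009L + replicate * 31L) %%
               2147483647)
}

segment_name_levels <- c("tss", "utr5", "cds", "stop_codon", "utr3")

#' Simulate a transcriptome with planted m6A truth
#'
#' @param config A [simulation_config()].
#' @return list with `models` (`transcript_models`), `sequences`
#'   (`DNAStringSet`, mRNA sense), and `truth`: a list of `sites`
#'   (one row per planted site: position, segment, per-condition
#'   stoichiometry, motif flag, direction) and `transcripts`
#'   (per-condition relative abundance, methylation and differential
#'   flags). Deterministic given `config$seed`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed %% 2147483647))
  n <- config$n_transcripts
  ids <- sprintf("tx%04d", seq_len(n))

  utr5 <- sample(config$utr5_range[1]:config$utr5_range[2], n, replace = TRUE)
  cds <- sample(config$cds_range[1]:config$cds_range[2], n, replace = TRUE)
  cds <- pmax(6L, as.integer(round(cds / 3) * 3))
  utr3 <- sample(config$utr3_range[1]:config$utr3_range[2], n, replace = TRUE)
  len <- utr5 + cds + utr3

  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.28, 0.22, 0.22, 0.28)), collapse = ""),
    character(1))

  # genomic layout: each transcript on its own contig; a fraction are
  # two-exon and/or minus-strand so coordinate conversion is exercised
  strand <- sample(c("+", "-"), n, replace = TRUE)
  two_exon <- stats::runif(n) < 0.5
  models <- vector("list", n)
  for (i in seq_len(n)) {
    L <- len[i]
    if (two_exon[i] && L >= 40L) {
      brk <- sample(20:(L - 20), 1L)       # transcript-space split point
      intron <- 80L
      if (strand[i] == "+") {
        exons <- rbind(c(100L, 100L + brk),
                       c(100L + brk + intron, 100L + L + intron))
      } else {
        # transcript 5' end must map to the genomic right-most base
        exons <- rbind(c(100L, 100L + (L - brk)),
                       c(100L + (L - brk) + intron, 100L + L + intron))
      }
    } else {
      exons <- rbind(c(100L, 100L + L))
    }
    models[[i]] <- transcript_model(ids[i], sub("^tx", "g", ids[i]),
                                    paste0("chr_", ids[i]), strand[i],
                                    exons, utr5[i], utr5[i] + cds[i])
  }
  names(models) <- ids
  class(models) <- "transcript_models"

  # abundance: lognormal, normalized to mean 1
  ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  ab <- ab / mean(ab)

  # methylated transcripts and site placement
  n_meth <- round(config$fraction_methylated * n)
  meth_idx <- if (n_meth > 0) sort(sample.int(n, n_meth)) else integer()
  w <- config$segment_weights / sum(config$segment_weights)

  site_tx <- character(0); site_pos <- integer(0); site_seg <- character(0)
  for (i in meth_idx) {
    m <- models[[i]]
    part <- partition_transcript(m)
    nt <- part$nt[segment_name_levels]
    pw <- w * as.numeric(nt > 0)
    if (sum(pw) == 0) stop("infeasible config: no eligible segment for '",
                           ids[i], "'")
    seg <- sample(segment_name_levels, 1L, prob = pw)
    iv <- part$intervals[part$intervals$segment == seg, , drop = FALSE]
    # keep sites >= 3 nt from the transcript ends so a motif fits
    pos <- sample(unlist(mapply(seq.int, iv$start, iv$end - 1L,
                                SIMPLIFY = FALSE)), 1L)
    pos <- min(max(pos, 3L), m$length_t - 4L)
    site_tx <- c(site_tx, ids[i]); site_pos <- c(site_pos, pos)
    site_seg <- c(site_seg, seg)
  }

  # motif embedding: UGUAYY (DNA: TGTAYY, Y in {C,T}) centred on the
  # site (site at the Y-1 position of the hexamer -> hexamer occupies
  # [pos-3, pos+3))
  has_motif <- stats::runif(length(site_pos)) < config$motif_fraction
  for (k in seq_along(site_pos)) {
    if (!has_motif[k]) next
    i <- match(site_tx[k], ids)
    hex <- paste0("TGTA", paste(sample(c("C", "T"), 2, replace = TRUE),
                                collapse = ""))
    substr(seqs[i], site_pos[k] - 2L, site_pos[k] + 3L) <- hex
  }

  # differential methylation: enrichment fold change planted on the
  # measurable scale boost(s) = 1 + (E-1) s
  E <- config$enrichment_factor
  s_hi <- config$stoichiometry
  s_lo <- max(0.02, ((1 + (E - 1) * s_hi) / config$diff_m6a_fc - 1) / (E - 1))
  n_sites <- length(site_pos)
  dirn <- rep("none", n_sites)
  if (n_sites > 0 && config$diff_fraction > 0) {
    nd <- round(config$diff_fraction * n_sites)
    di <- sample.int(n_sites, nd)
    up <- stats::runif(nd) < config$hyper_fraction
    dirn[di[up]] <- "up"        # hypermethylated in condition B
    dirn[di[!up]] <- "down"
  }
  stoich_A <- ifelse(dirn == "up", s_lo, s_hi)
  stoich_B <- ifelse(dirn == "down", s_lo, s_hi)

  # expression coupling on differential transcripts
  ab_B <- ab
  if (config$coupling != 0 && n_sites > 0) {
    f <- config$expr_fc
    for (k in which(dirn != "none")) {
      i <- match(site_tx[k], ids)
      change <- if (dirn[k] == "up") config$coupling < 0 else config$coupling > 0
      ab_B[i] <- if (change) ab[i] / f else ab[i] * f
    }
  }

  sites <- data.frame(transcript_id = site_tx, position = site_pos,
                      segment = site_seg, stoich_A = stoich_A,
                      stoich_B = stoich_B, motif = has_motif,
                      direction = dirn, stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = ids,
                            gene_id = sub("^tx", "g", ids),
                            length_t = len,
                            abundance_A = ab, abundance_B = ab_B,
                            methylated = ids %in% site_tx,
                            stringsAsFactors = FALSE)
  list(models = models,
       sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       truth = list(sites = sites, transcripts = transcripts),
       config = config)
}

#' Simulate IP and input coverage for one replicate
#'
#' Input counts are Poisson around `mean_coverage * abundance`, with a
#' per-transcript Gamma rate multiplier (variance = `dispersion`)
#' drawn once per replicate and shared between the IP and input
#' libraries of that replicate - both derive from the same mRNA
#' preparation - so marginal counts are negative-binomial while the
#' IP-vs-input contrast stays calibrated. IP means equal the input
#' means boosted by `1 + (enrichment_factor - 1) * stoichiometry`
#' inside the fragment-length window around each planted site, then
#' rescaled globally to the target IP depth.
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param condition `"A"` or `"B"`.
#' @param replicate Replicate number (1-based).
#' @return list with `ip` and `input` [coverage_set()]s and `ip_scale`,
#'   the global IP renormalization factor (exposed for closed-form
#'   checks).
#' @export
simulate_counts <- function(sim, condition = c("A", "B"), replicate = 1L) {
  condition <- match.arg(condition)
  cfg <- sim$config
  set.seed(substream_seed(cfg$seed, condition, replicate))
  tr <- sim$truth$transcripts
  sites <- sim$truth$sites
  ab <- if (condition == "A") tr$abundance_A else tr$abundance_B
  stoich <- if (condition == "A") sites$stoich_A else sites$stoich_B
  half <- cfg$fragment_length %/% 2L

  n <- nrow(tr)
  mu <- cfg$mean_coverage * ab
  # per-transcript replicate-level biological multiplier
  g <- if (cfg$dispersion > 0)
    stats::rgamma(n, shape = 1 / cfg$dispersion, scale = cfg$dispersion)
  else rep(1, n)

  # expectation bookkeeping for the global IP renormalization
  total_in <- sum(mu * tr$length_t)
  boost_extra <- 0
  site_by_tx <- split(seq_len(nrow(sites)), sites$transcript_id)
  for (tx in names(site_by_tx)) {
    i <- match(tx, tr$transcript_id)
    for (k in site_by_tx[[tx]]) {
      wlen <- min(sites$position[k] + half, tr$length_t[i]) -
        max(sites$position[k] - half, 0L)
      boost_extra <- boost_extra +
        mu[i] * wlen * (cfg$enrichment_factor - 1) * stoich[k]
    }
  }
  ip_scale <- cfg$ip_depth_ratio * total_in / (total_in + boost_extra)

  ip_tracks <- vector("list", n); in_tracks <- vector("list", n)
  for (i in seq_len(n)) {
    L <- tr$length_t[i]
    lambda_in <- mu[i] * g[i]
    in_tracks[[i]] <- stats::rpois(L, lambda_in)
    boost <- rep(1, L)
    for (k in site_by_tx[[tr$transcript_id[i]]]) {
      a <- max(sites$position[k] - half, 0L) + 1L
      b <- min(sites$position[k] + half, L)
      boost[a:b] <- boost[a:b] + (cfg$enrichment_factor - 1) * stoich[k]
    }
    ip_tracks[[i]] <- stats::rpois(L, lambda_in * boost * ip_scale)
  }
  names(ip_tracks) <- tr$transcript_id
  names(in_tracks) <- tr$transcript_id
  list(ip = coverage_set(ip_tracks), input = coverage_set(in_tracks),
       ip_scale = ip_scale)
}

#' Simulate all replicates for one or both conditions
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param conditions Character vector among `"A"`, `"B"`.
#' @return Nested list `[[condition]][[replicate]]`, each element as
#'   returned by [simulate_counts()].
#' @export
simulate_replicates <- function(sim, conditions = "A") {
  out <- lapply(conditions, function(cond)
    lapply(seq_len(sim$config$n_replicates), function(r)
      simulate_counts(sim, cond, r)))
  stats::setNames(out, conditions)
}

#' Write a simulated dataset to disk
#'
#' Emits GFF3 annotation, transcript FASTA, per-condition/replicate
#' IP and input bedGraph pairs, truth TSVs, and the configuration as
#' YAML; everything re-loadable by [load_dataset()].
#'
#' @param sim Output of [simulate_transcriptome()].
#' @param dir Output directory (created if needed).
#' @param conditions Conditions to simulate and write.
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(sim, dir, conditions = "A") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$models, file.path(dir, "annotation.gff3"))
  Biostrings::writeXStringSet(sim$sequences,
                              file.path(dir, "transcripts.fa"))
  utils::write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$transcripts,
                     file.path(dir, "truth_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  for (cond in conditions) {
    for (r in seq_len(sim$config$n_replicates)) {
      cnt <- simulate_counts(sim, cond, r)
      write_bedgraph(cnt$ip,
                     file.path(dir, sprintf("%s_rep%d_ip.bedgraph", cond, r)))
      write_bedgraph(cnt$input,
                     file.path(dir, sprintf("%s_rep%d_input.bedgraph",
                                            cond, r)))
    }
  }
  invisible(dir)
}

#' Load a dataset written by [emit_dataset()]
#'
#' @param dir Dataset directory.
#' @return list with `models`, `sequences`, `truth`, `config`, and
#'   `counts` (nested `[[condition]][[replicate]]` lists of `ip` /
#'   `input` coverage sets).
#' @export
load_dataset <- function(dir) {
  needed <- c("annotation.gff3", "transcripts.fa", "truth_sites.tsv",
              "truth_transcripts.tsv", "config.yaml")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    stop("dataset file missing from '", dir, "': ", missing[1L])
  models <- parse_annotation(file.path(dir, "annotation.gff3"))
  seqs <- read_fasta(file.path(dir, "transcripts.fa"))
  sites <- utils::read.table(file.path(dir, "truth_sites.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  transcripts <- utils::read.table(file.path(dir, "truth_transcripts.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$segment_weights <- unlist(cfg$segment_weights)
  cfg <- do.call(simulation_config, cfg[names(cfg) %in%
                                          names(formals(simulation_config))])
  counts <- list()
  bg <- list.files(dir, pattern = "_ip\\.bedgraph$")
  for (f in bg) {
    base <- sub("_ip\\.bedgraph$", "", f)
    cond <- sub("_rep\\d+$", "", base)
    rep <- as.integer(sub("^.*_rep", "", base))
    counts[[cond]][[rep]] <- list(
      ip = read_bedgraph(file.path(dir, f), models),
      input = read_bedgraph(file.path(dir, paste0(base, "_input.bedgraph")),
                            models))
  }
  list(models = models, sequences = seqs,
       truth = list(sites = sites, transcripts = transcripts),
       config = cfg, counts = counts)
}
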