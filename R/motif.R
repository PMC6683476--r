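# Hexamer motif enrichment in peak sequences.
#
# Peak subsequences are the targets; the exonic sequence outside peaks
# - chopped into peak-length-matched fragments - is the background.
# Enrichment is scored per k-mer by a hypergeometric test on
# sequence-level occurrence (how many sequences contain the k-mer at
# least once), a simple exchangeable-unit approximation to
# zero-or-one-occurrence motif scoring.

#' Build target and background sequence sets
#'
#' Targets are the peak-interval subsequences; the background is each
#' transcript's sequence with every peak interval excised, split into
#' fragments matched to the median peak length so sequence counts are
#' comparable. All sequences are returned as RNA (T -> U).
#'
#' @param peaks Peak data.frame with `transcript_id`, `start`, `end`.
#' @param sequences Named `DNAStringSet` of transcript sequences.
#' @param fragment_length Background fragment length; defaults to the
#'   median peak width (or 100 nt when there are no peaks).
#' @param min_length Fragments shorter than this are dropped (default:
#'   the k-mer length, 6).
#' @return list with `target` and `background` `RNAStringSet`s.
#' @export
build_sequence_sets <- function(peaks, sequences, fragment_length = NULL,
                                min_length = 6L) {
  if (nrow(peaks) > 0L) {
    missing <- setdiff(peaks$transcript_id, names(sequences))
    if (length(missing))
      stop("peak on transcript without sequence: ", missing[1L])
    lens <- Biostrings::width(sequences)[match(peaks$transcript_id,
                                               names(sequences))]
    if (any(peaks$start < 0L) || any(peaks$end > lens))
      stop("peak outside transcript bounds")
  }
  if (is.null(fragment_length))
    fragment_length <- if (nrow(peaks)) {
      as.integer(stats::median(peaks$end - peaks$start))
    } else 100L

  targets <- if (nrow(peaks)) {
    Biostrings::DNAStringSet(sequences[peaks$transcript_id],
                             start = peaks$start + 1L, end = peaks$end)
  } else Biostrings::DNAStringSet()

  bg <- list()
  for (tx in names(sequences)) {
    L <- Biostrings::width(sequences[tx])
    p <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    if (nrow(p)) {
      keep_runs <- IRanges::gaps(IRanges::reduce(
        IRanges::IRanges(p$start + 1L, p$end)), start = 1L, end = L)
    } else {
      keep_runs <- IRanges::IRanges(1L, L)
    }
    for (j in seq_along(keep_runs)) {
      a <- BiocGenerics::start(keep_runs)[j]
      b <- BiocGenerics::end(keep_runs)[j]
      starts <- seq(a, b, by = fragment_length)
      ends <- pmin(starts + fragment_length - 1L, b)
      ok <- ends - starts + 1L >= min_length
      if (any(ok))
        bg[[length(bg) + 1L]] <- Biostrings::DNAStringSet(
          rep(sequences[tx], sum(ok)),
          start = starts[ok], end = ends[ok])
    }
  }
  background <- if (length(bg)) do.call(c, bg) else Biostrings::DNAStringSet()
  list(target = Biostrings::RNAStringSet(targets),
       background = Biostrings::RNAStringSet(background))
}

#' Rank k-mers enriched in target over background sequences
#'
#' For each of the 4^k RNA k-mers, the number of target and background
#' sequences containing at least one occurrence is counted; the
#' p-value is the hypergeometric upper tail of drawing that many
#' k-mer-containing sequences in a target-sized sample from the pooled
#' sequence population. BH adjustment is applied over all 4^k k-mers.
#'
#' @param targets,background `RNAStringSet`s (or `DNAStringSet`s) from
#'   [build_sequence_sets()].
#' @param k K-mer length (default 6).
#' @return data.frame of `kmer`, `target_count`, `background_count`,
#'   `p_value`, `q_value`, `rank`, sorted by rank (ascending p; ties
#'   broken by descending target count, then alphabetically).
#' @export
kmer_enrichment <- function(targets, background, k = 6L) {
  presence_counts <- function(x) {
    if (length(x) == 0L)
      return(NULL)
    m <- Biostrings::oligonucleotideFrequency(x, width = k)
    colSums(m > 0L)
  }
  tc <- presence_counts(targets)
  bc <- presence_counts(background)
  kmers <- if (!is.null(tc)) names(tc) else names(bc)
  if (is.null(kmers)) stop("both sequence sets are empty")
  if (is.null(tc)) tc <- stats::setNames(numeric(length(kmers)), kmers)
  if (is.null(bc)) bc <- stats::setNames(numeric(length(kmers)), kmers)
  n_t <- length(targets)
  n_b <- length(background)
  K <- tc + bc[kmers]
  p <- stats::phyper(tc - 1, m = K, n = n_t + n_b - K, k = n_t,
                     lower.tail = FALSE)
  res <- data.frame(kmer = kmers, target_count = as.integer(tc),
                    background_count = as.integer(bc[kmers]),
                    p_value = pmin(1, p),
                    q_value = stats::p.adjust(pmin(1, p), method = "BH"))
  ord <- order(res$p_value, -res$target_count, res$kmer)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

iupac_rna <- list(A = "A", C = "C", G = "G", U = "U", T = "U",
                  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                  W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                  B = c("C", "G", "U"), D = c("A", "G", "U"),
                  H = c("A", "C", "U"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "U"))

#' Match a k-mer against an IUPAC pattern
#'
#' RNA alphabet; `T` in either argument is treated as `U`. Degenerate
#' codes follow the IUPAC convention (in particular Y = C/U).
#'
#' @param kmer Plain k-mer string.
#' @param iupac_pattern Pattern of the same length, e.g. `"UGUAYY"`.
#' @return `TRUE` if every position of `kmer` is allowed by the
#'   pattern.
#' @export
match_pattern <- function(kmer, iupac_pattern) {
  a <- strsplit(chartr("Tt", "Uu", toupper(kmer)), "")[[1L]]
  b <- strsplit(toupper(iupac_pattern), "")[[1L]]
  if (length(a) != length(b)) return(FALSE)
  all(mapply(function(x, pat) {
    allowed <- iupac_rna[[pat]]
    if (is.null(allowed)) stop("unknown IUPAC code '", pat, "'")
    x %in% allowed
  }, a, b))
}
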