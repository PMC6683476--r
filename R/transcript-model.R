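# Transcript models and transcript-space coordinates.
#
# All internal coordinates are 0-based, half-open. GFF3/GTF input
# (1-based, closed) is converted at the parsing boundary and converted
# back on export, so no other code ever sees 1-based coordinates.

#' Construct a transcript model
#'
#' A transcript model holds one mRNA's exon structure on the genome and
#' the derived transcript-space coordinate system used by all topology
#' and peak arithmetic. Position 0 is always the 5' end of the mature
#' transcript, on either strand.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of genomic exon
#'   intervals (0-based, half-open), in ascending genomic order,
#'   non-overlapping.
#' @param cds_start_t,cds_end_t Transcript-space offsets (0-based,
#'   half-open) of the coding region *including* the stop codon, or
#'   `NA` for non-coding transcripts.
#' @return An object of class `transcript_model` with fields
#'   `length_t` (total exonic length) and `coding`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds_start_t = NA_integer_,
                             cds_end_t = NA_integer_) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript '", transcript_id, "': no exons")
  if (any(exons[, "start"] < 0L) || any(exons[, "end"] <= exons[, "start"]))
    stop("transcript '", transcript_id, "': invalid exon coordinates")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("transcript '", transcript_id, "': overlapping exons")
  if (!strand %in% c("+", "-"))
    stop("transcript '", transcript_id, "': strand must be '+' or '-'")
  length_t <- sum(exons[, "end"] - exons[, "start"])
  coding <- !is.na(cds_start_t) && !is.na(cds_end_t)
  if (coding) {
    cds_start_t <- as.integer(cds_start_t)
    cds_end_t <- as.integer(cds_end_t)
    if (cds_start_t < 0L || cds_start_t >= cds_end_t || cds_end_t > length_t)
      stop("transcript '", transcript_id, "': CDS outside transcript bounds")
    if ((cds_end_t - cds_start_t) %% 3L != 0L)
      stop("transcript '", transcript_id,
           "': CDS length not a multiple of 3")
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, contig = contig,
         strand = strand, exons = exons,
         cds_start_t = if (coding) cds_start_t else NA_integer_,
         cds_end_t = if (coding) cds_end_t else NA_integer_,
         length_t = as.integer(length_t), coding = coding),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s nexon=%d length=%d %s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), x$length_t,
              if (x$coding)
                sprintf("CDS[%d,%d)", x$cds_start_t, x$cds_end_t)
              else "non-coding"))
  invisible(x)
}

# Exon lengths in transcript (5'->3') order.
exon_lengths_tx <- function(model) {
  len <- model$exons[, "end"] - model$exons[, "start"]
  if (model$strand == "-") rev(len) else len
}

#' Map genomic positions onto a transcript
#'
#' @param model A `transcript_model`.
#' @param gpos Vector of genomic positions (0-based).
#' @return Integer vector of transcript offsets (0-based from the 5'
#'   end), `NA` where a position is intronic or outside the transcript.
#' @export
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  n <- nrow(ex)
  len <- ex[, "end"] - ex[, "start"]
  # cumulative transcript offset at the 5'-most base of each exon,
  # indexed in ascending genomic order
  if (model$strand == "+") {
    off5 <- cumsum(c(0L, len))[seq_len(n)]
  } else {
    off5 <- rev(cumsum(c(0L, rev(len)))[seq_len(n)])
  }
  idx <- findInterval(gpos, ex[, "start"])
  res <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1L & idx <= n
  ok[ok] <- gpos[ok] < ex[idx[ok], "end"]
  i <- idx[ok]
  if (model$strand == "+") {
    res[ok] <- off5[i] + (gpos[ok] - ex[i, "start"])
  } else {
    res[ok] <- off5[i] + (ex[i, "end"] - 1L - gpos[ok])
  }
  as.integer(res)
}

#' Map transcript offsets back to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on exonic space.
#'
#' @param model A `transcript_model`.
#' @param tpos Vector of transcript offsets (0-based).
#' @return Integer vector of genomic positions; `NA` outside
#'   `[0, length_t)`.
#' @export
transcript_to_genomic <- function(model, tpos) {
  ex <- model$exons
  len_tx <- exon_lengths_tx(model)
  bounds <- cumsum(c(0L, len_tx))
  n <- nrow(ex)
  res <- rep(NA_integer_, length(tpos))
  ok <- !is.na(tpos) & tpos >= 0L & tpos < model$length_t
  j <- findInterval(tpos[ok], bounds)        # exon index in transcript order
  within <- tpos[ok] - bounds[j]
  if (model$strand == "+") {
    res[ok] <- ex[j, "start"] + within
  } else {
    gi <- n + 1L - j                          # genomic-order index
    res[ok] <- ex[gi, "end"] - 1L - within
  }
  as.integer(res)
}

# ---------------------------------------------------------------------------
# Annotation parsing

validate_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- !grepl("^(#|\\s*$)", lines)
  nfield <- lengths(strsplit(lines[data], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(data)[which(nfield < 9L)[1L]]
    stop("malformed annotation record at line ", bad, " of '", path,
         "' (expected 9 tab-separated fields)")
  }
  invisible(TRUE)
}

#' Parse a GFF3/GTF annotation into transcript models
#'
#' Exon and CDS features are grouped by transcript; every transcript
#' with at least one exon yields a model. Transcripts without an
#' annotated CDS are flagged non-coding (`coding = FALSE`) and are
#' excluded by the segment/topology functions, which operate on mRNAs
#' only. The CDS is taken to include the stop codon.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return Named list of [transcript_model()] objects
#'   (class `transcript_models`).
#' @export
parse_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  validate_annotation_lines(path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if ("transcript_id" %in% names(mc)) {            # GTF
    txid <- as.character(mc$transcript_id)
    gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else txid
  } else if ("Parent" %in% names(mc)) {            # GFF3
    txid <- vapply(mc$Parent, function(p)
      if (length(p)) as.character(p[1L]) else NA_character_, character(1))
    gid <- rep(NA_character_, length(txid))
  } else stop("annotation carries neither 'transcript_id' nor 'Parent'")
  if (anyNA(txid)) stop("exon/CDS feature without a transcript identifier")

  start0 <- BiocGenerics::start(gr) - 1L           # to 0-based half-open
  end0 <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  contig <- as.character(GenomicRanges::seqnames(gr))

  out <- list()
  for (tx in unique(txid)) {
    sel <- txid == tx
    exo <- sel & type == "exon"
    if (!any(exo)) next
    cds <- sel & type == "CDS"
    exons <- cbind(start = start0[exo], end = end0[exo])
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    st <- strand[exo][1L]
    model_nc <- transcript_model(tx, gid[which(sel)[1L]],
                                 contig[exo][1L], st, exons)
    if (any(cds)) {
      cg <- range(c(start0[cds], end0[cds] - 1L))
      t1 <- genomic_to_transcript(model_nc, cg[1L])
      t2 <- genomic_to_transcript(model_nc, cg[2L])
      if (anyNA(c(t1, t2)))
        stop("transcript '", tx, "': CDS not contained in exons")
      cds_t <- sort(c(t1, t2))
      out[[tx]] <- transcript_model(tx, model_nc$gene_id, model_nc$contig,
                                    st, exons, cds_t[1L], cds_t[2L] + 1L)
    } else {
      out[[tx]] <- model_nc
    }
  }
  if (!is.null(gid[1]) && anyNA(vapply(out, `[[`, "", "gene_id"))) {
    for (tx in names(out))
      if (is.na(out[[tx]]$gene_id)) out[[tx]]$gene_id <- tx
  }
  structure(out, class = "transcript_models")
}

#' Write transcript models as GFF3
#'
#' Emits gene/mRNA/exon/CDS records (1-based, closed, per the format);
#' [parse_annotation()] is its inverse.
#'
#' @param models `transcript_models` list.
#' @param path Output path.
#' @export
write_annotation <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    n <- nrow(ex)
    gene <- data.frame(contig = m$contig, start = min(ex[, "start"]) + 1L,
                       end = max(ex[, "end"]), strand = m$strand,
                       type = c("gene", "mRNA"),
                       id = c(m$gene_id, m$transcript_id),
                       parent = c(NA, m$gene_id))
    exr <- data.frame(contig = m$contig, start = ex[, "start"] + 1L,
                      end = ex[, "end"], strand = m$strand, type = "exon",
                      id = NA, parent = m$transcript_id)
    out <- rbind(gene, exr)
    if (m$coding) {
      g1 <- transcript_to_genomic(m, c(m$cds_start_t, m$cds_end_t - 1L))
      lo <- min(g1); hi <- max(g1)
      cds_ex <- ex[ex[, "end"] > lo & ex[, "start"] <= hi, , drop = FALSE]
      cds_ex[1L, "start"] <- max(cds_ex[1L, "start"], lo)
      cds_ex[nrow(cds_ex), "end"] <- min(cds_ex[nrow(cds_ex), "end"], hi + 1L)
      out <- rbind(out, data.frame(contig = m$contig,
                                   start = cds_ex[, "start"] + 1L,
                                   end = cds_ex[, "end"], strand = m$strand,
                                   type = "CDS", id = NA,
                                   parent = m$transcript_id))
    }
    out
  })
  tab <- do.call(rbind, rows)
  attrs <- ifelse(is.na(tab$id),
                  paste0("Parent=", tab$parent),
                  ifelse(is.na(tab$parent), paste0("ID=", tab$id),
                         paste0("ID=", tab$id, ";Parent=", tab$parent)))
  lines <- sprintf("%s\tmeripr\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   tab$contig, tab$type, tab$start, tab$end, tab$strand,
                   ifelse(tab$type == "CDS", "0", "."), attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Interval and coverage I/O (transcript space; BED/bedGraph conventions,
# 0-based half-open)

#' Read a BED file of transcript-space intervals
#'
#' @param path Path to a BED3+/BED6 file.
#' @return data.frame with columns `transcript_id`, `start`, `end`, and
#'   (when present) `name`, `score`, `strand`. Empty file gives an
#'   empty data.frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character())
  if (file.size(path) == 0L) return(empty)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (nrow(tab) == 0L) return(empty)
  names(tab)[1:3] <- c("transcript_id", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "name"
  if (ncol(tab) >= 5L) names(tab)[5L] <- "score"
  if (ncol(tab) >= 6L) names(tab)[6L] <- "strand"
  if (any(tab$start < 0L) || any(tab$end <= tab$start))
    stop("invalid BED interval in ", path)
  tab
}

#' Write transcript-space intervals as BED
#'
#' @param intervals data.frame as returned by [read_bed()]; extra
#'   columns beyond the first six are dropped.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("transcript_id", "start", "end", "name", "score",
                      "strand"), names(intervals))
  tab <- intervals[, cols, drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage set constructor
#'
#' One sequencing library's per-nucleotide fragment counts across all
#' transcripts, plus its total mapped-fragment count.
#'
#' @param tracks Named list (by transcript) of non-negative count
#'   vectors, one entry per transcript, vector length = transcript
#'   length.
#' @param library_size Total mapped fragments; defaults to the sum of
#'   all counts.
#' @export
coverage_set <- function(tracks, library_size = NULL) {
  total <- sum(vapply(tracks, sum, numeric(1)))
  if (is.null(library_size)) library_size <- total
  if (library_size < total)
    stop("library_size smaller than summed track counts")
  structure(list(tracks = tracks, library_size = library_size),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("coverage_set: %d transcripts, library size %.4g\n",
              length(x$tracks), x$library_size))
  invisible(x)
}

#' Write a coverage set as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are kept so the file is
#' self-describing. The library size is recorded on a `#library_size=`
#' header line.
#'
#' @param cov A [coverage_set()].
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#library_size=%.10g", cov$library_size), con)
  for (tx in names(cov$tracks)) {
    r <- rle(cov$tracks[[tx]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.10g", tx, start, end, r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' @param path Path written by [write_bedgraph()] (or any bedGraph in
#'   transcript space).
#' @param models Optional `transcript_models`; when given, vector
#'   lengths are validated/padded to each transcript's length and
#'   out-of-bounds records are an error.
#' @return A [coverage_set()].
#' @export
read_bedgraph <- function(path, models = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lib <- NULL
  hdr <- grep("^#library_size=", lines)
  if (length(hdr)) lib <- as.numeric(sub("^#library_size=", "", lines[hdr[1]]))
  lines <- lines[!grepl("^(#|track)", lines)]
  if (!length(lines)) return(coverage_set(list(), library_size = lib))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- data.frame(tx = vapply(parts, `[`, "", 1L),
                    start = as.integer(vapply(parts, `[`, "", 2L)),
                    end = as.integer(vapply(parts, `[`, "", 3L)),
                    value = as.numeric(vapply(parts, `[`, "", 4L)))
  tracks <- lapply(split(tab, tab$tx), function(d) {
    len <- max(d$end)
    if (!is.null(models)) {
      m <- models[[d$tx[1L]]]
      if (is.null(m)) stop("bedGraph transcript '", d$tx[1L],
                           "' absent from models")
      if (len > m$length_t)
        stop("bedGraph interval beyond transcript bounds for '",
             d$tx[1L], "'")
      len <- m$length_t
    }
    v <- numeric(len)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    v
  })
  if (!is.null(models)) {
    missing <- setdiff(names(models), names(tracks))
    for (tx in missing) tracks[[tx]] <- numeric(models[[tx]]$length_t)
    tracks <- tracks[names(models)]
  }
  coverage_set(tracks, library_size = lib)
}

#' Read a FASTA file of transcript sequences
#'
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet` named by transcript.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  Biostrings::readDNAStringSet(path)
}
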