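# Transcript model: genome + GTF loading, intron derivation, strand-aware
# sequence extraction. All internal coordinates are 0-based half-open;
# GTF (1-based inclusive) and BED (0-based half-open) are converted at the
# I/O boundary. Exon/intron indices are numbered in transcription order.

#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into a `DNAStringSet`. Record IDs are
#' truncated at the first whitespace and sequences are normalised to upper
#' case, so downstream sequence comparisons are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA record IDs: ", paste(dup, collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  out
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a genomic interval's sequence
#'
#' Returns the forward-strand slice `[start, end)` of `chrom`, or its reverse
#' complement when `strand` is `"-"`. Coordinates are 0-based half-open.
#'
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A character string.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom)
  }
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds on %s (length %d)",
                 start, end, chrom, len))
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

#' @noRd
new_transcript_model <- function(transcript_id, gene_id, gene_name,
                                 chrom, strand, exons, introns) {
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_name = gene_name, chrom = chrom, strand = strand,
         exons = exons, introns = introns),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s%s) on %s[%s]: %d exon(s), %d intron(s)\n",
              x$transcript_id, x$gene_id,
              if (nzchar(x$gene_name)) paste0("/", x$gene_name) else "",
              x$chrom, x$strand, nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Derive introns from a transcript's exons
#'
#' Introns are the gaps between genomically adjacent exons, indexed in
#' transcription order so that intron *k* lies between exon *k* and exon
#' *k + 1* on both strands.
#'
#' @param tx A `transcript_model`, or a data frame of exon intervals with
#'   columns `start`, `end` (0-based half-open, transcription order) plus a
#'   `strand` argument.
#' @param strand Used only when `tx` is a bare exon data frame.
#' @return A data frame with columns `start`, `end`, `index` in transcription
#'   order (zero rows for single-exon transcripts).
#' @export
derive_introns <- function(tx, strand = NULL) {
  if (inherits(tx, "transcript_model")) {
    exons <- tx$exons
    strand <- tx$strand
    id <- tx$transcript_id
  } else {
    exons <- tx
    if (is.null(strand)) stop("strand required when passing bare exons")
    id <- "<exons>"
  }
  n <- nrow(exons)
  if (n <= 1L) {
    return(data.frame(start = integer(0), end = integer(0), index = integer(0)))
  }
  g <- exons[order(exons$start), , drop = FALSE]
  istart <- g$end[-n]
  iend <- g$start[-1]
  if (any(iend <= istart)) {
    stop("malformed transcript model (touching or overlapping exons): ", id)
  }
  introns <- data.frame(start = istart, end = iend)
  # genomic order; transcription order reverses on the minus strand
  if (identical(strand, "-")) introns <- introns[rev(seq_len(n - 1L)), , drop = FALSE]
  introns$index <- seq_len(n - 1L)
  rownames(introns) <- NULL
  introns
}

#' Read a transcript annotation from GTF
#'
#' Parses exon features of a GTF file into a collection of transcript models.
#' GTF 1-based inclusive coordinates become internal 0-based half-open
#' intervals; exons are sorted in transcription order (ascending genomic
#' coordinates on `+`, descending on `-`) and indexed from 1; introns are
#' derived as the gaps between adjacent exons. Exon phase is taken from the
#' attribute named by `phase_attr` when present; missing or unparseable
#' phases are stored as `-1` (noncoding/unknown), the Ensembl sentinel.
#'
#' @param path Path to a GTF file.
#' @param phase_attr Name of the GTF attribute carrying the exon phase.
#' @return A `transcript_db`: list with `transcripts` (named list of
#'   `transcript_model`s) and `index` (a [GenomicRanges::GRanges] of
#'   transcript spans used for fast candidate lookup).
#' @export
read_annotation <- function(path, phase_attr = "exon_phase") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
         else rep(NA_character_, length(gr))
  miss <- is.na(tid) | !nzchar(tid)
  if (any(miss)) {
    warning(sum(miss), " exon feature(s) missing transcript_id skipped")
    gr <- gr[!miss]
    mc <- S4Vectors::mcols(gr)
    tid <- as.character(mc$transcript_id)
  }
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tid
  gname <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else ""
  gname[is.na(gname)] <- ""
  phase <- rep(-1L, length(gr))
  if (phase_attr %in% names(mc)) {
    ph <- suppressWarnings(as.integer(as.character(mc[[phase_attr]])))
    phase[!is.na(ph)] <- ph[!is.na(ph)]
  }

  transcripts <- list()
  for (id in unique(tid)) {
    sel <- which(tid == id)
    chrom <- as.character(GenomicRanges::seqnames(gr))[sel[1]]
    strand <- as.character(GenomicRanges::strand(gr))[sel[1]]
    if (!strand %in% c("+", "-")) strand <- "+"
    ex <- data.frame(start = GenomicRanges::start(gr)[sel] - 1L,
                     end = GenomicRanges::end(gr)[sel],
                     phase = phase[sel])
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n > 1L && any(ex$start[-1] < ex$end[-n])) {
      stop("overlapping exons within transcript: ", id)
    }
    if (identical(strand, "-")) ex <- ex[rev(seq_len(n)), , drop = FALSE]
    ex$index <- seq_len(n)
    rownames(ex) <- NULL
    tx <- new_transcript_model(
      transcript_id = id, gene_id = gid[sel[1]], gene_name = gname[sel[1]],
      chrom = chrom, strand = strand,
      exons = ex[, c("start", "end", "index", "phase")],
      introns = data.frame(start = integer(0), end = integer(0),
                           index = integer(0)))
    tx$introns <- derive_introns(tx)
    transcripts[[id]] <- tx
  }

  spans <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(chrom = tx$chrom,
               start = min(tx$exons$start), end = max(tx$exons$end),
               strand = tx$strand, transcript_id = tx$transcript_id)
  }))
  index <- GenomicRanges::GRanges(
    seqnames = spans$chrom,
    ranges = IRanges::IRanges(start = spans$start + 1L, end = spans$end),
    strand = spans$strand, transcript_id = spans$transcript_id)
  structure(list(transcripts = transcripts, index = index),
            class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("<transcript_db> %d transcript(s) on %d sequence(s)\n",
              length(x$transcripts),
              length(unique(as.character(GenomicRanges::seqnames(x$index))))))
  invisible(x)
}

#' Total spliced length of a transcript
#' @param tx A `transcript_model`.
#' @return Integer sum of exon widths.
#' @export
spliced_length <- function(tx) {
  sum(tx$exons$end - tx$exons$start)
}

#' All exon and intron regions of a transcript
#'
#' @param tx A `transcript_model`.
#' @return Data frame with columns `type` (`"exon"`/`"intron"`), `index`,
#'   `label` (e.g. `"EXON2"`), `start`, `end`.
#' @export
transcript_regions <- function(tx) {
  ex <- data.frame(type = "exon", index = tx$exons$index,
                   start = tx$exons$start, end = tx$exons$end)
  if (nrow(tx$introns)) {
    it <- data.frame(type = "intron", index = tx$introns$index,
                     start = tx$introns$start, end = tx$introns$end)
    ex <- rbind(ex, it)
  }
  ex$label <- paste0(toupper(ex$type), ex$index)
  ex
}

#' Sequence of one exon or intron region, in transcription orientation
#' @noRd
region_sequence <- function(tx, genome, type, index) {
  tab <- if (type == "exon") tx$exons else tx$introns
  row <- tab[tab$index == index, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("region %s%d absent from transcript %s",
                 toupper(type), index, tx$transcript_id))
  }
  extract_sequence(genome, tx$chrom, row$start, row$end, tx$strand)
}
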