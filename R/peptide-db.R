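# Customized AS junction-peptide database: 120-nt flank synthesis around the
# splice boundary, phase-based reading-frame inference with three-frame
# longest-peptide fallback, and target/decoy FASTA emission.

#' @noRd
parse_region_label <- function(label) {
  if (is.na(label) || !grepl("^(EXON|INTRON)[0-9]+$", label)) {
    stop("malformed region label: ", label)
  }
  list(type = tolower(sub("[0-9]+$", "", label)),
       index = as.integer(sub("^(EXON|INTRON)", "", label)))
}

#' Synthesize the nucleotide sequence for a splicing event
#'
#' Junction-category (two-region) events take the last `flank` nucleotides
#' of the transcriptionally upstream region joined to the first `flank`
#' nucleotides of the downstream region, yielding a 240-nt synthesized
#' transcript when both regions are long enough; single-region events take
#' the first `flank` nucleotides of the region (120 nt). Regions shorter
#' than the flank contribute their full length and set the corresponding
#' truncation flag. Sequences are in transcription orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param event One event: a list or single-row data frame with fields
#'   `event_id`, `category`, `transcript_id`, `left_region`, `right_region`.
#' @param txdb A `transcript_db`.
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param flank Nucleotides taken on each side of the junction (default 120,
#'   matching the length distribution of MS/MS-detectable tryptic fragments).
#' @return A `splice_seq` list: `event_id`, `category`, `transcript_id`,
#'   `nt_sequence`, `junction_offset` (0-based position of the splice
#'   boundary within the sequence; `NA` for single-region events),
#'   `left_truncated`, `right_truncated`, and `left_offset` (0-based offset
#'   of the sequence start within the left/only region, needed for frame
#'   inference).
#' @export
synthesize_event_sequence <- function(event, txdb, genome, flank = 120) {
  tx <- txdb$transcripts[[event$transcript_id]]
  if (is.null(tx)) stop("unknown transcript: ", event$transcript_id)
  left <- parse_region_label(event$left_region)
  left_seq <- region_sequence(tx, genome, left$type, left$index)
  llen <- nchar(left_seq)
  single <- is.na(event$right_region) || identical(event$right_region, ".")
  if (single) {
    used <- min(flank, llen)
    return(structure(list(
      event_id = event$event_id, category = event$category,
      transcript_id = event$transcript_id,
      nt_sequence = substr(left_seq, 1L, used),
      junction_offset = NA_integer_,
      left_truncated = llen < flank, right_truncated = FALSE,
      left_offset = 0L), class = "splice_seq"))
  }
  right <- parse_region_label(event$right_region)
  right_seq <- region_sequence(tx, genome, right$type, right$index)
  rlen <- nchar(right_seq)
  lused <- min(flank, llen)
  rused <- min(flank, rlen)
  structure(list(
    event_id = event$event_id, category = event$category,
    transcript_id = event$transcript_id,
    nt_sequence = paste0(substr(left_seq, llen - lused + 1L, llen),
                         substr(right_seq, 1L, rused)),
    junction_offset = lused,
    left_truncated = llen < flank, right_truncated = rlen < flank,
    left_offset = llen - lused), class = "splice_seq")
}

#' Infer the translation frame from an exon phase
#'
#' The Ensembl exon phase gives the codon position at which the exon starts;
#' the codon position of the synthesized sequence's first base is then
#' `(phase + offset) mod 3`, where `offset` is that base's 0-based position
#' within the exon, and translation must skip `(3 - position) mod 3` bases
#' to land on a codon boundary.
#'
#' @param phase Exon phase: 0, 1, 2, or -1 / `NA` for noncoding/unknown.
#' @param offset 0-based offset of the sequence start within the exon.
#' @return Frame 0, 1 or 2, or `NA` when the phase is unknown (callers then
#'   fall back to three-frame translation).
#' @export
infer_frame_from_phase <- function(phase, offset) {
  if (is.na(phase) || phase < 0L) return(NA_integer_)
  codon_pos <- (phase + offset) %% 3L
  as.integer((3L - codon_pos) %% 3L)
}

#' Longest stop-free peptide over a set of reading frames
#'
#' Translates the sequence in each requested frame with the standard genetic
#' code, splits each translation at stop codons, and returns the single
#' longest stop-free peptide over all requested frames. Ties are broken by
#' the lowest frame index, then the earliest start within the frame.
#'
#' @param nt Nucleotide string.
#' @param frames Subset of `c(0, 1, 2)`.
#' @return List with `peptide` (possibly `""` when no codon translates),
#'   `frame` (`NA` when `peptide` is empty), and `start_nt` (0-based offset
#'   of the peptide's first codon within `nt`).
#' @export
translate_longest <- function(nt, frames = 0:2) {
  stopifnot(length(frames) >= 1L, all(frames %in% 0:2))
  nt <- toupper(nt)
  best <- list(peptide = "", frame = NA_integer_, start_nt = NA_integer_)
  for (f in sort(unique(as.integer(frames)))) {
    s <- substr(nt, f + 1L, nchar(nt))
    n3 <- (nchar(s) %/% 3L) * 3L
    if (n3 < 3L) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n3)), no.init.codon = TRUE))
    m <- gregexpr("[^*]+", aa)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    i <- which.max(lens)  # first maximum = earliest start
    if (lens[i] > nchar(best$peptide)) {
      best <- list(peptide = substr(aa, m[i], m[i] + lens[i] - 1L),
                   frame = f,
                   start_nt = f + 3L * (as.integer(m[i]) - 1L))
    }
  }
  best
}

#' Build the customized AS peptide database
#'
#' For every selected event the junction sequence is synthesized with
#' [synthesize_event_sequence()]. When the upstream region is an exon with a
#' known phase, the translation frame is inferred from that phase and only
#' that frame is translated (`frame_source = "phase"`); otherwise all three
#' frames are translated and the longest stop-free peptide is kept
#' (`frame_source = "3frame"`). Records whose peptide is shorter than
#' `min_peptide_len` are dropped (count reported via `message()`).
#'
#' @param biomarkers Data frame of selected events (needs `event_id`,
#'   `category`, `gene_id`, `transcript_id`, `left_region`, `right_region`).
#' @param txdb A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @param flank Flank length in nucleotides (default 120).
#' @param min_peptide_len Minimum peptide length in residues (default 6, a
#'   tryptic-detectability floor).
#' @return Data frame of peptide records: `event_id`, `category`, `gene_id`,
#'   `transcript_id`, `frame`, `frame_source`, `peptide`, `nt_sequence`,
#'   `junction_offset`, `spans_junction`, `header`.
#' @export
build_peptide_db <- function(biomarkers, txdb, genome, flank = 120,
                             min_peptide_len = 6) {
  recs <- list()
  dropped <- 0L
  for (i in seq_len(nrow(biomarkers))) {
    ev <- biomarkers[i, , drop = FALSE]
    ss <- synthesize_event_sequence(ev, txdb, genome, flank)
    left <- parse_region_label(ev$left_region)
    frame <- NA_integer_
    if (left$type == "exon") {
      tx <- txdb$transcripts[[ev$transcript_id]]
      phase <- tx$exons$phase[tx$exons$index == left$index]
      frame <- infer_frame_from_phase(phase, ss$left_offset)
    }
    if (!is.na(frame)) {
      tr <- translate_longest(ss$nt_sequence, frames = frame)
      src <- "phase"
    } else {
      tr <- translate_longest(ss$nt_sequence, frames = 0:2)
      src <- "3frame"
    }
    if (nchar(tr$peptide) < min_peptide_len) {
      dropped <- dropped + 1L
      next
    }
    spans <- !is.na(ss$junction_offset) &&
      tr$start_nt < ss$junction_offset &&
      tr$start_nt + 3L * nchar(tr$peptide) > ss$junction_offset
    recs[[length(recs) + 1L]] <- data.frame(
      event_id = ev$event_id, category = ev$category,
      gene_id = ev$gene_id, transcript_id = ev$transcript_id,
      frame = tr$frame, frame_source = src, peptide = tr$peptide,
      nt_sequence = ss$nt_sequence,
      junction_offset = ss$junction_offset,
      peptide_start_nt = tr$start_nt,
      spans_junction = spans,
      header = sprintf("AS|%s|%s|%s|%s|frame=%d|src=%s",
                       ev$event_id, ev$category, ev$gene_id,
                       ev$transcript_id, tr$frame, src),
      stringsAsFactors = FALSE)
  }
  if (dropped) {
    message(dropped, " record(s) below min_peptide_len dropped")
  }
  if (!length(recs)) {
    return(data.frame(event_id = character(0), category = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      frame = integer(0), frame_source = character(0),
                      peptide = character(0), nt_sequence = character(0),
                      junction_offset = integer(0),
                      peptide_start_nt = integer(0),
                      spans_junction = logical(0), header = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Reverse-sequence decoy records
#'
#' Builds the decoy companion of a target peptide database by reversing each
#' entry's full peptide string and prefixing the header with `DECOY_` — the
#' standard inverse-sequence target-decoy construction, giving a decoy
#' database of exactly the target database's size and length distribution.
#' Palindromic peptides (decoy identical to target) are reported via
#' `message()`.
#'
#' @param records Peptide records from [build_peptide_db()].
#' @return The records with reversed peptides and `DECOY_`-prefixed headers.
#' @export
build_decoy <- function(records) {
  rev1 <- function(x) {
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
  }
  out <- records
  out$peptide <- rev1(records$peptide)
  out$header <- paste0("DECOY_", records$header)
  pal <- sum(out$peptide == records$peptide)
  if (pal) message(pal, " palindromic peptide(s): decoy identical to target")
  out
}

#' Write peptide records to FASTA
#'
#' @param records Peptide records (target or decoy) with `header` and
#'   `peptide` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(records, path) {
  if (anyDuplicated(records$header)) {
    stop("duplicate FASTA headers: ",
         paste(unique(records$header[duplicated(records$header)]),
               collapse = ", "))
  }
  aa <- Biostrings::AAStringSet(records$peptide)
  names(aa) <- records$header
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Junction-site notation for a peptide record
#'
#' Renders the peptide with the splice boundary marked: `^` separates the
#' residues translated from the upstream and downstream sides of the
#' junction; when the boundary falls inside a codon, the residue straddling
#' it is shared by both sides and is wrapped in parentheses instead.
#' Single-region events (no junction within the sequence) are returned
#' unchanged.
#'
#' @param record One row of a [build_peptide_db()] table.
#' @return Annotated peptide string.
#' @export
junction_notation <- function(record) {
  pep <- record$peptide
  j <- record$junction_offset
  if (is.na(j)) return(pep)
  k <- j - record$peptide_start_nt
  n <- nchar(pep)
  if (k <= 0L) return(paste0("^", pep))
  if (k >= 3L * n) return(paste0(pep, "^"))
  if (k %% 3L == 0L) {
    i <- k %/% 3L
    return(paste0(substr(pep, 1L, i), "^", substr(pep, i + 1L, n)))
  }
  i <- k %/% 3L + 1L  # residue whose codon straddles the boundary
  paste0(substr(pep, 1L, i - 1L), "(", substr(pep, i, i), ")",
         substr(pep, i + 1L, n))
}
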