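# Junction parsing and annotation: overlap rates between junction blocks and
# transcript regions, argmax region assignment at a 90% minimum overlap, and
# classification into the six alternative-splicing categories.

AS_CATEGORIES <- c("EXON_NM", "INTRON_AS", "I_E_AS", "E_I_AS", "E_E_NM", "E_E_AS")

#' Parse a BED12 junction track
#'
#' Reads junction-spanning read evidence in the `junctions.bed` dialect: each
#' record has exactly two blocks (the aligned segments on either side of the
#' splice) and carries the supporting read count in the score column. Records
#' with a block count other than two are skipped with a warning.
#'
#' @param path Path to a BED12 file.
#' @param sample_id Sample label attached to every observation.
#' @return A `junction_obs` data frame with columns `sample_id`, `chrom`,
#'   `b1_start`, `b1_end`, `b2_start`, `b2_end` (0-based half-open genomic
#'   block intervals, block 1 genomically left) and `read_count`.
#' @export
parse_junction_bed <- function(path, sample_id) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(empty_observations())
  bl <- rtracklayer::blocks(gr)
  nb <- S4Vectors::elementNROWS(bl)
  if (any(nb != 2L)) {
    warning(sum(nb != 2L), " record(s) with blockCount != 2 skipped in ", path)
  }
  keep <- nb == 2L
  if (!any(keep)) return(empty_observations())
  gr <- gr[keep]
  bl <- bl[keep]
  ir <- unlist(IRanges::ranges(bl), use.names = FALSE)
  s <- GenomicRanges::start(ir) - 1L
  e <- GenomicRanges::end(ir)
  i1 <- seq(1L, length(s), by = 2L)
  obs <- data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    b1_start = s[i1], b1_end = e[i1],
    b2_start = s[i1 + 1L], b2_end = e[i1 + 1L],
    read_count = as.integer(GenomicRanges::score(gr)),
    stringsAsFactors = FALSE)
  bad <- obs$b1_end > obs$b2_start
  if (any(bad)) stop("overlapping junction blocks in ", path)
  class(obs) <- c("junction_obs", class(obs))
  obs
}

#' @noRd
empty_observations <- function() {
  obs <- data.frame(sample_id = character(0), chrom = character(0),
                    b1_start = integer(0), b1_end = integer(0),
                    b2_start = integer(0), b2_end = integer(0),
                    read_count = integer(0), stringsAsFactors = FALSE)
  class(obs) <- c("junction_obs", class(obs))
  obs
}

#' Parse single-block region coverage from TSV
#'
#' First-category evidence (whole-exon / whole-intron coverage) is consumed
#' from a simple tab-separated table with columns `chrom`, `start`, `end`,
#' `read_count` (0-based half-open). A header line is tolerated when its
#' first field is `"chrom"`.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample label attached to every observation.
#' @return A `junction_obs` data frame; `b2_start`/`b2_end` are `NA` for these
#'   one-block observations.
#' @export
parse_region_tsv <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_observations())
  if (grepl("^chrom\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) return(empty_observations())
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "read_count"),
                          colClasses = c("character", "integer", "integer",
                                         "integer"))
  if (any(df$read_count < 0)) stop("negative read count in ", path)
  obs <- data.frame(sample_id = sample_id, chrom = df$chrom,
                    b1_start = df$start, b1_end = df$end,
                    b2_start = NA_integer_, b2_end = NA_integer_,
                    read_count = df$read_count, stringsAsFactors = FALSE)
  class(obs) <- c("junction_obs", class(obs))
  obs
}

#' Overlap rate between a junction block and a region
#'
#' The asymmetric overlap rate `|A ∩ B| / |A|`, where A is the junction block
#' and B the exon or intron region. Both intervals are 0-based half-open on
#' the same chromosome (intervals on different chromosomes simply do not
#' intersect and score 0). Vectorised over all arguments.
#'
#' @param block_start,block_end Block interval (the denominator).
#' @param region_start,region_end Region interval.
#' @return Numeric in `[0, 1]`.
#' @export
overlap_rate <- function(block_start, block_end, region_start, region_end) {
  ov <- pmax(0L, pmin(block_end, region_end) - pmax(block_start, region_start))
  ov / (block_end - block_start)
}

# Assign one block to the transcript region maximising the overlap rate.
# Ties prefer the exon over the intron, then the lower region index.
#' @noRd
assign_block <- function(bs, be, regions, min_overlap) {
  rate <- overlap_rate(bs, be, regions$start, regions$end)
  ord <- order(-rate, regions$type != "exon", regions$index)
  best <- ord[1]
  if (rate[best] < min_overlap) return(NULL)
  list(type = regions$type[best], index = regions$index[best],
       label = regions$label[best], rate = rate[best])
}

#' @noRd
event_category <- function(up, down) {
  if (is.null(down)) {
    return(if (up$type == "exon") "EXON_NM" else "INTRON_AS")
  }
  if (up$type == "exon" && down$type == "exon") {
    return(if (abs(down$index - up$index) == 1L) "E_E_NM" else "E_E_AS")
  }
  if (up$type == "intron" && down$type == "exon") return("I_E_AS")
  if (up$type == "exon" && down$type == "intron") return("E_I_AS")
  NA_character_  # intron-intron: outside the six categories
}

#' @noRd
make_event_id <- function(category, transcript_id, left, right) {
  paste(category, transcript_id, left,
        ifelse(is.na(right), ".", right), sep = "|")
}

#' Classify one junction observation against a transcript model
#'
#' Each block is assigned to the exon or intron of a candidate transcript
#' that maximises the overlap rate, subject to the rate meeting
#' `min_overlap`; when two regions tie, the exon is preferred over the
#' intron, then the lower region index. An observation whose blocks all pass
#' on a transcript yields one annotated event per such transcript; block
#' order is re-expressed in transcription order so the left region is the
#' transcriptionally upstream one. Category follows the region types:
#' one exon = `EXON_NM`, one intron = `INTRON_AS`, intron-exon = `I_E_AS`,
#' exon-intron = `E_I_AS`, and exon-exon = `E_E_NM` when the indices are
#' adjacent, else `E_E_AS` (exon skipping). Observations failing the
#' threshold on every transcript are unannotated and yield zero rows.
#'
#' @param obs A single-row `junction_obs` data frame (or a list with the same
#'   fields).
#' @param txdb A `transcript_db` from [read_annotation()].
#' @param min_overlap Minimum acceptable overlap rate (default 0.90).
#' @return A data frame of annotated events (possibly zero rows) with columns
#'   `event_id`, `category`, `gene_id`, `transcript_id`, `left_region`,
#'   `right_region`, `sample_id`, `read_count`.
#' @export
classify_junction <- function(obs, txdb, min_overlap = 0.90) {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  annotate_observations(obs[1, , drop = FALSE], txdb, min_overlap)
}

#' @noRd
empty_events <- function() {
  data.frame(event_id = character(0), category = character(0),
             gene_id = character(0), transcript_id = character(0),
             left_region = character(0), right_region = character(0),
             sample_id = character(0), read_count = integer(0),
             stringsAsFactors = FALSE)
}

#' Annotate a table of junction observations
#'
#' Applies [classify_junction()] to every row of a `junction_obs` table; a
#' junction annotating to several transcripts yields one event per
#' transcript.
#'
#' @inheritParams classify_junction
#' @param obs A `junction_obs` data frame (any number of rows).
#' @return A data frame of annotated events in long (per-sample) form, with
#'   the number of observations that annotated to at least one transcript
#'   attached as attribute `n_annotated_obs`.
#' @export
annotate_observations <- function(obs, txdb, min_overlap = 0.90) {
  n <- nrow(obs)
  if (n == 0L) return(empty_events())
  two <- !is.na(obs$b2_start)
  span_end <- ifelse(two, obs$b2_end, obs$b1_end)
  q <- GenomicRanges::GRanges(obs$chrom,
                              IRanges::IRanges(obs$b1_start + 1L, span_end))
  hits <- GenomicRanges::findOverlaps(q, txdb$index, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  tids <- txdb$index$transcript_id[S4Vectors::subjectHits(hits)]
  # cache each transcript's region table once
  region_cache <- lapply(txdb$transcripts, transcript_regions)
  res <- vector("list", length(qh))
  for (k in seq_along(qh)) {
    i <- qh[k]
    id <- tids[k]
    tx <- txdb$transcripts[[id]]
    regions <- region_cache[[id]]
    a1 <- assign_block(obs$b1_start[i], obs$b1_end[i], regions, min_overlap)
    if (is.null(a1)) next
    a2 <- NULL
    if (two[i]) {
      a2 <- assign_block(obs$b2_start[i], obs$b2_end[i], regions, min_overlap)
      if (is.null(a2)) next
    }
    # transcription order: on the minus strand the genomically right block
    # is upstream
    if (two[i] && identical(tx$strand, "-")) {
      up <- a2; down <- a1
    } else {
      up <- a1; down <- a2
    }
    category <- event_category(up, down)
    if (is.na(category)) next
    right <- if (is.null(down)) NA_character_ else down$label
    res[[k]] <- c(make_event_id(category, id, up$label, right), category,
                  tx$gene_id, id, up$label, right,
                  obs$sample_id[i], obs$read_count[i])
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    out <- empty_events()
    attr(out, "n_annotated_obs") <- 0L
    return(out)
  }
  m <- do.call(rbind, res[ok])
  out <- data.frame(event_id = m[, 1], category = m[, 2], gene_id = m[, 3],
                    transcript_id = m[, 4], left_region = m[, 5],
                    right_region = m[, 6], sample_id = m[, 7],
                    read_count = as.integer(m[, 8]), stringsAsFactors = FALSE)
  attr(out, "n_annotated_obs") <- length(unique(qh[ok]))
  out
}

#' Merge annotated events across samples into a count matrix
#'
#' Events with identical `event_id` are merged; per-sample supporting-read
#' counts are summed into an event-by-sample matrix, with zero counts for
#' samples in which an event was not observed.
#'
#' @param events Long-form annotated events from [annotate_observations()].
#' @param samples Optional character vector of sample IDs to force as columns
#'   (samples with no events then appear as all-zero columns).
#' @return An `as_event_set`: list with `events` (one row per distinct event:
#'   `event_id`, `category`, `gene_id`, `transcript_id`, `left_region`,
#'   `right_region`) and `counts` (integer matrix, events x samples).
#' @export
merge_observations <- function(events, samples = NULL) {
  meta_cols <- c("event_id", "category", "gene_id", "transcript_id",
                 "left_region", "right_region")
  pairs <- unique(events[, c("event_id", "category")])
  if (anyDuplicated(pairs$event_id)) {
    stop("conflicting category for event_id (key collision): ",
         paste(unique(pairs$event_id[duplicated(pairs$event_id)]),
               collapse = ", "))
  }
  meta <- events[!duplicated(events$event_id), meta_cols, drop = FALSE]
  meta <- meta[order(meta$event_id), , drop = FALSE]
  rownames(meta) <- NULL
  samples <- sort(unique(c(samples, events$sample_id)))
  counts <- matrix(0L, nrow = nrow(meta), ncol = length(samples),
                   dimnames = list(meta$event_id, samples))
  if (nrow(events)) {
    agg <- stats::aggregate(read_count ~ event_id + sample_id, data = events,
                            FUN = sum)
    counts[cbind(agg$event_id, agg$sample_id)] <- as.integer(agg$read_count)
  }
  structure(list(events = meta, counts = counts), class = "as_event_set")
}

#' @export
print.as_event_set <- function(x, ...) {
  cat(sprintf("<as_event_set> %d event(s) x %d sample(s)\n",
              nrow(x$events), ncol(x$counts)))
  if (nrow(x$events)) print(table(x$events$category))
  invisible(x)
}

#' Filter events by minimum read support
#'
#' Junctions need a minimum number of supporting RNA-Seq reads (default 6)
#' to be retained. With `scope = "pooled"` the threshold applies to the total
#' count across all samples; with `scope = "per_sample"` an event is kept
#' when at least one sample alone reaches the threshold.
#'
#' @param es An `as_event_set`.
#' @param min_reads Minimum supporting reads (default 6).
#' @param scope `"pooled"` (default) or `"per_sample"`.
#' @return The filtered `as_event_set`.
#' @export
filter_min_support <- function(es, min_reads = 6,
                               scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  keep <- if (scope == "pooled") {
    rowSums(es$counts) >= min_reads
  } else {
    apply(es$counts, 1L, max) >= min_reads
  }
  structure(list(events = es$events[keep, , drop = FALSE],
                 counts = es$counts[keep, , drop = FALSE]),
            class = "as_event_set")
}

#' Per-category event counts with a ledger total
#'
#' Summarises an event set (or any data frame with a `category` column) into
#' per-category counts over the six alternative-splicing categories plus a
#' `Total` row, the same ledger layout used for reporting.
#'
#' @param x An `as_event_set` or a data frame with a `category` column.
#' @return Data frame with columns `category` and `count`.
#' @export
category_summary <- function(x) {
  cats <- if (inherits(x, "as_event_set")) x$events$category else x$category
  n <- vapply(AS_CATEGORIES, function(k) sum(cats == k), integer(1))
  data.frame(category = c(AS_CATEGORIES, "Total"),
             count = c(unname(n), length(cats)),
             stringsAsFactors = FALSE)
}
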