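# Fixture builders (everything generated in code; tiny FASTA/GTF/TSV files
# are written to tempfiles) and independent brute-force oracles used to
# cross-check the package's computations.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fixture_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

# exons: data frame with chrom, start (1-based inclusive, GTF convention),
# end, strand, gene_id, transcript_id, and optionally phase
write_fixture_gtf <- function(exons) {
  path <- tempfile(fileext = ".gtf")
  phase_attr <- if ("phase" %in% names(exons)) {
    sprintf(' exon_phase "%d";', exons$phase)
  } else ""
  writeLines(sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
    exons$chrom, exons$start, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id, phase_attr), path)
  path
}

# one-row junction observation table
obs_row <- function(chrom, b1, b2 = NULL, sample_id = "s1", count = 10L) {
  data.frame(sample_id = sample_id, chrom = chrom,
             b1_start = b1[1], b1_end = b1[2],
             b2_start = if (is.null(b2)) NA_integer_ else b2[1],
             b2_end = if (is.null(b2)) NA_integer_ else b2[2],
             read_count = count, stringsAsFactors = FALSE)
}

# a ready-made two/three-exon transcript fixture on one 1000-nt chromosome:
# exons at [100,200), [300,400), [500,600) (0-based half-open)
three_exon_fixture <- function(strand = "+", phase = NULL, seed = 42) {
  set.seed(seed)
  genome_path <- write_fixture_genome(list(chrT = rand_dna(1000)))
  ex <- data.frame(chrom = "chrT", start = c(101L, 301L, 501L),
                   end = c(200L, 400L, 600L), strand = strand,
                   gene_id = "G1", transcript_id = "TX1")
  if (!is.null(phase)) {
    ex$phase <- if (strand == "+") phase else rev(phase)
  }
  gtf_path <- write_fixture_gtf(ex)
  list(genome = read_genome(genome_path), txdb = read_annotation(gtf_path),
       genome_path = genome_path, gtf_path = gtf_path)
}

# ---- independent oracles ---------------------------------------------------

# set-based interval overlap rate (denominator = block)
oracle_overlap <- function(bs, be, rs, re) {
  length(intersect(seq.int(bs, be - 1L), seq.int(rs, re - 1L))) / (be - bs)
}

# hand-coded standard genetic code
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate_frame <- function(nt, frame) {
  s <- substr(toupper(nt), frame + 1L, nchar(nt))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  paste(vapply(seq_len(n), function(i) {
    unname(CODON_TABLE[substr(s, 3L * i - 2L, 3L * i)])
  }, character(1)), collapse = "")
}

oracle_longest_peptide <- function(nt, frames = 0:2) {
  best <- list(peptide = "", frame = NA_integer_)
  for (f in sort(frames)) {
    aa <- oracle_translate_frame(nt, f)
    if (!nchar(aa)) next
    for (frag in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(frag) > nchar(best$peptide)) {
        best <- list(peptide = frag, frame = f)
      }
    }
  }
  best
}

# brute-force junction classifier enumerating all (block, region) pairs
oracle_classify <- function(obs, txdb, min_overlap = 0.9) {
  pick_region <- function(regs, bs, be) {
    rates <- vapply(seq_len(nrow(regs)), function(r) {
      oracle_overlap(bs, be, regs$start[r], regs$end[r])
    }, numeric(1))
    best <- NULL
    best_rate <- -1
    for (r in order(regs$type != "exon", regs$index)) {
      if (rates[r] > best_rate + 1e-12) {
        best_rate <- rates[r]
        best <- regs[r, ]
      }
    }
    if (best_rate < min_overlap) NULL else best
  }
  out <- character(0)
  for (tx in txdb$transcripts) {
    if (tx$chrom != obs$chrom) next
    regs <- rbind(
      data.frame(type = "exon", index = tx$exons$index,
                 start = tx$exons$start, end = tx$exons$end),
      if (nrow(tx$introns)) data.frame(type = "intron",
                                       index = tx$introns$index,
                                       start = tx$introns$start,
                                       end = tx$introns$end))
    r1 <- pick_region(regs, obs$b1_start, obs$b1_end)
    if (is.null(r1)) next
    if (is.na(obs$b2_start)) {
      cat_ <- if (r1$type == "exon") "EXON_NM" else "INTRON_AS"
      lab <- paste0(toupper(r1$type), r1$index)
      out <- c(out, paste(cat_, tx$transcript_id, lab, ".", sep = "|"))
      next
    }
    r2 <- pick_region(regs, obs$b2_start, obs$b2_end)
    if (is.null(r2)) next
    if (tx$strand == "-") { tmp <- r1; r1 <- r2; r2 <- tmp }
    cat_ <- if (r1$type == "exon" && r2$type == "exon") {
      if (abs(r2$index - r1$index) == 1) "E_E_NM" else "E_E_AS"
    } else if (r1$type == "intron" && r2$type == "exon") {
      "I_E_AS"
    } else if (r1$type == "exon" && r2$type == "intron") {
      "E_I_AS"
    } else NA_character_
    if (is.na(cat_)) next
    out <- c(out, paste(cat_, tx$transcript_id,
                        paste0(toupper(r1$type), r1$index),
                        paste0(toupper(r2$type), r2$index), sep = "|"))
  }
  sort(out)
}

# exhaustive-prefix target-decoy cutoff scan
oracle_fdr_cutoff <- function(evalue, is_decoy, fdr_max) {
  ue <- sort(unique(evalue))
  pass <- vapply(ue, function(e) {
    t <- sum(!is_decoy & evalue <= e)
    d <- sum(is_decoy & evalue <= e)
    t > 0 && d / t <= fdr_max
  }, logical(1))
  if (!any(pass)) return(-Inf)
  if (pass[length(ue)]) return(Inf)
  max(ue[pass])
}

# small event set built directly (events x samples count matrix)
make_event_set <- function(counts, categories = NULL) {
  ev <- data.frame(
    event_id = rownames(counts),
    category = if (is.null(categories)) rep("E_E_NM", nrow(counts))
               else categories,
    gene_id = "G", transcript_id = "T",
    left_region = "EXON1", right_region = "EXON2",
    stringsAsFactors = FALSE)
  structure(list(events = ev, counts = counts), class = "as_event_set")
}

make_design <- function(n1 = 20, n2 = 20, groups = c("normal", "cancer")) {
  data.frame(
    sample_id = c(sprintf("%s_%02d", groups[1], seq_len(n1)),
                  sprintf("%s_%02d", groups[2], seq_len(n2))),
    group = rep(groups, c(n1, n2)), stringsAsFactors = FALSE)
}
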