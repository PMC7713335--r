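# Events on the three-exon fixture (exons [100,200), [300,400), [500,600);
# regions are 100 nt, shorter than the 120-nt default flank, so most tests
# use flank = 40 for untruncated flanks unless truncation is the point.

fixture_event <- function(category, left, right = NA_character_,
                          id = NULL) {
  data.frame(event_id = id %||% paste(category, "TX1", left,
                                      ifelse(is.na(right), ".", right),
                                      sep = "|"),
             category = category, gene_id = "G1", transcript_id = "TX1",
             left_region = left, right_region = right,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("junction events synthesize flank-joined sequences", {
  fx <- three_exon_fixture("+")
  ev <- fixture_event("E_E_NM", "EXON1", "EXON2")
  ss <- synthesize_event_sequence(ev, fx$txdb, fx$genome, flank = 40)
  expect_equal(nchar(ss$nt_sequence), 80L)
  expect_equal(ss$junction_offset, 40L)
  expect_false(ss$left_truncated)
  expect_false(ss$right_truncated)
  # exact content: last 40 nt of exon 1 + first 40 nt of exon 2
  e1 <- extract_sequence(fx$genome, "chrT", 100, 200, "+")
  e2 <- extract_sequence(fx$genome, "chrT", 300, 400, "+")
  expect_equal(ss$nt_sequence,
               paste0(substr(e1, 61, 100), substr(e2, 1, 40)))
  # regions shorter than the flank are taken whole and flagged
  ss120 <- synthesize_event_sequence(ev, fx$txdb, fx$genome, flank = 120)
  expect_equal(nchar(ss120$nt_sequence), 200L)
  expect_true(ss120$left_truncated)
  expect_true(ss120$right_truncated)
})

test_that("single-region events take the first flank nucleotides", {
  fx <- three_exon_fixture("+")
  ev <- fixture_event("EXON_NM", "EXON2")
  ss <- synthesize_event_sequence(ev, fx$txdb, fx$genome, flank = 40)
  e2 <- extract_sequence(fx$genome, "chrT", 300, 400, "+")
  expect_equal(ss$nt_sequence, substr(e2, 1, 40))
  expect_true(is.na(ss$junction_offset))
  expect_equal(ss$left_offset, 0L)
})

test_that("minus-strand synthesis is in transcription orientation", {
  fx <- three_exon_fixture("-")
  # on '-', exon 1 is [500,600): its sequence is the reverse complement
  ev <- fixture_event("E_E_NM", "EXON1", "EXON2")
  ss <- synthesize_event_sequence(ev, fx$txdb, fx$genome, flank = 30)
  e1 <- revcomp(extract_sequence(fx$genome, "chrT", 500, 600, "+"))
  e2 <- revcomp(extract_sequence(fx$genome, "chrT", 300, 400, "+"))
  expect_equal(ss$nt_sequence,
               paste0(substr(e1, 71, 100), substr(e2, 1, 30)))
})

test_that("unknown regions or transcripts are rejected", {
  fx <- three_exon_fixture("+")
  expect_error(synthesize_event_sequence(
    fixture_event("EXON_NM", "EXON9"), fx$txdb, fx$genome), "absent")
  bad <- fixture_event("EXON_NM", "EXON1")
  bad$transcript_id <- "NOPE"
  expect_error(synthesize_event_sequence(bad, fx$txdb, fx$genome),
               "unknown transcript")
})

test_that("frame inference follows the exon phase and flank offset", {
  expect_equal(infer_frame_from_phase(0, 0), 0L)
  expect_equal(infer_frame_from_phase(0, 1), 2L)
  expect_true(is.na(infer_frame_from_phase(-1, 5)))
  expect_true(is.na(infer_frame_from_phase(NA, 0)))
  # oracle: enumerate codon positions base by base
  for (phase in 0:2) {
    for (offset in 0:7) {
      codon_pos <- (phase + offset) %% 3  # position within its codon
      skip <- (3 - codon_pos) %% 3        # bases to reach the next boundary
      expect_equal(infer_frame_from_phase(phase, offset), as.integer(skip))
    }
  }
})

test_that("translation keeps the longest stop-free peptide across frames", {
  tr <- translate_longest("ATGAAATAG", frames = 0)
  expect_equal(tr$peptide, "MK")
  expect_equal(tr$frame, 0L)
  # frame 0 is all stop codons; frames 1 and 2 tie at 5 residues and the
  # lower frame index wins
  nt <- strrep("TAA", 6)
  tr <- translate_longest(nt)
  expect_equal(tr$frame, 1L)
  expect_equal(tr$peptide, strrep("N", 5))
  expect_equal(oracle_longest_peptide(nt)$peptide, strrep("N", 5))
  # all-stop in frame 0; the other frames salvage short fragments
  tr <- translate_longest("TAATAATAA")
  expect_equal(tr$peptide, "NN")
  expect_equal(tr$frame, 1L)
  # too short for any codon
  expect_equal(translate_longest("AT")$peptide, "")
})

test_that("translation agrees with the brute-force oracle on random sequences", {
  set.seed(13)
  for (i in 1:300) {
    nt <- rand_dna(sample(3:120, 1))
    got <- translate_longest(nt)
    want <- oracle_longest_peptide(nt)
    expect_equal(got$peptide, want$peptide)
    if (nchar(want$peptide)) expect_equal(got$frame, want$frame)
    # no stop symbol, length bounded by available codons
    expect_false(grepl("*", got$peptide, fixed = TRUE))
    expect_lte(nchar(got$peptide), nchar(nt) %/% 3)
  }
})

test_that("phase-inferred translation equals the oracle's same-frame result", {
  fx <- three_exon_fixture("+", phase = c(0L, 1L, 2L))
  ev <- fixture_event("E_E_NM", "EXON1", "EXON2")
  recs <- build_peptide_db(ev, fx$txdb, fx$genome, flank = 40,
                           min_peptide_len = 1)
  expect_equal(recs$frame_source, "phase")
  # flank starts at offset 60 in a phase-0 exon: frame (3 - 60 %% 3) %% 3 = 0
  ss <- synthesize_event_sequence(ev, fx$txdb, fx$genome, flank = 40)
  frame <- infer_frame_from_phase(0L, ss$left_offset)
  expect_equal(recs$frame, frame)
  best <- oracle_longest_peptide(ss$nt_sequence, frames = frame)
  expect_equal(recs$peptide, best$peptide)
})

test_that("a codon-aligned normal junction translates continuously", {
  # both exon sides built from stop-free codons, flanks codon-aligned
  left <- strrep("GCT", 20)   # A x20
  right <- strrep("AAA", 20)  # K x20
  genome_path <- write_fixture_genome(list(chrC = paste0(
    strrep("T", 10), left, strrep("T", 5), right, strrep("T", 10))))
  gtf <- write_fixture_gtf(data.frame(
    chrom = "chrC", start = c(11L, 76L), end = c(70L, 135L), strand = "+",
    gene_id = "G", transcript_id = "T", phase = c(0L, 0L)))
  genome <- read_genome(genome_path)
  txdb <- read_annotation(gtf)
  ev <- data.frame(event_id = "E_E_NM|T|EXON1|EXON2", category = "E_E_NM",
                   gene_id = "G", transcript_id = "T",
                   left_region = "EXON1", right_region = "EXON2",
                   stringsAsFactors = FALSE)
  recs <- build_peptide_db(ev, txdb, genome, flank = 30, min_peptide_len = 1)
  expect_equal(recs$peptide,
               paste0(strrep("A", 10), strrep("K", 10)))
  expect_true(recs$spans_junction)
  expect_equal(junction_notation(recs[1, ]),
               paste0(strrep("A", 10), "^", strrep("K", 10)))
})

test_that("junction notation marks codon-straddling residues with parentheses", {
  rec <- data.frame(peptide = "AKLM", junction_offset = 7L,
                    peptide_start_nt = 0L)
  # boundary at nt 7 falls inside codon 3 (nt 6-8): residue L is shared
  expect_equal(junction_notation(rec[1, ]), "AK(L)M")
  rec$junction_offset <- 6L
  expect_equal(junction_notation(rec[1, ]), "AK^LM")
  rec$junction_offset <- NA_integer_
  expect_equal(junction_notation(rec[1, ]), "AKLM")
})

test_that("records below the peptide length floor are dropped with a message", {
  fx <- three_exon_fixture("+")
  ev <- fixture_event("EXON_NM", "EXON1")
  expect_message(
    recs <- build_peptide_db(ev, fx$txdb, fx$genome, flank = 12,
                             min_peptide_len = 10),
    "dropped")
  expect_equal(nrow(recs), 0L)
})

test_that("decoys are per-record reversals with DECOY_ headers", {
  recs <- data.frame(peptide = c("MKLV", "ADA"),
                     header = c("AS|e1|c|g|t|frame=0|src=phase",
                                "AS|e2|c|g|t|frame=1|src=3frame"),
                     stringsAsFactors = FALSE)
  expect_message(dec <- build_decoy(recs), "palindromic")
  expect_equal(dec$peptide, c("VLKM", "ADA"))
  expect_equal(nrow(dec), nrow(recs))
  expect_true(all(startsWith(dec$header, "DECOY_")))
  # identical size and length distribution
  expect_equal(sort(nchar(dec$peptide)), sort(nchar(recs$peptide)))
})

test_that("FASTA writing round-trips and rejects duplicate headers", {
  recs <- data.frame(peptide = c("MKLV", "ADAT"),
                     header = c("AS|e1|x", "AS|e2|x"),
                     stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".fasta")
  write_target_fasta(recs, p)
  back <- Biostrings::readAAStringSet(p)
  expect_equal(names(back), recs$header)
  expect_equal(as.character(back), stats::setNames(recs$peptide, recs$header))
  recs$header[2] <- recs$header[1]
  expect_error(write_target_fasta(recs, p), "duplicate")
})
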