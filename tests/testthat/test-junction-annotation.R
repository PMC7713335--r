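test_that("BED12 block arithmetic and score-as-count parsing", {
  p <- tempfile(fileext = ".bed")
  writeLines(paste0("chr1\t100\t360\tJ1\t7\t+\t100\t360\t255,0,0\t2\t",
                    "50,60\t0,200"), p)
  obs <- parse_junction_bed(p, "sampleA")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$b1_start, 100L)
  expect_equal(obs$b1_end, 150L)
  expect_equal(obs$b2_start, 300L)
  expect_equal(obs$b2_end, 360L)
  expect_equal(obs$read_count, 7L)
  expect_equal(obs$sample_id, "sampleA")
})

test_that("records with blockCount != 2 are skipped with a warning", {
  p <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t360\tJ1\t7\t+\t100\t360\t255,0,0\t2\t50,60\t0,200",
    "chr1\t100\t500\tJ2\t9\t+\t100\t500\t255,0,0\t3\t50,60,40\t0,200,360"),
    p)
  expect_warning(obs <- parse_junction_bed(p, "s"), "blockCount")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$read_count, 7L)
})

test_that("region TSV parsing: basic, header, empty, negative count", {
  p <- tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t200\t9", p)
  obs <- parse_region_tsv(p, "s")
  expect_equal(obs$b1_start, 100L)
  expect_equal(obs$b1_end, 200L)
  expect_true(is.na(obs$b2_start))
  expect_equal(obs$read_count, 9L)

  writeLines(c("chrom\tstart\tend\tread_count", "chr2\t5\t50\t3"), p)
  obs <- parse_region_tsv(p, "s")
  expect_equal(obs$chrom, "chr2")

  writeLines(character(0), p)
  expect_equal(nrow(parse_region_tsv(p, "s")), 0L)

  writeLines("chr1\t100\t200\t-1", p)
  expect_error(parse_region_tsv(p, "s"), "negative")
})

test_that("overlap rate is the block-normalised intersection width", {
  expect_equal(overlap_rate(100, 200, 100, 200), 1.0)
  expect_equal(overlap_rate(100, 200, 150, 300), 0.5)
  expect_equal(overlap_rate(100, 200, 110, 200), 0.9)
  expect_equal(overlap_rate(0, 50, 100, 200), 0.0)
  # asymmetric: denominator is the block
  expect_equal(overlap_rate(110, 200, 100, 200), 1.0)
})

test_that("overlap rate properties: range, containment, shift invariance", {
  set.seed(5)
  for (i in 1:200) {
    bs <- sample(0:500, 1); be <- bs + sample(1:100, 1)
    rs <- sample(0:500, 1); re <- rs + sample(1:100, 1)
    r <- overlap_rate(bs, be, rs, re)
    expect_gte(r, 0)
    expect_lte(r, 1)
    expect_equal(r, oracle_overlap(bs, be, rs, re))
    expect_equal(r == 1, bs >= rs && be <= re)
    d <- sample(-50:50, 1)
    expect_equal(overlap_rate(bs + d, be + d, rs + d, re + d), r)
  }
})

test_that("junctions classify into the six categories on a plus-strand model", {
  fx <- three_exon_fixture("+")
  # neighboring exon-exon: blocks at end of EXON1 and start of EXON2
  ev <- classify_junction(obs_row("chrT", c(150, 200), c(300, 350)), fx$txdb)
  expect_equal(ev$category, "E_E_NM")
  expect_equal(ev$left_region, "EXON1")
  expect_equal(ev$right_region, "EXON2")
  # exon skipping: EXON1 joined to EXON3
  ev <- classify_junction(obs_row("chrT", c(150, 200), c(500, 550)), fx$txdb)
  expect_equal(ev$category, "E_E_AS")
  # single block inside INTRON2 at rate 1.0
  ev <- classify_junction(obs_row("chrT", c(410, 480)), fx$txdb)
  expect_equal(ev$category, "INTRON_AS")
  expect_equal(ev$left_region, "INTRON2")
  # single block matching an exon
  ev <- classify_junction(obs_row("chrT", c(100, 200)), fx$txdb)
  expect_equal(ev$category, "EXON_NM")
  # exon-intron (right intron retention)
  ev <- classify_junction(obs_row("chrT", c(150, 200), c(210, 260)), fx$txdb)
  expect_equal(ev$category, "E_I_AS")
  # intron-exon (left intron retention)
  ev <- classify_junction(obs_row("chrT", c(230, 290), c(300, 350)), fx$txdb)
  expect_equal(ev$category, "I_E_AS")
})

test_that("blocks below the 90% overlap threshold are unannotated", {
  fx <- three_exon_fixture("+")
  # block [190,290): 10/100 in EXON1, 90/100 in INTRON1 -> best 0.90 passes
  ev <- classify_junction(obs_row("chrT", c(190, 290), c(300, 350)), fx$txdb)
  expect_equal(ev$category, "I_E_AS")
  # block [185,285): best rate 85% -> removed
  ev <- classify_junction(obs_row("chrT", c(185, 285), c(300, 350)), fx$txdb)
  expect_equal(nrow(ev), 0L)
  # a stricter threshold removes the 0.90 case too
  ev <- classify_junction(obs_row("chrT", c(190, 290), c(300, 350)), fx$txdb,
                          min_overlap = 0.95)
  expect_equal(nrow(ev), 0L)
})

test_that("minus-strand junctions report regions in transcription order", {
  fx <- three_exon_fixture("-")
  # on '-', exon 1 is [500,600); the junction to exon 2 [300,400) has the
  # genomically-left block in exon 2 and the right block in exon 1
  ev <- classify_junction(obs_row("chrT", c(350, 400), c(500, 550)), fx$txdb)
  expect_equal(ev$category, "E_E_NM")
  expect_equal(ev$left_region, "EXON1")
  expect_equal(ev$right_region, "EXON2")
})

test_that("category depends on the index difference of the exon pair", {
  # same genomic junction, two transcripts: one with an intervening exon
  set.seed(9)
  genome_path <- write_fixture_genome(list(chrT = rand_dna(1000)))
  gtf <- write_fixture_gtf(data.frame(
    chrom = "chrT",
    start = c(101L, 501L, 101L, 301L, 501L),
    end = c(200L, 600L, 200L, 400L, 600L),
    strand = "+", gene_id = "G1",
    transcript_id = c("SHORT", "SHORT", "LONG", "LONG", "LONG")))
  txdb <- read_annotation(gtf)
  ev <- classify_junction(obs_row("chrT", c(150, 200), c(500, 550)), txdb)
  ev <- ev[order(ev$transcript_id), ]
  expect_equal(ev$category[ev$transcript_id == "SHORT"], "E_E_NM")
  expect_equal(ev$category[ev$transcript_id == "LONG"], "E_E_AS")
})

test_that("classification agrees with the brute-force oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:15) {
    n_ex <- sample(2:4, 1)
    exl <- sample(30:80, n_ex, replace = TRUE)
    inl <- sample(30:80, n_ex - 1, replace = TRUE)
    starts <- 50 + c(0L, cumsum(exl[-n_ex] + inl))
    strand <- sample(c("+", "-"), 1)
    gtf <- write_fixture_gtf(data.frame(
      chrom = "chrR", start = starts + 1L, end = starts + exl,
      strand = strand, gene_id = "G", transcript_id = "T"))
    txdb <- read_annotation(gtf)
    span <- max(starts + exl)
    for (j in 1:20) {
      b1s <- sample(0:span, 1); b1e <- b1s + sample(5:60, 1)
      if (runif(1) < 0.3) {
        obs <- obs_row("chrR", c(b1s, b1e))
      } else {
        b2s <- b1e + sample(0:100, 1)
        obs <- obs_row("chrR", c(b1s, b1e), c(b2s, b2s + sample(5:60, 1)))
      }
      got <- sort(classify_junction(obs, txdb)$event_id)
      expect_equal(got, oracle_classify(obs, txdb))
    }
  }
})

test_that("merging pools counts per sample and is category-consistent", {
  fx <- three_exon_fixture("+")
  obs <- rbind(obs_row("chrT", c(150, 200), c(300, 350), "s1", 4L),
               obs_row("chrT", c(150, 200), c(300, 350), "s2", 5L),
               obs_row("chrT", c(150, 200), c(300, 350), "s3", 2L),
               obs_row("chrT", c(150, 200), c(500, 550), "s1", 8L))
  events <- annotate_observations(obs, fx$txdb)
  es <- merge_observations(events, samples = c("s1", "s2", "s3", "s4"))
  expect_equal(nrow(es$events), 2L)
  expect_equal(colnames(es$counts), c("s1", "s2", "s3", "s4"))
  nm <- es$counts["E_E_NM|TX1|EXON1|EXON2", ]
  expect_equal(unname(nm), c(4L, 5L, 2L, 0L))
  expect_true(all(es$counts[, "s4"] == 0L))

  bad <- events
  bad$category[1] <- "E_E_AS"  # same event_id, conflicting category
  expect_error(merge_observations(bad), "conflicting")
})

test_that("minimum-support filter applies at the stated boundary", {
  counts <- matrix(c(2L, 3L, 3L, 3L, 4L, 3L), nrow = 3,
                   dimnames = list(c("e5", "e6", "e7"), c("s1", "s2")))
  es <- make_event_set(counts)
  kept <- filter_min_support(es, min_reads = 6)
  expect_equal(rownames(kept$counts), c("e6", "e7"))
  expect_equal(nrow(filter_min_support(es, min_reads = 1)$events), 3L)
  # per-sample scope needs a single sample at the threshold
  kept_ps <- filter_min_support(es, min_reads = 4, scope = "per_sample")
  expect_equal(rownames(kept_ps$counts), "e6")
  empty <- filter_min_support(es, min_reads = 100)
  expect_equal(nrow(filter_min_support(empty, 6)$events), 0L)
})

test_that("category summary is exhaustive, exclusive, and sums to the total", {
  fx <- three_exon_fixture("+")
  obs <- rbind(obs_row("chrT", c(150, 200), c(300, 350)),
               obs_row("chrT", c(150, 200), c(500, 550)),
               obs_row("chrT", c(410, 480)),
               obs_row("chrT", c(100, 200)))
  events <- annotate_observations(obs, fx$txdb)
  es <- merge_observations(events)
  s <- category_summary(es)
  total <- s$count[s$category == "Total"]
  expect_equal(sum(s$count[s$category != "Total"]), total)
  expect_equal(total, nrow(es$events))
  # every retained event has exactly one category
  expect_equal(anyDuplicated(es$events$event_id), 0L)
})
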