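# Seeded simulator: toy genome + annotation, per-sample junction/region
# observations with planted differential splicing events, and OMSSA-style
# PSM tables with planted differential peptides. One integer seed governs
# everything; each stage uses a deterministic substream (seed + stage
# offset) so stages can be re-run independently.

#' Simulation configuration
#'
#' Defaults describe a two-group cohort of 20 + 20 samples with planted
#' differential splicing events included with probability 0.8 in the cancer
#' group versus 0.1 in the normal group, background junctions included at
#' 0.95 in both, negative-binomial junction read counts, and PSM emission
#' probabilities of 0.7 versus 0.05 for protein-differential peptides with
#' log-normal E-values well separated between true hits and decoys.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene,exon_len,intron_len Integer ranges `c(min, max)`.
#' @param intergenic Gap between genes in nt.
#' @param groups Two group labels.
#' @param n_per_group Samples per group, same order as `groups`.
#' @param n_planted Number of planted differential splicing events.
#' @param planted_categories Categories cycled over the planted events.
#' @param planted_protein_frac Fraction of planted events that are also
#'   differential at the protein (PSM) level.
#' @param incl_background Per-sample inclusion probability of background
#'   events (both groups).
#' @param incl_planted Inclusion probabilities of planted events, per group.
#' @param read_mu,read_size Negative-binomial read-count parameters (counts
#'   are drawn as `rnbinom(size, mu) + 1`).
#' @param emission_background,emission_planted Per-group PSM emission
#'   probabilities for background and protein-differential peptides.
#' @param decoy_rate Per-sample emission probability of each decoy peptide.
#' @param hit_log_e,decoy_log_e `c(mean, sd)` of log E-values for true hits
#'   and decoy hits.
#' @param anchor Junction block anchor length in nt.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 30,
                       exons_per_gene = c(3, 6),
                       exon_len = c(90, 300),
                       intron_len = c(80, 250),
                       intergenic = 200,
                       groups = c("normal", "cancer"),
                       n_per_group = c(20, 20),
                       n_planted = 8,
                       planted_categories = c("E_E_AS", "INTRON_AS"),
                       planted_protein_frac = 0.5,
                       incl_background = 0.95,
                       incl_planted = c(0.1, 0.8),
                       read_mu = 25, read_size = 8,
                       emission_background = c(0.4, 0.4),
                       emission_planted = c(0.05, 0.7),
                       decoy_rate = 0.2,
                       hit_log_e = c(mean = log(1e-4), sd = 1),
                       decoy_log_e = c(mean = log(0.5), sd = 0.8),
                       anchor = 50) {
  cfg <- as.list(environment())
  probs <- c(incl_background, incl_planted, emission_background,
             emission_planted, decoy_rate, planted_protein_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (exon_len[1] < 3 || intron_len[1] < 3) stop("region lengths must be >= 3")
  if (length(groups) != 2L) stop("exactly two groups required")
  structure(cfg, class = "sim_config")
}

#' @noRd
sim_design <- function(config) {
  data.frame(
    sample_id = unlist(lapply(1:2, function(g) {
      sprintf("%s_%02d", config$groups[g], seq_len(config$n_per_group[g]))
    })),
    group = rep(config$groups, config$n_per_group),
    stringsAsFactors = FALSE)
}

#' Simulate a toy reference genome and annotation
#'
#' Generates `n_genes` multi-exon genes on a single toy chromosome,
#' alternating strands, with uniform-random exon/intron lengths and a
#' uniform-random genome sequence. Exon phases are assigned consistently
#' along each transcript in transcription order (the whole transcript is
#' treated as coding): the first exon has phase 0 and each following phase
#' is the previous phase plus the exon length, modulo 3.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return List with paths `genome` (FASTA) and `gtf`.
#' @export
simulate_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  rint <- function(rng) sample(seq(rng[1], rng[2]), 1L)
  gtf <- character(0)
  pos <- config$intergenic
  for (g in seq_len(config$n_genes)) {
    n_ex <- rint(config$exons_per_gene)
    exl <- vapply(seq_len(n_ex), function(i) rint(config$exon_len), integer(1))
    inl <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(i) rint(config$intron_len), integer(1))
    } else integer(0)
    strand <- if (g %% 2L == 1L) "+" else "-"
    starts <- pos + c(0L, cumsum(exl[-n_ex] + inl))
    ends <- starts + exl
    # phases follow transcription order
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ph <- integer(n_ex)
    ph[ord[1]] <- 0L
    if (n_ex > 1) for (k in 2:n_ex) {
      prev <- ord[k - 1]
      ph[ord[k]] <- (ph[prev] + (ends[prev] - starts[prev])) %% 3L
    }
    gid <- sprintf("G%03d", g)
    tid <- sprintf("T%03d", g)
    gtf <- c(gtf, sprintf(
      'chrS\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "GENE%d"; exon_phase "%d";',
      starts + 1L, ends, strand, gid, tid, g, ph))
    pos <- ends[n_ex] + config$intergenic
  }
  genome_path <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "annotation.gtf")
  seq <- paste(sample(c("A", "C", "G", "T"), pos, replace = TRUE),
               collapse = "")
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- "chrS"
  Biostrings::writeXStringSet(dna, genome_path)
  writeLines(gtf, gtf_path)
  list(genome = genome_path, gtf = gtf_path)
}

# Genomic block intervals anchoring a junction between transcription-ordered
# regions U (upstream) and D (downstream); returns genomically-left block
# first, as in BED.
#' @noRd
junction_blocks <- function(up, down, strand, anchor) {
  au <- min(anchor, up$end - up$start)
  ad <- min(anchor, down$end - down$start)
  if (strand == "+") {
    b1 <- c(up$end - au, up$end)
    b2 <- c(down$start, down$start + ad)
  } else {
    b2 <- c(up$start, up$start + au)
    b1 <- c(down$end - ad, down$end)
  }
  list(left = b1, right = b2)
}

#' Simulate per-sample junction observations with planted events
#'
#' Emits, for every sample, a BED12 junction track and a single-block
#' region-coverage TSV. Background evidence consists of every transcript's
#' neighboring exon-exon junctions (E_E_NM) and first-exon coverage
#' (EXON_NM), included with the same probability in both groups. Planted
#' differential events — exon-skipping junctions joining exons 1 and 3, and
#' single-intron retention of intron 1, on distinct transcripts — are
#' included with group-specific probabilities. Supporting read counts are
#' negative-binomial.
#'
#' @param config A `sim_config`.
#' @param reference List of paths from [simulate_reference()].
#' @param dir Output directory.
#' @return List with `design` (path), `bed` and `regions` (named path
#'   vectors, one per sample), and `truth` (data frame of planted events:
#'   `event_id`, `category`, `transcript_id`, `protein_diff`).
#' @export
simulate_junction_observations <- function(config, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  txdb <- read_annotation(reference$gtf)
  txs <- txdb$transcripts
  design <- sim_design(config)
  design_path <- file.path(dir, "design.tsv")
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # choose planted events on distinct transcripts with enough exons
  elig <- names(txs)[vapply(txs, function(tx) nrow(tx$exons) >= 3L, logical(1))]
  if (length(elig) < config$n_planted) {
    stop("not enough multi-exon transcripts to plant ", config$n_planted,
         " events")
  }
  planted_tx <- sample(elig, config$n_planted)
  cats <- rep_len(config$planted_categories, config$n_planted)
  n_prot <- round(config$planted_protein_frac * config$n_planted)
  truth <- data.frame(
    event_id = character(config$n_planted), category = cats,
    transcript_id = planted_tx,
    protein_diff = seq_len(config$n_planted) <= n_prot,
    stringsAsFactors = FALSE)

  rc <- function() stats::rnbinom(1L, size = config$read_size,
                                  mu = config$read_mu) + 1L
  bed_paths <- character(0)
  region_paths <- character(0)
  sample_obs <- stats::setNames(
    rep(list(list(bed = character(0), reg = character(0))),
        nrow(design)), design$sample_id)

  emit_junction <- function(tx, up_index, down_index) {
    up <- tx$exons[tx$exons$index == up_index, ]
    down <- tx$exons[tx$exons$index == down_index, ]
    junction_blocks(up, down, tx$strand, config$anchor)
  }
  bed_line <- function(tx, blk, count, name) {
    sprintf("chrS\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
            blk$left[1], blk$right[2], name, count, tx$strand,
            blk$left[1], blk$right[2],
            blk$left[2] - blk$left[1], blk$right[2] - blk$right[1],
            blk$right[1] - blk$left[1])
  }

  for (si in seq_len(nrow(design))) {
    sid <- design$sample_id[si]
    gi <- match(design$group[si], config$groups)
    bed <- character(0)
    reg <- character(0)
    jn <- 0L
    for (tid in names(txs)) {
      tx <- txs[[tid]]
      n_ex <- nrow(tx$exons)
      pi_tx <- match(tid, truth$transcript_id)
      planted_cat <- if (is.na(pi_tx)) NA_character_ else truth$category[pi_tx]
      # background neighboring junctions
      if (n_ex > 1) for (k in seq_len(n_ex - 1)) {
        if (stats::runif(1) < config$incl_background) {
          jn <- jn + 1L
          bed <- c(bed, bed_line(tx, emit_junction(tx, k, k + 1L), rc(),
                                 sprintf("JUNC%05d", jn)))
        }
      }
      # background first-exon coverage
      if (stats::runif(1) < config$incl_background) {
        e1 <- tx$exons[tx$exons$index == 1L, ]
        reg <- c(reg, sprintf("chrS\t%d\t%d\t%d", e1$start, e1$end, rc()))
      }
      # planted differential event on this transcript
      if (!is.na(planted_cat) &&
          stats::runif(1) < config$incl_planted[gi]) {
        if (planted_cat == "E_E_AS") {
          jn <- jn + 1L
          bed <- c(bed, bed_line(tx, emit_junction(tx, 1L, 3L), rc(),
                                 sprintf("JUNC%05d", jn)))
        } else if (planted_cat == "INTRON_AS") {
          i1 <- tx$introns[tx$introns$index == 1L, ]
          reg <- c(reg, sprintf("chrS\t%d\t%d\t%d", i1$start, i1$end, rc()))
        } else {
          stop("unsupported planted category: ", planted_cat)
        }
      }
    }
    sample_obs[[sid]] <- list(bed = bed, reg = reg)
  }

  truth$event_id <- ifelse(
    truth$category == "E_E_AS",
    make_event_id("E_E_AS", truth$transcript_id, "EXON1", "EXON3"),
    make_event_id("INTRON_AS", truth$transcript_id, "INTRON1", NA_character_))

  for (sid in design$sample_id) {
    bp <- file.path(dir, paste0(sid, ".bed"))
    rp <- file.path(dir, paste0(sid, ".regions.tsv"))
    writeLines(sample_obs[[sid]]$bed, bp)
    writeLines(c("chrom\tstart\tend\tread_count", sample_obs[[sid]]$reg), rp)
    bed_paths[sid] <- bp
    region_paths[sid] <- rp
  }
  list(design = design_path, bed = bed_paths, regions = region_paths,
       truth = truth)
}

#' Simulate per-sample PSM tables against a peptide database
#'
#' For every sample, each target peptide emits a PSM with its group's
#' emission probability (the planted protein-differential probability when
#' the peptide's event is in `planted`, the background probability
#' otherwise) and a log-normal E-value; each decoy peptide (the reversed
#' companion of a target) emits with probability `decoy_rate` and a
#' stochastically larger log-normal E-value. Tables are written in the
#' OMSSA CSV dialect.
#'
#' @param config A `sim_config`.
#' @param records Target peptide records from [build_peptide_db()].
#' @param design Sample design data frame.
#' @param planted Character vector of protein-differential event IDs.
#' @param dir Output directory.
#' @return Named vector of per-sample CSV paths.
#' @export
simulate_psm_table <- function(config, records, design, planted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 3L)
  decoys <- suppressMessages(build_decoy(records))
  paths <- character(0)
  for (si in seq_len(nrow(design))) {
    sid <- design$sample_id[si]
    gi <- match(design$group[si], config$groups)
    rows <- list()
    spec <- 0L
    for (i in seq_len(nrow(records))) {
      p_em <- if (records$event_id[i] %in% planted) {
        config$emission_planted[gi]
      } else {
        config$emission_background[gi]
      }
      if (stats::runif(1) < p_em) {
        spec <- spec + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum = spec, file = sid, peptide = records$peptide[i],
          evalue = exp(stats::rnorm(1, config$hit_log_e[["mean"]],
                                    config$hit_log_e[["sd"]])),
          defline = records$header[i], stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(decoys))) {
      if (stats::runif(1) < config$decoy_rate) {
        spec <- spec + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum = spec, file = sid, peptide = decoys$peptide[i],
          evalue = exp(stats::rnorm(1, config$decoy_log_e[["mean"]],
                                    config$decoy_log_e[["sd"]])),
          defline = decoys$header[i], stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(spectrum = integer(0), file = character(0),
                 peptide = character(0), evalue = numeric(0),
                 defline = character(0), stringsAsFactors = FALSE)
    }
    names(df) <- c("Spectrum number", "Filename/id", "Peptide", "E-value",
                   "Defline")
    path <- file.path(dir, paste0(sid, ".psm.csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths[sid] <- path
  }
  paths
}
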