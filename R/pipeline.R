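# End-to-end pipeline: annotate -> test -> builddb -> msfilter, with a run
# manifest recording every tunable, input checksums, and the per-stage
# record ledger.

#' Default pipeline parameters
#'
#' Every tunable of the workflow with its default: the 90% minimum block
#' overlap, the 6-read pooled support filter, presence-based chi-square
#' without continuity correction, the q < 0.05 screen, 120-nt flanks with a
#' 6-residue peptide floor, and the 1% FDR + 0.1 E-value PSM filter with the
#' 2-hit rule.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(min_overlap = 0.90, min_reads = 6, support_scope = "pooled",
       phase_attr = "exon_phase", test_mode = "presence", presence_min = 1,
       yates = FALSE, q_max = 0.05, flank = 120, min_peptide_len = 6,
       fdr_max = 0.01, evalue_max = 0.1, fdr_scope = "pooled", min_hits = 2)
}

#' Run the full alternative-splicing biomarker pipeline
#'
#' Executes every stage in order on the inputs named in `config`: parse the
#' per-sample junction BED12 and region TSV files, annotate them against
#' the transcript model, merge and support-filter the events, test for
#' differential representation and select RNA biomarkers, build the target
#' and decoy peptide databases, and — when PSM tables are provided — filter
#' PSMs and report peptide biomarkers. All stage outputs are written under
#' `out_dir` together with a YAML run manifest whose stage counts are
#' non-increasing along each filter chain.
#'
#' @param config A list (or path to a YAML file) with elements `genome`,
#'   `gtf`, `design`, `bed` (named per-sample BED12 paths), optional
#'   `regions` (named per-sample TSV paths), optional `psms` (named
#'   per-sample PSM CSV paths), and optional `params` overriding
#'   [default_params()].
#' @param out_dir Output directory, created if needed.
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  inputs <- c(config$genome, config$gtf, config$design,
              unlist(config$bed), unlist(config$regions),
              unlist(config$psms))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_genome(config$genome)
  txdb <- read_annotation(config$gtf, phase_attr = params$phase_attr)
  design <- read_design(config$design)

  obs <- list()
  for (sid in names(config$bed)) {
    obs[[length(obs) + 1L]] <- parse_junction_bed(config$bed[[sid]], sid)
  }
  for (sid in names(config$regions)) {
    obs[[length(obs) + 1L]] <- parse_region_tsv(config$regions[[sid]], sid)
  }
  obs <- do.call(rbind, obs)

  events <- annotate_observations(obs, txdb, params$min_overlap)
  annotated_n <- attr(events, "n_annotated_obs")

  es <- merge_observations(events, samples = design$sample_id)
  es_f <- filter_min_support(es, params$min_reads,
                             scope = sub("-", "_", params$support_scope))
  results <- test_events(es_f, design, mode = params$test_mode,
                         presence_min = params$presence_min,
                         correct = params$yates)
  biomarkers <- select_biomarkers(results, params$q_max)

  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  events_out <- cbind(results, as.data.frame(es_f$counts))
  write_tsv(events_out, "events.tsv")
  write_tsv(biomarkers, "biomarkers.tsv")
  write_tsv(category_summary(biomarkers), "category_summary.tsv")

  records <- withCallingHandlers(
    build_peptide_db(biomarkers, txdb, genome, flank = params$flank,
                     min_peptide_len = params$min_peptide_len),
    message = function(m) invokeRestart("muffleMessage"))
  if (nrow(records)) {
    write_target_fasta(records, file.path(out_dir, "as_peptides.fasta"))
    decoys <- suppressMessages(build_decoy(records))
    write_target_fasta(decoys, file.path(out_dir, "as_peptides_decoy.fasta"))
  }

  counts <- list(
    junctions_parsed = nrow(obs),
    junctions_annotated = annotated_n,
    events_merged = nrow(es$events),
    events_min_support = nrow(es_f$events),
    rna_biomarkers = nrow(biomarkers),
    peptide_records = nrow(records))

  if (!is.null(config$psms)) {
    psms <- do.call(rbind, lapply(names(config$psms), function(sid) {
      read_psm_table(config$psms[[sid]], sid)
    }))
    accepted <- filter_psms(psms, fdr_max = params$fdr_max,
                            evalue_max = params$evalue_max,
                            per_sample = identical(params$fdr_scope,
                                                   "per_sample"))
    hits <- peptide_sample_hits(accepted, design)
    pb <- identify_peptide_biomarkers(hits, design, q_max = params$q_max,
                                      min_hits = params$min_hits,
                                      correct = params$yates)
    if (nrow(pb)) {
      idx <- match(pb$peptide, records$peptide)
      pb$junction_peptide <- vapply(idx, function(i) {
        if (is.na(i)) NA_character_
        else junction_notation(records[i, , drop = FALSE])
      }, character(1))
    }
    write_tsv(pb, "peptide_biomarkers.tsv")
    counts$psms_total <- nrow(psms)
    counts$psms_accepted <- nrow(accepted)
    counts$peptides_tested <- nrow(hits)
    counts$peptide_biomarkers <- nrow(pb)
  }

  manifest <- list(
    tool = "splicemark",
    version = as.character(utils::packageVersion("splicemark")),
    params = params,
    inputs = as.list(tools::md5sum(inputs)),
    counts = counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
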