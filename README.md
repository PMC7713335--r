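# splicemark

Proteogenomic discovery of alternative-splicing (AS) biomarkers. Given
RNA-Seq splice-junction evidence from two groups of samples (e.g. tumour
vs normal), a reference genome, and an Ensembl-style transcript
annotation, splicemark

1. **annotates** each junction against the transcript model and classifies
   it into one of six AS categories,
2. **selects** events differentially represented between the groups,
3. **synthesizes** a customized junction-peptide FASTA database (plus a
   reversed decoy database) for mass-spectrometry searching, and
4. **filters** the search engine's peptide-spectrum matches (PSMs) down to
   a final peptide biomarker list, each peptide traceable to its splicing
   event.

It is aimed at proteogenomics analysts who want splice-variant peptides —
which are absent from standard protein databases — to be discoverable in
their MS/MS data.

## The model in brief

Each junction block $A$ is assigned to the exon or intron region of a
transcript by maximising the asymmetric overlap rate

$$\mathrm{Overlap\_rate}(A,B) = \frac{|A\cap B|}{|A|}, \qquad
C^\* = \arg\max_C \mathrm{Overlap\_rate}(\mathrm{Region}_C, A)
\ \big|\ \mathrm{Overlap\_rate} \ge 0.90 .$$

Assigned region types give the category: single exon (`EXON_NM`), single
intron (`INTRON_AS`), neighbouring exon–exon (`E_E_NM`), exon skipping
(`E_E_AS`), and left/right intron retention (`I_E_AS`/`E_I_AS`). Events
with ≥ 6 supporting reads are tested for group differences with a Pearson
chi-square on sample-level presence tables; Storey–Tibshirani q-values
control the FDR and events with q < 0.05 become biomarkers. Around each
selected junction, 120 nt on either side are joined into a 240-nt
synthesized transcript (120 nt for single-region events), translated in
the phase-inferred frame when Ensembl exon phases are available or in all
three frames keeping the longest stop-free peptide otherwise. PSMs are
accepted at 1% target-decoy FDR with a 0.1 E-value cap, and peptides with
q < 0.05 and at least two hit samples in one group are reported.

## Worked example

A seeded simulator generates a full toy study — genome, annotation,
per-sample junction BED12 / region coverage, and OMSSA-style PSM tables
with planted differential events — so the whole pipeline runs without any
external data:

```r
library(splicemark)

cfg <- sim_config(seed = 7)              # 20 normal + 20 cancer samples
dir <- tempfile()
ref <- simulate_reference(cfg, dir)      # toy genome + GTF
sim <- simulate_junction_observations(cfg, ref, dir)

design <- read_design(sim$design)
genome <- read_genome(ref$genome)
txdb   <- read_annotation(ref$gtf)

obs <- do.call(rbind, lapply(design$sample_id, function(s) {
  rbind(parse_junction_bed(sim$bed[[s]], s),
        parse_region_tsv(sim$regions[[s]], s))
}))
events <- annotate_observations(obs, txdb)
es <- filter_min_support(merge_observations(events, design$sample_id))
es
#> <as_event_set> 143 event(s) x 40 sample(s)
#>    E_E_AS    E_E_NM   EXON_NM INTRON_AS
#>         4       105        30         4
```

143 distinct events survive the 6-read filter: mostly normal splicing
junctions (`E_E_NM`) and exon coverage (`EXON_NM`), plus the planted
exon-skipping and intron-retention events. Testing and selection:

```r
bm <- select_biomarkers(test_events(es, design))
head(bm[, c("event_id", "category", "chi2", "q")], 3)
#>                   event_id  category     chi2            q
#> 1 INTRON_AS|T019|INTRON1|. INTRON_AS 29.56522 7.731510e-06
#> 2  E_E_AS|T003|EXON1|EXON3    E_E_AS 25.85859 1.313337e-05
#> 3  E_E_AS|T024|EXON1|EXON3    E_E_AS 25.85859 1.313337e-05
```

The q-values say these events' presence split between groups would be
vanishingly unlikely under equal representation. The peptide stage builds
the database, simulates a search, and applies the FDR/E-value and 2-hit
rules:

```r
recs <- build_peptide_db(bm, txdb, genome)
psm_paths <- simulate_psm_table(cfg, recs, design,
  planted = sim$truth$event_id[sim$truth$protein_diff], dir)
psms <- do.call(rbind, lapply(design$sample_id, function(s) {
  read_psm_table(psm_paths[[s]], s)
}))
accepted <- filter_psms(psms)            # 1% FDR + 0.1 E-value
pb <- identify_peptide_biomarkers(peptide_sample_hits(accepted, design), design)
pb[, c("peptide", "event_id", "hits_normal", "hits_cancer", "q")]
#>                                             peptide                 event_id hits_normal hits_cancer            q
#> 1             EFSMPFAHLFSWPVPMPPGSVLAVRGMTSLRYPYASL INTRON_AS|T021|INTRON1|.           0          13 4.564623e-05
#> 2                LNRSCVRRMKAGGELLSATTCLRRKSFRTRVYVR INTRON_AS|T030|INTRON1|.           0          13 4.564623e-05
#> 3 STSKGLHNRESRGWRYHIPFVRLVHPQGRNSCIPGLANERPCGMQPTSL  E_E_AS|T006|EXON1|EXON3           2          15 8.561054e-05
#> 4                             RNDGSSASWLSCGRGACARWP  E_E_AS|T027|EXON1|EXON3           1          12 4.090227e-04
```

Exactly the four planted protein-differential events come back as peptide
biomarkers: each peptide was seen in 12–15 cancer samples but at most 2
normal samples. `run_all()` (or the `inst/scripts/splicemark` command-line
wrapper) chains the same stages from a YAML config and writes every output
plus a manifest ledger of record counts and parameters.

See `vignettes/splicemark-methods.Rmd` for the model, parameter defaults,
and design decisions.

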