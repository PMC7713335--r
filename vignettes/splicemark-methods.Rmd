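---
title: "Methods: proteogenomic discovery of alternative splicing biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic discovery of alternative splicing biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The workflow

splicemark implements a three-step proteogenomic workflow for finding
alternative-splicing (AS) biomarkers that are detectable in a proteome:

1. **Junction annotation and differential testing.** Splice-junction
   observations from RNA-Seq (BED12 records with two blocks per junction,
   plus single-block exon/intron coverage) are annotated against an
   Ensembl-style transcript model and tested for unequal representation
   between two sample groups.
2. **Customized peptide database.** Selected events are converted into
   short synthesized transcripts around the splice boundary, translated,
   and written as a target FASTA with a reversed-sequence decoy companion.
3. **PSM filtering.** Peptide-spectrum matches from an external search
   engine (OMSSA-style CSV) are filtered by target-decoy FDR and E-value,
   and peptides passing a final significance-plus-minimum-hit rule are
   reported as biomarkers, each traceable to its splicing event.

# Junction annotation

Every junction block A is compared to every exon and intron region B of a
candidate transcript by the asymmetric overlap rate

$$\mathrm{Overlap\_rate}(A, B) = \frac{|A \cap B|}{|A|},$$

and assigned to the region maximising it, subject to a minimum rate of
0.90 (`min_overlap`). Events are classified from the assigned region types
and indices, expressed in transcription order so labels are biologically
meaningful on both strands:

| category   | evidence                                    |
|------------|---------------------------------------------|
| `EXON_NM`  | single block covering an exon                |
| `INTRON_AS`| single block covering an intron              |
| `E_E_NM`   | junction joining neighbouring exons          |
| `E_E_AS`   | junction joining non-neighbouring exons (exon skipping) |
| `I_E_AS`   | intron-then-exon junction (left intron retention)  |
| `E_I_AS`   | exon-then-intron junction (right intron retention) |

Numerical and policy choices, all printed in the run manifest:

* **Per-block thresholding.** Both blocks of a junction must individually
  reach the 0.90 rate on the *same* transcript; a joint criterion is not
  used because the per-block argmax is what defines the assigned regions.
* **Tie-breaking.** When two regions tie on overlap rate, the exon is
  preferred over the intron, then the lower region index. This only
  triggers for blocks spanning a region boundary symmetrically and makes
  the assignment deterministic.
* **Intron–intron block pairs** fall outside the six categories and are
  treated as unannotated.
* **Multi-transcript junctions** yield one event per transcript, since
  biomarkers are reported at transcript resolution.
* **Support filter.** Events need at least 6 supporting reads
  (`min_reads`), applied by default to the count pooled across samples;
  `scope = "per_sample"` instead requires one sample alone to reach the
  threshold. Pooling is the default because junction discovery tools apply
  their own per-sample floor upstream.
* Event keys are `category|transcript|left_label|right_label`, so merging
  observations across samples is exact string equality.

# Differential representation

"Differential representation" is tested on sample-level presence: for each
event, samples with at least `presence_min` (default 1) supporting reads
count as present, giving a 2×2 group-by-presence table tested with
Pearson's chi-square (df = 1, no continuity correction by default; Yates
available via `correct = TRUE`). Presence semantics is the default because
it is the only interpretation that transfers unchanged to the proteome
stage, where a sample either yields a peptide hit or does not. A
read-count mode (`mode = "counts"`: the event's group read totals against
the group's reads for all other events) is provided for depth-sensitive
designs. Degenerate tables with a zero margin carry no information and
return statistic 0, p = 1.

Multiple testing uses the Storey–Tibshirani q-value: the null proportion
pi0 is estimated on the lambda grid 0, 0.05, ..., 0.90 with a natural
cubic smoothing spline (df = 3) evaluated at the largest lambda and
clipped to (0, 1]; with fewer than 100 p-values the spline is unstable on
the heavily discrete p-distributions produced by small 2×2 tables, so pi0
falls back to 1, making the q-values exactly Benjamini–Hochberg (a
property the tests assert against `p.adjust`). Biomarkers are events with
q strictly below 0.05.

# Peptide database construction

For a junction-category event, the last 120 nt of the transcriptionally
upstream region are joined to the first 120 nt of the downstream region,
giving a 240-nt synthesized transcript; single-region events take the
first 120 nt of the region. The 120-nt flank matches the length
distribution of tryptic fragments observable in MS/MS. Two deliberate
interpretations:

* Flanks are **region-limited**: a region shorter than the flank
  contributes its full length (flagged `left_truncated`/`right_truncated`)
  rather than extending into neighbouring exons.
* For single-region events the sequence is the **first 120 nt of the
  region itself** — the alternative (120 nt preceding the region) would
  contradict the event's own label.

When the upstream region is an exon with a known Ensembl phase, the
reading frame of the synthesized sequence is inferred: the codon position
of its first base is `(phase + offset) mod 3`, where offset is that base's
position within the exon, and translation skips `(3 - position) mod 3`
bases. Otherwise (unknown phase, or an intron on the upstream side) all
three frames are translated and the single longest stop-free peptide is
kept, ties broken by lowest frame then earliest start. Peptides shorter
than 6 residues (`min_peptide_len`, a tryptic-detectability floor) are
dropped with a reported count.

Decoys reverse each target peptide's full sequence under a `DECOY_` header
prefix — the standard inverse-sequence construction, which preserves the
size and length distribution of the target database exactly.

# PSM filtering

The FDR estimator is the decoy/target count ratio over the E-value-sorted
prefix (#decoy/#target rather than 2D/(T+D); the choice is configurable
and recorded in the manifest). The accepted E-value cutoff is the largest
observed E-value whose prefix FDR is at most 1%, with ties at the cutoff
included; a hard 0.1 E-value cap applies regardless. The cutoff is
computed on the pooled PSM list by default (`per_sample = TRUE` computes
it within samples). Final peptide biomarkers must reach q < 0.05 over all
peptides with at least one accepted PSM and have at least 2 hit samples
in one group — a hit being a sample with any accepted PSM for the peptide.

# The simulator

`sim_config()` defines the study conditions used throughout validation:
two groups of 20 samples; planted differential events (exon-skipping
junctions joining exons 1 and 3, and retained first introns, on distinct
transcripts) included per sample with probability 0.8 in the cancer group
versus 0.1 in the normal group; background neighbouring junctions and
first-exon coverage at 0.95 in both groups; supporting reads drawn as
negative binomial (mu 25, size 8) plus one. At the proteome stage,
protein-differential peptides emit PSMs with probability 0.7 versus 0.05,
background peptides at 0.4 in both groups, and each decoy at 0.2, with
log-normal E-values (true hits: meanlog log(1e-4), sdlog 1; decoys:
meanlog log(0.5), sdlog 0.8) so decoy scores are stochastically much
larger. Half of the planted events are differential only at the RNA level,
so the peptide stage has genuinely null members to reject. A single
integer seed drives everything; each stage draws from a deterministic
substream (seed + stage offset) so stages re-run independently.

The simulator emulates cohort structure, group-dependent inclusion, read
support, and score separation. It does **not** emulate read-level
alignment artifacts (soft-clipping, multi-mapping), overlapping gene
models, sequencing-depth variation between samples, isoform abundance
(PSI) shifts, or spectra. Passing closed-loop tests therefore demonstrate
correctness of the annotation/statistics/database/filter chain under clean
evidence, not robustness to aligner noise.

Validation problem sizes: unit and property suites use toy chromosomes of
about 1 kb with 2–5-exon transcripts; oracle-equivalence suites run 1,000
random junction classifications and 1,000 random translations against
brute-force re-implementations; the closed-loop suite runs 20 seeded
end-to-end replicates with 12 genes and 20 + 20 samples each, chosen to
exercise every category and stage while keeping a full run in a couple of
minutes on one core.

# Known limitations

* Junctions are matched to whole exon/intron regions; novel splice sites
  interior to a region are only annotated if a block still reaches 90%
  overlap with the containing region.
* Transcript models are held in memory; cohort-scale junction sets (10^5+)
  are fine, but genome-scale annotation (10^5 transcripts) has not been
  profiled.
* The chi-square approximation is poor for very small groups; with fewer
  than ~5 expected counts per cell an exact test would be preferable, but
  is not what this workflow specifies.
* No in-silico digestion is performed; the search engine is assumed to
  handle enzymatic specificity.
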