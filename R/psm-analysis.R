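# PSM filtering: OMSSA-style table parsing, target-decoy FDR E-value cutoff,
# the 1% FDR + 0.1 E-value filter, per-sample peptide hits, and the final
# q < 0.05 plus >= 2-hit peptide biomarker rule.

.omssa_columns <- c(spectrum_id = "Spectrum number",
                    peptide = "Peptide",
                    evalue = "E-value",
                    accession = "Defline")

#' Read a PSM table from a search engine
#'
#' Reads a delimited peptide-spectrum-match table. The OMSSA CSV column
#' names are supported natively (`dialect = "omssa"`); any other layout can
#' be mapped by passing a named character vector
#' `c(spectrum_id = ..., peptide = ..., evalue = ..., accession = ...)`.
#' Decoy status is derived from the `DECOY_` accession prefix.
#'
#' @param path Path to the delimited file.
#' @param sample_id Sample label attached to every record.
#' @param dialect `"omssa"` or a named column mapping.
#' @param sep Field separator (default `","`).
#' @return Data frame with columns `sample_id`, `spectrum_id`, `peptide`,
#'   `evalue`, `accession`, `is_decoy`.
#' @export
read_psm_table <- function(path, sample_id, dialect = "omssa", sep = ",") {
  map <- if (identical(dialect, "omssa")) .omssa_columns else dialect
  need <- c("spectrum_id", "peptide", "evalue", "accession")
  if (!all(need %in% names(map))) {
    stop("dialect mapping must name: ",
         paste(setdiff(need, names(map)), collapse = ", "))
  }
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  miss <- setdiff(unname(map[need]), names(df))
  if (length(miss)) {
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "))
  }
  ev <- as.numeric(df[[map[["evalue"]]]])
  if (any(is.na(ev)) || any(ev <= 0)) {
    stop("E-values must be positive numbers in ", path)
  }
  acc <- as.character(df[[map[["accession"]]]])
  data.frame(sample_id = rep(sample_id, nrow(df)),
             spectrum_id = as.character(df[[map[["spectrum_id"]]]]),
             peptide = as.character(df[[map[["peptide"]]]]),
             evalue = ev, accession = acc,
             is_decoy = startsWith(acc, "DECOY_"),
             stringsAsFactors = FALSE)
}

#' Target-decoy FDR E-value cutoff
#'
#' PSMs are sorted by ascending E-value; at each prefix the FDR is estimated
#' as the decoy/target count ratio. The cutoff is the largest observed
#' E-value whose prefix FDR is at most `fdr_max` (PSMs tied at the cutoff
#' are all inside the prefix). Returns `Inf` when the full list passes and
#' `-Inf` when no prefix does.
#'
#' @param psms PSM data frame with `evalue` and `is_decoy`.
#' @param fdr_max Maximum acceptable FDR (default 0.01).
#' @return The E-value cutoff.
#' @export
compute_fdr_threshold <- function(psms, fdr_max = 0.01) {
  if (!any(!psms$is_decoy)) stop("no target PSMs")
  o <- order(psms$evalue)
  e <- psms$evalue[o]
  d <- cumsum(psms$is_decoy[o])
  t <- cumsum(!psms$is_decoy[o])
  fdr <- ifelse(t == 0, Inf, d / t)
  last <- !duplicated(e, fromLast = TRUE)  # prefix boundary per unique E-value
  ue <- e[last]
  pass <- fdr[last] <= fdr_max
  if (!any(pass)) return(-Inf)
  if (pass[length(pass)]) return(Inf)
  max(ue[pass])
}

#' Filter PSMs by target-decoy FDR and E-value cap
#'
#' Retains target PSMs with E-value at most the minimum of the
#' [compute_fdr_threshold()] cutoff and the hard `evalue_max` cap (the
#' paper-style 1% FDR + 0.1 E-value criterion). Decoy PSMs are removed from
#' the output. With `per_sample = TRUE` the FDR cutoff is computed within
#' each sample instead of over the pooled list.
#'
#' @param psms PSM data frame.
#' @param fdr_max Maximum FDR (default 0.01).
#' @param evalue_max Hard E-value cap (default 0.1).
#' @param per_sample Compute the FDR cutoff per sample (default `FALSE`).
#' @return The accepted target PSMs.
#' @export
filter_psms <- function(psms, fdr_max = 0.01, evalue_max = 0.1,
                        per_sample = FALSE) {
  if (per_sample) {
    parts <- split(psms, psms$sample_id)
    out <- do.call(rbind, lapply(parts, filter_psms, fdr_max = fdr_max,
                                 evalue_max = evalue_max))
    rownames(out) <- NULL
    return(out)
  }
  cutoff <- compute_fdr_threshold(psms, fdr_max)
  thr <- min(cutoff, evalue_max)
  out <- psms[!psms$is_decoy & psms$evalue <= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group sample hit counts for each peptide
#'
#' A "hit" is a sample with at least one accepted PSM for the peptide
#' (multiple PSMs in one sample collapse to one hit).
#'
#' @param psms Accepted PSMs from [filter_psms()].
#' @param design Data frame from [read_design()].
#' @return Data frame with `peptide`, `accession` and one `hits_<group>`
#'   column per group; group names and sizes attached as attributes
#'   `groups` and `group_sizes`.
#' @export
peptide_sample_hits <- function(psms, design) {
  unknown <- setdiff(unique(psms$sample_id), design$sample_id)
  if (length(unknown)) {
    stop("sample_id not in design: ", paste(unknown, collapse = ", "))
  }
  groups <- design_groups(design)
  sizes <- vapply(groups, function(g) sum(design$group == g), integer(1))
  peps <- unique(psms$peptide)
  hits <- matrix(0L, length(peps), 2L, dimnames = list(peps, groups))
  ps <- unique(psms[, c("peptide", "sample_id")])
  ps$group <- design$group[match(ps$sample_id, design$sample_id)]
  if (nrow(ps)) {
    tab <- table(factor(ps$peptide, levels = peps),
                 factor(ps$group, levels = groups))
    hits[] <- as.integer(tab)
  }
  out <- data.frame(peptide = peps,
                    accession = psms$accession[match(peps, psms$peptide)],
                    stringsAsFactors = FALSE)
  out[[paste0("hits_", groups[1])]] <- hits[, 1]
  out[[paste0("hits_", groups[2])]] <- hits[, 2]
  attr(out, "groups") <- groups
  attr(out, "group_sizes") <- sizes
  out
}

# Header schema: AS|<event_id>|<category>|<gene_id>|<transcript_id>|frame=..|src=..
# where <event_id> is itself 4 pipe-separated tokens
# (category|transcript|left|right), so a full header has 10 tokens.
#' @noRd
parse_as_header <- function(accession) {
  parts <- strsplit(sub("^DECOY_", "", accession), "|", fixed = TRUE)
  field <- function(p, i) if (length(p) >= 10L) p[i] else NA_character_
  data.frame(
    event_id = vapply(parts, function(p) {
      if (length(p) >= 10L) paste(p[2:5], collapse = "|") else NA_character_
    }, character(1)),
    category = vapply(parts, field, character(1), i = 6L),
    gene_id = vapply(parts, field, character(1), i = 7L),
    transcript_id = vapply(parts, field, character(1), i = 8L),
    stringsAsFactors = FALSE)
}

#' Final peptide biomarker selection
#'
#' Each peptide's group-by-hit presence table is tested with [chi_square()];
#' Storey q-values are computed over all peptides with at least one accepted
#' PSM. Reported biomarkers must satisfy `q < q_max` (strict) and have at
#' least `min_hits` hit samples in one of the two groups. Event identity and
#' category are recovered from the accession header so every biomarker is
#' traceable to the splicing event behind it.
#'
#' @param hits Data frame from [peptide_sample_hits()].
#' @param design Data frame from [read_design()].
#' @param q_max Significance threshold (default 0.05).
#' @param min_hits Minimum sample hits in either group (default 2).
#' @param correct Yates continuity correction (default `FALSE`).
#' @return Data frame of peptide biomarkers sorted by q then peptide:
#'   `peptide`, `event_id`, `category`, `gene_id`, `transcript_id`,
#'   per-group hit counts, `chi2`, `p`, `q`.
#' @export
identify_peptide_biomarkers <- function(hits, design, q_max = 0.05,
                                        min_hits = 2, correct = FALSE) {
  groups <- design_groups(design)
  sizes <- vapply(groups, function(g) sum(design$group == g), integer(1))
  h1 <- hits[[paste0("hits_", groups[1])]]
  h2 <- hits[[paste0("hits_", groups[2])]]
  n <- nrow(hits)
  p <- numeric(n)
  chi2 <- numeric(n)
  for (i in seq_len(n)) {
    tab <- rbind(c(h1[i], sizes[1] - h1[i]),
                 c(h2[i], sizes[2] - h2[i]))
    ct <- chi_square(tab, correct = correct)
    chi2[i] <- ct$statistic
    p[i] <- ct$p.value
  }
  q <- storey_qvalues(p)
  meta <- parse_as_header(hits$accession)
  out <- cbind(data.frame(peptide = hits$peptide, stringsAsFactors = FALSE),
               meta, hits[, paste0("hits_", groups), drop = FALSE],
               data.frame(chi2 = chi2, p = p, q = q))
  keep <- out$q < q_max & pmax(h1, h2) >= min_hits
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$q, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}
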