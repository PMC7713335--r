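# Two-group differential representation of splicing events: per-event 2x2
# presence tables, Pearson chi-square, Storey-Tibshirani q-values, and the
# q < 0.05 biomarker screen.

#' Read a two-group sample design table
#'
#' @param path TSV with a header and columns `sample_id`, `group`.
#' @return Data frame with columns `sample_id`, `group`. Exactly two group
#'   labels with at least two samples each are required.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("design table needs columns sample_id and group")
  }
  df <- df[, c("sample_id", "group")]
  if (any(!nzchar(df$group))) stop("empty group label in design")
  validate_design(df)
  df
}

#' @noRd
validate_design <- function(design) {
  tab <- table(design$group)
  if (length(tab) != 2L) {
    stop("design must have exactly two groups, got: ",
         paste(names(tab), collapse = ", "))
  }
  if (any(tab < 2L)) stop("each group needs at least two samples")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  invisible(design)
}

#' @noRd
design_groups <- function(design) unique(design$group)

#' Group-by-presence contingency table for one event
#'
#' A sample counts as "present" for an event when its supporting-read count
#' reaches `presence_min`. The resulting 2x2 table (rows: groups, columns:
#' present/absent) is the input to the chi-square test of equal
#' representation between the two groups.
#'
#' @param counts Named integer vector of per-sample read counts for the
#'   event; must cover every sample in the design.
#' @param design Data frame from [read_design()].
#' @param presence_min Minimum read count for presence (default 1).
#' @return 2x2 integer matrix, rows named by group, columns
#'   `present`/`absent`.
#' @export
presence_table <- function(counts, design, presence_min = 1) {
  miss <- setdiff(design$sample_id, names(counts))
  if (length(miss)) {
    stop("design sample(s) missing from count matrix: ",
         paste(miss, collapse = ", "))
  }
  groups <- design_groups(design)
  tab <- matrix(0L, 2L, 2L, dimnames = list(groups, c("present", "absent")))
  for (g in groups) {
    ids <- design$sample_id[design$group == g]
    pres <- sum(counts[ids] >= presence_min)
    tab[g, ] <- c(pres, length(ids) - pres)
  }
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square with one degree of freedom, without Yates continuity
#' correction by default. Degenerate tables (any zero row or column margin)
#' carry no information about group differences and return statistic 0,
#' p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p.value`.
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative cell in contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p.value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ..., 0.90
#' with a natural cubic smoothing spline evaluated at the largest lambda,
#' clipped to (0, 1]; for fewer than 100 p-values the spline is unstable and
#' pi0 falls back to 1 (in which case the q-values coincide with
#' Benjamini-Hochberg adjusted p-values). q for the i-th ordered p-value is
#' `min_{j >= i} pi0 * m * p_(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 overriding the estimate.
#' @param lambda Grid for the pi0 estimate.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0, 0.90, by = 0.05)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(p)
  v <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(v))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Test every event for differential representation between two groups
#'
#' For each event a 2x2 table is formed — in `"presence"` mode the
#' group-by-presence table of [presence_table()]; in `"counts"` mode the
#' group's total supporting reads for the event against the group's reads
#' for all other events — and tested with [chi_square()]. q-values over all
#' tested events come from [storey_qvalues()].
#'
#' @param es An `as_event_set` from [merge_observations()].
#' @param design Data frame from [read_design()].
#' @param mode `"presence"` (default) or `"counts"`.
#' @param presence_min Presence threshold for `"presence"` mode.
#' @param correct Yates continuity correction (default `FALSE`).
#' @return Data frame: event metadata plus `chi2`, `p`, `q`.
#' @export
test_events <- function(es, design, mode = c("presence", "counts"),
                        presence_min = 1, correct = FALSE) {
  mode <- match.arg(mode)
  validate_design(design)
  res <- es$events
  n <- nrow(res)
  res$chi2 <- numeric(n)
  res$p <- numeric(n)
  if (n == 0L) {
    res$q <- numeric(0)
    return(res)
  }
  groups <- design_groups(design)
  if (mode == "counts") {
    grp_tot <- vapply(groups, function(g) {
      sum(es$counts[, design$sample_id[design$group == g], drop = FALSE])
    }, numeric(1))
  }
  for (i in seq_len(n)) {
    if (mode == "presence") {
      tab <- presence_table(es$counts[i, ], design, presence_min)
    } else {
      ev <- vapply(groups, function(g) {
        sum(es$counts[i, design$sample_id[design$group == g]])
      }, numeric(1))
      tab <- cbind(event = ev, other = grp_tot - ev)
    }
    ct <- chi_square(tab, correct = correct)
    res$chi2[i] <- ct$statistic
    res$p[i] <- ct$p.value
  }
  res$q <- storey_qvalues(res$p)
  res
}

#' Select significant biomarker events
#'
#' Retains events with q strictly below `q_max`, sorted by q then event ID
#' for a deterministic order under ties.
#'
#' @param results Data frame from [test_events()] (needs `q`, `event_id`).
#' @param q_max Significance threshold (default 0.05, strict inequality).
#' @return The filtered, sorted data frame.
#' @export
select_biomarkers <- function(results, q_max = 0.05) {
  out <- results[results$q < q_max, , drop = FALSE]
  out <- out[order(out$q, out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
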