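# Screen classification (Groups I/II/III), tallying, and the sterility
# contingency test.
#
# Classification rule: a transcript with smFISH foci in at least one P
# blastomere is foci-positive; foci-positive transcripts with the PGC
# maintenance pattern (one enriched cell at the ~40- and ~60-cell stages,
# two cells at the ~100-cell stage) are Group I, the rest Group II.
# Transcripts never enriched in foci are Group III regardless of the PGC
# pattern (a few Group III transcripts do show it).

#' Classify transcripts into Groups I/II/III
#'
#' @param screen a data frame with logical columns `foci_P1`..`foci_P4` and
#'   `pgc_pattern`.
#' @return a character vector of `"I"`, `"II"`, `"III"`, one per row.
#' @export
classify_transcript <- function(screen) {
  req <- c("foci_P1", "foci_P2", "foci_P3", "foci_P4", "pgc_pattern")
  miss <- setdiff(req, names(screen))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  flags <- as.matrix(screen[, c("foci_P1", "foci_P2", "foci_P3", "foci_P4")])
  if (any(is.na(flags)) || any(is.na(screen$pgc_pattern)))
    stop("all foci and pgc_pattern flags must be set")
  foci_pos <- rowSums(flags) > 0
  ifelse(foci_pos, ifelse(screen$pgc_pattern, "I", "II"), "III")
}

#' Tally a classified screen table
#'
#' @param screen a screen table; the `group` column is (re)derived from the
#'   flags via [classify_transcript()] so tallies always reflect the rule.
#' @return an object of class `screen_tally`: counts (`n_total`,
#'   `n_foci_positive`, `n_group1`, `n_group2`, `n_group3`), full-precision
#'   percentages (foci-positive of all, Group I and II of foci-positive,
#'   Group III of all), and the same percentages rounded half-up to
#'   integers for reporting.
#' @export
tally_screen <- function(screen) {
  if (!nrow(screen)) stop("empty screen table")
  grp <- classify_transcript(screen)
  n <- length(grp)
  n1 <- sum(grp == "I"); n2 <- sum(grp == "II"); n3 <- sum(grp == "III")
  npos <- n1 + n2
  pct <- c(foci_positive = 100 * npos / n,
           group1_of_foci_positive = if (npos) 100 * n1 / npos else NA_real_,
           group2_of_foci_positive = if (npos) 100 * n2 / npos else NA_real_,
           group3_of_all = 100 * n3 / n)
  structure(list(counts = c(n_total = n, n_foci_positive = npos,
                            n_group1 = n1, n_group2 = n2, n_group3 = n3),
                 percentages = pct,
                 report = round_half_up(pct)),
            class = "screen_tally")
}

#' @export
print.screen_tally <- function(x, ...) {
  ct <- x$counts; rp <- x$report
  cat(sprintf("screen tally: %d transcripts\n", ct["n_total"]))
  cat(sprintf("  foci-positive: %d/%d (%d%%)\n", ct["n_foci_positive"],
              ct["n_total"], rp["foci_positive"]))
  cat(sprintf("  Group I:  %d/%d of foci-positive (%d%%)\n", ct["n_group1"],
              ct["n_foci_positive"], rp["group1_of_foci_positive"]))
  cat(sprintf("  Group II: %d/%d of foci-positive (%d%%)\n", ct["n_group2"],
              ct["n_foci_positive"], rp["group2_of_foci_positive"]))
  cat(sprintf("  Group III: %d/%d of all (%d%%)\n", ct["n_group3"],
              ct["n_total"], rp["group3_of_all"]))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value computed from first principles: with all margins
#' fixed, the probability of each table in the hypergeometric support is
#' evaluated and those no more probable than the observed table (within a
#' 1e-7 relative slack) are summed.
#'
#' @param table a 2x2 matrix (or length-4 vector, filled by column) of
#'   non-negative counts, e.g. sterile/fertile by condition/control.
#' @return the two-sided p-value. Degenerate tables (an empty margin) give
#'   p = 1 by convention (logged).
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2L, 2L)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) {
    gf_log("degenerate 2x2 margin; p = 1 by convention")
    return(1)
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Unpaired two-sample t-test (thin utility)
#'
#' Classic equal-variance unpaired t-test used for sterility/enrichment
#' group comparisons; a thin wrapper over [stats::t.test()].
#'
#' @param x,y numeric vectors.
#' @return the `htest` object.
#' @export
group_t_test <- function(x, y) stats::t.test(x, y, var.equal = TRUE)
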