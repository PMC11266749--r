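# Single-molecule intensity calibration, molecule-count binning and cluster
# calling.
#
# The calibration rests on the biological observation that the large
# majority of smFISH foci in somatic blastomeres are single transcripts, so
# the median integrated intensity of somatic spots is the intensity of one
# molecule; the median is robust to a modest multi-molecule tail.

#' Calibrate the single-molecule intensity from somatic spots
#'
#' @param spots a spot table; if a `lineage` column is present, only rows
#'   whose lineage is in `somatic_lineages` are used.
#' @param min_spots minimum number of somatic spots required; fewer is an
#'   error (image more somatic fields of view).
#' @param somatic_lineages lineage labels treated as somatic.
#' @return an object of class `calibration_result`: `unit_intensity`
#'   (median), `dispersion` (MAD), `n_spots_used`, `source_cells`. A warning
#'   fires when MAD/median exceeds 0.5 (poorly calibrated distribution).
#' @export
calibrate_unit_intensity <- function(spots, min_spots = 50L,
                                     somatic_lineages = "somatic") {
  stopifnot(is.data.frame(spots), "intensity" %in% names(spots))
  if ("lineage" %in% names(spots)) {
    sel <- !is.na(spots$lineage) & spots$lineage %in% somatic_lineages
    spots <- spots[sel, , drop = FALSE]
  }
  n <- nrow(spots)
  if (n < min_spots)
    stop("only ", n, " somatic spots available (need >= ", min_spots,
         "); image more somatic fields of view")
  unit <- stats::median(spots$intensity)
  disp <- stats::mad(spots$intensity)
  if (!isTRUE(unit > 0)) stop("calibrated unit intensity is not positive")
  if (disp / unit > 0.5)
    warning(sprintf("somatic intensity MAD/median = %.2f > 0.5: calibration may be poor",
                    disp / unit))
  structure(list(unit_intensity = unit, dispersion = disp, n_spots_used = n,
                 source_cells = unique(stats::na.omit(spots$lineage))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("single-molecule intensity: %.4g (MAD %.3g, n = %d spots)\n",
              x$unit_intensity, x$dispersion, x$n_spots_used))
  invisible(x)
}

#' Assign molecule counts and call clusters
#'
#' `n_molecules = max(1, round_half_up(intensity / unit))`: nearest integer
#' with half-integer ratios rounding up (documented tie rule) and a floor of
#' one molecule. Spots with `n_molecules >= cluster_min_molecules` (default
#' 4, the protocol's cluster definition) are flagged as clusters.
#'
#' @param spots a spot table with an `intensity` column.
#' @param unit_intensity a scalar or a `calibration_result`.
#' @param cluster_min_molecules cluster-calling threshold.
#' @return the spot table with `n_molecules` and `is_cluster` columns.
#' @export
assign_molecule_counts <- function(spots, unit_intensity,
                                   cluster_min_molecules = 4L) {
  if (inherits(unit_intensity, "calibration_result"))
    unit_intensity <- unit_intensity$unit_intensity
  stopifnot(isTRUE(unit_intensity > 0), cluster_min_molecules >= 2)
  spots$n_molecules <- pmax(1L,
                            as.integer(round_half_up(spots$intensity / unit_intensity)))
  spots$is_cluster <- spots$n_molecules >= cluster_min_molecules
  spots
}

#' Per-cell molecule-count summary
#'
#' @param spots a spot table with assigned `n_molecules`/`is_cluster`
#'   (see [assign_molecule_counts()]).
#' @return a data frame with one row per lineage group (plus an `"all"`
#'   total row when groups exist): spot and molecule totals, the percentage
#'   of molecules in clusters (molecule-weighted), and the largest cluster.
#'   An empty table yields a zero-row frame.
#' @export
molecule_count_summary <- function(spots) {
  cols <- c("group", "n_spots", "n_molecules", "n_cluster_spots",
            "pct_molecules_in_clusters", "max_cluster_size")
  if (!nrow(spots))
    return(stats::setNames(data.frame(character(), integer(), integer(),
                                      integer(), numeric(), integer()), cols))
  stopifnot(all(c("n_molecules", "is_cluster") %in% names(spots)))
  grp <- if ("lineage" %in% names(spots))
    ifelse(is.na(spots$lineage), "unassigned", spots$lineage)
  else rep("all", nrow(spots))
  one <- function(sub, label) {
    data.frame(group = label, n_spots = nrow(sub),
               n_molecules = sum(sub$n_molecules),
               n_cluster_spots = sum(sub$is_cluster),
               pct_molecules_in_clusters =
                 100 * sum(sub$n_molecules[sub$is_cluster]) / sum(sub$n_molecules),
               max_cluster_size = max(sub$n_molecules),
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(grp)), function(g) one(spots[grp == g, ], g))
  out <- do.call(rbind, parts)
  if (length(unique(grp)) > 1L) out <- rbind(out, one(spots, "all"))
  rownames(out) <- NULL
  out
}
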