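# Spot/granule and cluster/cluster colocalization.
#
# Membership follows the published cube rule: a spot belongs to a granule
# when its (z, y, x) centre lies inside the granule's padded bounding cube
# (inclusive boundaries). Cluster-cluster colocalization uses per-axis
# tolerances (2 px in x/y, 2 slices in z by default) and one-to-one nearest
# matching.

#' Assign spots to granule membership cubes
#'
#' Inclusive boundary test on all three axes; a spot inside several
#' overlapping cubes is assigned to the granule with the nearest centroid
#' (ties to the lower `granule_id`).
#'
#' @param spots a spot table with `z`, `y`, `x`.
#' @param cubes membership cubes from [granule_bounding_cube()].
#' @return an integer vector of granule ids (`NA` where the spot is in no
#'   cube), one per spot row.
#' @export
spot_in_granule <- function(spots, cubes) {
  n <- nrow(spots)
  out <- rep(NA_integer_, n)
  if (!n || !nrow(cubes)) return(out)
  dz <- abs(outer(spots$z, cubes$z, "-"))
  dy <- abs(outer(spots$y, cubes$y, "-"))
  dx <- abs(outer(spots$x, cubes$x, "-"))
  inside <- sweep(dz, 2, cubes$half_z, "<=") &
    sweep(dy, 2, cubes$half_y, "<=") &
    sweep(dx, 2, cubes$half_x, "<=")
  dist <- sqrt(dz^2 + dy^2 + dx^2)
  dist[!inside] <- Inf
  hit <- apply(dist, 1, function(r) if (all(is.infinite(r))) NA_integer_
               else which.min(r))  # which.min: first (lowest id) on ties
  ifelse(is.na(hit), NA_integer_, cubes$granule_id[hit])
}

#' Percentage of RNA molecules inside granules
#'
#' Molecule-weighted: the summed `n_molecules` of spots assigned to any
#' granule cube over the summed `n_molecules` of all spots, times 100.
#'
#' @param spots a spot table with `n_molecules` assigned.
#' @param cubes membership cubes.
#' @return a percentage in `[0, 100]`.
#' @export
pct_molecules_in_granules <- function(spots, cubes) {
  if (!nrow(spots)) stop("empty spot table")
  if (!"n_molecules" %in% names(spots))
    stop("assign molecule counts before computing granule percentages")
  gid <- spot_in_granule(spots, cubes)
  100 * sum(spots$n_molecules[!is.na(gid)]) / sum(spots$n_molecules)
}

#' Fraction of cytoplasm covered by granule membership cubes
#'
#' The geometric baseline matched to the cube membership rule: the
#' percentage of cytoplasmic voxels lying inside at least one membership
#' cube. For RNAs with no granule affinity, [pct_molecules_in_granules()]
#' is expected to equal this occupancy (the "not enriched, but not
#' excluded" baseline); note it exceeds [cytoplasm_fraction()] because the
#' padded cube is larger than the ellipsoidal granule it bounds.
#'
#' @param cubes membership cubes.
#' @param roi a `cell_roi` with 3D masks.
#' @return a percentage in `[0, 100]`.
#' @export
granule_occupancy_fraction <- function(cubes, roi) {
  stopifnot(inherits(roi, "cell_roi"))
  d <- dim(roi$cell_mask)
  if (length(d) != 3L) stop("granule_occupancy_fraction needs 3D masks")
  cyto <- roi$cell_mask & !roi$nucleus_mask
  if (!any(cyto)) stop("empty cytoplasm mask")
  inbox <- array(FALSE, d)
  for (i in seq_len(nrow(cubes))) {
    z0 <- max(1L, ceiling(cubes$z[i] - cubes$half_z[i]) + 1L)
    z1 <- min(d[1], floor(cubes$z[i] + cubes$half_z[i]) + 1L)
    y0 <- max(1L, ceiling(cubes$y[i] - cubes$half_y[i]) + 1L)
    y1 <- min(d[2], floor(cubes$y[i] + cubes$half_y[i]) + 1L)
    x0 <- max(1L, ceiling(cubes$x[i] - cubes$half_x[i]) + 1L)
    x1 <- min(d[3], floor(cubes$x[i] + cubes$half_x[i]) + 1L)
    if (z0 <= z1 && y0 <= y1 && x0 <= x1) inbox[z0:z1, y0:y1, x0:x1] <- TRUE
  }
  100 * sum(inbox & cyto) / sum(cyto)
}

#' Cluster-cluster colocalization between two RNA species
#'
#' Two clusters are colocalization candidates when within the tolerance on
#' every axis (default 2 px in x and y, 2 slices in z). Matching is
#' one-to-one: candidate pairs are accepted in order of increasing Euclidean
#' distance (ties by lower A id, then lower B id) while both partners are
#' unused, so the unordered pair set is symmetric in A and B.
#'
#' @param clusters_a,clusters_b spot tables; rows with `is_cluster == FALSE`
#'   are dropped when the column is present.
#' @param tol_xy_px,tol_z_slices per-axis tolerances.
#' @return a list: `pairs` (data frame `a_id`, `b_id`, `distance`),
#'   `pct_a_not_colocalized`, `pct_b_not_colocalized`, and the cluster
#'   counts used.
#' @export
cluster_colocalization <- function(clusters_a, clusters_b,
                                   tol_xy_px = 2, tol_z_slices = 2) {
  pick <- function(df) {
    if ("is_cluster" %in% names(df)) df <- df[df$is_cluster, , drop = FALSE]
    if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
    df
  }
  a <- pick(clusters_a); b <- pick(clusters_b)
  pairs <- data.frame(a_id = integer(), b_id = integer(), distance = numeric())
  if (nrow(a) && nrow(b)) {
    dz <- abs(outer(a$z, b$z, "-"))
    dy <- abs(outer(a$y, b$y, "-"))
    dx <- abs(outer(a$x, b$x, "-"))
    ok <- which(dz <= tol_z_slices & dy <= tol_xy_px & dx <= tol_xy_px,
                arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- data.frame(ai = ok[, 1], bi = ok[, 2],
                         distance = sqrt(dz[ok]^2 + dy[ok]^2 + dx[ok]^2))
      cand <- cand[order(cand$distance, a$id[cand$ai], b$id[cand$bi]), ]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      sel <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        if (!used_a[cand$ai[k]] && !used_b[cand$bi[k]]) {
          sel[k] <- TRUE
          used_a[cand$ai[k]] <- TRUE; used_b[cand$bi[k]] <- TRUE
        }
      }
      cand <- cand[sel, , drop = FALSE]
      pairs <- data.frame(a_id = a$id[cand$ai], b_id = b$id[cand$bi],
                          distance = cand$distance)
    }
  }
  list(pairs = pairs,
       n_clusters_a = nrow(a), n_clusters_b = nrow(b),
       pct_a_not_colocalized =
         if (nrow(a)) 100 * (1 - nrow(pairs) / nrow(a)) else NA_real_,
       pct_b_not_colocalized =
         if (nrow(b)) 100 * (1 - nrow(pairs) / nrow(b)) else NA_real_)
}

#' Granule content summary for two RNA species
#'
#' Partitions granules into those containing clusters of species A only, B
#' only, both, or neither (membership by the cube rule), with counts and
#' percentages that sum to the total granule count.
#'
#' @param cubes membership cubes (one row per granule).
#' @param spots_a,spots_b spot tables (pre-filter to clusters for the
#'   published cluster-content summaries).
#' @return a data frame with rows `a_only`, `b_only`, `both`, `neither`.
#' @export
granule_content_summary <- function(cubes, spots_a, spots_b) {
  ga <- unique(stats::na.omit(spot_in_granule(spots_a, cubes)))
  gb <- unique(stats::na.omit(spot_in_granule(spots_b, cubes)))
  n <- nrow(cubes)
  both <- length(intersect(ga, gb))
  a_only <- length(setdiff(ga, gb))
  b_only <- length(setdiff(gb, ga))
  neither <- n - both - a_only - b_only
  counts <- c(a_only = a_only, b_only = b_only, both = both, neither = neither)
  data.frame(category = names(counts), n_granules = as.integer(counts),
             pct = if (n > 0) 100 * counts / n else rep(NA_real_, 4),
             row.names = NULL, stringsAsFactors = FALSE)
}
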