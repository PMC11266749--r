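# Germ-granule segmentation: maximum-entropy (Kapur) thresholding of the
# blurred marker channel, per-slice distance-transform watershed to split
# touching granules, 3D linking of slice labels, and the 3D measurements
# (minor/major radius, volume, bounding cube) that drive colocalization.

#' Kapur maximum-entropy threshold of a histogram
#'
#' Maximizes the sum of the Shannon entropies of the background (bins
#' `1..t`) and foreground (bins `t+1..n`) class distributions over all split
#' points `t`; ties break toward the lower threshold. This is the MaxEntropy
#' auto-threshold of common image-analysis tools.
#'
#' @param counts non-negative histogram counts.
#' @return the split index `t` (1-based bin index): bins `1..t` are
#'   background, bins above `t` foreground. An error is raised when fewer
#'   than two bins are occupied (nothing to separate).
#' @export
max_entropy_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || !all(is.finite(counts)))
    stop("histogram counts must be finite and non-negative")
  if (sum(counts > 0) < 2L)
    stop("histogram has fewer than two occupied bins; nothing to separate")
  p <- counts / sum(counts)
  n <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Stot <- S[n]
  t <- seq_len(n - 1L)
  Pb <- P[t]
  valid <- Pb > 0 & Pb < 1
  Hb <- log(Pb) - S[t] / Pb
  Hf <- log(1 - Pb) - (Stot - S[t]) / (1 - Pb)
  obj <- ifelse(valid, Hb + Hf, -Inf)
  which.max(obj)  # which.max takes the first (lowest) maximizer
}

# Threshold a stack: 256-bin histogram over the intensity range, Kapur split,
# returned as the intensity at the split bin's upper edge (foreground is
# strictly above).
stack_max_entropy_threshold <- function(voxels, n_bins = 256L) {
  rng <- range(voxels)
  if (rng[1] == rng[2]) stop("single-valued image; nothing to separate")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(voxels, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  t <- max_entropy_threshold(counts)
  breaks[t + 1L]
}

# Merge per-slice watershed labels into 3D components: two labels in
# adjacent slices belong to the same granule when their masks overlap.
link_slices_3d <- function(slice_labels) {
  d <- dim(slice_labels)
  offs <- c(0L, cumsum(apply(slice_labels, 1, max))[-d[1]])
  glob <- slice_labels
  for (z in seq_len(d[1])) {
    sl <- slice_labels[z, , ]
    sl[sl > 0] <- sl[sl > 0] + offs[z]
    glob[z, , ] <- sl
  }
  nlab <- max(glob)
  if (nlab == 0L) return(glob)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (z in seq_len(d[1] - 1L)) {
    a <- glob[z, , ]; b <- glob[z + 1L, , ]
    both <- a > 0 & b > 0
    if (!any(both)) next
    prs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(prs))) {
      ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  glob[glob > 0] <- root[glob[glob > 0]]
  glob
}

#' Segment granules in the marker channel
#'
#' Per-slice rolling-ball background subtraction, per-slice Gaussian blur
#' (`config$blur_sigma`, in-plane), Kapur maximum-entropy threshold (falling back to
#' `config$manual_granule_threshold` when thresholding fails), per-slice
#' distance-transform watershed to split touching objects (or a full-3D
#' watershed when `config$watershed_3d`), 3D linking of slice labels, a
#' minimum-volume filter, and per-component measurements.
#'
#' The minor radius is the equivalent-circle radius of the component's
#' largest-area z-slice; the major radius is the larger of the z half-extent
#' and the half-length of the longest principal axis (granules tend to be
#' tallest in z).
#'
#' @param stack marker-channel `image_stack`.
#' @param config a [pipeline_config()].
#' @return a list: `labels` (integer label volume) and `granules`, a granule
#'   table with `granule_id`, centroid `z`,`y`,`x`, `minor_radius_px`,
#'   `major_radius_px`, `volume_vox`, sorted by centroid. An image with no
#'   detectable granules yields an empty table (logged), not an error.
#' @export
segment_granules <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  bs <- subtract_background(stack, config$background_radius_px)
  # per-slice (in-plane) blur: 1 px laterally is ~65 nm while 1 slice is
  # ~300 nm, so blurring across slices would badly dilate the z-extent
  bl <- gaussian_blur(bs$voxels, c(0, config$blur_sigma, config$blur_sigma))
  thr <- tryCatch(stack_max_entropy_threshold(bl), error = function(e) {
    if (!is.null(config$manual_granule_threshold)) {
      gf_log("max-entropy threshold failed (%s); using manual threshold",
             conditionMessage(e))
      config$manual_granule_threshold
    } else stop(e)
  })
  empty <- data.frame(granule_id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), minor_radius_px = numeric(),
                      major_radius_px = numeric(), volume_vox = integer())
  # degenerate-input guard: on a structureless (noise-only) channel the
  # entropy split lands inside the noise distribution; require the threshold
  # to clear the bulk of the image by a few robust deviations
  contrast <- (thr - stats::median(bl)) / max(stats::mad(bl), 1e-9)
  if (contrast < config$min_threshold_contrast) {
    gf_log("threshold contrast %.1f MAD < %.1f: no granules called",
           contrast, config$min_threshold_contrast)
    return(list(labels = array(0L, d), granules = empty))
  }
  mask <- bl > thr
  if (!any(mask)) {
    gf_log("no voxels above the granule threshold")
    return(list(labels = array(0L, d), granules = empty))
  }
  if (isTRUE(config$watershed_3d)) {
    dm <- EBImage::distmap(mask)
    labels <- array(as.integer(EBImage::watershed(dm, config$watershed_tolerance)), d)
  } else {
    slabs <- array(0L, d)
    for (z in seq_len(d[1])) {
      mz <- mask[z, , ]
      if (!any(mz)) next
      w <- EBImage::watershed(EBImage::distmap(mz), config$watershed_tolerance)
      slabs[z, , ] <- as.integer(w)
    }
    labels <- link_slices_3d(slabs)
  }
  # minimum-volume filter and sequential relabelling
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= config$min_granule_vox)
  if (!length(keep)) {
    gf_log("all components below the minimum volume (%d vox)",
           config$min_granule_vox)
    return(list(labels = array(0L, d), granules = empty))
  }
  gran <- measure_granules(labels, keep)
  ord <- order(gran$z, gran$y, gran$x)
  gran <- gran[ord, , drop = FALSE]
  remap <- integer(max(labels))
  remap[gran$old_label] <- seq_len(nrow(gran))
  labels[labels > 0] <- remap[labels[labels > 0]]
  gran$granule_id <- seq_len(nrow(gran))
  gran$old_label <- NULL
  rownames(gran) <- NULL
  list(labels = labels,
       granules = gran[, c("granule_id", "z", "y", "x", "minor_radius_px",
                           "major_radius_px", "volume_vox")])
}

measure_granules <- function(labels, keep) {
  cond <- labels > 0 & array(labels %in% keep, dim(labels))
  idx <- which(cond, arr.ind = TRUE)
  lab <- labels[cond]
  co <- idx - 1  # 0-based (z, y, x)
  out <- lapply(split(seq_len(nrow(co)), lab), function(rows) {
    cc <- co[rows, , drop = FALSE]
    zcounts <- table(cc[, 1])
    area <- max(zcounts)
    minor <- sqrt(area / pi)
    z_half <- (diff(range(cc[, 1])) + 1) / 2
    pc_half <- z_half
    if (nrow(cc) >= 4) {
      cv <- stats::cov(cc)
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      proj <- cc %*% ev
      pc_half <- (diff(range(proj)) + 1) / 2
    }
    major <- max(z_half, pc_half, minor)
    data.frame(z = mean(cc[, 1]), y = mean(cc[, 2]), x = mean(cc[, 3]),
               minor_radius_px = minor, major_radius_px = major,
               volume_vox = nrow(cc))
  })
  res <- do.call(rbind, out)
  res$old_label <- as.integer(names(out))
  res
}

#' Granule membership cubes
#'
#' Axis-aligned boxes centred on each granule centroid, following the
#' published estimate: full extent `(minor_radius + pad) * 2` in x and y
#' (the pad leaves room for error, default 2 px) and `major_radius * 2` in
#' z. These cubes are the membership regions for spot assignment.
#'
#' @param granules a granule table (see [segment_granules()]).
#' @param cube_pad_px pad added to the minor radius in x/y.
#' @return a data frame: `granule_id`, centre `z`,`y`,`x`, half-extents
#'   `half_z`, `half_y`, `half_x`.
#' @export
granule_bounding_cube <- function(granules, cube_pad_px = 2) {
  stopifnot(cube_pad_px >= 0)
  if (!nrow(granules))
    return(data.frame(granule_id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), half_z = numeric(), half_y = numeric(),
                      half_x = numeric()))
  data.frame(granule_id = granules$granule_id, z = granules$z,
             y = granules$y, x = granules$x,
             half_z = granules$major_radius_px,
             half_y = granules$minor_radius_px + cube_pad_px,
             half_x = granules$minor_radius_px + cube_pad_px)
}

#' Fraction of cytoplasm occupied by granules
#'
#' Total granule volume divided by the cytoplasmic volume (cell minus
#' nucleus), as a percentage.
#'
#' @param granules a granule table.
#' @param roi a `cell_roi` with 3D masks.
#' @return a percentage in `[0, 100]`.
#' @export
cytoplasm_fraction <- function(granules, roi) {
  stopifnot(inherits(roi, "cell_roi"))
  if (length(dim(roi$cell_mask)) != 3L)
    stop("cytoplasm_fraction needs 3D cell/nucleus masks")
  cyto <- sum(roi$cell_mask) - sum(roi$nucleus_mask)
  if (cyto <= 0) stop("nucleus volume >= cell volume")
  100 * sum(granules$volume_vox) / cyto
}
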