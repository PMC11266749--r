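# Synthetic embryo generator with exhaustive ground truth.
#
# Emulates the statistical structure of the real data: diffraction-limited
# smFISH foci of unit intensity per molecule, multi-molecule homotypic
# clusters, ellipsoidal germ granules in a marker channel, ellipsoidal
# cell/nucleus geometry, asymmetric P-lineage partitioning, and a
# Poisson-shot + Gaussian-read camera noise model on top of an optional
# background gradient. Every latent variable is returned as ground truth.

#' Simulation parameters
#'
#' Defaults describe one P blastomere imaged at 65 nm/px and 300 nm/slice
#' with a ~150 nm PSF (sigma 1 px laterally, 1.1 slices axially), a
#' single-molecule integrated intensity of 8000 counts over a background of
#' 100 counts (peak SNR about 40), Poisson shot noise plus 3-count read
#' noise, ten ellipsoidal granules with their long axis in z, and cluster
#' sizes drawn from a truncated geometric distribution (cap 35 molecules).
#'
#' @param dim stack dimensions `c(z, y, x)`.
#' @param pixel_size_xy,z_step acquisition geometry (nm).
#' @param lineage lineage label for the simulated cell.
#' @param cell_frac ellipsoid semi-axes of the cell as fractions of `dim`
#'   (z, y, x).
#' @param nucleus_frac nucleus semi-axes as a fraction of the cell's.
#' @param n_molecules total number of mRNA molecules.
#' @param p_granule probability that a focus is granule-associated.
#' @param cluster_size_mean mean of the truncated geometric distribution of
#'   molecules per focus; 1 means every molecule is its own focus.
#' @param cluster_size_max truncation cap on molecules per focus.
#' @param n_granules number of granules.
#' @param granule_minor_range,granule_major_range uniform ranges for the
#'   in-plane (px) and axial (slices) granule semi-axes.
#' @param granule_gap_px minimum gap enforced between granules.
#' @param psf_sigma_xy_px,psf_sigma_z_slices PSF Gaussian sd.
#' @param unit_intensity integrated counts contributed by one molecule.
#' @param background_level mean background (counts).
#' @param background_gradient relative amplitude of a linear background ramp
#'   along x (0 = flat).
#' @param poisson_noise apply Poisson shot noise.
#' @param read_noise_sd sd of additive Gaussian read noise (counts; rounded
#'   to integer ADU, clipped at 0).
#' @param granule_channel render the granule marker channel.
#' @param granule_level marker intensity inside granules (counts).
#' @param granule_background marker channel background (counts).
#' @param granule_blur_sigma optical blur applied to the marker channel.
#' @param foci_min_separation_px minimum Chebyshev separation enforced
#'   between foci (0 disables; used for localization oracles).
#' @param render_channels render the image channels; `FALSE` skips
#'   rendering (stacks are `NULL`) and returns geometry and ground truth
#'   only — useful for partition-model studies that never touch pixels.
#' @param rng_seed seed; `NULL` uses the current RNG stream.
#' @return an object of class `sim_params` (a named list).
#' @export
sim_params <- function(dim = c(20L, 96L, 96L),
                       pixel_size_xy = 65, z_step = 300,
                       lineage = "P2",
                       cell_frac = c(0.42, 0.40, 0.40),
                       nucleus_frac = 0.35,
                       n_molecules = 300L,
                       p_granule = 0.5,
                       cluster_size_mean = 1.5,
                       cluster_size_max = 35L,
                       n_granules = 10L,
                       granule_minor_range = c(1.5, 3),
                       granule_major_range = c(2, 4),
                       granule_gap_px = 2,
                       psf_sigma_xy_px = 1.0,
                       psf_sigma_z_slices = 1.1,
                       unit_intensity = 8000,
                       background_level = 100,
                       background_gradient = 0.2,
                       poisson_noise = TRUE,
                       read_noise_sd = 3,
                       granule_channel = TRUE,
                       granule_level = 300,
                       granule_background = 20,
                       granule_blur_sigma = 0.8,
                       foci_min_separation_px = 0,
                       render_channels = TRUE,
                       rng_seed = NULL) {
  p <- structure(as.list(environment()), class = "sim_params")
  stopifnot(p$p_granule >= 0, p$p_granule <= 1, p$unit_intensity > 0,
            p$n_molecules >= 0, p$n_granules >= 0, p$cluster_size_mean >= 1)
  p
}

# Quadratic-form field ((v - c) / r)^2 summed over axes, on a (z, y, x) grid.
ellipsoid_q <- function(dim, center, radii) {
  qz <- ((0:(dim[1] - 1) - center[1]) / radii[1])^2
  qy <- ((0:(dim[2] - 1) - center[2]) / radii[2])^2
  qx <- ((0:(dim[3] - 1) - center[3]) / radii[3])^2
  array(rep(qz, times = dim[2] * dim[3]) +
          rep(rep(qy, each = dim[1]), times = dim[3]) +
          rep(qx, each = dim[1] * dim[2]), dim = dim)
}

ellipsoid_mask <- function(dim, center, radii) ellipsoid_q(dim, center, radii) <= 1

# Uniform point inside an ellipsoid (0-based continuous coordinates).
runif_ellipsoid <- function(center, radii) {
  repeat {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) <= 1) return(center + u * radii)
  }
}

# Truncated geometric cluster-size distribution with the given mean.
rcluster_sizes <- function(n, mean_size, max_size) {
  if (mean_size <= 1) return(rep(1L, n))
  p <- 1 / mean_size
  s <- 1L + stats::rgeom(n, p)
  pmin(s, as.integer(max_size))
}

#' Generate one synthetic embryo image with ground truth
#'
#' Places foci uniformly in the cytoplasm or inside granules according to
#' `p_granule`, renders each focus as a pixel-integrated 3D Gaussian whose
#' integrated intensity is `n_molecules * unit_intensity`, renders granules
#' as blurred ellipsoids in a second channel, applies background and camera
#' noise (yielding integer counts), and returns everything alongside the
#' latent truth.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `embryo_sim` with elements `rna` (`image_stack`),
#'   `granule` (`image_stack` or `NULL`), `roi` (`cell_roi`) and `truth`
#'   (lists `foci`, `molecules`, `granules` data frames, the granule label
#'   volume, and the parameters used).
#' @export
generate_embryo <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed, generate_embryo_impl(params))
}

generate_embryo_impl <- function(p) {
  d <- as.integer(p$dim)
  center <- (d - 1) / 2
  cell_r <- p$cell_frac * d
  nuc_r <- p$nucleus_frac * cell_r
  cell_mask <- ellipsoid_mask(d, center, cell_r)
  nuc_mask <- ellipsoid_mask(d, center, nuc_r)
  roi <- cell_roi(cell_mask, nuc_mask, lineage = p$lineage)

  ## granule geometry -------------------------------------------------------
  granules <- data.frame(granule_id = integer(), z = numeric(), y = numeric(),
                         x = numeric(), minor_radius_px = numeric(),
                         major_radius_px = numeric(), volume_vox = integer())
  granule_labels <- array(0L, dim = d)
  ng <- as.integer(p$n_granules)
  if (ng > 0) {
    placed <- 0L; tries <- 0L
    cz <- numeric(0); cy <- numeric(0); cx <- numeric(0)
    rz <- numeric(0); rxy <- numeric(0)
    while (placed < ng) {
      tries <- tries + 1L
      if (tries > 500L * ng)
        stop("could not place ", ng, " granules inside the cytoplasm")
      minor <- stats::runif(1, p$granule_minor_range[1], p$granule_minor_range[2])
      major <- stats::runif(1, max(minor, p$granule_major_range[1]),
                            max(minor, p$granule_major_range[2]))
      g_r <- c(major, minor, minor)  # long axis along z
      ctr <- runif_ellipsoid(center, pmax(cell_r - g_r - 1, 0.5))
      # fully inside the cell (conservative), outside the nucleus
      if (sum(((abs(ctr - center) + g_r) / cell_r)^2) > 1) next
      if (sum((abs(ctr - center) / (nuc_r + g_r))^2) < 1) next
      if (placed > 0) {
        sep <- sqrt((ctr[1] - cz)^2 / (rz + major + p$granule_gap_px)^2 +
                    (ctr[2] - cy)^2 / (rxy + minor + p$granule_gap_px)^2 +
                    (ctr[3] - cx)^2 / (rxy + minor + p$granule_gap_px)^2)
        if (any(sep < 1)) next
      }
      placed <- placed + 1L
      cz <- c(cz, ctr[1]); cy <- c(cy, ctr[2]); cx <- c(cx, ctr[3])
      rz <- c(rz, major); rxy <- c(rxy, minor)
      m <- ellipsoid_mask(d, ctr, g_r)
      granule_labels[m] <- placed
      granules <- rbind(granules, data.frame(
        granule_id = placed, z = ctr[1], y = ctr[2], x = ctr[3],
        minor_radius_px = minor, major_radius_px = major,
        volume_vox = sum(m)))
    }
  }

  ## foci and molecules -----------------------------------------------------
  n_mol <- as.integer(p$n_molecules)
  foci <- data.frame(focus_id = integer(), z = numeric(), y = numeric(),
                     x = numeric(), n_molecules = integer(),
                     in_granule = logical(), granule_id = integer())
  if (n_mol > 0) {
    sizes <- integer(0)
    while (sum(sizes) < n_mol)
      sizes <- c(sizes, rcluster_sizes(max(16L, n_mol %/% 4L),
                                       p$cluster_size_mean, p$cluster_size_max))
    sizes <- sizes[cumsum(sizes) - sizes < n_mol]
    sizes[length(sizes)] <- n_mol - sum(sizes[-length(sizes)])
    nf <- length(sizes)
    in_gran <- if (ng > 0) stats::runif(nf) < p$p_granule else rep(FALSE, nf)
    pos <- matrix(0, nf, 3)
    cyto_ok <- function(q) {  # inside cell, outside nucleus and granules
      iq <- round(q) + 1
      all(iq >= 1 & iq <= d) && cell_mask[iq[1], iq[2], iq[3]] &&
        !nuc_mask[iq[1], iq[2], iq[3]] &&
        granule_labels[iq[1], iq[2], iq[3]] == 0L &&
        sum(((q - center) / cell_r)^2) <= 1 &&
        sum(((q - center) / nuc_r)^2) > 1
    }
    gid <- rep(NA_integer_, nf)
    for (i in seq_len(nf)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 2000L)
          stop("cannot place focus ", i, " with min separation ",
               p$foci_min_separation_px, " px; lower the density or separation")
        if (in_gran[i]) {
          gid[i] <- sample.int(nrow(granules), 1L)
          g <- granules[gid[i], ]
          q <- runif_ellipsoid(c(g$z, g$y, g$x),
                              c(g$major_radius_px, g$minor_radius_px,
                                g$minor_radius_px))
        } else {
          repeat { q <- runif_ellipsoid(center, cell_r); if (cyto_ok(q)) break }
        }
        if (p$foci_min_separation_px <= 0 || i == 1L ||
            all(pmax(abs(pos[seq_len(i - 1L), 1, drop = FALSE] - q[1]),
                     abs(pos[seq_len(i - 1L), 2, drop = FALSE] - q[2]),
                     abs(pos[seq_len(i - 1L), 3, drop = FALSE] - q[3])) >=
                p$foci_min_separation_px)) break
      }
      pos[i, ] <- q
    }
    foci <- data.frame(focus_id = seq_len(nf), z = pos[, 1], y = pos[, 2],
                       x = pos[, 3], n_molecules = as.integer(sizes),
                       in_granule = in_gran, granule_id = gid)
  }
  molecules <- if (nrow(foci)) {
    idx <- rep(seq_len(nrow(foci)), foci$n_molecules)
    data.frame(z = foci$z[idx], y = foci$y[idx], x = foci$x[idx],
               parent_focus_id = foci$focus_id[idx])
  } else data.frame(z = numeric(), y = numeric(), x = numeric(),
                    parent_focus_id = integer())

  ## render + noise ---------------------------------------------------------
  if (!isTRUE(p$render_channels))
    return(structure(list(rna = NULL, granule = NULL, roi = roi,
                          truth = list(foci = foci, molecules = molecules,
                                       granules = granules,
                                       granule_labels = granule_labels,
                                       params = p)),
                     class = "embryo_sim"))
  bg <- p$background_level *
    (1 + p$background_gradient * ((0:(d[3] - 1)) / max(d[3] - 1, 1) - 0.5))
  signal <- array(rep(bg, each = d[1] * d[2]), dim = d)
  signal <- render_foci(signal, foci, p$psf_sigma_xy_px, p$psf_sigma_z_slices,
                        p$unit_intensity)
  rna <- image_stack(apply_camera_noise(signal, p),
                     pixel_size_xy = p$pixel_size_xy, z_step = p$z_step,
                     channel = "rna")
  gr_stack <- NULL
  if (isTRUE(p$granule_channel)) {
    gsig <- array(p$granule_background, dim = d) +
      p$granule_level * (granule_labels > 0)
    if (p$granule_blur_sigma > 0)
      gsig <- gaussian_blur(gsig, p$granule_blur_sigma)
    gr_stack <- image_stack(apply_camera_noise(gsig, p),
                            pixel_size_xy = p$pixel_size_xy, z_step = p$z_step,
                            channel = "granule")
  }

  structure(list(rna = rna, granule = gr_stack, roi = roi,
                 truth = list(foci = foci, molecules = molecules,
                              granules = granules,
                              granule_labels = granule_labels,
                              params = p)),
            class = "embryo_sim")
}

# Add pixel-integrated 3D Gaussian foci to a signal array.
render_foci <- function(signal, foci, sigma_xy, sigma_z, unit_intensity) {
  if (!nrow(foci)) return(signal)
  d <- dim(signal)
  hz <- ceiling(4 * sigma_z); hxy <- ceiling(4 * sigma_xy)
  for (i in seq_len(nrow(foci))) {
    z0 <- max(0L, floor(foci$z[i]) - hz); z1 <- min(d[1] - 1L, ceiling(foci$z[i]) + hz)
    y0 <- max(0L, floor(foci$y[i]) - hxy); y1 <- min(d[2] - 1L, ceiling(foci$y[i]) + hxy)
    x0 <- max(0L, floor(foci$x[i]) - hxy); x1 <- min(d[3] - 1L, ceiling(foci$x[i]) + hxy)
    wz <- gauss_mass_1d(z0:z1, foci$z[i], sigma_z)
    wy <- gauss_mass_1d(y0:y1, foci$y[i], sigma_xy)
    wx <- gauss_mass_1d(x0:x1, foci$x[i], sigma_xy)
    amp <- foci$n_molecules[i] * unit_intensity
    signal[(z0:z1) + 1, (y0:y1) + 1, (x0:x1) + 1] <-
      signal[(z0:z1) + 1, (y0:y1) + 1, (x0:x1) + 1] +
      amp * (wz %o% wy %o% wx)
  }
  signal
}

# Poisson shot noise + rounded Gaussian read noise, clipped at zero:
# integer ADU counts, as a camera would deliver.
apply_camera_noise <- function(signal, p) {
  v <- signal
  if (isTRUE(p$poisson_noise)) v[] <- stats::rpois(length(v), pmax(v, 0))
  if (p$read_noise_sd > 0)
    v <- v + round(stats::rnorm(length(v), 0, p$read_noise_sd))
  pmax(v, 0)
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("embryo_sim [%s]: %d foci / %d molecules, %d granules%s\n",
              x$roi$lineage, nrow(x$truth$foci), sum(x$truth$foci$n_molecules),
              nrow(x$truth$granules),
              if (is.null(x$granule)) " (no marker channel)" else ""))
  invisible(x)
}

#' Simulate an asymmetric P-lineage series (P1 -> P4)
#'
#' At each division the P daughter keeps `inherit_fraction` of
#' granule-associated molecules and a binomial share of cytoplasmic
#' molecules proportional to its volume; the cell volume shrinks by
#' `volume_ratio` (semi-axes scale by `volume_ratio^(1/3)`, granule radii
#' with them). Under the idealized model (full granule localization,
#' all-granule inheritance, volume halving) the concentration doubles per
#' division: eightfold from P1 to P4.
#'
#' @param params a [sim_params()] for the first (P1) stage.
#' @param n_divisions number of divisions simulated (3 reaches P4).
#' @param inherit_fraction fraction of granule-associated molecules kept by
#'   the P daughter.
#' @param volume_ratio fraction of the mother's volume kept by the P
#'   daughter (also the cytoplasmic inheritance probability).
#' @return a list with one element per stage: the `embryo_sim` plus `stage`
#'   label, molecule counts, cytoplasmic volume and the ground-truth
#'   concentration `n_molecules / cytoplasmic volume` (molecules per voxel).
#' @export
generate_lineage_series <- function(params = sim_params(), n_divisions = 3L,
                                    inherit_fraction = 1, volume_ratio = 0.5) {
  stopifnot(n_divisions >= 1, inherit_fraction >= 0, inherit_fraction <= 1,
            volume_ratio > 0, volume_ratio < 1)
  base_seed <- params$rng_seed
  stages <- vector("list", n_divisions + 1L)
  p <- params
  scale <- 1
  n_gran <- NA_integer_; n_cyto <- NA_integer_
  for (s in seq_len(n_divisions + 1L)) {
    p$rng_seed <- if (is.null(base_seed)) NULL else base_seed + 7919L * (s - 1L)
    if (s == 1L) p$lineage <- "P1"
    else p$lineage <- paste0("P", min(s, 4L))
    emb <- generate_embryo(p)
    tf <- emb$truth$foci
    n_gran <- sum(tf$n_molecules[tf$in_granule])
    n_cyto <- sum(tf$n_molecules[!tf$in_granule])
    cyto_vol <- emb$roi$volume_vox["cell"] - emb$roi$volume_vox["nucleus"]
    stages[[s]] <- list(stage = p$lineage, embryo = emb,
                        n_molecules = n_gran + n_cyto,
                        n_granule_molecules = n_gran,
                        cytoplasm_volume_vox = unname(cyto_vol),
                        truth_concentration = unname((n_gran + n_cyto) / cyto_vol))
    if (s > n_divisions) break
    # partition molecules to the next P daughter
    keep_g <- stats::rbinom(1L, n_gran, inherit_fraction)
    keep_c <- stats::rbinom(1L, n_cyto, volume_ratio)
    n_next <- keep_g + keep_c
    lin_scale <- volume_ratio^(1 / 3)
    scale <- scale * lin_scale
    p$cell_frac <- p$cell_frac * lin_scale
    p$granule_minor_range <- pmax(p$granule_minor_range * lin_scale, 0.75)
    p$granule_major_range <- pmax(p$granule_major_range * lin_scale, 1.0)
    p$n_molecules <- n_next
    p$p_granule <- if (n_next > 0) keep_g / n_next else 0
  }
  stages
}

#' Generate a synthetic screen annotation table with known labels
#'
#' Allocates transcripts to Groups I/II/III by exact largest-remainder
#' apportionment of `group_probs` (so requested tallies are hit exactly),
#' fills per-stage foci flags consistent with each group, and lets a stated
#' small fraction of Group III transcripts carry the PGC maintenance pattern
#' anyway (defaults mirror the published screen: 131/310/46 of 487, five
#' Group III transcripts with the pattern).
#'
#' @param n_transcripts number of rows.
#' @param group_probs probabilities for Groups I, II, III (must sum to 1).
#' @param pgc_group3_prob probability that a Group III transcript still
#'   shows the PGC pattern.
#' @param rng_seed seed; `NULL` uses the current stream.
#' @return a data frame with `transcript_id`, `foci_P1..P4`, `pgc_pattern`
#'   and the generator's `true_group`.
#' @export
generate_screen_table <- function(n_transcripts = 487L,
                                  group_probs = c(131, 310, 46) / 487,
                                  pgc_group3_prob = 5 / 46,
                                  rng_seed = NULL) {
  stopifnot(abs(sum(group_probs) - 1) < 1e-8, n_transcripts >= 1)
  with_seed(rng_seed, {
    base <- floor(n_transcripts * group_probs)
    rem <- n_transcripts - sum(base)
    if (rem > 0) {
      frac <- n_transcripts * group_probs - base
      base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1
    }
    grp <- rep(c("I", "II", "III"), times = base)
    n <- length(grp)
    foci <- matrix(FALSE, n, 4)
    pos <- grp != "III"
    foci[pos, ] <- stats::runif(sum(pos) * 4) < 0.7
    none <- pos & rowSums(foci) == 0
    foci[none, 2] <- TRUE  # foci-positive transcripts show foci somewhere
    pgc <- ifelse(grp == "I", TRUE,
                  ifelse(grp == "II", FALSE,
                         stats::runif(n) < pgc_group3_prob))
    ord <- sample.int(n)
    data.frame(transcript_id = sprintf("txp%04d", seq_len(n)),
               foci_P1 = foci[ord, 1], foci_P2 = foci[ord, 2],
               foci_P3 = foci[ord, 3], foci_P4 = foci[ord, 4],
               pgc_pattern = pgc[ord], true_group = grp[ord],
               stringsAsFactors = FALSE)
  })
}
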