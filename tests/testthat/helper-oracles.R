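# Shared fixtures and independent brute-force oracles.
# Oracles are written as plain loops, independent of the package internals
# they check.

# -- brute-force Kapur objective: evaluate both class entropies explicitly --
oracle_max_entropy <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:(n - 1)) {
    Pb <- sum(p[1:t]); Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    hb <- 0
    for (i in 1:t) if (p[i] > 0) hb <- hb - (p[i] / Pb) * log(p[i] / Pb)
    hf <- 0
    for (i in (t + 1):n) if (p[i] > 0) hf <- hf - (p[i] / Pf) * log(p[i] / Pf)
    if (hb + hf > best + 1e-12) { best <- hb + hf; best_t <- t }
  }
  best_t
}

# -- exhaustive two-sided Fisher p: enumerate all tables with fixed margins --
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# -- brute-force spot-in-cube assignment: loop over cubes, nearest centroid --
oracle_spot_in_granule <- function(spots, cubes) {
  out <- rep(NA_integer_, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    best_d <- Inf; best_g <- NA_integer_
    for (j in seq_len(nrow(cubes))) {
      if (abs(spots$z[i] - cubes$z[j]) <= cubes$half_z[j] &&
          abs(spots$y[i] - cubes$y[j]) <= cubes$half_y[j] &&
          abs(spots$x[i] - cubes$x[j]) <= cubes$half_x[j]) {
        d <- sqrt((spots$z[i] - cubes$z[j])^2 + (spots$y[i] - cubes$y[j])^2 +
                    (spots$x[i] - cubes$x[j])^2)
        if (d < best_d - 1e-12) { best_d <- d; best_g <- cubes$granule_id[j] }
      }
    }
    out[i] <- best_g
  }
  out
}

# -- O(n^2) one-to-one pairing oracle: repeatedly take the globally closest
#    admissible pair --
oracle_cluster_pairs <- function(a, b, tol_xy = 2, tol_z = 2) {
  pairs <- NULL
  free_a <- rep(TRUE, nrow(a)); free_b <- rep(TRUE, nrow(b))
  repeat {
    best <- c(Inf, NA, NA)
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (!free_a[i] || !free_b[j]) next
      if (abs(a$z[i] - b$z[j]) > tol_z || abs(a$y[i] - b$y[j]) > tol_xy ||
          abs(a$x[i] - b$x[j]) > tol_xy) next
      d <- sqrt((a$z[i] - b$z[j])^2 + (a$y[i] - b$y[j])^2 + (a$x[i] - b$x[j])^2)
      if (d < best[1] - 1e-12) best <- c(d, i, j)
    }
    if (!is.finite(best[1])) break
    pairs <- rbind(pairs, c(a$id[best[2]], b$id[best[3]]))
    free_a[best[2]] <- FALSE; free_b[best[3]] <- FALSE
  }
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

# -- greedy matching of detected spots to truth foci within a radius --------
match_to_truth <- function(spots, truth, radius = 1.5) {
  if (!nrow(spots) || !nrow(truth))
    return(list(recall = 0, precision = 0, spot_idx = integer(),
                truth_idx = integer()))
  m <- sqrt(outer(spots$z, truth$z, "-")^2 + outer(spots$y, truth$y, "-")^2 +
              outer(spots$x, truth$x, "-")^2)
  nn <- apply(m, 2, which.min)
  ok <- apply(m, 2, min) < radius
  list(recall = mean(ok),
       precision = mean(apply(m, 1, min) < radius),
       spot_idx = nn[ok], truth_idx = which(ok))
}

# small high-SNR embryo with well-separated single-molecule foci
separated_embryo <- function(seed, n = 120, dim = c(20L, 128L, 128L),
                             lineage = "P2", ...) {
  generate_embryo(sim_params(rng_seed = seed, n_molecules = n,
                             cluster_size_mean = 1, p_granule = 0,
                             n_granules = 0, granule_channel = FALSE,
                             lineage = lineage, dim = dim,
                             foci_min_separation_px = 5, ...))
}

# noiseless stack with hand-placed Gaussian foci (uses the package renderer)
render_stack <- function(foci, dim = c(16L, 48L, 48L), sigma_xy = 1.0,
                         sigma_z = 1.1, unit = 5000, background = 0) {
  sig <- array(background, dim = dim)
  sig <- granulefish:::render_foci(sig, foci, sigma_xy, sigma_z, unit)
  image_stack(sig)
}

fast_cfg <- function(...) pipeline_config(background_radius_px = 12, ...)
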