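# Ground-truth integrity and the statistical contracts of the simulator.

test_that("the same seed reproduces bit-identical embryos", {
  p <- sim_params(rng_seed = 21, n_molecules = 80, dim = c(12L, 64L, 64L),
                  n_granules = 4)
  a <- generate_embryo(p)
  b <- generate_embryo(p)
  expect_identical(a$rna$voxels, b$rna$voxels)
  expect_identical(a$granule$voxels, b$granule$voxels)
  expect_identical(a$truth$foci, b$truth$foci)
})

test_that("foci molecule counts partition the molecule total", {
  e <- generate_embryo(sim_params(rng_seed = 3, n_molecules = 137,
                                  cluster_size_mean = 2.5,
                                  dim = c(12L, 64L, 64L), n_granules = 4))
  expect_equal(sum(e$truth$foci$n_molecules), 137)
  expect_equal(nrow(e$truth$molecules), 137)
  expect_true(all(e$truth$foci$n_molecules >= 1))
  expect_true(all(e$truth$foci$n_molecules <= 35))
})

test_that("with p_granule = 1 every focus lies inside its granule", {
  e <- generate_embryo(sim_params(rng_seed = 5, n_molecules = 60,
                                  p_granule = 1, dim = c(14L, 72L, 72L),
                                  n_granules = 6, granule_channel = FALSE))
  f <- e$truth$foci
  g <- e$truth$granules
  expect_true(all(f$in_granule))
  q <- vapply(seq_len(nrow(f)), function(i) {
    gr <- g[f$granule_id[i], ]
    (f$z[i] - gr$z)^2 / gr$major_radius_px^2 +
      (f$y[i] - gr$y)^2 / gr$minor_radius_px^2 +
      (f$x[i] - gr$x)^2 / gr$minor_radius_px^2
  }, numeric(1))
  expect_true(all(q <= 1 + 1e-9))
})

test_that("zero molecules yield a background-only image with empty truth", {
  e <- generate_embryo(sim_params(rng_seed = 6, n_molecules = 0,
                                  n_granules = 0, granule_channel = FALSE,
                                  dim = c(8L, 48L, 48L)))
  expect_equal(nrow(e$truth$foci), 0L)
  expect_lt(max(e$rna$voxels), 250)  # background 100 +/- noise, no foci
})

test_that("photons are conserved: excess intensity matches molecules x unit", {
  p <- sim_params(rng_seed = 8, n_molecules = 400, cluster_size_mean = 1.5,
                  p_granule = 0, n_granules = 0, granule_channel = FALSE,
                  dim = c(20L, 96L, 96L), cell_frac = c(0.33, 0.33, 0.33),
                  background_gradient = 0, read_noise_sd = 0)
  e <- generate_embryo(p)
  excess <- sum(e$rna$voxels) - p$background_level * prod(dim(e$rna))
  expected <- 400 * p$unit_intensity
  expect_lt(abs(excess - expected) / expected, 0.015)
})

test_that("the idealized lineage model concentrates 2-fold per division", {
  p <- sim_params(rng_seed = 31, n_molecules = 20000, cluster_size_mean = 1,
                  p_granule = 1, n_granules = 20, granule_channel = FALSE,
                  render_channels = FALSE, dim = c(20L, 96L, 96L))
  ser <- generate_lineage_series(p, n_divisions = 3, inherit_fraction = 1,
                                 volume_ratio = 0.5)
  conc <- vapply(ser, `[[`, numeric(1), "truth_concentration")
  expect_equal(conc[4] / conc[1], 8, tolerance = 0.05)
  expect_equal(conc[2] / conc[1], 2, tolerance = 0.05)
  expect_equal(vapply(ser, `[[`, character(1), "stage"),
               c("P1", "P2", "P3", "P4"))
})

test_that("neutral partitioning keeps concentration flat", {
  p <- sim_params(rng_seed = 32, n_molecules = 20000, cluster_size_mean = 1,
                  p_granule = 0, n_granules = 0, granule_channel = FALSE,
                  render_channels = FALSE, dim = c(20L, 96L, 96L))
  ser <- generate_lineage_series(p, n_divisions = 3, inherit_fraction = 0.5,
                                 volume_ratio = 0.5)
  conc <- vapply(ser, `[[`, numeric(1), "truth_concentration")
  expect_equal(conc[4] / conc[1], 1, tolerance = 0.05)
})

test_that("screen tables honour exact group apportionment and determinism", {
  tab <- generate_screen_table(487, rng_seed = 9)
  expect_equal(as.integer(table(tab$true_group)[c("I", "II", "III")]),
               c(131L, 310L, 46L))
  tab2 <- generate_screen_table(487, rng_seed = 9)
  expect_identical(tab, tab2)
  g3 <- tab[tab$true_group == "III", ]
  expect_true(all(!g3$foci_P1 & !g3$foci_P2 & !g3$foci_P3 & !g3$foci_P4))
  pos <- tab[tab$true_group != "III", ]
  expect_true(all(pos$foci_P1 | pos$foci_P2 | pos$foci_P3 | pos$foci_P4))
  all3 <- generate_screen_table(50, group_probs = c(0, 0, 1), rng_seed = 2)
  expect_true(all(!all3$foci_P1 & !all3$foci_P2 & !all3$foci_P3 & !all3$foci_P4))
})
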