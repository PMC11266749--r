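# Maximum-entropy thresholding, watershed segmentation and granule geometry.

test_that("max-entropy threshold separates a two-spike histogram", {
  counts <- numeric(256)
  counts[10] <- 400; counts[200] <- 100
  t <- max_entropy_threshold(counts)
  # bins <= t are background: the split must fall between the two spikes
  expect_gte(t, 10); expect_lt(t, 200)
  expect_equal(sum(counts[1:t]), 400)
  expect_equal(sum(counts[(t + 1):256]), 100)
})

test_that("max-entropy threshold equals the brute-force oracle", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(16:128, 1)
    counts <- stats::rpois(n, stats::runif(1, 0.5, 30)) +
      ifelse(stats::runif(n) < 0.1, stats::rpois(n, 200), 0)
    if (sum(counts > 0) < 2) next
    expect_identical(max_entropy_threshold(counts), oracle_max_entropy(counts))
  }
})

test_that("degenerate histograms are rejected", {
  expect_error(max_entropy_threshold(c(0, 17, 0)), "fewer than two")
  expect_error(max_entropy_threshold(c(-1, 2)), "non-negative")
})

test_that("bounding cubes follow the (minor + pad) x 2 / major x 2 rule", {
  g <- data.frame(granule_id = 1:2, z = c(10, 5), y = c(20, 6), x = c(30, 7),
                  minor_radius_px = c(3, 1), major_radius_px = c(5, 1),
                  volume_vox = c(100L, 4L))
  cb <- granule_bounding_cube(g, 2)
  expect_equal(2 * cb$half_x, c(10, 6))
  expect_equal(2 * cb$half_y, c(10, 6))
  expect_equal(2 * cb$half_z, c(10, 2))
  cb0 <- granule_bounding_cube(g, 0)
  expect_equal(2 * cb$half_x - 2 * cb0$half_x, c(4, 4))
  expect_equal(cb$half_z, cb0$half_z)
})

test_that("cytoplasm fraction is granule volume over cell-minus-nucleus", {
  cm <- array(FALSE, c(12, 20, 20)); cm[2:11, 3:18, 3:18] <- TRUE  # 2560 vox
  nm <- array(FALSE, c(12, 20, 20)); nm[5:8, 8:13, 8:13] <- TRUE   # 144 vox
  roi <- cell_roi(cm, nm, "P4")
  g <- data.frame(granule_id = 1, z = 3, y = 5, x = 5,
                  minor_radius_px = 2, major_radius_px = 2,
                  volume_vox = 241.6)
  expect_equal(cytoplasm_fraction(g, roi), 10)
  expect_equal(cytoplasm_fraction(g[0, ], roi), 0)
  broken <- structure(list(cell_mask = nm, nucleus_mask = nm, lineage = "P4"),
                      class = "cell_roi")
  expect_error(cytoplasm_fraction(g, broken), "nucleus volume")
})

test_that("a rendered ellipsoid is segmented with faithful geometry", {
  p <- sim_params(rng_seed = 55, n_molecules = 0, n_granules = 1,
                  granule_minor_range = c(3, 3), granule_major_range = c(5, 5),
                  granule_blur_sigma = 0, dim = c(20L, 64L, 64L))
  e <- generate_embryo(p)
  seg <- segment_granules(e$granule, fast_cfg())
  expect_equal(nrow(seg$granules), 1L)
  tg <- e$truth$granules
  expect_lt(abs(seg$granules$z - tg$z), 1)
  expect_lt(abs(seg$granules$y - tg$y), 1)
  expect_lt(abs(seg$granules$x - tg$x), 1)
  expect_lt(abs(seg$granules$minor_radius_px - tg$minor_radius_px), 1.5)
  expect_lt(abs(seg$granules$major_radius_px - tg$major_radius_px), 1.5)
})

test_that("touching spheres are split by the watershed", {
  # two spheres 2.5 radii apart whose masks bridge after blurring
  d <- c(10L, 48L, 48L)
  lab <- array(0, d)
  q1 <- granulefish:::ellipsoid_mask(d, c(5, 24, 19), c(4, 4, 4))
  q2 <- granulefish:::ellipsoid_mask(d, c(5, 24, 29), c(4, 4, 4))
  sig <- 20 + 300 * (q1 | q2)
  sig <- granulefish:::gaussian_blur(sig, c(0, 1, 1))
  st <- image_stack(sig, channel = "granule")
  seg <- segment_granules(st, fast_cfg())
  expect_equal(nrow(seg$granules), 2L)
  expect_equal(sort(round(seg$granules$x)), c(19, 29), tolerance = 0.1)
})

test_that("noise-only stacks give no granules after the volume filter", {
  set.seed(56)
  st <- image_stack(array(stats::rpois(12 * 64 * 64, 20), c(12, 64, 64)),
                    channel = "granule")
  seg <- segment_granules(st, fast_cfg(min_granule_vox = 6))
  expect_equal(nrow(seg$granules), 0L)
})

test_that("segmentation labels are invariant under global intensity scaling", {
  p <- sim_params(rng_seed = 58, n_molecules = 0, n_granules = 5,
                  dim = c(14L, 72L, 72L), read_noise_sd = 0,
                  poisson_noise = FALSE)
  e <- generate_embryo(p)
  seg1 <- segment_granules(e$granule, fast_cfg())
  scaled <- image_stack(e$granule$voxels * 11, channel = "granule")
  seg2 <- segment_granules(scaled, fast_cfg())
  expect_identical(seg1$labels, seg2$labels)
})

test_that("the manual threshold fallback rescues a flat marker channel", {
  st <- image_stack(array(7, c(4, 40, 40)), channel = "granule")
  expect_error(segment_granules(st, fast_cfg()), "nothing to separate")
  seg <- segment_granules(st, fast_cfg(manual_granule_threshold = 100))
  expect_equal(nrow(seg$granules), 0L)
})
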