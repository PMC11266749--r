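# Background subtraction, candidate detection and Gaussian-mask fitting.

test_that("a flat background is removed completely", {
  st <- image_stack(array(37, c(3, 40, 40)))
  out <- subtract_background(st, 8)
  expect_true(all(out$voxels == 0))
})

test_that("a linear ramp does not perturb integrated spot intensities", {
  foci <- data.frame(z = c(6, 8), y = c(15.3, 30.2), x = c(20.7, 34.4),
                     n_molecules = c(1L, 1L))
  flat <- render_stack(foci, dim = c(16L, 48L, 48L))
  ramp <- flat
  ramp$voxels <- ramp$voxels +
    aperm(array(rep(seq(0, 400, length.out = 48), each = 16 * 48),
                c(16, 48, 48)), c(1, 2, 3))
  fit_both <- function(st) {
    bs <- subtract_background(st, 10)
    vapply(seq_len(nrow(foci)), function(i)
      fit_gaussian_mask(bs, round(c(foci$z[i], foci$y[i], foci$x[i])))$intensity,
      numeric(1))
  }
  i_flat <- fit_both(flat)
  i_ramp <- fit_both(ramp)
  expect_true(all(abs(i_ramp / i_flat - 1) < 0.05))
})

test_that("background radius must fit the image plane", {
  st <- image_stack(array(1, c(2, 30, 30)))
  expect_error(subtract_background(st, 20), "exceeds the image plane")
  expect_error(subtract_background(st, 0), ">= 1")
})

test_that("candidate detection finds 3D maxima with deterministic order", {
  # noise-only image above threshold: nothing
  set.seed(11)
  noise <- image_stack(array(stats::rpois(8 * 40 * 40, 50), c(8, 40, 40)))
  expect_equal(nrow(detect_candidates(noise, threshold = 500)), 0L)
  # two spots 6 px apart survive min_separation 3
  foci <- data.frame(z = c(7, 7), y = c(20, 20), x = c(18, 24),
                     n_molecules = c(1L, 1L))
  st <- render_stack(foci)
  cand <- detect_candidates(st, 50, min_separation_px = 3)
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$intensity == sort(cand$intensity, decreasing = TRUE)))
  # a spot straddling a slice boundary is one 3D maximum, not one per slice
  st2 <- render_stack(data.frame(z = 7.5, y = 20, x = 20, n_molecules = 1L))
  expect_equal(nrow(detect_candidates(st2, 50, min_separation_px = 3)), 1L)
})

test_that("detection count is monotonically non-increasing in threshold", {
  e <- separated_embryo(13, n = 60, dim = c(16L, 96L, 96L))
  bs <- subtract_background(e$rna, 12)
  counts <- vapply(c(50, 120, 300, 800, 2000), function(thr)
    nrow(detect_candidates(bs, thr, 2)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Gaussian-mask fitting is accurate, symmetric and linear", {
  # sub-pixel truth recovered within 0.05 px, intensity within 2%
  st <- render_stack(data.frame(z = 5.0, y = 20.4, x = 31.7, n_molecules = 1L),
                     dim = c(12L, 48L, 48L))
  f <- fit_gaussian_mask(st, c(5, 20, 32))
  expect_lt(abs(f$z - 5.0), 0.05)
  expect_lt(abs(f$y - 20.4), 0.05)
  expect_lt(abs(f$x - 31.7), 0.05)
  expect_lt(abs(f$intensity / 5000 - 1), 0.02)
  # perfectly voxel-centred symmetric spot: fitted centre is that voxel
  st2 <- render_stack(data.frame(z = 6, y = 24, x = 24, n_molecules = 1L))
  f2 <- fit_gaussian_mask(st2, c(6, 24, 24))
  expect_equal(c(f2$z, f2$y, f2$x), c(6, 24, 24), tolerance = 1e-6)
  # doubling the amplitude doubles the integrated intensity within 1%
  st3 <- render_stack(data.frame(z = 6, y = 24.3, x = 24.6, n_molecules = 2L))
  f3 <- fit_gaussian_mask(st3, c(6, 24, 25))
  f1 <- fit_gaussian_mask(render_stack(
    data.frame(z = 6, y = 24.3, x = 24.6, n_molecules = 1L)), c(6, 24, 25))
  expect_lt(abs(f3$intensity / (2 * f1$intensity) - 1), 0.01)
})

test_that("intensity estimates are phase-invariant within 2%", {
  ints <- vapply(seq(0, 0.9, by = 0.15), function(off) {
    st <- render_stack(data.frame(z = 6 + off / 3, y = 20 + off, x = 25 - off,
                                  n_molecules = 1L))
    fit_gaussian_mask(st, c(6, 20, 25))$intensity
  }, numeric(1))
  expect_lt(max(abs(ints / 5000 - 1)), 0.02)
})

test_that("localization is equivariant under integer voxel shifts", {
  base <- data.frame(z = 6.2, y = 18.6, x = 17.4, n_molecules = 1L)
  shifted <- base; shifted$z <- base$z + 2; shifted$y <- base$y + 5
  shifted$x <- base$x + 7
  f0 <- fit_gaussian_mask(render_stack(base), c(6, 19, 17))
  f1 <- fit_gaussian_mask(render_stack(shifted), c(8, 24, 24))
  expect_equal(c(f1$z - f0$z, f1$y - f0$y, f1$x - f0$x), c(2, 5, 7),
               tolerance = 1e-3)
})

test_that("detect_spots is deterministic and recovers separated foci", {
  e <- separated_embryo(17, n = 100)
  cfg <- fast_cfg()
  sp1 <- detect_spots(e$rna, cfg, roi = e$roi)
  sp2 <- detect_spots(e$rna, cfg, roi = e$roi)
  expect_identical(sp1, sp2)
  m <- match_to_truth(sp1, e$truth$foci)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
  expect_true(all(sp1$lineage == "P2"))
})

test_that("an all-zero stack yields an empty spot table", {
  st <- image_stack(array(0, c(6, 40, 40)))
  expect_equal(nrow(detect_spots(st, fast_cfg())), 0L)
})
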