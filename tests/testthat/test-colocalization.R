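# Cube membership, cluster pairing and granule content summaries.

cube_df <- function(z, y, x, hz, hy = hz, hx = hy, id = seq_along(z)) {
  data.frame(granule_id = id, z = z, y = y, x = x,
             half_z = hz, half_y = hy, half_x = hx)
}
pts <- function(z, y, x, n = 1L, id = seq_along(z)) {
  data.frame(id = id, z = z, y = y, x = x, n_molecules = n)
}

test_that("cube membership is inclusive with nearest-centroid tie-breaking", {
  cubes <- cube_df(z = c(10, 10), y = c(10, 16), x = c(10, 10), hz = 4)
  expect_equal(spot_in_granule(pts(10, 10, 10), cubes), 1L)   # at a centroid
  expect_equal(spot_in_granule(pts(10, 10, 15), cubes), NA_integer_)  # 1 px out
  expect_equal(spot_in_granule(pts(10, 10, 14), cubes), 1L)   # on the face
  # inside both cubes: nearer centroid wins
  expect_equal(spot_in_granule(pts(10, 12.9, 10), cubes), 1L)
  expect_equal(spot_in_granule(pts(10, 13.1, 10), cubes), 2L)
  # exact midpoint: lower granule_id
  expect_equal(spot_in_granule(pts(10, 13, 10), cubes), 1L)
})

test_that("molecule percentages are molecule-weighted", {
  cubes <- cube_df(10, 10, 10, hz = 3)
  inside4 <- pts(10, 10, 10, n = 4L)
  outside <- pts(c(2, 2, 2, 2), c(30, 31, 32, 33), c(30, 30, 30, 30),
                 n = 1L, id = 2:5)
  expect_equal(pct_molecules_in_granules(rbind(inside4, outside), cubes), 50)
  expect_equal(pct_molecules_in_granules(inside4, cubes), 100)
  expect_error(pct_molecules_in_granules(inside4[0, ], cubes), "empty")
})

test_that("membership and pairing match brute-force oracles on random scenes", {
  set.seed(61)
  for (scene in 1:12) {
    ng <- sample(3:10, 1)
    cubes <- cube_df(z = runif(ng, 0, 20), y = runif(ng, 0, 60),
                     x = runif(ng, 0, 60), hz = runif(ng, 2, 5),
                     hy = runif(ng, 3, 6), hx = runif(ng, 3, 6))
    ns <- sample(10:40, 1)
    sp <- pts(runif(ns, 0, 20), runif(ns, 0, 60), runif(ns, 0, 60))
    expect_identical(spot_in_granule(sp, cubes), oracle_spot_in_granule(sp, cubes))
    na <- sample(5:15, 1); nb <- sample(5:15, 1)
    a <- pts(runif(na, 0, 10), runif(na, 0, 25), runif(na, 0, 25))
    b <- pts(runif(nb, 0, 10), runif(nb, 0, 25), runif(nb, 0, 25))
    got <- cluster_colocalization(a, b)
    want <- oracle_cluster_pairs(a, b)
    expect_equal(nrow(got$pairs), nrow(want))
    if (nrow(want)) {
      expect_identical(got$pairs$a_id, as.integer(want[, 1]))
      expect_identical(got$pairs$b_id, as.integer(want[, 2]))
    }
    # symmetry: the unordered pair set is the same from (B, A)
    rev <- cluster_colocalization(b, a)
    expect_identical(got$pairs$a_id[order(got$pairs$a_id)],
                     rev$pairs$b_id[order(rev$pairs$b_id)])
  }
})

test_that("pairing respects the all-axes tolerance rule", {
  a <- pts(5, 10, 10)
  expect_equal(nrow(cluster_colocalization(a, pts(5, 10, 10))$pairs), 1L)
  expect_equal(nrow(cluster_colocalization(a, pts(5, 13, 10))$pairs), 0L)
  expect_equal(nrow(cluster_colocalization(a, pts(5, 12, 12))$pairs), 1L)
  res <- cluster_colocalization(a, pts(8, 10, 10))
  expect_equal(res$pct_a_not_colocalized, 100)
})

test_that("only cluster-flagged rows participate when the flag is present", {
  a <- pts(c(5, 5), c(10, 20), c(10, 20)); a$is_cluster <- c(TRUE, FALSE)
  b <- pts(c(5, 5), c(10, 20), c(10, 20)); b$is_cluster <- c(TRUE, TRUE)
  res <- cluster_colocalization(a, b)
  expect_equal(res$n_clusters_a, 1L)
  expect_equal(nrow(res$pairs), 1L)
})

test_that("granule content partitions into A/B/both/neither", {
  cubes <- cube_df(z = rep(10, 10), y = 10 * (1:10), x = rep(10, 10), hz = 2)
  # hand-placed: granules 1,2 get A; 2,3 get B; others empty
  a <- pts(c(10, 10), c(10, 20), c(10, 10))
  b <- pts(c(10, 10), c(20, 30), c(10, 10))
  out <- granule_content_summary(cubes, a, b)
  counts <- stats::setNames(out$n_granules, out$category)
  expect_equal(unname(counts[c("a_only", "b_only", "both", "neither")]),
               c(1L, 1L, 1L, 7L))
  expect_equal(sum(out$n_granules), 10L)
  expect_equal(sum(out$pct), 100)
  none <- granule_content_summary(cubes, a[0, ], b[0, ])
  expect_equal(none$pct[none$category == "neither"], 100)
  one <- granule_content_summary(cubes[1, ], a[1, ], pts(10, 10, 10))
  expect_equal(one$pct[one$category == "both"], 100)
})

test_that("granule membership is monotone in the cube pad", {
  e <- generate_embryo(sim_params(rng_seed = 62, n_molecules = 150,
                                  p_granule = 0.3, n_granules = 6,
                                  granule_channel = FALSE,
                                  dim = c(16L, 80L, 80L)))
  sp <- e$truth$foci
  sp$n_molecules <- sp$n_molecules
  pcts <- vapply(c(0, 1, 2, 4), function(pad)
    pct_molecules_in_granules(sp, granule_bounding_cube(e$truth$granules, pad)),
    numeric(1))
  expect_true(all(diff(pcts) >= 0))
})
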