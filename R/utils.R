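# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulations do not disturb the
#' caller's RNG stream. With `seed = NULL` the expression runs on the current
#' stream.
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage log line on stderr; every pipeline stage funnels through this.
gf_log <- function(fmt, ...) {
  message(sprintf("[granulefish %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

# Pixel-integrated Gaussian mass on unit-width voxels centred at integer
# coordinates `idx` (0-based), for a Gaussian centred at `mu` with sd `sigma`.
# Voxel i spans [i - 0.5, i + 0.5]; masses over all Z sum to 1.
gauss_mass_1d <- function(idx, mu, sigma) {
  stats::pnorm((idx + 0.5 - mu) / sigma) - stats::pnorm((idx - 0.5 - mu) / sigma)
}

# Separable Gaussian blur of a (z, y, x) array; sigma is per-axis in voxel
# units, radius 3*sigma, truncated kernels renormalized at the borders.
gaussian_blur <- function(voxels, sigma) {
  stopifnot(length(dim(voxels)) == 3L)
  sigma <- rep_len(as.numeric(sigma), 3L)
  out <- voxels
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- dim(out)[ax]
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      w <- k[ok]
      K[i, j[ok]] <- w / sum(w)
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    d <- dim(a)
    a <- K %*% matrix(a, nrow = d[1])
    dim(a) <- d
    out <- aperm(a, order(perm))
  }
  out
}

# round() uses banker's rounding; the pipeline's documented tie rule is
# half-up, which this implements for non-negative x.
round_half_up <- function(x) floor(x + 0.5)

# Greedy non-maximum suppression. `coords` is an n x 3 matrix (z, y, x)
# already ordered by priority (highest first); returns logical keep vector.
# A point is dropped when within `radius` of an already-kept point under
# `metric` ("chebyshev" or "euclidean", strict inequality).
nms_keep <- function(coords, radius, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  n <- nrow(coords)
  keep <- logical(n)
  if (n == 0L) return(keep)
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0L) { keep[i] <- TRUE; kept <- coords[i, , drop = FALSE]; next }
    d <- abs(sweep(kept, 2, coords[i, ]))
    dist <- if (metric == "chebyshev") apply(d, 1, max) else sqrt(rowSums(d^2))
    if (all(dist >= radius)) { keep[i] <- TRUE; kept <- rbind(kept, coords[i, ]) }
  }
  keep
}
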