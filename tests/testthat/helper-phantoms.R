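# Small shared fixtures; built once per test run.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), spacing_mm = 4, ...)
}

# cached small supine phantom used by several test files
cached_phantom <- local({
  env <- new.env()
  function(key = "supine", ...) {
    if (is.null(env[[key]])) env[[key]] <- generate_phantom(small_spec(...))
    env[[key]]
  }
})

# independent brute-force Wilcoxon signed-rank p-value over all 2^n sign
# assignments (mid-ranks on |d|)
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  Wall <- signs %*% r
  mean(abs(Wall) >= abs(W) - 1e-9)
}

# independent finite-difference Jacobian at one voxel by cofactor expansion
fd_jacobian_at <- function(field, spacing, i, j, k) {
  d <- dim(field)
  g <- matrix(0, 3, 3)  # g[cc, ax] = d u_cc / d ax
  for (ax in 1:3) for (cc in 1:3) {
    idx <- c(i, j, k)
    if (idx[ax] > 1 && idx[ax] < d[ax]) {
      hi <- idx; hi[ax] <- hi[ax] + 1
      lo <- idx; lo[ax] <- lo[ax] - 1
      g[cc, ax] <- (field[hi[1], hi[2], hi[3], cc] -
                    field[lo[1], lo[2], lo[3], cc]) / (2 * spacing[ax])
    } else {
      hi <- idx; lo <- idx
      if (idx[ax] == 1) hi[ax] <- 2 else lo[ax] <- d[ax] - 1
      g[cc, ax] <- (field[hi[1], hi[2], hi[3], cc] -
                    field[lo[1], lo[2], lo[3], cc]) / spacing[ax]
    }
  }
  m <- diag(3) + g
  # cofactor expansion along the first row
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
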