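# Shared numeric helpers: seeded evaluation, separable array resampling,
# FFT Gaussian smoothing, block down/upsampling for the multiresolution
# field estimator.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Resample img along peAxis at positions x + d(x) (linear interpolation,
# edge-clamped). d is a scalar or an array of img's shape, in voxels.
# With jacobian = TRUE the result is modulated by (1 + dd/dx), clipped at 0,
# which preserves integrated intensity under smooth compressions.
# Works for numeric and complex arrays.
resamplePE <- function(img, d, peAxis = 2L, jacobian = FALSE) {
  dm <- dim(img)
  perm <- c(peAxis, setdiff(seq_along(dm), peAxis))
  A <- aperm(img, perm)
  pdm <- dim(A)
  n <- pdm[1]; m <- prod(pdm[-1])
  dim(A) <- c(n, m)
  D <- if (length(d) == 1L) matrix(as.numeric(d), n, m) else {
    Dp <- aperm(d, perm); dim(Dp) <- c(n, m); Dp
  }
  s <- matrix(seq_len(n), n, m) + D
  s <- pmin(pmax(s, 1), n)
  i0 <- pmin(floor(s), n - 1)
  w <- s - i0
  off <- matrix((seq_len(m) - 1L) * n, n, m, byrow = TRUE)
  out <- A[i0 + off] * (1 - w) + A[i0 + 1 + off] * w
  if (jacobian) {
    dd <- D
    if (n > 2) dd[2:(n - 1), ] <- (D[3:n, , drop = FALSE] -
                                   D[1:(n - 2), , drop = FALSE]) / 2
    dd[1, ] <- D[2, ] - D[1, ]
    dd[n, ] <- D[n, ] - D[n - 1, ]
    out <- out * pmax(1 + dd, 0)
  }
  dim(out) <- pdm
  aperm(out, order(perm))
}

# central-difference derivative along peAxis (one-sided at the edges)
diffPE <- function(a, peAxis = 2L) {
  dm <- dim(a)
  perm <- c(peAxis, setdiff(seq_along(dm), peAxis))
  A <- aperm(a, perm)
  pdm <- dim(A); n <- pdm[1]
  dim(A) <- c(n, prod(pdm[-1]))
  g <- A
  if (n > 2) g[2:(n - 1), ] <- (A[3:n, , drop = FALSE] -
                                A[1:(n - 2), , drop = FALSE]) / 2
  g[1, ] <- A[2, ] - A[1, ]
  g[n, ] <- A[n, ] - A[n - 1, ]
  dim(g) <- pdm
  aperm(g, order(perm))
}

# Gaussian smoothing of a 3-D array via FFT (periodic boundaries); sigma in
# voxels, scalar or per-axis.
gaussSmooth3D <- function(a, sigma) {
  dm <- dim(a)
  sigma <- rep_len(sigma, 3)
  tf <- lapply(1:3, function(ax) {
    n <- dm[ax]
    k <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))
    if (n == 1) k <- 0
    w <- 2 * pi * k / n
    exp(-0.5 * sigma[ax]^2 * w^2)
  })
  H <- outer(outer(tf[[1]], tf[[2]]), tf[[3]])
  dim(H) <- dm
  Re(stats::fft(stats::fft(a) * H, inverse = TRUE)) / prod(dm)
}

# average consecutive groups of f along the first axis
fold1 <- function(a, f) {
  dm <- dim(a)
  v <- colMeans(matrix(as.numeric(a), nrow = f))
  array(v, c(dm[1] / f, dm[2], dm[3]))
}

# downsample a 3-D array by integer factor f (block mean)
blockMean <- function(a, f) {
  if (f == 1) return(a)
  stopifnot(all(dim(a) %% f == 0))
  a <- fold1(a, f)
  a <- aperm(fold1(aperm(a, c(2, 1, 3)), f), c(2, 1, 3))
  aperm(fold1(aperm(a, c(3, 2, 1)), f), c(3, 2, 1))
}

# linear upsampling of the first axis to length N (cell-centered)
linUp1 <- function(a, N) {
  dm <- dim(a); n <- dm[1]
  A <- matrix(as.numeric(a), n, prod(dm[-1]))
  x <- (seq_len(N) - 0.5) * n / N + 0.5
  x <- pmin(pmax(x, 1), n)
  i0 <- pmin(floor(x), n - 1); w <- x - i0
  out <- A[i0, , drop = FALSE] * (1 - w) + A[i0 + 1, , drop = FALSE] * w
  array(out, c(N, dm[-1]))
}

# trilinear upsampling to a target 3-D shape
upsample3 <- function(a, target) {
  a <- linUp1(a, target[1])
  a <- aperm(linUp1(aperm(a, c(2, 1, 3)), target[2]), c(2, 1, 3))
  aperm(linUp1(aperm(a, c(3, 2, 1)), target[3]), c(3, 2, 1))
}

# circular shift along one axis
circShift <- function(a, by, axis) {
  dm <- dim(a)
  idx <- lapply(dm, seq_len)
  n <- dm[axis]
  idx[[axis]] <- ((seq_len(n) - 1 - by) %% n) + 1
  do.call(`[`, c(list(a), idx))
}
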