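# Independent numerical oracles used across the suite. These deliberately
# re-derive the quantities they check from first principles (brute-force
# integration, Monte-Carlo sampling, direct resampling with stats::approx)
# without touching the package's internal kernels.

# Brute-force forward-Euler Bloch integrator (step dt ms). The free
# relaxation between pulses is the Euler recursion
#   m <- m + dt * (1 - m) / t1
# whose n-step composition is evaluated in closed form,
#   m_n = 1 + (m_0 - 1) * (1 - dt/t1)^n,
# which is algebraically identical to running the n steps one by one
# (checked below at small n by eulerRelaxLoop). Returns the mz-before-pulse
# vector of the final cycle.
eulerIROracle <- function(p, t1, b1 = 1, dt = 0.01, nCycles = 30) {
  n <- p@shotsPerTiBlock
  offs <- (seq_len(n) - (n + 1) / 2) * p@trShot
  times <- c(p@ti1 + offs, p@ti2 + offs)
  alpha <- rep(c(p@fa1, p@fa2), each = n) * b1 * pi / 180
  relax <- function(m, T) {
    ns <- floor(T / dt); r <- T - ns * dt
    m <- 1 + (m - 1) * (1 - dt / t1)^ns
    m + r * (1 - m) / t1
  }
  m <- 1; eff <- p@inversionEfficiency
  mzB <- numeric(length(times))
  for (cy in seq_len(nCycles)) {
    m <- -eff * m
    tprev <- 0
    for (j in seq_along(times)) {
      m <- relax(m, times[j] - tprev); tprev <- times[j]
      mzB[j] <- m
      m <- m * cos(alpha[j])
    }
    m <- relax(m, p@trIR - tprev)
  }
  mzB
}

# literal step-by-step Euler relaxation, for validating the closed form
eulerRelaxLoop <- function(m, T, t1, dt = 0.01) {
  ns <- floor(T / dt)
  for (k in seq_len(ns)) m <- m + dt * (1 - m) / t1
  m + (T - ns * dt) * (1 - m) / t1
}

# Monte-Carlo SD of the contrast under iid Gaussian noise on both signals
mcContrastSD <- function(sGm, sWm, sigma, n = 1e6, seed = 99) {
  set.seed(seed)
  a <- sGm + stats::rnorm(n, 0, sigma)
  b <- sWm + stats::rnorm(n, 0, sigma)
  stats::sd((a - b) / (abs(a) + abs(b)))
}

# Independent PE-axis resampler built on stats::approx (sample at x + d,
# edge rule 2), optionally with Jacobian modulation from finite differences.
approxResamplePE <- function(img, d, peAxis = 2L, jacobian = FALSE) {
  dm <- dim(img)
  out <- array(NA_real_, dm)
  idx <- seq_len(dm[peAxis])
  dArr <- if (length(d) == 1) array(d, dm) else d
  ii <- expand.grid(a = seq_len(dm[1]), c = seq_len(dm[3]))
  for (k in seq_len(nrow(ii))) {
    line <- img[ii$a[k], , ii$c[k]]
    dl <- dArr[ii$a[k], , ii$c[k]]
    v <- stats::approx(idx, line, xout = pmin(pmax(idx + dl, 1), dm[peAxis]),
                       rule = 2)$y
    if (jacobian) {
      gr <- c(dl[2] - dl[1], (dl[-(1:2)] - dl[seq_len(dm[peAxis] - 2)]) / 2,
              dl[dm[peAxis]] - dl[dm[peAxis] - 1])
      v <- v * pmax(1 + gr, 0)
    }
    out[ii$a[k], , ii$c[k]] <- v
  }
  out
}

rmseOf <- function(a, b) sqrt(mean((a - b)^2))
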