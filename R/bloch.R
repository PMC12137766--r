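# Forward Bloch model for the two-inversion Look-Locker 3D-EPI cycle.
#
# One inversion-recovery (IR) period of duration trIR:
#   t = 0        adiabatic inversion        Mz -> -eff * Mz
#   TI1 block    shotsPerTiBlock excitations at flip b1 * fa1, spacing trShot,
#                centered on ti1
#   TI2 block    same, flip b1 * fa2, centered on ti2
#   free T1 relaxation Mz(t+D) = m0 + (Mz(t) - m0) exp(-D/t1) between events
# Each excitation reads mxy = Mz sin(a) and leaves Mz cos(a) (perfect
# spoiling). Cycles are chained until steady state. Relaxation between events
# is evaluated in closed form (exact exponential segments), not by ODE
# integration.

# Event schedule of one IR cycle: times (ms since inversion), block id.
irEventSchedule <- function(p) {
  n <- p@shotsPerTiBlock
  offs <- (seq_len(n) - (n + 1) / 2) * p@trShot
  list(times = c(p@ti1 + offs, p@ti2 + offs),
       block = rep(1:2, each = n))
}

# Vectorized steady-state engine. t1, m0, fa1, fa2, b1 are recycled to a
# common length M; per event the state is a length-M vector. Returns
# mzBefore and mxy as (events x M) matrices in fraction-of-m0 units, for the
# last simulated cycle, plus per-cycle bookkeeping.
irSteadyEngine <- function(p, t1, m0 = 1, fa1 = p@fa1, fa2 = p@fa2, b1 = 1,
                           nCycles = 50L, tol = 1e-9, mz0 = 1) {
  M <- max(length(t1), length(m0), length(fa1), length(fa2), length(b1))
  t1 <- rep_len(t1, M); m0 <- rep_len(m0, M)
  fa1 <- rep_len(fa1, M); fa2 <- rep_len(fa2, M); b1 <- rep_len(b1, M)
  sched <- irEventSchedule(p)
  nE <- length(sched$times)
  alpha <- matrix(0, nE, M)  # radians, event x combo
  alpha[sched$block == 1L, ] <- rep(b1 * fa1 * pi / 180, each = sum(sched$block == 1L))
  alpha[sched$block == 2L, ] <- rep(b1 * fa2 * pi / 180, each = sum(sched$block == 2L))
  sinA <- sin(alpha); cosA <- cos(alpha)
  # decay factors per inter-event gap (event x combo)
  gaps <- diff(c(0, sched$times))
  decay <- exp(-outer(gaps, t1, "/"))
  tailDecay <- exp(-(p@trIR - sched$times[nE]) / t1)
  eff <- p@inversionEfficiency
  mz <- rep_len(mz0, M)  # fraction of m0
  mzBefore <- mxy <- matrix(NA_real_, nE, M)
  prev <- NULL; converged <- FALSE; cyc <- 0L
  while (cyc < nCycles) {
    cyc <- cyc + 1L
    mz <- -eff * mz
    for (j in seq_len(nE)) {
      mz <- 1 + (mz - 1) * decay[j, ]
      mzBefore[j, ] <- mz
      mxy[j, ] <- mz * sinA[j, ]
      mz <- mz * cosA[j, ]
    }
    mz <- 1 + (mz - 1) * tailDecay
    if (!is.null(prev) && max(abs(mzBefore - prev)) < tol) {
      converged <- TRUE
      break
    }
    prev <- mzBefore
  }
  list(times = sched$times, block = sched$block, mzBefore = mzBefore,
       mxy = mxy, m0 = m0, cycles = cyc, converged = converged)
}

#' Simulate the inversion-recovery cycle to steady state
#'
#' Chains IR cycles of the two-block Look-Locker readout until two
#' consecutive cycles agree to within \code{tol} (or \code{nCycles} is
#' exhausted, in which case the result carries \code{converged = FALSE}
#' with a warning). Returns the event-wise trajectory of the final cycle:
#' the saw-tooth of Mz sampled just before each excitation, and the
#' transverse signal each excitation creates.
#'
#' @param p a validated [ProtocolParams-class]
#' @param tissue a [TissueParams-class] (or its T1 in ms)
#' @param b1Scale relative transmit field; realized flip angles are
#'   \code{b1Scale * fa1} and \code{b1Scale * fa2}
#' @param nCycles maximum number of IR cycles to chain
#' @param tol steady-state tolerance on Mz (fraction of m0)
#' @param mz0 initial longitudinal magnetization, fraction of m0
#' @return an [MzTrajectory-class]
#' @examples
#' traj <- simulateIRCycles(retrospectiveProtocol(), tissueParams("GM", 1900))
#' traj
#' @export
simulateIRCycles <- function(p, tissue, b1Scale = 1, nCycles = 50L,
                             tol = 1e-9, mz0 = 1) {
  validateProtocol(p)
  if (is.numeric(tissue)) tissue <- tissueParams("tissue", tissue)
  stopifnot(is(tissue, "TissueParams"), b1Scale > 0, nCycles >= 1)
  e <- irSteadyEngine(p, t1 = tissue@t1, m0 = tissue@m0, b1 = b1Scale,
                      nCycles = as.integer(nCycles), tol = tol, mz0 = mz0)
  if (!e$converged)
    warning("steady state not reached within ", nCycles, " cycles")
  new("MzTrajectory", times = e$times, mzBefore = as.numeric(e$mzBefore),
      mxy = as.numeric(e$mxy), block = e$block,
      cycleIndex = e$cycles, converged = e$converged)
}

# index of the shot acquiring the k-space center within a block of n shots
kCenterShot <- function(n) as.integer(floor(n / 2) + 1)

#' Steady-state signals at the two inversion times
#'
#' Runs [simulateIRCycles()] to steady state and picks, within each TI
#' block, the transverse signal of the shot that acquires the k-space
#' center (the middle shot under linear segment ordering). Signals are
#' signed and in m0 units, so they scale linearly with the tissue's m0.
#'
#' @inheritParams simulateIRCycles
#' @return a [SignalPair-class]
#' @export
steadyStateSignals <- function(p, tissue, b1Scale = 1, nCycles = 50L,
                               tol = 1e-9) {
  if (is.numeric(tissue)) tissue <- tissueParams("tissue", tissue)
  traj <- simulateIRCycles(p, tissue, b1Scale, nCycles, tol)
  k <- kCenterShot(p@shotsPerTiBlock)
  i1 <- which(traj@block == 1L)[k]
  i2 <- which(traj@block == 2L)[k]
  new("SignalPair", s1 = tissue@m0 * traj@mxy[i1],
      s2 = tissue@m0 * traj@mxy[i2])
}

# Vectorized signal pairs for many (t1, m0, fa1, fa2, b1) combinations.
# Returns list(s1, s2) in m0 units. Used by the CNR grid search, lookup-table
# generation and the phantom forward simulator.
steadyStateSignalsGrid <- function(p, t1, m0 = 1, fa1 = p@fa1, fa2 = p@fa2,
                                   b1 = 1, nCycles = 50L, tol = 1e-9) {
  e <- irSteadyEngine(p, t1 = t1, m0 = m0, fa1 = fa1, fa2 = fa2, b1 = b1,
                      nCycles = nCycles, tol = tol)
  k <- kCenterShot(p@shotsPerTiBlock)
  i1 <- which(e$block == 1L)[k]
  i2 <- which(e$block == 2L)[k]
  list(s1 = e$m0 * e$mxy[i1, ], s2 = e$m0 * e$mxy[i2, ],
       converged = e$converged)
}

#' Compare two trajectories for steady state
#'
#' @param trajA,trajB consecutive [MzTrajectory-class] cycles from the same
#'   simulation
#' @param tol tolerance on the maximum absolute Mz difference
#' @return TRUE iff \code{max |mzBefore difference| < tol}
#' @export
steadyStateDetect <- function(trajA, trajB, tol = 1e-9) {
  stopifnot(is(trajA, "MzTrajectory"), is(trajB, "MzTrajectory"))
  if (length(trajA@mzBefore) != length(trajB@mzBefore))
    stop("trajectories have mismatched lengths")
  max(abs(trajA@mzBefore - trajB@mzBefore)) < tol
}

#' Constant-flip-angle pulse train (Look-Locker limit)
#'
#' Simulates a single train of \code{nPulses} identical excitations spaced
#' \code{tau} apart with the same relax-excite-spoil kernel used by
#' [simulateIRCycles()]. In this limit the per-shot magnetization before
#' excitation converges to the Look-Locker steady state
#' \code{m0 (1 - E) / (1 - E cos a)} with \code{E = exp(-tau/t1)}, at
#' apparent rate \code{1/T1* = 1/t1 - log(cos a)/tau}.
#'
#' @param t1 tissue T1 (ms)
#' @param fa flip angle (degrees)
#' @param tau pulse spacing (ms)
#' @param nPulses number of pulses
#' @param m0 equilibrium magnetization
#' @param mz0 starting Mz (fraction of m0; -1 mimics a preceding inversion)
#' @return list with per-pulse \code{mzBefore} and \code{mxy} (m0 units)
#' @seealso [lookLockerSteadyState()]
#' @export
simulatePulseTrain <- function(t1, fa, tau, nPulses, m0 = 1, mz0 = -1) {
  stopifnot(t1 > 0, tau > 0, nPulses >= 1)
  a <- fa * pi / 180
  E <- exp(-tau / t1)
  mz <- mz0
  mzBefore <- mxy <- numeric(nPulses)
  for (k in seq_len(nPulses)) {
    mz <- 1 + (mz - 1) * E
    mzBefore[k] <- mz
    mxy[k] <- mz * sin(a)
    mz <- mz * cos(a)
  }
  list(mzBefore = m0 * mzBefore, mxy = m0 * mxy)
}

#' Closed-form Look-Locker steady state and apparent rate
#'
#' For a constant train of flip-angle-\code{fa} pulses spaced \code{tau}:
#' the fixed point of the relax-excite recursion is
#' \code{m0 (1 - E)/(1 - E cos a)}, and transients decay with apparent
#' relaxation rate \code{1/T1* = 1/t1 - log(cos a)/tau}, which always
#' exceeds the free rate \code{1/t1} (spin-history driven saturation).
#'
#' @inheritParams simulatePulseTrain
#' @return for \code{lookLockerSteadyState}, the steady-state Mz before
#'   excitation (m0 units); for \code{lookLockerRate}, the apparent rate
#'   1/T1* in 1/ms
#' @export
lookLockerSteadyState <- function(t1, fa, tau, m0 = 1) {
  E <- exp(-tau / t1)
  m0 * (1 - E) / (1 - E * cos(fa * pi / 180))
}

#' @rdname lookLockerSteadyState
#' @export
lookLockerRate <- function(t1, fa, tau) {
  1 / t1 - log(cos(fa * pi / 180)) / tau
}

#' Construct tissue parameters
#'
#' @param name compartment label
#' @param t1 longitudinal relaxation time (ms)
#' @param m0 equilibrium magnetization (arbitrary units)
#' @return a [TissueParams-class]
#' @export
tissueParams <- function(name, t1, m0 = 1) {
  new("TissueParams", name = as.character(name), t1 = as.numeric(t1),
      m0 = as.numeric(m0))
}

#' @export
setMethod("show", "TissueParams", function(object) {
  cat(sprintf("TissueParams '%s': T1 = %g ms, M0 = %g\n",
              object@name, object@t1, object@m0))
})

#' @export
setMethod("show", "MzTrajectory", function(object) {
  cat(sprintf("MzTrajectory: %d excitations over [%g, %g] ms, cycle %d (%s)\n",
              length(object@times), min(object@times), max(object@times),
              object@cycleIndex,
              if (object@converged) "steady state" else "NOT converged"))
  cat(sprintf("  Mz before excitation in [%.4f, %.4f] (fraction of m0)\n",
              min(object@mzBefore), max(object@mzBefore)))
})

#' @export
setMethod("show", "SignalPair", function(object) {
  cat(sprintf("SignalPair: s1 = %.5f, s2 = %.5f (m0 units), ratio = %.5f\n",
              object@s1, object@s2, object@s1 / object@s2))
})

#' Signal accessors
#'
#' @param x a [SignalPair-class]
#' @return the signed steady-state signal at TI1 or TI2 (m0 units)
#' @export
s1 <- function(x) x@s1

#' @rdname s1
#' @export
s2 <- function(x) x@s2
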