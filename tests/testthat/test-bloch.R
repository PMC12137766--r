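test_that("first-cycle trajectory matches the closed-form inversion recovery
           when excitation vanishes", {
  # flip angles ~0: Mz(t) = 1 - 2 exp(-t/t1) after a perfect inversion
  p <- protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23,
                      trIR = 3097, fa1 = 1e-6, fa2 = 1e-6,
                      shotsPerTiBlock = 5L)
  t1 <- 1400
  traj <- suppressWarnings(simulateIRCycles(p, t1, nCycles = 1L))
  expect_false(traj@converged)
  expect_equal(traj@mzBefore, 1 - 2 * exp(-traj@times / t1), tolerance = 1e-8)
  # zero crossing at t1 * ln 2
  pz <- protocolParams(ti1 = t1 * log(2), ti2 = 2368, te = 8, trShot = 23,
                       trIR = 3097, fa1 = 1e-6, fa2 = 1e-6)
  tz <- suppressWarnings(simulateIRCycles(pz, t1, nCycles = 1L))
  expect_lt(abs(tz@mzBefore[1]), 1e-8)
})

test_that("near-zero inversion efficiency turns the cycle into saturation
           recovery", {
  # the inversion maps Mz -> -eff * Mz, so eff ~ 0 nulls the longitudinal
  # magnetization and each cycle becomes 1 - exp(-t/t1) recovery
  p <- protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23,
                      trIR = 3097, fa1 = 1e-7, fa2 = 1e-7,
                      inversionEfficiency = 1e-7)
  traj <- simulateIRCycles(p, 1500)
  expect_equal(traj@mzBefore, 1 - exp(-traj@times / 1500),
               tolerance = 1e-5)
})

test_that("event-driven recursion agrees with a fine-step Euler integrator", {
  # the closed-form per-interval evaluation of the Euler recursion in the
  # oracle equals the literal step loop
  expect_equal(eulerRelaxLoop(-0.4, 37.77, 1300),
               1 + (-0.4 - 1) * (1 - 0.01 / 1300)^3777 +
                 (37.77 - 3777 * 0.01) *
                 (1 - (1 + (-0.4 - 1) * (1 - 0.01 / 1300)^3777)) / 1300,
               tolerance = 1e-12)
  p <- proto32()
  for (t1 in c(900, 1900)) {
    o <- eulerIROracle(p, t1)
    traj <- simulateIRCycles(p, t1)
    expect_lt(max(abs(traj@mzBefore - o)) / max(abs(o)), 1e-4)
  }
})

test_that("constant-flip-angle train converges to the Look-Locker fixed
           point at the analytic apparent rate", {
  for (t1 in c(800, 1400, 2200)) {
    st <- simulatePulseTrain(t1, fa = 10, tau = 23, nPulses = 3000)
    ss <- lookLockerSteadyState(t1, fa = 10, tau = 23)
    expect_lt(abs(st$mzBefore[3000] - ss) / ss, 1e-9)
    dif <- st$mzBefore - ss
    rate <- -log(dif[101] / dif[100]) / 23
    expect_lt(abs(rate - lookLockerRate(t1, 10, 23)) /
              lookLockerRate(t1, 10, 23), 1e-9)
    # spin history accelerates apparent relaxation beyond the free rate
    expect_gt(rate, 1 / t1)
  }
})

test_that("frozen relaxation gives s1 = -sin(alpha) on the first cycle", {
  p <- singleShotProtocol()
  tis <- tissueParams("frozen", 1e9)
  traj <- suppressWarnings(simulateIRCycles(p, tis, nCycles = 1L))
  expect_equal(traj@mxy[1], -sin(10 * pi / 180), tolerance = 1e-5)
})

test_that("steady-state signals separate T1s and respect m0 linearity and
           the B1/flip-angle equivalence", {
  p <- proto32()
  sa <- steadyStateSignals(p, tissueParams("a", 1900))
  sb <- steadyStateSignals(p, tissueParams("b", 1200))
  expect_false(isTRUE(all.equal(c(s1(sa), s2(sa)), c(s1(sb), s2(sb)))))
  expect_false(isTRUE(all.equal(s1(sa) / s2(sa), s1(sb) / s2(sb))))
  # linear in m0
  s2x <- steadyStateSignals(p, tissueParams("a", 1900, m0 = 2))
  expect_equal(c(s1(s2x), s2(s2x)), 2 * c(s1(sa), s2(sa)), tolerance = 1e-12)
  # halving B1 equals halving both flip angles
  ph <- protocolParams(ti1 = p@ti1, ti2 = p@ti2, te = p@te,
                       trShot = p@trShot, trIR = p@trIR, fa1 = p@fa1 / 2,
                       fa2 = p@fa2 / 2, shotsPerTiBlock = p@shotsPerTiBlock)
  sHalf <- steadyStateSignals(p, tissueParams("a", 1900), b1Scale = 0.5)
  sEq <- steadyStateSignals(ph, tissueParams("a", 1900))
  expect_equal(c(s1(sHalf), s2(sHalf)), c(s1(sEq), s2(sEq)),
               tolerance = 1e-12)
})

test_that("steady state is reached, detected, and independent of the
           starting magnetization", {
  p <- retrospectiveProtocol()
  tis <- tissueParams("GM", 1900)
  # cycle 1 vs cycle 2 of a slow tissue are not yet converged
  c1 <- suppressWarnings(simulateIRCycles(p, tis, nCycles = 1L, tol = 0))
  c2 <- suppressWarnings(simulateIRCycles(p, tis, nCycles = 2L, tol = 0))
  expect_false(steadyStateDetect(c1, c2))
  # cycles 20 vs 21 agree to 1e-9
  c20 <- suppressWarnings(simulateIRCycles(p, tis, nCycles = 20L, tol = 0))
  c21 <- suppressWarnings(simulateIRCycles(p, tis, nCycles = 21L, tol = 0))
  expect_true(steadyStateDetect(c20, c21, tol = 1e-9))
  expect_true(steadyStateDetect(c20, c20))
  # different initial Mz converge to the same trajectory
  a <- simulateIRCycles(p, tis, mz0 = 1)
  b <- simulateIRCycles(p, tis, mz0 = -0.3)
  expect_lt(max(abs(a@mzBefore - b@mzBefore)), 1e-8)
  # mismatched lengths error
  cS <- simulateIRCycles(singleShotProtocol(), tis)
  expect_error(steadyStateDetect(c20, cS), "mismatch")
})
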