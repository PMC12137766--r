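test_that("identical inputs yield a near-zero field and swapping the pair
           negates it", {
  ph <- phantom32()
  p <- proto32()
  img <- Mod(simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0,
                                 rippleAmp = 0)@data)
  f0 <- estimateField(img, img)
  expect_lt(max(abs(f0@d)), 0.05)
  vp <- Mod(simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  vn <- Mod(simulateAcquisition(ph, p, 1, -1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  fwd <- estimateField(vp, vn)
  swp <- estimateField(vn, vp)
  expect_lt(max(abs(swp@d + fwd@d)), 0.05)
})

test_that("estimation recovers the simulator's ground-truth field and
           reduces the pair dissimilarity", {
  p <- demoProtocol(c(64, 64, 64))
  ph <- makePhantom(c(64, 64, 64), seed = 3, blobAmpHz = 30)
  vp <- Mod(simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  vn <- Mod(simulateAcquisition(ph, p, 1, -1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  f <- estimateField(vp, vn, effEsp = effectiveEchoSpacing(p))
  dTrue <- ph@b0Map * (effectiveEchoSpacing(p) / 1000) * 64
  msk <- brainMask(ph)
  expect_lt(rmseOf(f@d[msk], dTrue[msk]), 0.3)
  # the estimated field explains the pair better than no field at all
  ssd <- epiT1:::fieldSSD
  expect_lt(ssd(vp, vn, f@d, 2L), ssd(vp, vn, array(0, dim(vp)), 2L))
})

test_that("field estimation is equivariant under in-plane translation
           perpendicular to the phase-encode axis", {
  ph <- phantom32()
  p <- proto32()
  vp <- Mod(simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  vn <- Mod(simulateAcquisition(ph, p, 1, -1, 2, ghostAmp = 0,
                                rippleAmp = 0)@data)
  f <- estimateField(vp, vn)
  sh <- 4L  # multiple of every pyramid factor
  fs <- estimateField(epiT1:::circShift(vp, sh, 1L),
                      epiT1:::circShift(vn, sh, 1L))
  expect_lt(max(abs(fs@d - epiT1:::circShift(f@d, sh, 1L))), 0.05)
})

test_that("field scaling is exact: identity, zero, and group property", {
  d <- array(stats::rnorm(4 * 4 * 4), c(4, 4, 4))
  f <- new("DisplacementField", d = d, peAxis = 2L, effEsp = 0.8,
           smoothness = 0.1, converged = TRUE)
  expect_identical(scaleField(f, 1)@d, d)
  expect_true(all(scaleField(f, 0)@d == 0))
  expect_equal(scaleField(scaleField(f, 2), 0.5)@d, d)
  expect_equal(scaleField(f, 2)@effEsp, 1.6)
})

test_that("applying fields: zero field is exact, constant field is an
           edge-padded shift, and warps approximately invert", {
  ph <- phantom32()
  p <- proto32()
  img <- epiT1:::idealImage(ph, p, 2L)
  dm <- dim(img)
  zero <- new("DisplacementField", d = array(0, dm), peAxis = 2L,
              effEsp = 1, smoothness = 0, converged = TRUE)
  expect_identical(applyField(img, zero, jacobian = FALSE), img)
  # constant +3: out(y) = img(y + 3), edge-padded
  c3 <- new("DisplacementField", d = array(3, dm), peAxis = 2L,
            effEsp = 1, smoothness = 0, converged = TRUE)
  out <- applyField(img, c3, jacobian = FALSE)
  expect_equal(out[, 1:(dm[2] - 3), ], img[, 4:dm[2], ])
  expect_equal(out[, dm[2] - 2, ], img[, dm[2], ])
  # smooth-field geometric round trip within 1% of the intensity range
  # (without Jacobian modulation, which negation does not invert); linear
  # interpolation loss scales with image curvature, so the bound applies
  # to a smooth image, not the piecewise-constant phantom edges
  smoothImg <- epiT1:::gaussSmooth3D(img, 1.5)
  dTrue <- ph@b0Map * (1 / 1000) * dm[2]
  fwd <- new("DisplacementField", d = dTrue, peAxis = 2L, effEsp = 1,
             smoothness = 0, converged = TRUE)
  rt <- applyField(applyField(smoothImg, fwd, jacobian = FALSE),
                   scaleField(fwd, -1), jacobian = FALSE)
  expect_lt(rmseOf(rt, smoothImg) / diff(range(smoothImg)), 0.01)
})

test_that("distortion-matched synthesis reproduces the acquired distortion
           level at the source spacing and at twice the spacing", {
  shape <- c(64, 64, 64)
  p <- demoProtocol(shape)
  ph <- makePhantom(shape, seed = 4, blobAmpHz = 30)
  mkMag <- function(prot, phase) Mod(simulateAcquisition(
    ph, prot, 1, phase, 2, ghostAmp = 0, rippleAmp = 0)@data)
  vp <- mkMag(p, 1); vn <- mkMag(p, -1)
  f <- estimateField(vp, vn, effEsp = effectiveEchoSpacing(p))
  corrected <- (applyField(vp, f) + applyField(vn, scaleField(f, -1))) / 2
  # target 0: unchanged corrected image
  expect_identical(synthesizeMatched(corrected, f, 0), corrected)
  # target = source spacing: reproduces the +PE acquisition
  re <- synthesizeMatched(corrected, f, effectiveEchoSpacing(p))
  expect_lt(rmseOf(re, vp) / diff(range(vp)), 0.02)
  # target = 2x: matches a fresh simulation at doubled echo spacing
  p2 <- protocolParams(ti1 = p@ti1, ti2 = p@ti2, te = p@te,
                       trShot = p@trShot, trIR = p@trIR, fa1 = p@fa1,
                       fa2 = p@fa2, matrixSize = p@matrixSize,
                       echoSpacing = 2 * p@echoSpacing,
                       shotsPerTiBlock = p@shotsPerTiBlock, tag = "2x")
  fresh2x <- mkMag(p2, 1)
  syn2x <- synthesizeMatched(corrected, f, effectiveEchoSpacing(p2))
  expect_lt(rmseOf(syn2x, fresh2x) / diff(range(fresh2x)), 0.03)
  expect_error(synthesizeMatched(corrected,
                                 new("DisplacementField", d = f@d,
                                     peAxis = 2L, effEsp = 0,
                                     smoothness = 0, converged = TRUE),
                                 0.35), "echo spacing")
})

test_that("fields round-trip through NIfTI + sidecar storage", {
  d <- array(stats::rnorm(32 * 32 * 32, sd = 0.5), c(32, 32, 32))
  f <- new("DisplacementField", d = d, peAxis = 2L, effEsp = 0.7,
           smoothness = 0.1, converged = TRUE)
  stem <- tempfile("field")
  writeField(f, stem)
  f2 <- readField(stem)
  expect_equal(f2@d, d, tolerance = 1e-6)
  expect_identical(f2@peAxis, 2L)
  expect_equal(f2@effEsp, 0.7)
  expect_true(f2@converged)
})
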