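test_that("phantom construction is deterministic with all compartments and
           a normalized depth map", {
  ph1 <- makePhantom(c(32, 32, 32), seed = 5)
  ph2 <- makePhantom(c(32, 32, 32), seed = 5)
  expect_identical(ph1@labels, ph2@labels)
  expect_identical(ph1@b0Map, ph2@b0Map)
  expect_identical(ph1@depthMap, ph2@depthMap)
  ph3 <- makePhantom(c(32, 32, 32), seed = 6)
  expect_false(identical(ph1@b0Map, ph3@b0Map))
  counts <- table(factor(makePhantom(c(64, 64, 64))@labels, levels = 0:3))
  expect_true(all(counts > 0))
  gm <- ph1@labels == 2L
  expect_equal(min(ph1@depthMap[gm]), 0)
  expect_equal(max(ph1@depthMap[gm]), 1)
  expect_true(all(ph1@b1Map >= 0.7 & ph1@b1Map <= 1.3))
  expect_error(makePhantom(c(16, 32, 32)), "at least 32")
})

test_that("acquisition equals the ideal image in the artifact-free limit", {
  ph <- phantom32()
  ph@b0Map[] <- 0
  p <- proto32()
  ideal <- epiT1:::idealImage(ph, p, 1L)
  for (rp in c(1, -1)) for (pp in c(1, -1)) {
    v <- simulateAcquisition(ph, p, rp, pp, whichTi = 1, noiseSigma = 0,
                             ghostAmp = 0, rippleAmp = 0)
    expect_equal(Re(v@data), ideal, tolerance = 1e-12)
    expect_equal(max(abs(Im(v@data))), 0)
  }
})

test_that("opposite phase polarities carry exactly opposite displacements,
           matching an independent resampling oracle", {
  ph <- phantom32()
  p <- proto32()
  ideal <- epiT1:::idealImage(ph, p, 2L)
  dTrue <- ph@b0Map * (effectiveEchoSpacing(p) / 1000) * dim(ph@labels)[2]
  vp <- simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0, rippleAmp = 0)
  vn <- simulateAcquisition(ph, p, 1, -1, 2, ghostAmp = 0, rippleAmp = 0)
  expP <- approxResamplePE(ideal, -dTrue, jacobian = TRUE)
  expN <- approxResamplePE(ideal, +dTrue, jacobian = TRUE)
  expect_equal(Re(vp@data), expP, tolerance = 1e-10)
  expect_equal(Re(vn@data), expN, tolerance = 1e-10)
})

test_that("distortion resampling conserves integrated intensity", {
  ph <- phantom32()
  p <- proto32()
  ideal <- epiT1:::idealImage(ph, p, 2L)
  v <- simulateAcquisition(ph, p, 1, 1, 2, ghostAmp = 0, rippleAmp = 0)
  expect_lt(abs(sum(Mod(v@data)) - sum(abs(ideal))) / sum(abs(ideal)),
            0.005)
})

test_that("ghost energy is zero without a ghost and scales linearly", {
  ph <- phantom32()
  p <- proto32()
  dm <- dim(ph@labels)
  shifted <- array(FALSE, dm)
  bm <- brainMask(ph)
  shifted[, c((dm[2] / 2 + 1):dm[2], 1:(dm[2] / 2)), ] <- bm
  roi <- shifted & !bm  # where only the wrapped ghost lands
  expect_gt(sum(roi), 100)
  energy <- function(g) {
    # the ghost is the only imaginary component of the simulated volume
    v <- simulateAcquisition(ph, p, 1, 1, 1, ghostAmp = g, rippleAmp = 0)
    sum(Im(v@data[roi])^2)
  }
  e0 <- energy(0)
  expect_equal(e0, 0)
  e1 <- energy(0.05); e2 <- energy(0.10)
  expect_gt(e1, 0)
  expect_equal(e2 / e1, 4, tolerance = 0.05)  # amplitude doubles, energy x4
})

test_that("a full session yields 8 deterministic volumes over the 4
           polarity combinations with consistent sidecar metadata", {
  ph <- phantom32()
  p <- proto32()
  s1 <- acquireFullSession(ph, p, noiseSigma = 0.003, seed = 11)
  expect_length(s1, 8)
  tags <- t(vapply(s1, function(v)
    c(v@readPolarity, v@phasePolarity, v@ti), numeric(3)))
  expect_equal(nrow(unique(tags)), 8)
  expect_equal(nrow(unique(tags[, 1:2])), 4)
  expect_true(all(vapply(s1, function(v) v@effEsp, 0) ==
                  effectiveEchoSpacing(p)))
  s2 <- acquireFullSession(ph, p, noiseSigma = 0.003, seed = 11)
  for (nm in names(s1)) expect_identical(s1[[nm]]@data, s2[[nm]]@data)
  s3 <- acquireFullSession(ph, p, noiseSigma = 0.003, seed = 12)
  expect_false(identical(s1[[1]]@data, s3[[1]]@data))
  # written session round-trips through NIfTI + sidecars
  dir <- tempfile("session")
  writeSession(s1, dir)
  expect_length(list.files(dir, pattern = "_real\\.nii\\.gz$"), 8)
  sc <- jsonlite::read_json(file.path(dir, "ti1_readpos_phasepos.json"),
                            simplifyVector = TRUE)
  expect_equal(sc$effective_echo_spacing_ms, effectiveEchoSpacing(p))
  re <- as.array(RNifti::readNifti(
    file.path(dir, "ti2_readneg_phaseneg_real.nii.gz")))
  expect_equal(array(as.numeric(re), dim(re)),
               Re(s1$ti2_readneg_phaseneg@data), tolerance = 1e-7)
})

test_that("the true T1 volume carries the injected laminar dip", {
  ph <- phantom32()
  plain <- trueT1Volume(ph)
  expect_equal(sort(unique(as.numeric(plain[!is.na(plain)]))),
               c(1200, 1900, 4000))
  dipped <- trueT1Volume(ph, dipDepth = 0.5, dipAmp = 100, dipWidth = 0.1)
  gm <- ph@labels == 2L
  mid <- gm & !is.na(ph@depthMap) & abs(ph@depthMap - 0.5) < 0.05
  expect_lt(max(dipped[mid]), 1850)
  expect_identical(dipped[ph@labels == 3L], plain[ph@labels == 3L])
})
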