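test_that("the two reference protocols validate and print their timings", {
  p1 <- retrospectiveProtocol()
  expect_s4_class(p1, "ProtocolParams")
  expect_equal(c(p1@ti1, p1@ti2, p1@te, p1@trShot, p1@trIR),
               c(930, 2368, 8, 23, 3097))
  expect_equal(c(p1@fa1, p1@fa2), c(10, 10))
  p2 <- acquisitionMatchedProtocol()
  expect_equal(c(p2@ti1, p2@ti2, p2@te, p2@trShot, p2@trIR),
               c(1378, 3793, 26, 78, 5050))
  expect_output(show(p1), "930/2368/8/23/3097")
})

test_that("validation errors name the offending field", {
  expect_error(protocolParams(ti1 = 930, ti2 = 930, te = 8, trShot = 23,
                              trIR = 3097, fa1 = 10, fa2 = 10), "ti2")
  expect_error(protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23,
                              trIR = 3097, fa1 = 0, fa2 = 10), "fa1")
  expect_error(protocolParams(ti1 = 930, ti2 = 2368, te = -1, trShot = 23,
                              trIR = 3097, fa1 = 10, fa2 = 10), "te")
  expect_error(protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23,
                              trIR = 2000, fa1 = 10, fa2 = 10), "trIR")
  # TI1 block must finish before TI2 begins
  expect_error(protocolParams(ti1 = 930, ti2 = 1000, te = 8, trShot = 23,
                              trIR = 3097, fa1 = 10, fa2 = 10,
                              shotsPerTiBlock = 27L), "shotsPerTiBlock")
})

test_that("effective echo spacing follows echoSpacing/(segments x R)", {
  mk <- function(seg, r, esp) protocolParams(
    ti1 = 930, ti2 = 2368, te = 8, trShot = 23, trIR = 3097, fa1 = 10,
    fa2 = 10, nSegments = seg, rInplane = r, echoSpacing = esp)
  expect_equal(effectiveEchoSpacing(mk(1L, 1L, 1.0)), 1.0)
  expect_equal(effectiveEchoSpacing(mk(2L, 2L, 1.0)), 0.25)
  # the acquisition-matched configuration realizes the 0.35 ms target
  expect_equal(effectiveEchoSpacing(acquisitionMatchedProtocol()), 0.35)
  # strictly decreasing in segments and R
  esp <- vapply(1:8, function(s) effectiveEchoSpacing(mk(s, 1L, 1.05)), 0)
  expect_true(all(diff(esp) < 0))
  espR <- vapply(1:8, function(r) effectiveEchoSpacing(mk(1L, r, 1.05)), 0)
  expect_true(all(diff(espR) < 0))
})

test_that("matchSegmentation is minimal, verified by brute force", {
  brute <- function(target, esp, r) {
    # tolerance so an exactly attainable target (e.g. 1.05/3 = 0.35) is
    # not rejected by the last binary digit
    for (n in 1:64) if (esp / (n * r) <= target * (1 + 1e-9)) return(n)
    NA_integer_
  }
  expect_identical(matchSegmentation(0.35, 1.05, 3L), brute(0.35, 1.05, 3))
  expect_identical(matchSegmentation(0.35, 1.05, 3L), 1L)
  expect_identical(matchSegmentation(0.35, 1.05, 1L), brute(0.35, 1.05, 1))
  expect_identical(matchSegmentation(0.35, 1.05, 1L), 3L)
  expect_identical(matchSegmentation(1.05, 1.05, 1L), 1L)
  set.seed(11)
  for (k in 1:25) {
    target <- runif(1, 0.05, 1.5); esp <- runif(1, 0.5, 2)
    r <- sample(1:4, 1)
    n <- matchSegmentation(target, esp, r)
    expect_identical(n, brute(target, esp, r))
    expect_lte(esp / (n * r), target * (1 + 1e-9))
    if (n > 1L) expect_gt(esp / ((n - 1) * r), target)
  }
  expect_error(matchSegmentation(0, 1.05, 1L), "targetEffEsp")
})

test_that("distortion scale factor is the ratio of effective echo spacings", {
  p <- acquisitionMatchedProtocol()  # effective 0.35 ms
  expect_equal(distortionScaleFactor(p, effectiveEchoSpacing(p)), 1.0)
  expect_equal(distortionScaleFactor(p, 0), 0.0)
  expect_equal(distortionScaleFactor(p, 0.7), 0.7 / 0.35)
})

test_that("scan duration reproduces the printed whole-brain range", {
  # degenerate single-cycle volume
  p1 <- protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23,
                       trIR = 3097, fa1 = 10, fa2 = 10,
                       matrixSize = c(64L, 64L, 4L), caipiDz = 4L,
                       shotsPerTiBlock = 1L)
  expect_equal(scanDuration(p1, 4L), 4 * 3097 / 1000)
  # both shipped protocols fall in the printed 3:00-3:40 min window
  expect_gte(scanDuration(retrospectiveProtocol()), 180)
  expect_lte(scanDuration(retrospectiveProtocol()), 220)
  expect_gte(scanDuration(acquisitionMatchedProtocol()), 180)
  expect_lte(scanDuration(acquisitionMatchedProtocol()), 220)
})

test_that("scan duration is monotone in block size, nz and trIR", {
  mk <- function(spb, nz = 186L, trIR = 3097) protocolParams(
    ti1 = 930, ti2 = 2368, te = 8, trShot = 23, trIR = trIR, fa1 = 10,
    fa2 = 10, nSegments = 14L, matrixSize = c(232L, 232L, nz),
    caipiDz = 3L, shotsPerTiBlock = spb)
  durs <- vapply(1:62, function(s) scanDuration(mk(as.integer(s))), 0)
  expect_true(all(diff(durs) <= 0))
  expect_true(all(diff(vapply(c(60L, 120L, 186L),
                              function(nz) scanDuration(mk(27L, nz)), 0))
                  >= 0))
  expect_true(all(diff(vapply(c(3097, 3400, 3800),
                              function(tr) scanDuration(mk(27L, trIR = tr)),
                              0)) >= 0))
})

test_that("protocols round-trip through the YAML configs", {
  for (nm in c("retrospective", "acquisition_matched")) {
    path <- system.file("extdata", paste0(nm, ".yaml"), package = "epiT1")
    expect_true(nzchar(path))
    p <- readProtocol(path)
    ref <- if (nm == "retrospective") retrospectiveProtocol()
           else acquisitionMatchedProtocol()
    for (sl in slotNames("ProtocolParams"))
      expect_equal(slot(p, sl), slot(ref, sl), info = paste(nm, sl))
  }
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("ti1: 930", "nonsense_key: 1"), bad)
  expect_error(readProtocol(bad), "nonsense")
})
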