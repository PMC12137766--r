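#' Construct a protocol parameter set
#'
#' Builds and validates a [ProtocolParams-class] object. All durations are in
#' milliseconds and flip angles in degrees. The two shot blocks are centered
#' on \code{ti1} and \code{ti2}; \code{shotsPerTiBlock} excitations spaced
#' \code{trShot} apart form each block.
#'
#' @param ti1,ti2 inversion times (ms), 0 < ti1 < ti2 < trIR
#' @param te echo time (ms); metadata only, no T2* decay is modeled
#' @param trShot shot repetition time (ms)
#' @param trIR inversion-recovery cycle duration (ms)
#' @param fa1,fa2 excitation flip angles (degrees) in (0, 90]
#' @param nSegments EPI segmentation factor (shots covering in-plane k-space)
#' @param matrixSize integer triple (nx, ny, nz)
#' @param partialFourier phase partial Fourier factor: 1, 7/8, 6/8 or 5/8
#' @param caipiDz kz undersampling factor (skipped-CAIPI)
#' @param rInplane in-plane acceleration factor
#' @param echoSpacing actual echo spacing (ms) per acquired line
#' @param inversionEfficiency fraction of Mz inverted, in (0, 1]
#' @param shotsPerTiBlock excitations per TI block
#' @param voxelSize voxel size (mm), length 1 or 3
#' @param tag free-text protocol label
#' @return a validated \code{ProtocolParams} object
#' @examples
#' p <- retrospectiveProtocol()
#' effectiveEchoSpacing(p)
#' @export
protocolParams <- function(ti1, ti2, te, trShot, trIR, fa1, fa2,
                           nSegments = 1L, matrixSize = c(64L, 64L, 64L),
                           partialFourier = 1, caipiDz = 1L, rInplane = 1L,
                           echoSpacing = 1.0, inversionEfficiency = 1.0,
                           shotsPerTiBlock = 1L, voxelSize = c(0.8, 0.8, 0.8),
                           tag = "protocol") {
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  p <- new("ProtocolParams", ti1 = as.numeric(ti1), ti2 = as.numeric(ti2),
           te = as.numeric(te), trShot = as.numeric(trShot),
           trIR = as.numeric(trIR), fa1 = as.numeric(fa1),
           fa2 = as.numeric(fa2), nSegments = as.integer(nSegments),
           matrixSize = as.integer(matrixSize),
           partialFourier = as.numeric(partialFourier),
           caipiDz = as.integer(caipiDz), rInplane = as.integer(rInplane),
           echoSpacing = as.numeric(echoSpacing),
           inversionEfficiency = as.numeric(inversionEfficiency),
           shotsPerTiBlock = as.integer(shotsPerTiBlock),
           voxelSize = as.numeric(voxelSize), tag = as.character(tag))
  validateProtocol(p)
}

#' Validate a protocol parameter set
#'
#' Checks every protocol invariant and returns the object unchanged when all
#' hold; otherwise stops with an error naming the offending field.
#'
#' Invariants: 0 < ti1 < ti2 < trIR; flip angles in (0, 90]; counts and
#' accelerations at least 1; shotsPerTiBlock x trShot must fit into the
#' ti2 - ti1 window (the TI1 block finishes before the TI2 block begins);
#' both shot blocks lie inside (0, trIR); all durations strictly positive.
#'
#' @param p a [ProtocolParams-class] object
#' @return \code{p}, invisibly unchanged
#' @export
validateProtocol <- function(p) {
  stopifnot(is(p, "ProtocolParams"))
  fail <- function(field, msg) stop("invalid protocol: field '", field, "' ",
                                    msg, call. = FALSE)
  for (f in c("ti1", "ti2", "te", "trShot", "trIR", "echoSpacing"))
    if (!(is.finite(slot(p, f)) && slot(p, f) > 0))
      fail(f, "must be a strictly positive duration")
  if (!(p@ti1 < p@ti2)) fail("ti2", "must satisfy 0 < ti1 < ti2")
  if (!(p@ti2 < p@trIR)) fail("trIR", "must satisfy ti2 < trIR")
  for (f in c("fa1", "fa2"))
    if (!(slot(p, f) > 0 && slot(p, f) <= 90))
      fail(f, "must lie in (0, 90] degrees")
  if (p@nSegments < 1L) fail("nSegments", "must be >= 1")
  if (p@rInplane < 1L) fail("rInplane", "must be >= 1")
  if (p@caipiDz < 1L) fail("caipiDz", "must be >= 1")
  if (p@shotsPerTiBlock < 1L) fail("shotsPerTiBlock", "must be >= 1")
  if (length(p@matrixSize) != 3L || any(p@matrixSize < 1L))
    fail("matrixSize", "must be a positive integer triple")
  if (!isTRUE(all.equal(p@partialFourier, 1)) &&
      !any(vapply(c(7/8, 6/8, 5/8), function(x)
        isTRUE(all.equal(p@partialFourier, x)), logical(1))))
    fail("partialFourier", "must be one of 1, 7/8, 6/8, 5/8")
  if (!(p@inversionEfficiency > 0 && p@inversionEfficiency <= 1))
    fail("inversionEfficiency", "must lie in (0, 1]")
  if (p@shotsPerTiBlock * p@trShot > (p@ti2 - p@ti1))
    fail("shotsPerTiBlock",
         "x trShot must not exceed ti2 - ti1 (TI1 block must end before TI2)")
  half <- (p@shotsPerTiBlock - 1) / 2 * p@trShot
  if (p@ti1 - half <= 0)
    fail("ti1", "is too early: the TI1 shot block would start before t = 0")
  if (p@ti2 + half >= p@trIR)
    fail("trIR", "is too short: the TI2 shot block would outlast the IR cycle")
  invisible(p)
}

#' Effective echo spacing
#'
#' The per-k-space-line phase-evolution interval that governs EPI distortion
#' magnitude: \code{echoSpacing / (nSegments * rInplane)}. Interleaved
#' segmentation and in-plane acceleration both widen the spacing of
#' *acquired* lines in k-space, shrinking the effective spacing of the
#' reconstructed line grid by the same factor.
#'
#' @param p a validated [ProtocolParams-class]
#' @return effective echo spacing in ms
#' @export
effectiveEchoSpacing <- function(p) {
  stopifnot(is(p, "ProtocolParams"))
  p@echoSpacing / (p@nSegments * p@rInplane)
}

#' Smallest segmentation factor reaching a target effective echo spacing
#'
#' Returns the smallest integer number of EPI segments such that
#' \code{echoSpacing / (nSegments * rInplane) <= targetEffEsp}. Used to
#' configure an acquisition whose distortions match a functional protocol at
#' the acquisition level.
#'
#' @param targetEffEsp target effective echo spacing (ms), > 0
#' @param echoSpacing actual echo spacing (ms)
#' @param rInplane in-plane acceleration factor
#' @return integer segmentation factor
#' @export
matchSegmentation <- function(targetEffEsp, echoSpacing, rInplane = 1L) {
  if (!(is.finite(targetEffEsp) && targetEffEsp > 0))
    stop("targetEffEsp must be > 0")
  stopifnot(echoSpacing > 0, rInplane >= 1)
  # small tolerance so an exactly attainable target does not round up
  as.integer(max(1, ceiling(echoSpacing / (rInplane * targetEffEsp) -
                            1e-9)))
}

#' Distortion field scale factor between two effective echo spacings
#'
#' The factor by which a displacement field estimated at the structural
#' protocol's effective echo spacing must be multiplied to synthesize the
#' distortion level of data acquired at \code{targetEffEsp}. A target of 0
#' corresponds to distortion-free synthesis (applying the negated estimated
#' field).
#'
#' @param pStruct structural [ProtocolParams-class]
#' @param targetEffEsp target effective echo spacing (ms), >= 0
#' @return dimensionless scale factor
#' @export
distortionScaleFactor <- function(pStruct, targetEffEsp) {
  stopifnot(is(pStruct, "ProtocolParams"), targetEffEsp >= 0)
  targetEffEsp / effectiveEchoSpacing(pStruct)
}

#' Total scan duration
#'
#' Accounts shots per volume from the segmentation factor and the kz loop
#' (nz reduced by the CAIPI kz undersampling), packs two shot blocks into
#' each IR cycle, and repeats the volume once per read/phase polarity
#' combination.
#'
#' @param p a validated [ProtocolParams-class]
#' @param nPolarityVolumes number of polarity volumes acquired (default 4:
#'   all read/phase combinations)
#' @return total duration in seconds
#' @export
scanDuration <- function(p, nPolarityVolumes = 4L) {
  stopifnot(is(p, "ProtocolParams"), nPolarityVolumes >= 1)
  if (p@shotsPerTiBlock == 0L) stop("shotsPerTiBlock must be nonzero")
  totalShots <- p@nSegments * ceiling(p@matrixSize[3] / p@caipiDz)
  nCycles <- ceiling(totalShots / (2 * p@shotsPerTiBlock))
  nPolarityVolumes * nCycles * p@trIR / 1000
}

#' @describeIn protocolParams Retrospectively distortion-matched whole-brain
#'   protocol (930/2368/8/23/3097 ms, FA 10/10, segmentation 14, 232 x 232 x
#'   186 matrix, partial Fourier 6/8, kz-CAIPI 3).
#' @export
retrospectiveProtocol <- function() {
  protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23, trIR = 3097,
                 fa1 = 10, fa2 = 10, nSegments = 14L,
                 matrixSize = c(232L, 232L, 186L), partialFourier = 6/8,
                 caipiDz = 3L, rInplane = 1L, echoSpacing = 1.05,
                 shotsPerTiBlock = 27L, voxelSize = 0.8,
                 tag = "retrospective")
}

#' @describeIn protocolParams Acquisition distortion-matched protocol
#'   (1378/3793/26/78/5050 ms, FA 10/10) configured for an effective echo
#'   spacing of 0.35 ms.
#' @export
acquisitionMatchedProtocol <- function() {
  protocolParams(ti1 = 1378, ti2 = 3793, te = 26, trShot = 78, trIR = 5050,
                 fa1 = 10, fa2 = 10, nSegments = 3L,
                 matrixSize = c(232L, 232L, 186L), partialFourier = 6/8,
                 caipiDz = 3L, rInplane = 1L, echoSpacing = 1.05,
                 shotsPerTiBlock = 10L, voxelSize = 0.8,
                 tag = "acquisition_matched")
}

#' @describeIn protocolParams Small-matrix demonstration protocol used with
#'   the 64-cube digital phantom; single-shot in-plane readout so the
#'   phantom's simulated distortions span a few voxels.
#' @export
demoProtocol <- function(shape = c(64L, 64L, 64L)) {
  protocolParams(ti1 = 930, ti2 = 2368, te = 8, trShot = 23, trIR = 3097,
                 fa1 = 10, fa2 = 10, nSegments = 1L,
                 matrixSize = as.integer(shape), partialFourier = 1,
                 caipiDz = 1L, rInplane = 1L, echoSpacing = 1.0,
                 shotsPerTiBlock = 27L, voxelSize = 0.8, tag = "demo")
}

#' Read a protocol from a YAML config file
#'
#' Keys mirror the [protocolParams()] arguments (snake_case also accepted,
#' e.g. \code{tr_shot}). Fixture configs for the two reference protocols ship
#' in \code{system.file("extdata", package = "epiT1")}.
#'
#' @param path YAML file path
#' @return a validated [ProtocolParams-class]
#' @export
readProtocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(protocolParams))
  norm <- function(x) tolower(gsub("_", "", x))
  idx <- match(norm(names(cfg)), norm(known))
  if (anyNA(idx))
    stop("unknown protocol keys: ",
         paste(names(cfg)[is.na(idx)], collapse = ", "))
  names(cfg) <- known[idx]
  do.call(protocolParams, cfg)
}

#' @export
setMethod("show", "ProtocolParams", function(object) {
  cat(sprintf("ProtocolParams '%s'\n", object@tag))
  cat(sprintf("  TI1/TI2/TE/TRshot/TRIR = %g/%g/%g/%g/%g ms, FA = %g/%g deg\n",
              object@ti1, object@ti2, object@te, object@trShot, object@trIR,
              object@fa1, object@fa2))
  cat(sprintf("  segments %d, R %d, kz-CAIPI %d, partial Fourier %g\n",
              object@nSegments, object@rInplane, object@caipiDz,
              object@partialFourier))
  cat(sprintf("  matrix %s, voxel %s mm, echo spacing %g ms (effective %g ms)\n",
              paste(object@matrixSize, collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x"),
              object@echoSpacing, effectiveEchoSpacing(object)))
  cat(sprintf("  %d shots per TI block, inversion efficiency %g\n",
              object@shotsPerTiBlock, object@inversionEfficiency))
})
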