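#' @import methods
NULL

#' Protocol parameters for a two-inversion segmented 3D-EPI acquisition
#'
#' Holds every timing, geometry and flip-angle parameter of one acquisition
#' protocol. All durations are in milliseconds; flip angles in degrees.
#' \code{te} is carried as metadata only: no transverse decay is modeled.
#'
#' @slot ti1,ti2 inversion times (ms) at which the two shot blocks are centered
#' @slot te echo time (ms), metadata only
#' @slot trShot shot repetition time within a block (ms)
#' @slot trIR duration of one inversion-recovery cycle (ms)
#' @slot fa1,fa2 excitation flip angles (degrees) of the TI1 and TI2 blocks
#' @slot nSegments in-plane EPI segmentation factor
#' @slot matrixSize integer triple (nx, ny, nz)
#' @slot partialFourier phase partial Fourier fraction (1, 7/8, 6/8 or 5/8)
#' @slot caipiDz kz undersampling factor of the skipped-CAIPI scheme
#' @slot rInplane in-plane parallel-imaging acceleration factor
#' @slot echoSpacing actual echo spacing per acquired k-space line (ms)
#' @slot inversionEfficiency fraction of Mz inverted by the adiabatic pulse
#' @slot shotsPerTiBlock number of excitations per TI block
#' @slot voxelSize voxel dimensions (mm triple)
#' @slot tag free-text protocol label
#'
#' @seealso [protocolParams()], [validateProtocol()], [effectiveEchoSpacing()]
#' @export
setClass("ProtocolParams", representation(
  ti1 = "numeric", ti2 = "numeric", te = "numeric",
  trShot = "numeric", trIR = "numeric",
  fa1 = "numeric", fa2 = "numeric",
  nSegments = "integer", matrixSize = "integer",
  partialFourier = "numeric", caipiDz = "integer", rInplane = "integer",
  echoSpacing = "numeric", inversionEfficiency = "numeric",
  shotsPerTiBlock = "integer", voxelSize = "numeric", tag = "character"))

#' One tissue compartment
#'
#' @slot name compartment label
#' @slot t1 longitudinal relaxation time (ms)
#' @slot m0 equilibrium magnetization (arbitrary units)
#' @export
setClass("TissueParams",
  representation(name = "character", t1 = "numeric", m0 = "numeric"))

setValidity("TissueParams", function(object) {
  if (!(length(object@t1) == 1 && is.finite(object@t1) && object@t1 > 0))
    return("t1 must be a single positive number (ms)")
  if (!(length(object@m0) == 1 && is.finite(object@m0) && object@m0 > 0))
    return("m0 must be a single positive number")
  TRUE
})

#' Longitudinal magnetization trajectory over one inversion-recovery cycle
#'
#' Event-wise record of the final simulated IR cycle: the instants of the
#' excitation pulses, the longitudinal magnetization immediately before each
#' pulse (as a fraction of m0), and the transverse signal each pulse creates.
#'
#' @slot times event instants within the cycle (ms), strictly increasing
#' @slot mzBefore Mz just before each excitation, fraction of m0
#' @slot mxy transverse signal of each excitation, fraction of m0
#' @slot block 1 or 2: which TI block each event belongs to
#' @slot cycleIndex index of the returned cycle (1-based)
#' @slot converged whether consecutive cycles agreed within tolerance
#' @export
setClass("MzTrajectory", representation(
  times = "numeric", mzBefore = "numeric", mxy = "numeric",
  block = "integer", cycleIndex = "integer", converged = "logical"))

setValidity("MzTrajectory", function(object) {
  n <- length(object@times)
  if (length(object@mzBefore) != n || length(object@mxy) != n ||
      length(object@block) != n)
    return("times, mzBefore, mxy and block must have equal length")
  if (n > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(abs(object@mzBefore) > 1 + 1e-9))
    return("|mzBefore| exceeds 1 + tolerance")
  TRUE
})

#' Steady-state signal pair at the two inversion times
#'
#' Signed transverse signals (in m0 units) of the k-space-center shot of the
#' TI1 and TI2 blocks at steady state. \code{s2 >= s1} is not required: the
#' TI1 signal is typically still negative after inversion.
#'
#' @slot s1,s2 signed signals at TI1 and TI2 (m0 units)
#' @export
setClass("SignalPair", representation(s1 = "numeric", s2 = "numeric"))

setValidity("SignalPair", function(object) {
  if (!all(is.finite(c(object@s1, object@s2)))) return("signals must be finite")
  TRUE
})

#' Lookup table mapping T1 to the TI1/TI2 signal ratio
#'
#' @slot t1Axis strictly ascending T1 grid (ms)
#' @slot ratioAxis signed steady-state s1/s2 ratio at each grid T1
#' @slot b1Scale relative transmit-field scale the table was simulated at
#' @slot protocolTag label of the generating protocol
#' @slot monotonicDomain (t1 min, t1 max) of the largest strictly monotonic
#'   contiguous sub-range of the ratio
#' @export
setClass("LookupTable", representation(
  t1Axis = "numeric", ratioAxis = "numeric", b1Scale = "numeric",
  protocolTag = "character", monotonicDomain = "numeric"))

setValidity("LookupTable", function(object) {
  if (length(object@t1Axis) != length(object@ratioAxis))
    return("t1Axis and ratioAxis must have equal length")
  if (length(object@t1Axis) > 1 && any(diff(object@t1Axis) <= 0))
    return("t1Axis must be strictly ascending")
  idx <- which(object@t1Axis >= object@monotonicDomain[1] &
               object@t1Axis <= object@monotonicDomain[2])
  if (length(idx) > 2) {
    d <- diff(object@ratioAxis[idx])
    if (!(all(d > 0) || all(d < 0)))
      return("ratio is not strictly monotonic inside monotonicDomain")
  }
  TRUE
})

#' Quantitative T1 map
#'
#' @slot values 3-D array of T1 in ms; undefined voxels are NA
#' @slot units always "ms"
#' @export
setClass("T1Map", representation(values = "array", units = "character"))

#' Digital brain phantom
#'
#' Nested-ellipsoid phantom with a WM core, a GM ribbon, a CSF shell and
#' background, plus smooth off-resonance (B0, Hz), transmit-field (B1,
#' dimensionless) and cortical-depth maps.
#'
#' @slot labels integer array: 0 background, 1 CSF, 2 GM ribbon, 3 WM core
#' @slot tissueTable named list of [TissueParams-class], one per label
#' @slot b0Map off-resonance field (Hz)
#' @slot b1Map relative transmit field, near 1
#' @slot depthMap cortical depth in [0, 1] on the GM ribbon (NA elsewhere);
#'   0 = WM surface, 1 = pial surface
#' @slot voxelSize mm
#' @slot seed generator seed
#' @export
setClass("Phantom", representation(
  labels = "array", tissueTable = "list", b0Map = "array", b1Map = "array",
  depthMap = "array", voxelSize = "numeric", seed = "integer"))

setValidity("Phantom", function(object) {
  if (!all(dim(object@labels) == dim(object@b0Map)) ||
      !all(dim(object@labels) == dim(object@b1Map)) ||
      !all(dim(object@labels) == dim(object@depthMap)))
    return("labels, b0Map, b1Map and depthMap must share dimensions")
  if (any(object@b1Map <= 0)) return("b1Map must be strictly positive")
  gm <- object@labels == 2L
  if (any(is.na(object@depthMap[gm])) || any(!is.na(object@depthMap[!gm])))
    return("depthMap must be defined exactly on the GM ribbon")
  TRUE
})

#' One simulated polarity-tagged acquisition
#'
#' @slot data complex 3-D array
#' @slot readPolarity,phasePolarity +1 or -1
#' @slot effEsp effective echo spacing of the simulated readout (ms)
#' @slot peAxis phase-encode axis index (1..3)
#' @slot noiseSigma complex noise SD per component (m0 units)
#' @slot seed RNG seed used
#' @slot ti which inversion time the volume images (1 or 2)
#' @export
setClass("AcquiredVolume", representation(
  data = "array", readPolarity = "numeric", phasePolarity = "numeric",
  effEsp = "numeric", peAxis = "integer", noiseSigma = "numeric",
  seed = "integer", ti = "integer"))

setValidity("AcquiredVolume", function(object) {
  if (!object@readPolarity %in% c(-1, 1)) return("readPolarity must be +1/-1")
  if (!object@phasePolarity %in% c(-1, 1)) return("phasePolarity must be +1/-1")
  if (any(!is.finite(Re(object@data))) || any(!is.finite(Im(object@data))))
    return("data must be finite")
  TRUE
})

#' A polarity-combined volume
#'
#' Complex after read-polarity averaging, real non-negative once magnitude
#' has been formed.
#'
#' @slot data complex (pre-magnitude) or non-negative real 3-D array
#' @slot provenance tags of the contributing polarity volumes
#' @export
setClass("CombinedVolume",
  representation(data = "array", provenance = "character"))

setValidity("CombinedVolume", function(object) {
  if (length(object@provenance) < 1) return("provenance must be non-empty")
  if (!is.complex(object@data) && any(object@data < 0, na.rm = TRUE))
    return("magnitude data must be non-negative")
  TRUE
})

#' Phase-encode displacement field
#'
#' Voxelwise displacement (in voxels) along the phase-encode axis. The stored
#' field is the correction field of the +PE-polarity image: resampling the
#' +PE image at \code{x + d(x)} (and the -PE image at \code{x - d(x)})
#' recovers the undistorted geometry.
#'
#' @slot d displacement array (voxels)
#' @slot peAxis phase-encode axis index
#' @slot effEsp effective echo spacing (ms) of the acquisition it was
#'   estimated from
#' @slot smoothness regularization weight used during estimation
#' @slot converged optimizer convergence flag
#' @export
setClass("DisplacementField", representation(
  d = "array", peAxis = "integer", effEsp = "numeric",
  smoothness = "numeric", converged = "logical"))

setValidity("DisplacementField", function(object) {
  if (any(!is.finite(object@d))) return("field must be finite")
  if (!object@peAxis %in% seq_along(dim(object@d)))
    return("peAxis out of range")
  TRUE
})

#' Cortical depth profile
#'
#' @slot depthBins bin centers in [0, 1], ascending
#' @slot mean,sd per-bin mean and SD of the pooled map
#' @slot n per-bin voxel counts
#' @slot dipDepth depth of the detected landmark dip, or NA
#' @export
setClass("DepthProfile", representation(
  depthBins = "numeric", mean = "numeric", sd = "numeric",
  n = "integer", dipDepth = "numeric"))

setValidity("DepthProfile", function(object) {
  k <- length(object@depthBins)
  if (length(object@mean) != k || length(object@sd) != k ||
      length(object@n) != k)
    return("depthBins, mean, sd and n must have equal length")
  if (k > 1 && any(diff(object@depthBins) <= 0))
    return("depthBins must be ascending")
  if (any(object@n > 0 & !is.finite(object@mean)))
    return("mean must be defined where n > 0")
  TRUE
})
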