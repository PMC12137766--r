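# Digital brain phantom and forward acquisition simulator. The phantom is a
# nested-ellipsoid "brain" (WM core, GM ribbon, CSF shell) with smooth B0
# off-resonance (polynomial background plus one localized Gaussian blob,
# emulating air-cavity inhomogeneity), a smooth radial B1 profile, and a
# normalized cortical-depth map on the ribbon. The simulator turns it into
# polarity-tagged complex volumes with geometric distortion, an N/2 ghost
# whose phase flips with read polarity, low-frequency ripples, and complex
# Gaussian noise.

defaultTissueTable <- function() {
  list(csf = tissueParams("CSF", 4000, 1.00),
       gm  = tissueParams("GM",  1900, 0.85),
       wm  = tissueParams("WM",  1200, 0.70))
}

#' Construct a digital brain phantom
#'
#' Nested ellipsoids: WM core (label 3), a GM ribbon at least 3 voxels thick
#' (label 2), a CSF shell (label 1) and background (0). The B0 map is a
#' smooth low-order polynomial plus one localized Gaussian off-resonance
#' blob (position jittered by the seed); B1 is a smooth radial profile in
#' [0.7, 1.3]; the depth map is the through-ribbon distance normalized to
#' [0, 1] (0 = WM surface, 1 = pial). Fully deterministic given the seed.
#'
#' @param shape integer triple, at least 32 per axis
#' @param voxelSize voxel size in mm (isotropic scalar or triple)
#' @param seed integer seed controlling the B0 blob jitter
#' @param blobAmpHz amplitude of the Gaussian B0 blob (Hz)
#' @param tissueTable named list of [TissueParams-class] for csf, gm, wm
#' @return a [Phantom-class]
#' @examples
#' ph <- makePhantom(c(32, 32, 32), seed = 1)
#' table(ph@labels)
#' @export
makePhantom <- function(shape = c(64L, 64L, 64L), voxelSize = 0.8,
                        seed = 1L, blobAmpHz = 30,
                        tissueTable = defaultTissueTable()) {
  shape <- as.integer(rep_len(shape, 3))
  if (any(shape < 32L)) stop("shape must be at least 32 per axis")
  ax <- c(0.80, 0.86, 0.74)  # ellipsoid semi-axes, fraction of half-FOV
  cc <- lapply(1:3, function(k) (seq_len(shape[k]) - (shape[k] + 1) / 2) /
                                (shape[k] / 2))
  cx <- array(rep(cc[[1]], times = shape[2] * shape[3]), shape)
  cy <- array(rep(rep(cc[[2]], each = shape[1]), times = shape[3]), shape)
  cz <- array(rep(cc[[3]], each = shape[1] * shape[2]), shape)
  r <- sqrt((cx / ax[1])^2 + (cy / ax[2])^2 + (cz / ax[3])^2)
  rWm <- 0.55; rGm <- 0.82; rCsf <- 0.95
  labels <- array(0L, shape)
  labels[r < rCsf] <- 1L
  labels[r < rGm] <- 2L
  labels[r < rWm] <- 3L
  depth <- array(NA_real_, shape)
  gm <- labels == 2L
  dRaw <- (r[gm] - rWm) / (rGm - rWm)
  depth[gm] <- (dRaw - min(dRaw)) / (max(dRaw) - min(dRaw))
  jit <- withSeed(as.integer(seed), stats::runif(4, -0.05, 0.05))
  blobC <- c(0.0, 0.55, -0.30) + jit[1:3]
  blobSigma <- 0.16
  b0 <- 4 * cx + 6 * cy - 5 * cz + 8 * (cx^2 + cy^2 + cz^2 - 0.5) +
    blobAmpHz * (1 + jit[4]) *
      exp(-((cx - blobC[1])^2 + (cy - blobC[2])^2 + (cz - blobC[3])^2) /
          (2 * blobSigma^2))
  b1 <- pmax(0.7, 1.3 - 0.6 * pmin(r, 1)^2)
  new("Phantom", labels = labels, tissueTable = tissueTable,
      b0Map = b0, b1Map = array(b1, shape), depthMap = depth,
      voxelSize = rep_len(voxelSize, 3)[1], seed = as.integer(seed))
}

#' @export
setMethod("show", "Phantom", function(object) {
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", "CSF", "GM", "WM")))
  cat(sprintf("Phantom: %s voxels @ %g mm, seed %d\n",
              paste(dim(object@labels), collapse = "x"),
              object@voxelSize, object@seed))
  cat("  ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  B0 in [%.1f, %.1f] Hz, B1 in [%.2f, %.2f]\n",
              min(object@b0Map), max(object@b0Map),
              min(object@b1Map), max(object@b1Map)))
})

#' Brain mask of a phantom (all tissue labels)
#' @param ph a [Phantom-class]
#' @return logical array
#' @export
brainMask <- function(ph) ph@labels > 0L

#' Ground-truth T1 volume of a phantom, with an optional laminar dip
#'
#' Per-voxel T1 from the tissue table; optionally a Gaussian T1 depression
#' across cortical depth is injected into the GM ribbon, emulating the
#' heavily myelinated mid-depth band used as a laminar landmark.
#'
#' @param ph a [Phantom-class]
#' @param dipDepth cortical depth of the dip center in [0, 1], or NULL for
#'   no dip
#' @param dipAmp dip amplitude (ms)
#' @param dipWidth Gaussian SD of the dip in depth units
#' @return 3-D T1 array in ms (NA in the background)
#' @export
trueT1Volume <- function(ph, dipDepth = NULL, dipAmp = 100,
                         dipWidth = 0.1) {
  t1ByLabel <- c(NA_real_,
                 vapply(ph@tissueTable[c("csf", "gm", "wm")],
                        function(t) t@t1, 0))
  vol <- array(t1ByLabel[ph@labels + 1L], dim(ph@labels))
  if (!is.null(dipDepth)) {
    gm <- ph@labels == 2L
    vol[gm] <- vol[gm] - dipAmp *
      exp(-(ph@depthMap[gm] - dipDepth)^2 / (2 * dipWidth^2))
  }
  vol
}

# Noise-free ideal image of the phantom for one TI: per voxel the
# steady-state signal of its tissue at the local B1 (interpolated over a
# fine B1 grid; the signal is smooth in B1).
idealImage <- function(ph, p, whichTi = 1L, nB1Grid = 33L) {
  lab <- ph@labels
  tt <- ph@tissueTable
  rng <- range(ph@b1Map)
  b1Grid <- if (diff(rng) < 1e-9) mean(rng) else
    seq(rng[1], rng[2], length.out = nB1Grid)
  nb <- length(b1Grid)
  sig <- steadyStateSignalsGrid(
    p, t1 = rep(vapply(tt, function(t) t@t1, 0), each = nb),
    m0 = rep(vapply(tt, function(t) t@m0, 0), each = nb),
    b1 = rep(b1Grid, length(tt)))
  s <- if (whichTi == 1L) sig$s1 else sig$s2
  out <- array(0, dim(lab))
  for (k in seq_along(tt)) {
    vox <- which(lab == k)
    if (!length(vox)) next
    srow <- s[(k - 1) * nb + seq_len(nb)]
    out[vox] <- if (nb == 1) srow else
      stats::approx(b1Grid, srow, xout = ph@b1Map[vox], rule = 2)$y
  }
  out
}

# ground-truth +PE-polarity displacement field of a phantom/protocol pair:
# voxel shift = B0[Hz] * effective echo spacing [s] * n_pe
trueDisplacement <- function(ph, p, peAxis = 2L) {
  nPe <- dim(ph@labels)[peAxis]
  ph@b0Map * (effectiveEchoSpacing(p) / 1000) * nPe
}

#' Simulate one polarity-tagged acquisition of the phantom
#'
#' Forward model, in order: (i) ideal steady-state image of the selected TI
#' (per-voxel tissue T1/M0 at the local B1); (ii) geometric distortion along
#' the phase-encode axis by \code{B0[Hz] * effEsp[s] * nPE * phasePolarity}
#' voxels (linear resampling with Jacobian intensity modulation); (iii) an
#' N/2 ghost: \code{ghostAmp} times the image circularly shifted by half the
#' FOV, with pure-imaginary weight whose sign flips with read polarity;
#' (iv) a low-spatial-frequency ripple (fraction of the WM signal) whose
#' sign also flips with read polarity; (v) complex Gaussian noise.
#' Deterministic given (seed, settings).
#'
#' @param ph a [Phantom-class]
#' @param p a validated [ProtocolParams-class]
#' @param readPolarity,phasePolarity +1 or -1
#' @param whichTi 1 or 2
#' @param noiseSigma complex noise SD per component (m0 units)
#' @param ghostAmp ghost amplitude as a fraction of the shifted image
#' @param rippleAmp ripple amplitude as a fraction of the WM signal
#' @param seed RNG seed for the noise draw
#' @param peAxis phase-encode axis (1..3)
#' @return an [AcquiredVolume-class]
#' @export
simulateAcquisition <- function(ph, p, readPolarity = 1, phasePolarity = 1,
                                whichTi = 1L, noiseSigma = 0,
                                ghostAmp = 0.05, rippleAmp = 0.03,
                                seed = 1L, peAxis = 2L) {
  validateProtocol(p)
  stopifnot(is(ph, "Phantom"), readPolarity %in% c(-1, 1),
            phasePolarity %in% c(-1, 1), whichTi %in% 1:2)
  ideal <- idealImage(ph, p, whichTi = as.integer(whichTi))
  dTrue <- trueDisplacement(ph, p, peAxis)
  img <- resamplePE(ideal, -phasePolarity * dTrue, peAxis = peAxis,
                    jacobian = TRUE)
  img <- img + 0i
  dm <- dim(ideal)
  if (ghostAmp != 0) {
    img <- img + ghostAmp * circShift(img, floor(dm[peAxis] / 2), peAxis) *
      1i * readPolarity
  }
  if (rippleAmp != 0) {
    wmSig <- mean(abs(ideal[ph@labels == 3L]))
    cr <- (seq_len(dm[1]) - (dm[1] + 1) / 2) / (dm[1] / 2)
    ripple <- array(rep(sin(2 * pi * cr), times = dm[2] * dm[3]), dm)
    img <- img + rippleAmp * wmSig * ripple * readPolarity
  }
  if (noiseSigma > 0) {
    noise <- withSeed(as.integer(seed),
                      complex(real = stats::rnorm(length(img), 0, noiseSigma),
                              imaginary = stats::rnorm(length(img), 0,
                                                       noiseSigma)))
    img <- img + array(noise, dm)
  }
  new("AcquiredVolume", data = img, readPolarity = readPolarity,
      phasePolarity = phasePolarity, effEsp = effectiveEchoSpacing(p),
      peAxis = as.integer(peAxis), noiseSigma = noiseSigma,
      seed = as.integer(seed), ti = as.integer(whichTi))
}

#' Simulate a full four-polarity session
#'
#' One volume per read/phase polarity combination and inversion time:
#' 8 volumes total (4 distinct polarity pairs x 2 TIs), with sidecar
#' metadata recording polarities, effective echo spacing and seeds.
#'
#' @inheritParams simulateAcquisition
#' @param outDir optional directory; when given, volumes are written as
#'   NIfTI real/imaginary pairs with JSON sidecars
#' @return named list of [AcquiredVolume-class] plus a \code{meta} attribute
#' @export
acquireFullSession <- function(ph, p, noiseSigma = 0, seed = 1L,
                               ghostAmp = 0.05, rippleAmp = 0.03,
                               peAxis = 2L, outDir = NULL) {
  combos <- expand.grid(read = c(1, -1), phase = c(1, -1), ti = 1:2)
  vols <- vector("list", nrow(combos))
  names(vols) <- sprintf("ti%d_read%s_phase%s", combos$ti,
                         ifelse(combos$read > 0, "pos", "neg"),
                         ifelse(combos$phase > 0, "pos", "neg"))
  for (i in seq_len(nrow(combos))) {
    vols[[i]] <- simulateAcquisition(
      ph, p, readPolarity = combos$read[i], phasePolarity = combos$phase[i],
      whichTi = combos$ti[i], noiseSigma = noiseSigma, ghostAmp = ghostAmp,
      rippleAmp = rippleAmp, seed = as.integer(seed) + i, peAxis = peAxis)
  }
  meta <- list(effEsp = effectiveEchoSpacing(p), peAxis = peAxis,
               seed = as.integer(seed), noiseSigma = noiseSigma,
               ghostAmp = ghostAmp, rippleAmp = rippleAmp,
               protocol = p@tag)
  attr(vols, "meta") <- meta
  if (!is.null(outDir)) writeSession(vols, outDir)
  vols
}

#' Write a simulated session to NIfTI + JSON sidecars
#'
#' Complex volumes are stored as paired \code{*_real.nii.gz} and
#' \code{*_imag.nii.gz} files; each volume gets a JSON sidecar with its
#' polarities, effective echo spacing, noise level and seed.
#'
#' @param vols the list returned by [acquireFullSession()]
#' @param outDir output directory (created if missing)
#' @return \code{outDir}, invisibly
#' @export
writeSession <- function(vols, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(vols)) {
    v <- vols[[nm]]
    RNifti::writeNifti(Re(v@data), file.path(outDir,
                                             paste0(nm, "_real.nii.gz")))
    RNifti::writeNifti(Im(v@data), file.path(outDir,
                                             paste0(nm, "_imag.nii.gz")))
    sidecar <- list(read_polarity = v@readPolarity,
                    phase_polarity = v@phasePolarity,
                    effective_echo_spacing_ms = v@effEsp,
                    pe_axis = v@peAxis, noise_sigma = v@noiseSigma,
                    seed = v@seed, ti = v@ti)
    jsonlite::write_json(sidecar, file.path(outDir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  meta <- attr(vols, "meta")
  if (!is.null(meta))
    jsonlite::write_json(meta, file.path(outDir, "session.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' @export
setMethod("show", "AcquiredVolume", function(object) {
  cat(sprintf(
    "AcquiredVolume (TI%d): %s, read %+d, phase %+d, effEsp %g ms, sigma %g\n",
    object@ti, paste(dim(object@data), collapse = "x"),
    object@readPolarity, object@phasePolarity, object@effEsp,
    object@noiseSigma))
})
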