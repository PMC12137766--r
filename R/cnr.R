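# GM-WM contrast, CNR by first-order Gaussian uncertainty propagation, and
# flip-angle-pair optimization by exhaustive grid search.

#' Relative gray/white signal contrast
#'
#' \code{(sGm - sWm) / (|sGm| + |sWm|)}, bounded in [-1, 1]. Antisymmetric
#' under swapping the tissues; undefined (error) when both signals are zero.
#'
#' @param sGm,sWm signed tissue signals (same units)
#' @return dimensionless contrast in [-1, 1]
#' @export
signalContrast <- function(sGm, sWm) {
  den <- abs(sGm) + abs(sWm)
  if (any(den == 0)) stop("contrast undefined: both signals are zero")
  (sGm - sWm) / den
}

# analytic partials of the contrast away from sign changes
contrastPartials <- function(a, b) {
  den <- abs(a) + abs(b)
  list(da = (den - (a - b) * sign(a)) / den^2,
       db = (-den - (a - b) * sign(b)) / den^2)
}

#' CNR from a pair of tissue signals
#'
#' Propagates independent Gaussian noise of SD \code{sigma} on each signal
#' through the contrast to first order:
#' \code{sigmaC = sigma * sqrt((dC/dsGm)^2 + (dC/dsWm)^2)} with analytic
#' partials, and returns \code{cnr = contrast / sigmaC}. The CNR carries the
#' sign of the contrast and scales inversely with sigma.
#'
#' When the two signals have opposite signs the contrast saturates at
#' +/-1, where its first-order sensitivity to both signals is exactly
#' zero; the propagated SD is then 0 and the CNR is infinite. Protocol
#' optimization therefore works on magnitude signals (see
#' [cnrForProtocol()]).
#'
#' @param sGm,sWm signed tissue signals (m0 units)
#' @param sigma image noise SD (m0 units), > 0
#' @param fa1,fa2 flip angles to record alongside the result (degrees)
#' @return a list of class \code{cnrResult}: contrast, cnr, sigma, fa1, fa2
#' @export
cnrFromSignals <- function(sGm, sWm, sigma, fa1 = NA_real_, fa2 = NA_real_) {
  if (!all(is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  C <- signalContrast(sGm, sWm)
  pd <- contrastPartials(sGm, sWm)
  sigmaC <- sigma * sqrt(pd$da^2 + pd$db^2)
  structure(list(contrast = C, cnr = C / sigmaC, sigma = sigma,
                 fa1 = fa1, fa2 = fa2), class = "cnrResult")
}

#' @export
print.cnrResult <- function(x, ...) {
  cat(sprintf("CNR result: contrast = %+.4f, cnr = %+.2f (sigma = %g)\n",
              x$contrast, x$cnr, x$sigma))
  if (is.finite(x$fa1))
    cat(sprintf("  at flip angles %g / %g deg\n", x$fa1, x$fa2))
  invisible(x)
}

# noise propagation through the quotient r = s1/s2
ratioSigma <- function(s1, s2, sigma) {
  sigma * sqrt(1 / s2^2 + s1^2 / s2^4)
}

#' CNR of a protocol for a gray/white tissue pair
#'
#' Simulates steady-state signals for both tissues and computes the CNR of
#' the selected image: \code{whichTi = 1} (default) uses the T1-weighted TI1
#' image used for segmentation, \code{2} the TI2 image, and
#' \code{"combined"} the s1/s2 ratio with noise propagated through the
#' quotient before the contrast.
#'
#' For \code{whichTi} 1 or 2 the contrast is computed on magnitude signals:
#' a reconstructed image used for segmentation carries no polarity, and the
#' signed contrast saturates at +/-1 (with vanishing first-order noise
#' sensitivity, hence unbounded CNR) whenever the two tissues straddle the
#' signal null. The combined ratio keeps its sign, which encodes T1.
#'
#' @param p a validated [ProtocolParams-class]
#' @param gm,wm [TissueParams-class] for the two compartments
#' @param sigma image noise SD (m0 units)
#' @param whichTi 1, 2 or "combined"
#' @param fa1,fa2 optional flip-angle override (degrees; default protocol's)
#' @return a \code{cnrResult} list
#' @export
cnrForProtocol <- function(p, gm, wm, sigma, whichTi = 1,
                           fa1 = p@fa1, fa2 = p@fa2) {
  validateProtocol(p)
  sig <- steadyStateSignalsGrid(p, t1 = c(gm@t1, wm@t1),
                                m0 = c(gm@m0, wm@m0),
                                fa1 = fa1, fa2 = fa2)
  if (identical(whichTi, "combined")) {
    r <- sig$s1 / sig$s2
    C <- signalContrast(r[1], r[2])
    pd <- contrastPartials(r[1], r[2])
    sr <- ratioSigma(sig$s1, sig$s2, sigma)
    sigmaC <- sqrt((pd$da * sr[1])^2 + (pd$db * sr[2])^2)
    return(structure(list(contrast = C, cnr = C / sigmaC, sigma = sigma,
                          fa1 = fa1, fa2 = fa2), class = "cnrResult"))
  }
  s <- abs(if (whichTi == 1) sig$s1 else sig$s2)
  cnrFromSignals(s[1], s[2], sigma, fa1 = fa1, fa2 = fa2)
}

#' Optimize the flip-angle pair for GM-WM CNR
#'
#' Evaluates \code{|cnr|} at every node of a (fa1, fa2) grid by full Bloch
#' simulation of both tissues and returns the surface together with its
#' argmax. Exhaustive evaluation (no gradient ascent) side-steps local
#' basins; ties resolve to the smallest fa1, then smallest fa2. The argmax
#' is invariant to the (positive) noise level, which only scales the
#' surface.
#'
#' @inheritParams cnrForProtocol
#' @param fa1Grid,fa2Grid grid axes in degrees, within (0, 90]
#' @return a list of class \code{cnrGrid}: \code{fa1Axis}, \code{fa2Axis},
#'   \code{cnr} matrix (fa1 by fa2, signed), \code{argmax} = c(fa1, fa2)
#'   maximizing \code{|cnr|}
#' @export
optimizeFlipAngles <- function(p, gm, wm, sigma, fa1Grid, fa2Grid = fa1Grid,
                               whichTi = 1) {
  if (length(fa1Grid) == 0 || length(fa2Grid) == 0) stop("empty grid")
  if (any(fa1Grid <= 0 | fa1Grid > 90) || any(fa2Grid <= 0 | fa2Grid > 90))
    stop("grid flip angles must lie in (0, 90] degrees")
  nodes <- expand.grid(fa1 = fa1Grid, fa2 = fa2Grid)
  sig <- steadyStateSignalsGrid(
    p, t1 = rep(c(gm@t1, wm@t1), each = nrow(nodes)),
    m0 = rep(c(gm@m0, wm@m0), each = nrow(nodes)),
    fa1 = rep(nodes$fa1, 2), fa2 = rep(nodes$fa2, 2))
  i <- seq_len(nrow(nodes)); j <- nrow(nodes) + i
  cnr <- if (identical(whichTi, "combined")) {
    rg <- sig$s1[i] / sig$s2[i]; rw <- sig$s1[j] / sig$s2[j]
    C <- (rg - rw) / (abs(rg) + abs(rw))
    dg <- contrastPartials(rg, rw)
    sg <- ratioSigma(sig$s1[i], sig$s2[i], sigma)
    sw <- ratioSigma(sig$s1[j], sig$s2[j], sigma)
    C / sqrt((dg$da * sg)^2 + (dg$db * sw)^2)
  } else {
    sGm <- abs(if (whichTi == 1) sig$s1[i] else sig$s2[i])
    sWm <- abs(if (whichTi == 1) sig$s1[j] else sig$s2[j])
    C <- (sGm - sWm) / (abs(sGm) + abs(sWm))
    pd <- contrastPartials(sGm, sWm)
    C / (sigma * sqrt(pd$da^2 + pd$db^2))
  }
  surf <- matrix(cnr, nrow = length(fa1Grid), ncol = length(fa2Grid))
  if (any(!is.finite(surf))) stop("non-finite CNR on grid")
  # argmax of |cnr|; ties -> smallest fa1, then smallest fa2
  ties <- which(abs(surf) == max(abs(surf)), arr.ind = TRUE)
  bi <- ties[order(ties[, 1], ties[, 2])[1], ]
  structure(list(fa1Axis = fa1Grid, fa2Axis = fa2Grid, cnr = surf,
                 argmax = c(fa1 = fa1Grid[bi[1]], fa2 = fa2Grid[bi[2]]),
                 whichTi = whichTi, sigma = sigma), class = "cnrGrid")
}

#' @export
print.cnrGrid <- function(x, ...) {
  cat(sprintf("CNR grid: %d x %d flip-angle nodes, |cnr| max %.2f at fa1 = %g, fa2 = %g deg\n",
              length(x$fa1Axis), length(x$fa2Axis), max(abs(x$cnr)),
              x$argmax["fa1"], x$argmax["fa2"]))
  invisible(x)
}
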