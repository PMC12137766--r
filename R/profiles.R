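# Laminar pooling: scalar maps (typically quantitative T1) are averaged in
# equal-width cortical-depth bins across the GM ribbon, and the mid-depth
# landmark dip (the myeloarchitectonic band used to calibrate geometric
# depth to layers) is detected as the most prominent interior local minimum.

#' Pool a scalar map across cortical depth bins
#'
#' Voxels inside the mask with a defined depth are binned into
#' \code{nBins} equal-width depth bins on [0, 1]; per-bin mean, SD and
#' count are computed. Invariant to voxel order.
#'
#' @param map 3-D scalar array (e.g. T1 in ms) or [T1Map-class]
#' @param depthMap 3-D depth array in [0, 1] (NA outside the ribbon)
#' @param mask logical/0-1 array restricting the pooling (e.g. GM ribbon)
#' @param nBins number of depth bins, at least 3
#' @return a [DepthProfile-class] (without dip detection; see
#'   [detectDip()])
#' @export
extractProfile <- function(map, depthMap, mask = NULL, nBins = 21L) {
  if (is(map, "T1Map")) map <- map@values
  if (!all(dim(map) == dim(depthMap))) stop("map and depthMap shapes differ")
  if (nBins < 3) stop("nBins must be at least 3")
  if (is.null(mask)) mask <- !is.na(depthMap)
  if (!all(dim(mask) == dim(map))) stop("mask shape differs")
  sel <- as.logical(mask) & !is.na(depthMap) & !is.na(map)
  if (!any(sel)) stop("empty mask: no voxels to pool")
  dep <- depthMap[sel]; val <- map[sel]
  edges <- seq(0, 1, length.out = nBins + 1)
  bin <- pmin(pmax(findInterval(dep, edges, rightmost.closed = TRUE), 1L),
              nBins)
  n <- tabulate(bin, nBins)
  mu <- rep(NA_real_, nBins); sd <- rep(NA_real_, nBins)
  has <- which(n > 0)
  mu[has] <- vapply(has, function(k) mean(val[bin == k]), 0)
  sd[n > 1] <- vapply(which(n > 1), function(k) stats::sd(val[bin == k]), 0)
  sd[n == 1] <- 0
  new("DepthProfile", depthBins = (edges[-1] + edges[-(nBins + 1)]) / 2,
      mean = mu, sd = sd, n = as.integer(n), dipDepth = NA_real_)
}

#' Detect the landmark dip of a depth profile
#'
#' Returns the depth of the most prominent interior local minimum of the
#' per-bin mean with prominence at least \code{minProminence}, excluding
#' the two boundary bins (partial-volume edges); \code{NA} if none exists
#' (e.g. for a monotone profile). Prominence is measured as the lower of
#' the highest profile values on either side minus the minimum itself.
#' Adding a constant to the map shifts the means but not the dip depth.
#'
#' @param profile a [DepthProfile-class] with at least 5 bins
#' @param minProminence minimum dip prominence, in map units
#' @return dip depth in [0, 1], or NA
#' @export
detectDip <- function(profile, minProminence = 0) {
  stopifnot(is(profile, "DepthProfile"))
  mu <- profile@mean
  k <- length(mu)
  if (k < 5) stop("profile needs at least 5 bins")
  bestDepth <- NA_real_; bestProm <- -Inf
  for (i in 3:(k - 2)) {  # interior, boundary bins excluded
    if (!is.finite(mu[i])) next
    left <- mu[seq_len(i - 1)]; right <- mu[(i + 1):k]
    if (!any(is.finite(left)) || !any(is.finite(right))) next
    if (mu[i] >= min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)))
      next
    nb <- c(if (i > 1) mu[i - 1], if (i < k) mu[i + 1])
    if (any(is.finite(nb) & nb < mu[i])) next  # not a local minimum
    prom <- min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)) - mu[i]
    if (prom >= minProminence && prom > bestProm) {
      bestProm <- prom
      bestDepth <- profile@depthBins[i]
    }
  }
  bestDepth
}

#' Export a depth profile as CSV
#'
#' Columns: depth, mean, sd, n.
#'
#' @param profile a [DepthProfile-class]
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(data.frame(depth = profile@depthBins,
                              mean = profile@mean, sd = profile@sd,
                              n = profile@n),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile: %d bins, %d voxels pooled%s\n",
              length(object@depthBins), sum(object@n),
              if (is.finite(object@dipDepth))
                sprintf(", dip at depth %.2f", object@dipDepth) else ""))
})
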