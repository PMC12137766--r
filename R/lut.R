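# Lookup-table T1 quantification: the forward Bloch model is evaluated on a
# T1 grid to tabulate the signed steady-state s1/s2 signal ratio, and the
# table is inverted per voxel by piecewise-linear interpolation. Because the
# spin history depends on the locally realized flip angles, tables are
# B1-specific; volumes are quantified with a family of tables binned over
# the B1 map (first-order correction for transmit inhomogeneity).

#' Build a T1 lookup table for one B1 scale
#'
#' Tabulates the steady-state TI1/TI2 signal ratio of the forward Bloch
#' model over a T1 grid at the given relative transmit field. The largest
#' contiguous sub-range over which the ratio is strictly monotonic becomes
#' the table's invertible domain; grid points outside it trigger a warning.
#'
#' @param p a validated [ProtocolParams-class]
#' @param t1Axis strictly ascending positive T1 grid (ms)
#' @param b1Scale relative transmit field the table is simulated at
#' @return a [LookupTable-class]
#' @examples
#' lut <- buildLookupTable(retrospectiveProtocol(), seq(600, 3000, by = 10))
#' lutInvert(lut, ratioOf(lut, 1500))
#' @export
buildLookupTable <- function(p, t1Axis = seq(500, 4500, by = 10),
                             b1Scale = 1) {
  validateProtocol(p)
  if (any(t1Axis <= 0) || any(diff(t1Axis) <= 0))
    stop("t1Axis must be strictly ascending and positive")
  sig <- steadyStateSignalsGrid(p, t1 = t1Axis, b1 = b1Scale)
  ratio <- sig$s1 / sig$s2
  bad <- !is.finite(ratio)
  if (any(bad)) {
    warning(sum(bad), " table entries removed (s2 = 0 or non-finite ratio)")
    t1Axis <- t1Axis[!bad]; ratio <- ratio[!bad]
  }
  dom <- longestMonotonicRun(ratio)
  if (dom[2] - dom[1] + 1L < length(t1Axis))
    warning("ratio is not strictly monotonic over the full t1Axis; ",
            "monotonic domain restricted to [", t1Axis[dom[1]], ", ",
            t1Axis[dom[2]], "] ms")
  new("LookupTable", t1Axis = t1Axis, ratioAxis = ratio,
      b1Scale = b1Scale, protocolTag = p@tag,
      monotonicDomain = c(t1Axis[dom[1]], t1Axis[dom[2]]))
}

# indices (start, end) of the longest contiguous strictly monotonic run
longestMonotonicRun <- function(x) {
  n <- length(x)
  if (n < 2) return(c(1L, n))
  s <- sign(diff(x))
  best <- c(1L, 1L); i <- 1L
  while (i <= n - 1) {
    if (s[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n - 1 && s[j + 1L] == s[i]) j <- j + 1L
    if ((j + 1L - i) > (best[2] - best[1])) best <- c(i, j + 1L)
    i <- j + 1L
  }
  as.integer(best)
}

#' Forward ratio at an arbitrary T1 (table interpolation)
#'
#' @param lut a [LookupTable-class]
#' @param t1 T1 values (ms)
#' @return interpolated s1/s2 ratio (NA outside the table)
#' @export
ratioOf <- function(lut, t1) {
  stats::approx(lut@t1Axis, lut@ratioAxis, xout = t1, rule = 1)$y
}

#' Invert a lookup table at measured signal ratios
#'
#' Piecewise-linear interpolation of the inverse map restricted to the
#' table's strictly monotonic domain. Ratios outside the tabulated range
#' return NA (out-of-domain failures stay visible rather than clamping).
#'
#' @param lut a [LookupTable-class]
#' @param ratio measured s1/s2 values (vectorized)
#' @return T1 in ms, NA where the ratio falls outside the table
#' @export
lutInvert <- function(lut, ratio) {
  stopifnot(is(lut, "LookupTable"))
  keep <- lut@t1Axis >= lut@monotonicDomain[1] &
          lut@t1Axis <= lut@monotonicDomain[2]
  x <- lut@ratioAxis[keep]; y <- lut@t1Axis[keep]
  if (length(x) > 1 && x[1] > x[length(x)]) {  # ratio decreasing in T1
    x <- rev(x); y <- rev(y)
  }
  if (length(x) < 2) {
    out <- rep(NA_real_, length(ratio))
    out[!is.na(ratio) & abs(ratio - x[1]) < 1e-12] <- y[1]
    return(out)
  }
  stats::approx(x, y, xout = ratio, rule = 1, ties = "ordered")$y
}

#' Voxelwise T1 mapping with B1-binned lookup tables
#'
#' Converts a pair of signed TI1/TI2 volumes into a quantitative T1 map.
#' One lookup table is built per B1 bin (bin centers spanning the supplied
#' B1 map's range); each voxel's s1/s2 ratio is inverted with the table of
#' its nearest bin. Voxels with \code{|s2|} below \code{s2Floor}, or whose
#' ratio falls outside the table, are NA.
#'
#' @param s1Vol,s2Vol signed 3-D signal arrays (equal shape)
#' @param p a validated [ProtocolParams-class]
#' @param b1Map 3-D relative-B1 array of the same shape, or the scalar 1
#'   for a uniform transmit field
#' @param nB1Bins number of B1 bins (tables) across the B1 map's range
#' @param t1Axis T1 grid for the tables (ms)
#' @param s2Floor minimum \code{|s2|} for a defined ratio (m0 units)
#' @return a [T1Map-class]
#' @export
mapT1 <- function(s1Vol, s2Vol, p, b1Map = 1, nB1Bins = 20L,
                  t1Axis = seq(500, 4500, by = 10), s2Floor = 1e-6) {
  if (!all(dim(s1Vol) == dim(s2Vol)))
    stop("s1Vol and s2Vol shapes differ")
  uniformB1 <- length(b1Map) == 1L
  if (!uniformB1 && !all(dim(b1Map) == dim(s1Vol)))
    stop("b1Map shape differs from the signal volumes")
  ratio <- s1Vol / s2Vol
  ratio[abs(s2Vol) < s2Floor] <- NA_real_
  vals <- rep(NA_real_, length(ratio))
  if (uniformB1) {
    lut <- buildLookupTable(p, t1Axis, b1Scale = b1Map)
    vals <- lutInvert(lut, as.numeric(ratio))
  } else {
    rng <- range(b1Map)
    centers <- if (diff(rng) < 1e-8) mean(rng) else
      seq(rng[1], rng[2], length.out = nB1Bins)
    bin <- if (length(centers) == 1L) rep(1L, length(b1Map)) else
      pmin(pmax(round((as.numeric(b1Map) - centers[1]) /
                      (centers[2] - centers[1])) + 1L, 1L), length(centers))
    for (k in seq_along(centers)) {
      idx <- which(bin == k & !is.na(ratio))
      if (!length(idx)) next
      lut <- suppressWarnings(buildLookupTable(p, t1Axis,
                                               b1Scale = centers[k]))
      vals[idx] <- lutInvert(lut, as.numeric(ratio)[idx])
    }
  }
  new("T1Map", values = array(vals, dim = dim(s1Vol)), units = "ms")
}

#' @export
setMethod("show", "LookupTable", function(object) {
  cat(sprintf("LookupTable (%s, B1 = %g): %d T1 nodes in [%g, %g] ms\n",
              object@protocolTag, object@b1Scale, length(object@t1Axis),
              min(object@t1Axis), max(object@t1Axis)))
  cat(sprintf("  ratio in [%.4f, %.4f], monotonic domain [%g, %g] ms\n",
              min(object@ratioAxis), max(object@ratioAxis),
              object@monotonicDomain[1], object@monotonicDomain[2]))
})

#' @export
setMethod("show", "T1Map", function(object) {
  v <- object@values
  cat(sprintf("T1Map: %s voxels, %d defined, median %0.0f %s\n",
              paste(dim(v), collapse = "x"), sum(!is.na(v)),
              stats::median(v, na.rm = TRUE), object@units))
})

#' Serialize a lookup table to CSV
#'
#' Two columns (t1_ms, ratio) preceded by comment-prefixed header lines
#' carrying the protocol tag, B1 scale and monotonic domain.
#'
#' @param lut a [LookupTable-class]
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeLookupTable <- function(lut, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# protocol_tag: %s", lut@protocolTag),
               sprintf("# b1_scale: %g", lut@b1Scale),
               sprintf("# monotonic_domain_ms: %g %g",
                       lut@monotonicDomain[1], lut@monotonicDomain[2]),
               "t1_ms,ratio"), con)
  writeLines(sprintf("%g,%.12g", lut@t1Axis, lut@ratioAxis), con)
  invisible(path)
}

#' Read a lookup table written by [writeLookupTable()]
#'
#' @param path CSV path
#' @return a [LookupTable-class]
#' @export
readLookupTable <- function(path) {
  hdr <- readLines(path, n = 3)
  tag <- sub("^# protocol_tag: ", "", hdr[1])
  b1 <- as.numeric(sub("^# b1_scale: ", "", hdr[2]))
  dom <- as.numeric(strsplit(sub("^# monotonic_domain_ms: ", "",
                                 hdr[3]), " ")[[1]])
  tab <- utils::read.csv(path, comment.char = "#")
  new("LookupTable", t1Axis = tab$t1_ms, ratioAxis = tab$ratio,
      b1Scale = b1, protocolTag = tag, monotonicDomain = dom)
}
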