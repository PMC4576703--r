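# Distance-binned statistics around exons and CNEs, the CNE-to-exon
# distance kernel, profile convolution ("blurring") and far-field slope
# fits.

#' Distance from positions to the nearest feature
#'
#' Returns 0 for positions inside a feature, otherwise the coordinate
#' difference to the closest feature base (adjacent base = 1).
#'
#' @param positions integer positions.
#' @param features GRanges or IRanges, non-empty.
#' @return integer distances.
#' @export
nearestFeatureDistance <- function(positions, features) {
  ir <- if (is(features, "GRanges"))
    IRanges(start(features), end(features)) else features
  if (!length(ir)) stop("empty feature set")
  ir <- reduce(ir)
  s <- start(ir); e <- end(ir)
  # index of last feature starting at or before p
  idx <- findInterval(positions, s)
  inside <- idx >= 1L & positions <= e[pmax(idx, 1L)]
  dLeft <- ifelse(idx >= 1L, positions - e[pmax(idx, 1L)], Inf)
  dRight <- ifelse(idx < length(s), s[pmin(idx + 1L, length(s))] - positions,
                   Inf)
  out <- pmin(dLeft, dRight)
  out[inside] <- 0L
  as.integer(out)
}

#' Bin per-site statistics by distance to the nearest feature
#'
#' Each site is counted once, in the bin of its distance to the nearest
#' feature: distance D >= 1 falls in bin floor((D - 1) / binBp), i.e.
#' bins are (0, binBp], (binBp, 2 binBp], ... Sites inside features
#' (distance 0) and beyond `maxDistance` are dropped. The caller is
#' responsible for excluding sites that belong to other analysis classes.
#'
#' @param positions site positions (accessible, outside features).
#' @param piContrib per-site heterozygosity contribution ([sitePi()]).
#' @param divMatch logical per site: outgroup base differs from the
#'   ingroup major allele; NA where the outgroup base is unusable.
#' @param features GRanges/IRanges of the feature set.
#' @param binBp bin width (1000 for exon flanks, 100 for CNE flanks).
#' @param maxDistance profile extent in bp.
#' @param featureType label ("exon" or "cne").
#' @return a [FlankProfile-class].
#' @export
binFlankStatistics <- function(positions, piContrib, divMatch, features,
                               binBp, maxDistance,
                               featureType = "exon") {
  stopifnot(binBp > 0)
  dist <- nearestFeatureDistance(positions, features)
  keep <- dist >= 1L & dist <= maxDistance
  bin <- (dist[keep] - 1L) %/% as.integer(binBp)
  nBins <- as.integer(ceiling(maxDistance / binBp))
  fac <- factor(bin, levels = 0:(nBins - 1L))
  nSites <- as.integer(table(fac))
  piSum <- tapply(piContrib[keep], fac, sum, default = 0)
  usable <- !is.na(divMatch[keep])
  nDiv <- tapply(usable, fac, sum, default = 0)
  nDiff <- tapply(divMatch[keep] & usable, fac, sum, default = 0,
                  na.rm = TRUE)
  pi <- ifelse(nSites > 0, piSum / nSites, NA_real_)
  d <- ifelse(nDiv > 0, nDiff / nDiv, NA_real_)
  stats <- data.frame(
    bin_start = (0:(nBins - 1L)) * binBp,
    bin_end = (1:nBins) * binBp,
    pi = as.numeric(pi), d = as.numeric(d),
    pi_over_d = ifelse(!is.na(d) & d > 0, pi / d, NA_real_),
    n_sites = nSites, n_div_sites = as.integer(nDiv))
  new("FlankProfile", featureType = featureType,
      binBp = as.integer(binBp), maxDistance = as.integer(maxDistance),
      stats = stats)
}

#' Normalized CNE-to-nearest-exon distance kernel
#'
#' For each CNE interval, the edge-to-edge gap to the nearest exon is
#' computed (0 for adjacent or overlapping); gaps above `cap` are
#' dropped, and the histogram over `binBp` bins (bin k covers
#' [k binBp, (k+1) binBp)) is normalized to sum to 1.
#'
#' @param cnes a [CNESet-class] or GRanges.
#' @param exons GRanges of exons (non-empty).
#' @param cap maximum distance retained (bp).
#' @param binBp kernel bin width.
#' @return a [DistanceKernel-class].
#' @export
cneExonDistanceKernel <- function(cnes, exons, cap = 200000L,
                                  binBp = 100L) {
  gr <- if (is(cnes, "CNESet")) cnes@intervals else granges(cnes)
  if (!length(gr) || !length(exons)) stop("both feature sets required")
  exIr <- reduce(IRanges(start(exons), end(exons)))
  gap <- vapply(seq_along(gr), function(i) {
    d <- IRanges::distance(IRanges(start(gr)[i], end(gr)[i]), exIr)
    min(d, na.rm = TRUE)
  }, numeric(1))
  gap <- gap[gap <= cap]
  if (!length(gap)) stop("all CNEs beyond cap")
  nBins <- as.integer(cap %/% binBp)
  bin <- pmin(gap %/% binBp, nBins - 1L)
  w <- tabulate(bin + 1L, nBins)
  new("DistanceKernel", weights = w / sum(w), binBp = as.integer(binBp),
      cap = as.integer(cap))
}

#' Convolve a binned profile with a distance kernel
#'
#' out[i] = sum_k kernel[k] * in[i + k], with the input padded on the
#' right by the kernel's full width using `padValue`; the output has the
#' same length as the input. This "blurs" an exon-flank profile by the
#' CNE-to-exon distance distribution.
#'
#' @param values numeric vector of per-bin values (bin width must match
#'   the kernel's).
#' @param kernel a [DistanceKernel-class].
#' @param padValue value used to extend the profile (conventionally the
#'   mean pi over the 60-100 kb distance range).
#' @return numeric vector of blurred values, same length as `values`.
#' @export
convolveProfile <- function(values, kernel, padValue) {
  w <- kernel@weights
  if (abs(sum(w) - 1) > 1e-9) stop("kernel weights must sum to 1")
  padded <- c(values, rep(padValue, length(w)))
  n <- length(values)
  out <- numeric(n)
  for (k in seq_along(w))
    if (w[k] != 0)
      out <- out + w[k] * padded[seq_len(n) + (k - 1L)]
  out
}

#' Blur a flank profile by a distance kernel
#'
#' Rebins are not performed: the profile's bin width must equal the
#' kernel's. The pad value defaults to the site-weighted mean pi over
#' the `padRange` distance window (60-100 kb), computed from the profile
#' itself.
#'
#' @param profile a [FlankProfile-class] at the kernel's bin width.
#' @param kernel a [DistanceKernel-class].
#' @param padValue override for the padding value.
#' @param padRange distance window (bp) used to compute the default pad.
#' @return a [FlankProfile-class] with blurred `pi` (other statistics
#'   dropped).
#' @export
blurFlankProfile <- function(profile, kernel, padValue = NULL,
                             padRange = c(60000, 100000)) {
  if (profile@binBp != kernel@binBp)
    stop("profile and kernel bin widths differ")
  st <- profile@stats
  if (is.null(padValue)) {
    inWin <- st$bin_start >= padRange[1] & st$bin_end <= padRange[2] &
      st$n_sites > 0
    if (!any(inWin)) stop("no sites in the padding range")
    padValue <- sum(st$pi[inWin] * st$n_sites[inWin]) /
      sum(st$n_sites[inWin])
  }
  vals <- st$pi
  vals[is.na(vals)] <- padValue
  blurred <- convolveProfile(vals, kernel, padValue)
  out <- st
  out$pi <- blurred
  out$d <- NA_real_
  out$pi_over_d <- NA_real_
  new("FlankProfile", featureType = paste0(profile@featureType,
                                           "_blurred"),
      binBp = profile@binBp, maxDistance = profile@maxDistance,
      stats = out)
}

#' Far-field slope of a flank profile
#'
#' Ordinary least squares of per-bin pi on bin-midpoint distance over
#' the bins fully inside `window`, weighted by the number of sites per
#' bin.
#'
#' @param profile a [FlankProfile-class].
#' @param window distance range in bp (default 5-20 kb).
#' @return list with `slope` (per bp), `intercept`, `stderr` (of the
#'   slope) and `nBins`.
#' @export
fitFarSlope <- function(profile, window = c(5000, 20000)) {
  st <- profile@stats
  use <- st$bin_start >= window[1] & st$bin_end <= window[2] &
    st$n_sites > 0 & !is.na(st$pi)
  if (sum(use) < 3L) stop("fewer than 3 nonempty bins in window")
  mid <- (st$bin_start[use] + st$bin_end[use]) / 2
  fit <- lm(st$pi[use] ~ mid, weights = st$n_sites[use])
  # summary() warns on exactly collinear/noiseless inputs; harmless here
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       stderr = unname(sm[2, 2]), nBins = sum(use))
}
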