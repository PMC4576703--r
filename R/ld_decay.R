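# Genotype-based r^2 LD decay and offset plain/stretched exponential
# fits with the 1/(n-1) sample floor.

#' Genotype r-squared between two sites
#'
#' Squared Pearson correlation of genotype dosages over samples with
#' both calls present (genomic r^2 in the Rogers-Huff sense, computed on
#' unphased dosages).
#'
#' @param a,b equal-length dosage vectors in 0/1/2 with NA missing.
#' @return r^2, or NA when either vector has zero variance over the
#'   complete pairs (the pair is skipped by callers).
#' @export
genotypeR2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("fewer than 2 complete pairs")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Theoretical minimum of mean r-squared for a finite sample
#'
#' @param nSamples diploid sample size n (>= 2).
#' @return 1 / (n - 1).
#' @export
theoreticalR2Floor <- function(nSamples) {
  if (nSamples < 2) stop("need n >= 2")
  1 / (nSamples - 1)
}

#' LD-decay curve around focal SNPs
#'
#' Every focal SNP is paired with every SNP within `maxDistance` on
#' either side; r^2 values are pooled into `binBp` distance bins
#' (distance D falls in bin floor((D - 1) / binBp)) and averaged per
#' bin. When the focal set is all SNPs each unordered pair is counted
#' once; for a subset, pairs are focal-to-partner with a pair of two
#' focal SNPs counted once. If a focal SNP's window holds more than
#' `nMax` partners, a uniform subsample without replacement is taken.
#' Pairs where either site has zero dosage variance are skipped.
#'
#' @param gt integer dosage matrix, samples x sites, NA missing.
#' @param positions site positions (sorted), one per column of `gt`.
#' @param focal indices (into `positions`) of the focal SNPs; defaults
#'   to all sites.
#' @param maxDistance maximum pair distance in bp.
#' @param binBp bin width in bp.
#' @param nMax per-focal-window pair budget.
#' @param seed integer seed for subsampling.
#' @param focalSet label stored on the curve.
#' @return an [LDCurve-class].
#' @export
ldDecayCurve <- function(gt, positions, focal = seq_along(positions),
                         maxDistance = 40000L, binBp = 20L, nMax = Inf,
                         seed = 1L, focalSet = "all") {
  S <- length(positions)
  stopifnot(ncol(gt) == S, nMax >= 1)
  if (!length(focal)) stop("no focal SNPs")
  if (is.unsorted(positions)) stop("positions must be sorted")
  set.seed(seed)
  isFocal <- logical(S)
  isFocal[focal] <- TRUE
  allFocal <- all(isFocal)

  r2mat <- suppressWarnings(
    cor(gt, use = "pairwise.complete.obs"))^2

  nBins <- as.integer(ceiling(maxDistance / binBp))
  sumR2 <- numeric(nBins)
  cnt <- integer(nBins)
  lo <- findInterval(positions - maxDistance - 0.5, positions) + 1L
  hi <- findInterval(positions + maxDistance + 0.5, positions)
  for (fi in which(isFocal)) {
    js <- seq(lo[fi], hi[fi])
    js <- js[js != fi]
    if (allFocal) {
      js <- js[js > fi]          # unordered pair once
    } else {
      js <- js[!(isFocal[js] & js < fi)]   # focal pair once
    }
    if (!length(js)) next
    if (length(js) > nMax)
      js <- js[sort.int(sample.int(length(js), nMax))]
    r2 <- r2mat[fi, js]
    d <- abs(positions[js] - positions[fi])
    keep <- !is.na(r2) & d >= 1L
    if (!any(keep)) next
    bin <- (d[keep] - 1L) %/% as.integer(binBp) + 1L
    tb <- tabulate(bin, nBins)
    cnt <- cnt + tb
    sr <- numeric(nBins)
    agg <- tapply(r2[keep], bin, sum)
    sr[as.integer(names(agg))] <- agg
    sumR2 <- sumR2 + sr
  }
  stats <- data.frame(
    bin_start = (0:(nBins - 1L)) * binBp,
    bin_end = (1:nBins) * binBp,
    mean_r2 = ifelse(cnt > 0, sumR2 / cnt, NA_real_),
    pair_count = cnt)
  new("LDCurve", binBp = as.integer(binBp),
      maxDistance = as.integer(maxDistance), focalSet = focalSet,
      nSamples = as.integer(nrow(gt)), stats = stats)
}

.stretchedModel <- function(x, a, b, c, d) (a - c) * exp(-(x / b)^d) + c

.fitOne <- function(x, y, w, start, lower, upper, fixD) {
  fit <- tryCatch({
    if (is.null(fixD))
      nlsLM(y ~ (a - c) * exp(-(x / b)^d) + c,
            start = start, lower = lower, upper = upper, weights = w,
            control = nls.lm.control(maxiter = 200))
    else
      nlsLM(y ~ (a - c) * exp(-(x / b)^fixD) + c,
            start = start[c("a", "b", "c")],
            lower = lower[c("a", "b", "c")],
            upper = upper[c("a", "b", "c")], weights = w,
            control = nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (is.null(fixD)) dHat <- cf[["d"]] else dHat <- fixD
  pred <- .stretchedModel(x, cf[["a"]], cf[["b"]], cf[["c"]], dHat)
  list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]], d = dHat,
       rss = sum(w * (y - pred)^2),
       converged = fit$convInfo$isConv,
       se = tryCatch(summary(fit)$coefficients[, 2],
                     error = function(e) NULL))
}

#' Fit an offset stretched exponential to an LD-decay curve
#'
#' Fits g(x) = (a - c) exp(-(x/b)^d) + c by pair-count-weighted
#' nonlinear least squares (Levenberg-Marquardt with box constraints
#' b > 0, c >= 0, 0 < d <= 1), using a deterministic multistart grid
#' over b in {100, 300, 1000, 3000, 10000} bp and d in
#' {0.3, 0.5, 0.7, 0.9, 1}; the plain-exponential solution is added as a
#' further start so the free-d fit can never be worse than the nested
#' d = 1 fit. With `fixD` set (e.g. 0.5 for comparable characteristic
#' lengths b), d is pinned.
#'
#' @param curve an [LDCurve-class] with >= 5 nonempty bins (>= 4 when d
#'   is fixed).
#' @param fixD optional fixed stretching exponent in (0, 1].
#' @return a [StretchedExpFit-class]; `converged = FALSE` with the best
#'   point found when no start converged.
#' @export
fitStretchedExponential <- function(curve, fixD = NULL) {
  st <- curve@stats
  use <- st$pair_count > 0 & !is.na(st$mean_r2)
  need <- if (is.null(fixD)) 5L else 4L
  if (sum(use) < need)
    stop("need at least ", need, " nonempty bins")
  x <- (st$bin_start[use] + st$bin_end[use]) / 2
  y <- st$mean_r2[use]
  w <- st$pair_count[use] / mean(st$pair_count[use])

  a0 <- max(y)
  c0 <- max(min(y), 1e-6)
  lower <- c(a = 0, b = 1, c = 0, d = 0.01)
  upper <- c(a = 1.5, b = 1e8, c = 1, d = 1)
  starts <- list()
  dGrid <- if (is.null(fixD)) c(0.3, 0.5, 0.7, 0.9, 1) else 1
  for (b0 in c(100, 300, 1000, 3000, 10000))
    for (d0 in dGrid)
      starts <- c(starts, list(c(a = a0, b = b0, c = c0, d = d0)))

  best <- NULL
  anyConv <- FALSE
  tryFit <- function(start, fd) {
    r <- .fitOne(x, y, w, start, lower, upper, fd)
    if (!is.null(r)) {
      if (r$converged) anyConv <<- TRUE
      if (is.null(best) || r$rss < best$rss) best <<- r
    }
  }
  if (is.null(fixD)) {
    # nested d = 1 solution as an extra start
    for (s in starts) tryFit(s, 1)
    if (!is.null(best)) {
      bp <- best
      tryFit(c(a = bp$a, b = bp$b, c = bp$c, d = 1), NULL)
    }
    for (s in starts) tryFit(s, NULL)
  } else {
    for (s in starts) tryFit(s, fixD)
  }
  if (is.null(best)) stop("all fit starts failed")
  se <- rep(NA_real_, 4)
  names(se) <- c("a", "b", "c", "d")
  if (!is.null(best$se)) se[names(best$se)] <- best$se
  new("StretchedExpFit", a = best$a, b = max(best$b, 1e-12),
      c = max(best$c, 0), d = min(max(best$d, 1e-12), 1),
      fixedD = !is.null(fixD), se = se, residualSS = best$rss,
      converged = anyConv)
}

#' Fit an offset plain exponential (d = 1)
#'
#' Equivalent to [fitStretchedExponential()] with `fixD = 1`:
#' f(x) = (a - c) exp(-x/b) + c.
#'
#' @param curve an [LDCurve-class] with >= 4 nonempty bins.
#' @return a [StretchedExpFit-class] with `d = 1`, `fixedD = TRUE`.
#' @export
fitOffsetExponential <- function(curve) {
  fitStretchedExponential(curve, fixD = 1)
}
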