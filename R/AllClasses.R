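# Central S4 containers. Coordinates are 1-based inclusive inside the
# package (IRanges convention); BED/GFF conversion happens at the I/O
# boundary via rtracklayer.

#' Piecewise-constant demographic model
#'
#' An ordered sequence of epochs (most ancient first), each with a diploid
#' effective size and a duration in non-overlapping generations. The
#' simulator burns in at the size of the most ancient epoch before the
#' epoch sequence is applied.
#'
#' @slot sizes integer vector of diploid population sizes (all >= 2).
#' @slot durations numeric vector of epoch durations in generations
#'   (all >= 1), parallel to `sizes`.
#' @export
setClass("DemographyModel",
  representation(sizes = "integer", durations = "numeric"))

setValidity("DemographyModel", function(object) {
  if (length(object@sizes) < 1L) return("at least one epoch is required")
  if (length(object@sizes) != length(object@durations))
    return("sizes and durations must have equal length")
  if (any(object@sizes < 2L)) return("all epoch sizes must be >= 2")
  if (any(object@durations < 1)) return("all epoch durations must be >= 1")
  TRUE
})

#' @param sizes diploid sizes per epoch, most ancient first.
#' @param durations epoch durations in generations.
#' @rdname DemographyModel-class
#' @export
DemographyModel <- function(sizes, durations) {
  new("DemographyModel", sizes = as.integer(sizes),
      durations = as.numeric(durations))
}

setMethod("show", "DemographyModel", function(object) {
  cat("DemographyModel with", length(object@sizes), "epoch(s):\n")
  for (i in seq_along(object@sizes))
    cat(sprintf("  N = %d for %g generations\n",
                object@sizes[i], object@durations[i]))
})

#' Per-position selection coefficients
#'
#' Maps every position of a simulated region to a selection coefficient
#' `s` (fitness deficit of the derived allele; 0 = neutral) and a class
#' label used when generating ground truth.
#'
#' @slot s numeric vector, length L, all >= 0.
#' @slot label character vector, length L, one of `"exon"`, `"cne"`,
#'   `"neutral"`.
#' @export
setClass("SelectionMap", representation(s = "numeric", label = "character"))

setValidity("SelectionMap", function(object) {
  if (length(object@s) != length(object@label))
    return("s and label must have equal length")
  if (any(object@s < 0)) return("selection coefficients must be >= 0")
  if (any(object@s[object@label == "neutral"] != 0))
    return("neutral positions must have s = 0")
  if (!all(object@label %in% c("exon", "cne", "neutral")))
    return("labels must be exon, cne or neutral")
  TRUE
})

#' @param s numeric vector of selection coefficients.
#' @param label class label per position.
#' @rdname SelectionMap-class
#' @export
SelectionMap <- function(s, label = rep("neutral", length(s))) {
  new("SelectionMap", s = as.numeric(s), label = as.character(label))
}

#' A simulated diploid cohort with full ground truth
#'
#' Holds the reference and outgroup sequences, sampled haplotypes and
#' genotype dosages over the whole region, the per-sample depth and
#' per-site quality models used to exercise filters, the annotation, and
#' the `truth` list recording every simulation parameter.
#'
#' @slot chrom chromosome name used in emitted files.
#' @slot reference character scalar, the L-base reference sequence.
#' @slot outgroup character scalar, base-per-reference-position outgroup.
#' @slot haplotypes integer matrix (2 n_sample x L) of derived-allele
#'   indicators for the sampled haplotypes.
#' @slot genotypes integer matrix (n_sample x L) of dosages in 0/1/2 with
#'   NA for missing calls.
#' @slot altAllele character vector length L: the alternative base at
#'   positions segregating or fixed-derived in the sample, NA elsewhere.
#' @slot depth integer matrix (n_sample x L) of simulated read depths.
#' @slot qual numeric vector length L of site quality scores.
#' @slot exons GRanges of exon (single-CDS transcript) intervals with
#'   strand; metadata column `transcript_id`.
#' @slot cnes GRanges of conserved-noncoding-element intervals.
#' @slot truth list of generating parameters (mu, rec, demography, seed,
#'   t_split, missing_rate, sample size, ...).
#' @export
setClass("SimulatedCohort",
  representation(chrom = "character", reference = "character",
    outgroup = "character", haplotypes = "matrix", genotypes = "matrix",
    altAllele = "character", depth = "matrix", qual = "numeric",
    exons = "GRanges", cnes = "GRanges", truth = "list"))

setValidity("SimulatedCohort", function(object) {
  L <- nchar(object@reference)
  if (nchar(object@outgroup) != L)
    return("outgroup length must equal reference length")
  if (ncol(object@haplotypes) != L || ncol(object@genotypes) != L)
    return("haplotype/genotype matrices must have L columns")
  if (nrow(object@haplotypes) != 2L * nrow(object@genotypes))
    return("haplotypes must have two rows per diploid sample")
  # dosage consistency at non-missing entries
  dos <- object@haplotypes[seq(1L, nrow(object@haplotypes), 2L), , drop = FALSE] +
         object@haplotypes[seq(2L, nrow(object@haplotypes), 2L), , drop = FALSE]
  ok <- is.na(object@genotypes) | object@genotypes == dos
  if (!all(ok)) return("genotype dosages inconsistent with haplotypes")
  TRUE
})

setMethod("show", "SimulatedCohort", function(object) {
  nv <- sum(!is.na(object@altAllele))
  cat(sprintf(
    "SimulatedCohort: %d samples, %d bp on %s, %d variant positions\n",
    nrow(object@genotypes), nchar(object@reference), object@chrom, nv))
  cat(sprintf("  exons: %d  CNEs: %d  seed: %s\n",
              length(object@exons), length(object@cnes),
              as.character(object@truth$seed)))
})

#' Post-call filter configuration
#'
#' Defaults follow the filter stack used for a 12-sample cohort: site
#' quality >= 23, inbreeding coefficient F >= -0.8 (evaluated only when at
#' least `fMinSamples` samples are called), per-sample depth within 25%-
#' 300% of that sample's modal coverage (failing samples are set missing),
#' mean normalized coverage within 50%-140%, and at least 3 samples still
#' called. `proximityMd = 5` removes variant sites closer than 5 bp to
#' another variant site; 0 disables the filter.
#'
#' @slot minQual minimum site quality score.
#' @slot fMin minimum inbreeding coefficient.
#' @slot fMinSamples called-sample count below which F is not evaluated.
#' @slot perSampleCovBounds length-2 fractions of per-sample modal coverage.
#' @slot meanCovBounds length-2 fractions bounding mean normalized coverage.
#' @slot minCalled minimum called samples for a site to pass.
#' @slot proximityMd proximity-filter distance in bp (0 = off).
#' @slot cpgExclude whether CpG-prone sites are excluded downstream.
#' @export
setClass("FilterConfig",
  representation(minQual = "numeric", fMin = "numeric",
    fMinSamples = "integer", perSampleCovBounds = "numeric",
    meanCovBounds = "numeric", minCalled = "integer",
    proximityMd = "integer", cpgExclude = "logical"))

setValidity("FilterConfig", function(object) {
  if (length(object@perSampleCovBounds) != 2L ||
      diff(object@perSampleCovBounds) <= 0)
    return("perSampleCovBounds must be an increasing pair")
  if (length(object@meanCovBounds) != 2L || diff(object@meanCovBounds) <= 0)
    return("meanCovBounds must be an increasing pair")
  if (object@proximityMd < 0L) return("proximityMd must be >= 0")
  if (object@minCalled < 1L) return("minCalled must be >= 1")
  TRUE
})

#' @param minQual,fMin,fMinSamples,perSampleCovBounds,meanCovBounds
#'   see slots.
#' @param minCalled,proximityMd,cpgExclude see slots.
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(minQual = 23, fMin = -0.8, fMinSamples = 10L,
                         perSampleCovBounds = c(0.25, 3.0),
                         meanCovBounds = c(0.5, 1.4), minCalled = 3L,
                         proximityMd = 0L, cpgExclude = FALSE) {
  new("FilterConfig", minQual = minQual, fMin = fMin,
      fMinSamples = as.integer(fMinSamples),
      perSampleCovBounds = perSampleCovBounds,
      meanCovBounds = meanCovBounds, minCalled = as.integer(minCalled),
      proximityMd = as.integer(proximityMd), cpgExclude = cpgExclude)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0(
    "FilterConfig: QUAL >= %g, F >= %g (>= %d called), per-sample depth ",
    "in [%g, %g] x modal,\n  mean normalized depth in [%g, %g], ",
    ">= %d called, proximity md = %d bp, cpgExclude = %s\n"),
    object@minQual, object@fMin, object@fMinSamples,
    object@perSampleCovBounds[1], object@perSampleCovBounds[2],
    object@meanCovBounds[1], object@meanCovBounds[2], object@minCalled,
    object@proximityMd, object@cpgExclude))
})

#' Accessible-site bookkeeping
#'
#' One status per considered position: `"pass"` or `"fail:<reason>"`,
#' where `<reason>` is the first failing filter. All denominators in the
#' statistics modules are taken over `passPositions()`.
#'
#' @slot chrom chromosome name.
#' @slot pos integer positions (1-based, sorted).
#' @slot status character, `"pass"` or `"fail:<reason>"` per position.
#' @export
setClass("CallabilityMask",
  representation(chrom = "character", pos = "integer", status = "character"))

setValidity("CallabilityMask", function(object) {
  if (length(object@pos) != length(object@status))
    return("pos and status must have equal length")
  if (is.unsorted(object@pos, strictly = TRUE))
    return("positions must be strictly increasing")
  bad <- !(object@status == "pass" | startsWith(object@status, "fail:"))
  if (any(bad)) return("status must be 'pass' or 'fail:<reason>'")
  TRUE
})

setMethod("show", "CallabilityMask", function(object) {
  cat(sprintf("CallabilityMask on %s: %d positions, %d pass\n",
              object@chrom, length(object@pos),
              sum(object@status == "pass")))
  tab <- table(object@status[object@status != "pass"])
  if (length(tab))
    for (i in seq_along(tab))
      cat(sprintf("  %s: %d\n", names(tab)[i], tab[[i]]))
})

#' Per-sample modal coverage
#'
#' @slot modal named integer vector, modal depth per sample (all >= 1).
#' @export
setClass("CoverageProfile", representation(modal = "integer"))

setValidity("CoverageProfile", function(object) {
  if (any(object@modal < 1L)) return("modal coverage must be >= 1")
  TRUE
})

#' Per-position analysis classes
#'
#' Assignment of every position of a region to one analysis class:
#' consistently 0-, 2- or 4-fold degenerate exonic site, CNE, CNE neutral
#' flank, unclassified (`none`), or `excluded` with a reason
#' (`inconsistent_degeneracy`, `threefold`, `invalid_transcript`, ...).
#'
#' @slot chrom chromosome name.
#' @slot classes factor of length L with levels fold0, fold2, fold4, cne,
#'   cne_flank, none, excluded.
#' @slot reason character of length L; non-NA only where excluded.
#' @export
setClass("SiteClassMap",
  representation(chrom = "character", classes = "factor",
                 reason = "character"))

.SITE_CLASS_LEVELS <- c("fold0", "fold2", "fold4", "cne", "cne_flank",
                        "none", "excluded")

setValidity("SiteClassMap", function(object) {
  if (!identical(levels(object@classes), .SITE_CLASS_LEVELS))
    return("classes must use the canonical level set")
  if (length(object@reason) != length(object@classes))
    return("reason must parallel classes")
  TRUE
})

setMethod("show", "SiteClassMap", function(object) {
  cat(sprintf("SiteClassMap on %s: %d positions\n", object@chrom,
              length(object@classes)))
  print(table(object@classes))
})

#' Folded site-frequency spectrum at a fixed projected sample size
#'
#' `counts[k + 1]` holds the (possibly fractional, after hypergeometric
#' projection) number of sites with minor-allele count k among `nProj`
#' haploid genomes; bin 0 holds monomorphic accessible sites.
#'
#' @slot nProj haploid projected sample size.
#' @slot counts numeric vector of length floor(nProj/2) + 1.
#' @slot label site-class label.
#' @slot nSkipped number of sites skipped because fewer than nProj
#'   alleles were called.
#' @export
setClass("FoldedSFS",
  representation(nProj = "integer", counts = "numeric", label = "character",
                 nSkipped = "integer"))

setValidity("FoldedSFS", function(object) {
  if (length(object@counts) != floor(object@nProj / 2) + 1L)
    return("counts must have floor(nProj/2) + 1 bins")
  if (any(object@counts < -1e-9)) return("counts must be >= 0")
  TRUE
})

setMethod("show", "FoldedSFS", function(object) {
  cat(sprintf("FoldedSFS (%s): nProj = %d, %g sites (%d skipped)\n",
              object@label, object@nProj, sum(object@counts),
              object@nSkipped))
  print(round(object@counts, 3))
})

#' Distance kernel over 100 bp bins
#'
#' Normalized distribution of CNE-to-nearest-exon distances used to
#' convolve ("blur") exon-flank profiles.
#'
#' @slot weights numeric, non-negative, summing to 1; bin k covers
#'   distances ((k-1) binBp, k binBp].
#' @slot binBp bin width in bp.
#' @slot cap maximum distance retained, in bp.
#' @export
setClass("DistanceKernel",
  representation(weights = "numeric", binBp = "integer", cap = "integer"))

setValidity("DistanceKernel", function(object) {
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  TRUE
})

#' Distance-binned statistics around features
#'
#' @slot featureType `"exon"` or `"cne"`.
#' @slot binBp bin width in bp.
#' @slot maxDistance largest distance profiled, in bp.
#' @slot stats data.frame with columns bin_start, bin_end (distance range,
#'   half-open (start, end]), pi, d, pi_over_d, n_sites, n_div_sites.
#' @export
setClass("FlankProfile",
  representation(featureType = "character", binBp = "integer",
                 maxDistance = "integer", stats = "data.frame"))

setMethod("show", "FlankProfile", function(object) {
  cat(sprintf("FlankProfile (%s flanks): %d bins of %d bp up to %d bp\n",
              object@featureType, nrow(object@stats), object@binBp,
              object@maxDistance))
})

#' Mean r-squared per distance bin
#'
#' @slot binBp bin width in bp (20 by default).
#' @slot maxDistance maximum pair distance in bp.
#' @slot focalSet label of the focal-SNP set (all/exon/cne).
#' @slot nSamples diploid sample size (sets the 1/(n-1) floor).
#' @slot stats data.frame with columns bin_start, bin_end, mean_r2,
#'   pair_count.
#' @export
setClass("LDCurve",
  representation(binBp = "integer", maxDistance = "integer",
                 focalSet = "character", nSamples = "integer",
                 stats = "data.frame"))

setValidity("LDCurve", function(object) {
  r2 <- object@stats$mean_r2
  if (any(r2 < -1e-9 | r2 > 1 + 1e-9, na.rm = TRUE))
    return("mean_r2 must lie in [0, 1]")
  if (any(object@stats$pair_count < 0)) return("pair_count must be >= 0")
  TRUE
})

setMethod("show", "LDCurve", function(object) {
  cat(sprintf(
    "LDCurve (focal = %s): %d bins of %d bp, %d pairs, n = %d samples\n",
    object@focalSet, nrow(object@stats), object@binBp,
    sum(object@stats$pair_count), object@nSamples))
})

#' Offset (stretched) exponential fit to an LD-decay curve
#'
#' Model g(x) = (a - c) exp(-(x/b)^d) + c with intercept a, characteristic
#' length b (bp), offset c (floored at 0), and stretching exponent
#' 0 < d <= 1; d = 1 gives the plain offset exponential.
#'
#' @slot a,b,c,d fitted parameters.
#' @slot fixedD TRUE when d was pinned rather than estimated.
#' @slot se named numeric of standard errors (NA where unavailable).
#' @slot residualSS weighted residual sum of squares.
#' @slot converged whether the optimizer reported convergence.
#' @export
setClass("StretchedExpFit",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
    fixedD = "logical", se = "numeric", residualSS = "numeric",
    converged = "logical"))

setValidity("StretchedExpFit", function(object) {
  if (object@b <= 0) return("b must be > 0")
  if (object@d <= 0 || object@d > 1) return("d must be in (0, 1]")
  if (object@c < 0) return("c must be >= 0")
  TRUE
})

setMethod("show", "StretchedExpFit", function(object) {
  cat(sprintf(paste0(
    "StretchedExpFit: a = %.4g, b = %.4g bp, c = %.4g, d = %.3g%s\n",
    "  residual SS = %.4g, converged = %s\n"),
    object@a, object@b, object@c, object@d,
    if (object@fixedD) " (fixed)" else "", object@residualSS,
    object@converged))
})

#' In-memory variant table
#'
#' Column-oriented representation of a (single-chromosome) VCF slice:
#' site-level fields plus per-sample dosage and depth matrices. Invariant
#' records (ALT = ".") are retained so that accessible-site denominators
#' can be computed; indel records are held separately for masking.
#'
#' @slot chrom chromosome name.
#' @slot pos integer positions, 1-based, sorted.
#' @slot ref,alt reference / alternative base per site (alt NA when
#'   invariant).
#' @slot qual numeric site quality.
#' @slot f numeric inbreeding coefficient (NA when absent).
#' @slot gt integer matrix (sites x samples) of dosages with NA missing.
#' @slot dp integer matrix (sites x samples) of depths.
#' @slot multiallelic logical per site.
#' @slot indels data.frame with columns pos, ref, alt, type ("ins"/"del"),
#'   len.
#' @export
setClass("VariantTable",
  representation(chrom = "character", pos = "integer", ref = "character",
    alt = "character", qual = "numeric", f = "numeric", gt = "matrix",
    dp = "matrix", multiallelic = "logical", indels = "data.frame"))

setValidity("VariantTable", function(object) {
  n <- length(object@pos)
  if (nrow(object@gt) != n || nrow(object@dp) != n)
    return("gt/dp must have one row per site")
  if (is.unsorted(object@pos)) return("positions must be sorted")
  TRUE
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf(
    "VariantTable on %s: %d sites (%d variant, %d multiallelic), %d samples, %d indels\n",
    object@chrom, length(object@pos), sum(!is.na(object@alt)),
    sum(object@multiallelic), ncol(object@gt), nrow(object@indels)))
})
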