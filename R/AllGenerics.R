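# Generics and simple accessors.

#' Positions passing all filters recorded in a mask
#'
#' @param x a [CallabilityMask-class].
#' @return sorted integer vector of passing positions.
#' @export
setGeneric("passPositions", function(x) standardGeneric("passPositions"))

#' @rdname passPositions
#' @export
setMethod("passPositions", "CallabilityMask", function(x)
  x@pos[x@status == "pass"])

#' Tabulate failure reasons of a mask
#'
#' @param x a [CallabilityMask-class].
#' @return named integer vector of counts per status (including pass).
#' @export
setGeneric("maskSummary", function(x) standardGeneric("maskSummary"))

#' @rdname maskSummary
#' @export
setMethod("maskSummary", "CallabilityMask", function(x) {
  tab <- table(x@status)
  setNames(as.integer(tab), names(tab))
})

#' Modal coverage per sample
#'
#' @param x a [CoverageProfile-class].
#' @return named integer vector.
#' @export
setGeneric("modalCoverage", function(x) standardGeneric("modalCoverage"))

#' @rdname modalCoverage
#' @export
setMethod("modalCoverage", "CoverageProfile", function(x) x@modal)

#' Positions carrying a given analysis class
#'
#' @param x a [SiteClassMap-class].
#' @param class one of `"fold0"`, `"fold2"`, `"fold4"`, `"cne"`,
#'   `"cne_flank"`, `"none"`, `"excluded"`.
#' @return integer positions.
#' @export
setGeneric("sitesOfClass", function(x, class) standardGeneric("sitesOfClass"))

#' @rdname sitesOfClass
#' @export
setMethod("sitesOfClass", "SiteClassMap", function(x, class) {
  class <- match.arg(class, .SITE_CLASS_LEVELS)
  which(x@classes == class)
})

#' SFS counts accessor
#'
#' @param x a [FoldedSFS-class].
#' @return numeric vector of per-bin counts (bin 0 first).
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname sfsCounts
#' @export
setMethod("sfsCounts", "FoldedSFS", function(x) x@counts)

#' Per-bin statistics table of a profile or curve
#'
#' @param x a [FlankProfile-class], [LDCurve-class] or [DistanceKernel-class].
#' @return data.frame of per-bin values.
#' @export
setGeneric("binStats", function(x) standardGeneric("binStats"))

#' @rdname binStats
#' @export
setMethod("binStats", "FlankProfile", function(x) x@stats)

#' @rdname binStats
#' @export
setMethod("binStats", "LDCurve", function(x) x@stats)

#' @rdname binStats
#' @export
setMethod("binStats", "DistanceKernel", function(x)
  data.frame(bin_start = (seq_along(x@weights) - 1L) * x@binBp,
             bin_end = seq_along(x@weights) * x@binBp,
             weight = x@weights))

#' Fitted parameters of an LD-decay fit
#'
#' @param object a [StretchedExpFit-class].
#' @param ... unused.
#' @return named numeric `c(a, b, c, d)`.
#' @export
setMethod("coef", "StretchedExpFit", function(object, ...)
  c(a = object@a, b = object@b, c = object@c, d = object@d))

#' Number of samples / genotype dosages of a variant table
#'
#' @param x a [VariantTable-class].
#' @return `dosageMatrix`: integer matrix sites x samples; `variantPositions`:
#'   positions of biallelic SNVs segregating or fixed-derived.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname dosageMatrix
#' @export
setMethod("dosageMatrix", "VariantTable", function(x) x@gt)

#' @rdname dosageMatrix
#' @export
setGeneric("variantPositions", function(x)
  standardGeneric("variantPositions"))

#' @rdname dosageMatrix
#' @export
setMethod("variantPositions", "VariantTable", function(x)
  x@pos[!is.na(x@alt) & !x@multiallelic])

#' Indel records of a variant table
#'
#' @param x a [VariantTable-class].
#' @return data.frame with columns pos, ref, alt, type, len.
#' @export
setGeneric("indelRecords", function(x) standardGeneric("indelRecords"))

#' @rdname indelRecords
#' @export
setMethod("indelRecords", "VariantTable", function(x) x@indels)
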