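# Reading variant data and the post-call filter stack. All denominators
# downstream are taken over the CallabilityMask produced here.

#' Read a multi-sample VCF into a VariantTable
#'
#' Reads a VCF v4.x (via vcfR), checks coordinate order, converts
#' genotypes to dosages, flags multi-allelic SNVs, and routes indel
#' records into the table's `indels` slot (retrievable with
#' [indelRecords()]) for use by [indelMask()]. Invariant records
#' (ALT = ".") are kept so accessible-site denominators can be formed.
#'
#' @param vcfPath path to an (uncompressed or bgzipped) VCF.
#' @return a [VariantTable-class].
#' @export
readVariants <- function(vcfPath) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(new("VariantTable", chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), qual = numeric(0),
               f = numeric(0), gt = matrix(NA_integer_, 0, 0),
               dp = matrix(NA_integer_, 0, 0), multiallelic = logical(0),
               indels = data.frame(pos = integer(0), ref = character(0),
                 alt = character(0), type = character(0),
                 len = integer(0))))
  chrom <- unname(fix[, "CHROM"])
  pos <- unname(as.integer(fix[, "POS"]))
  bad <- which(chrom[-1] == chrom[-n] & diff(pos) <= 0)
  if (length(bad))
    stop(sprintf("VCF not coordinate-sorted: record %d (%s:%d)",
                 bad[1] + 1L, chrom[bad[1] + 1L], pos[bad[1] + 1L]))
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  alt[alt %in% c(".", "")] <- NA_character_
  qual <- unname(suppressWarnings(as.numeric(fix[, "QUAL"])))
  info <- unname(fix[, "INFO"])
  f <- suppressWarnings(as.numeric(sub(".*(?:^|;)F=([^;]+).*", "\\1",
                                       info, perl = TRUE)))
  f[!grepl("(^|;)F=", info)] <- NA_real_

  multiallelic <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  firstAlt <- sub(",.*", "", alt)
  isIndel <- !is.na(alt) & !multiallelic &
    (nchar(ref) != 1L | nchar(firstAlt) != 1L)

  gtChar <- vcfR::extract.gt(vcf, element = "GT")
  dpChar <- vcfR::extract.gt(vcf, element = "DP")
  toDosage <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  gt <- matrix(toDosage(gtChar), nrow = n,
               dimnames = list(NULL, colnames(gtChar)))
  dp <- matrix(suppressWarnings(as.integer(dpChar)), nrow = n,
               dimnames = list(NULL, colnames(dpChar)))

  idx <- which(isIndel)
  indels <- data.frame(pos = integer(0), ref = character(0),
                       alt = character(0), type = character(0),
                       len = integer(0), stringsAsFactors = FALSE)
  if (length(idx)) {
    del <- nchar(ref[idx]) > nchar(firstAlt[idx])
    indels <- data.frame(
      # del: pos of the first deleted base; ins: base before the insertion
      pos = ifelse(del, pos[idx] + 1L, pos[idx]),
      ref = ref[idx], alt = firstAlt[idx],
      type = ifelse(del, "del", "ins"),
      len = abs(nchar(ref[idx]) - nchar(firstAlt[idx])),
      stringsAsFactors = FALSE)
  }
  keep <- !isIndel
  new("VariantTable", chrom = unique(chrom)[1], pos = pos[keep],
      ref = ref[keep], alt = firstAlt[keep], qual = qual[keep],
      f = f[keep], gt = gt[keep, , drop = FALSE],
      dp = dp[keep, , drop = FALSE], multiallelic = multiallelic[keep],
      indels = indels)
}

#' Modal coverage per sample from depth histograms
#'
#' The modal coverage is the depth bin with the largest count, computed
#' over positive depths (a genome-wide mode of zero means the sample is
#' unusable). Ties are broken toward the smallest depth, which is
#' conservative against duplicated regions inflating coverage.
#'
#' @param histograms a named list, one element per sample, each a named
#'   count vector (names are integer depths), e.g. from `table(depths)`;
#'   or an integer depth matrix (sites x samples) from which histograms
#'   are tabulated.
#' @return a [CoverageProfile-class].
#' @export
computeModalCoverage <- function(histograms) {
  if (is.matrix(histograms))
    histograms <- lapply(seq_len(ncol(histograms)), function(j) {
      h <- table(histograms[, j])
      stats::setNames(as.numeric(h), names(h))
    })
  modal <- vapply(histograms, function(h) {
    if (!length(h) || sum(h) == 0) stop("no usable coverage: empty histogram")
    depths <- as.integer(names(h))
    keep <- depths > 0L & h > 0
    if (!any(keep)) stop("no usable coverage: all depth mass at zero")
    depths <- depths[keep]; counts <- h[keep]
    depths[order(-counts, depths)][1]
  }, integer(1))
  if (is.null(names(modal)) || any(names(modal) == ""))
    names(modal) <- sprintf("s%02d", seq_along(modal))
  new("CoverageProfile", modal = modal)
}

#' Per-site inbreeding coefficient
#'
#' F = 1 - H_obs / H_exp with H_obs the fraction of heterozygous calls
#' among called samples and H_exp = 2 p (1 - p) from the called allele
#' frequency. Not computed (NA) when fewer than `minSamples` samples are
#' called or when H_exp is zero.
#'
#' @param gt integer dosage vector (0/1/2, NA = missing) at one site.
#' @param minSamples minimum called samples required.
#' @return F, or NA when absent.
#' @export
inbreedingCoefficient <- function(gt, minSamples = 10L) {
  called <- gt[!is.na(gt)]
  nc <- length(called)
  if (nc < minSamples) return(NA_real_)
  p <- sum(called) / (2 * nc)
  hExp <- 2 * p * (1 - p)
  if (hExp == 0) return(NA_real_)
  1 - mean(called == 1L) / hExp
}

#' Apply the site-level filter stack
#'
#' A site passes iff: it is not multi-allelic; QUAL >= `minQual`; the
#' inbreeding coefficient (taken from the VCF INFO F where present,
#' otherwise computed from the genotypes when at least `fMinSamples`
#' samples are called) is absent or >= `fMin`; the mean over all samples
#' of depth / that sample's modal coverage lies within `meanCovBounds`;
#' and at least `minCalled` samples remain called after samples whose
#' depth falls outside `perSampleCovBounds` x modal have been set
#' missing. The mask records the first failing reason per site, in that
#' order.
#'
#' @param vt a [VariantTable-class].
#' @param coverage a [CoverageProfile-class] covering all samples.
#' @param config a [FilterConfig-class].
#' @return list with `records` (the VariantTable with out-of-bounds
#'   sample calls set missing) and `mask` (a [CallabilityMask-class] over
#'   the table's positions).
#' @export
applySiteFilters <- function(vt, coverage, config = FilterConfig()) {
  modal <- coverage@modal
  if (length(modal) != ncol(vt@gt))
    stop("coverage profile does not cover all samples (",
         length(modal), " vs ", ncol(vt@gt), ")")
  n <- length(vt@pos)
  status <- rep("pass", n)

  fVal <- vt@f
  need <- which(is.na(fVal))
  if (length(need))
    fVal[need] <- apply(vt@gt[need, , drop = FALSE], 1,
                        inbreedingCoefficient,
                        minSamples = config@fMinSamples)

  norm <- sweep(vt@dp, 2, modal, "/")
  meanNorm <- rowMeans(norm, na.rm = TRUE)
  inSample <- !is.na(norm) & norm >= config@perSampleCovBounds[1] &
    norm <= config@perSampleCovBounds[2]
  gt <- vt@gt
  gt[!inSample] <- NA_integer_
  nCalled <- rowSums(!is.na(gt))

  fail <- function(cond, reason) {
    hit <- which(cond & status == "pass")
    status[hit] <<- paste0("fail:", reason)
  }
  fail(vt@multiallelic, "multiallelic")
  fail(is.na(vt@qual) | vt@qual < config@minQual, "qual")
  fail(!is.na(fVal) & fVal < config@fMin, "F")
  fail(!is.finite(meanNorm) | meanNorm < config@meanCovBounds[1] |
       meanNorm > config@meanCovBounds[2], "coverage")
  fail(nCalled < config@minCalled, "min_called")

  out <- vt
  out@gt <- gt
  mask <- new("CallabilityMask", chrom = vt@chrom, pos = vt@pos,
              status = status)
  list(records = out, mask = mask)
}

#' Variant-proximity filter
#'
#' Removes every variant position that lies at a distance strictly less
#' than `md` bp from another *original* variant position; evaluation uses
#' the pre-removal positions, so removals do not cascade.
#'
#' @param positions sorted integer variant positions (one chromosome).
#' @param md distance threshold in bp; `md = 0` disables the filter.
#' @return the retained positions.
#' @export
proximityFilter <- function(positions, md) {
  stopifnot(md >= 0)
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (md == 0L || length(positions) < 2L) return(positions)
  gap <- diff(positions)
  tooClose <- c(gap < md, FALSE) | c(FALSE, gap < md)
  positions[!tooClose]
}

#' Mask positions around indels
#'
#' A deletion of length L whose first deleted base is at `pos` masks
#' `[pos - 1, pos + L]`; an insertion of length L between `pos` and
#' `pos + 1` masks `[pos - L, pos + 1 + L]` (the inserted length on
#' either side plus the two flanking bases). Overlapping spans are
#' merged.
#'
#' @param indels data.frame with columns `pos`, `type` ("del"/"ins") and
#'   `len`, as produced by [readVariants()] / [indelRecords()].
#' @param L optional region length for clipping.
#' @return an `IRanges` of merged masked spans.
#' @export
indelMask <- function(indels, L = NULL) {
  if (nrow(indels) == 0L) return(IRanges())
  if (any(indels$len < 0)) stop("negative indel length")
  del <- indels$type == "del"
  from <- ifelse(del, indels$pos - 1L, indels$pos - indels$len)
  to <- ifelse(del, indels$pos + indels$len, indels$pos + 1L + indels$len)
  from <- pmax(from, 1L)
  if (!is.null(L)) to <- pmin(to, L)
  reduce(IRanges(from, to))
}

#' Flag CpG-prone positions
#'
#' A position is CpG-prone iff, in any of the provided aligned
#' sequences, the preceding base is C or the following base is G. The
#' first and last positions evaluate only their existing neighbor.
#'
#' @param sequences character vector (or DNAStringSet) of equal-length
#'   sequences on the same coordinates (e.g. reference and outgroup).
#' @return logical vector of length L.
#' @export
cpgProneMask <- function(sequences) {
  sequences <- as.character(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  L <- lens[1]
  flag <- logical(L)
  for (s in sequences) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    prevC <- c(FALSE, b[-L] == "C")
    nextG <- c(b[-1] == "G", FALSE)
    flag <- flag | prevC | nextG
  }
  flag
}
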