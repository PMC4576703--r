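# Classification of positions into analysis classes: consistently 0/2/4-
# fold degenerate exonic sites, CNE set variants, and CNE neutral flanks.

#' A CNE set variant
#'
#' @slot intervals GRanges; split segments inherit the original element id
#'   in metadata column `element_id`.
#' @slot variant `"noOverlap"` (exon-overlapping segments trimmed),
#'   `"strict"` (elements with any exon overlap dropped) or
#'   `"noOverlap_lt1kb"` (noOverlap restricted to elements shorter than
#'   1 kb).
#' @export
setClass("CNESet",
  representation(intervals = "GRanges", variant = "character"))

setMethod("show", "CNESet", function(object) {
  cat(sprintf("CNESet (%s): %d intervals, %d bp\n", object@variant,
              length(object@intervals), sum(width(object@intervals))))
})

#' Intervals of a CNE set
#' @param x a [CNESet-class].
#' @return GRanges.
#' @export
setGeneric("cneIntervals", function(x) standardGeneric("cneIntervals"))

#' @rdname cneIntervals
#' @export
setMethod("cneIntervals", "CNESet", function(x) x@intervals)

# degeneracy of codon position: number of the 3 possible substitutions
# that leave the amino acid unchanged, mapped 0 -> fold0, 1 -> fold2,
# 3 -> fold4; 2 (3-fold, e.g. Ile position 3) is excluded.
.degeneracyTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- names(GENETIC_CODE)
    m <- matrix(NA_integer_, 64, 3, dimnames = list(codons, NULL))
    for (cd in codons) {
      for (p in 1:3) {
        alts <- vapply(setdiff(c("A", "C", "G", "T"),
                               substr(cd, p, p)), function(b) {
          x <- cd
          substr(x, p, p) <- b
          GENETIC_CODE[[x]] == GENETIC_CODE[[cd]]
        }, logical(1))
        m[cd, p] <- sum(alts)
      }
    }
    tab <<- m
    m
  }
})

#' Validate a CDS sequence as a complete transcript
#'
#' A transcript is complete iff its CDS length is a multiple of 3, it
#' starts with ATG, terminates with a stop codon, and contains no
#' internal stop codon.
#'
#' @param cdsSequence character scalar: the CDS assembled 5' to 3'
#'   (reverse-complemented for minus-strand transcripts).
#' @return list with `valid` (logical) and `reason` (NA or one of
#'   `ambiguous_base`, `length_not_multiple_of_3`, `no_start_codon`,
#'   `no_stop_codon`, `premature_stop`).
#' @export
validateTranscript <- function(cdsSequence) {
  bad <- function(reason) list(valid = FALSE, reason = reason)
  if (grepl("[^ACGT]", cdsSequence)) return(bad("ambiguous_base"))
  n <- nchar(cdsSequence)
  if (n %% 3L != 0L || n < 6L) return(bad("length_not_multiple_of_3"))
  codons <- substring(cdsSequence, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  if (codons[1] != "ATG") return(bad("no_start_codon"))
  if (any(GENETIC_CODE[codons[-length(codons)]] == "*"))
    return(bad("premature_stop"))
  if (!codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    return(bad("no_stop_codon"))
  list(valid = TRUE, reason = NA_character_)
}

# genomic positions of a transcript's CDS bases in 5'->3' order
.cdsPositions <- function(intervals, minus) {
  ord <- order(start(intervals))
  gpos <- unlist(lapply(ord, function(i)
    start(intervals)[i]:end(intervals)[i]))
  if (minus) rev(gpos) else gpos
}

#' Classify exonic positions by codon degeneracy
#'
#' For every valid (complete) transcript, each CDS position is assigned
#' the degeneracy of its codon position (0-, 2- or 4-fold; 3-fold
#' positions are excluded). A reference position obtains a fold class iff
#' all valid transcripts covering it agree; disagreements are excluded
#' with reason `inconsistent_degeneracy`, and positions covered only by
#' invalid transcripts with reason `invalid_transcript`.
#'
#' @param transcripts GRanges of CDS intervals with metadata column
#'   `transcript_id` and strand (as from [readCdsTranscripts()]).
#' @param reference reference sequence (character scalar or DNAString).
#' @param L region length; defaults to `nchar(reference)`.
#' @param chrom chromosome name for the returned map.
#' @return a [SiteClassMap-class] with exonic classes filled in and all
#'   other positions `none`.
#' @export
classifyDegeneracy <- function(transcripts, reference,
                               L = nchar(as.character(reference)),
                               chrom = "chr1") {
  reference <- as.character(reference)
  refBases <- strsplit(reference, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  degTab <- .degeneracyTable()

  # per-position accumulation: -1 unseen, 0/2/4 fold, 3 threefold,
  # -2 conflict, -3 invalid-transcript-only
  acc <- rep(-1L, L)
  invalidTouched <- logical(L)

  ids <- unique(mcols(transcripts)$transcript_id)
  for (id in ids) {
    tx <- transcripts[mcols(transcripts)$transcript_id == id]
    minus <- as.character(GenomicRanges::strand(tx))[1] == "-"
    gpos <- .cdsPositions(granges(tx), minus)
    seqBases <- refBases[gpos]
    if (minus) seqBases <- comp[seqBases]
    cds <- paste(seqBases, collapse = "")
    v <- validateTranscript(cds)
    if (!v$valid) {
      invalidTouched[gpos] <- TRUE
      next
    }
    nCodon <- length(gpos) / 3L
    codons <- substring(cds, 3L * seq_len(nCodon) - 2L,
                        3L * seq_len(nCodon))
    degPerBase <- as.vector(t(degTab[codons, , drop = FALSE]))
    # map: 0 substitutions -> 0 (fold0); 1 -> 2 (fold2); 3 -> 4 (fold4);
    # 2 -> 3 (threefold marker)
    code <- ifelse(degPerBase == 0L, 0L,
            ifelse(degPerBase == 1L, 2L,
            ifelse(degPerBase == 3L, 4L, 3L)))
    prev <- acc[gpos]
    newv <- ifelse(prev == -1L, code, ifelse(prev == code, prev, -2L))
    acc[gpos] <- newv
  }

  classes <- rep("none", L)
  reason <- rep(NA_character_, L)
  classes[acc == 0L] <- "fold0"
  classes[acc == 2L] <- "fold2"
  classes[acc == 4L] <- "fold4"
  classes[acc == 3L] <- "excluded"
  reason[acc == 3L] <- "threefold"
  classes[acc == -2L] <- "excluded"
  reason[acc == -2L] <- "inconsistent_degeneracy"
  onlyInvalid <- invalidTouched & acc == -1L
  classes[onlyInvalid] <- "excluded"
  reason[onlyInvalid] <- "invalid_transcript"
  new("SiteClassMap", chrom = chrom,
      classes = factor(classes, levels = .SITE_CLASS_LEVELS),
      reason = reason)
}

#' Build a CNE set variant against exon annotation
#'
#' @param rawElements GRanges of raw conserved elements (sorted, merged
#'   within themselves).
#' @param exons GRanges of annotated exons (valid and invalid).
#' @param variant `"noOverlap"`, `"strict"` or `"noOverlap_lt1kb"`.
#' @return a [CNESet-class]; for `noOverlap`, trimming may split an
#'   element into several intervals that share its `element_id`. The
#'   `lt1kb` variant keeps only elements whose original length is below
#'   1000 bp.
#' @export
buildCneSets <- function(rawElements, exons,
                         variant = c("noOverlap", "strict",
                                     "noOverlap_lt1kb")) {
  variant <- match.arg(variant)
  rawElements <- granges(rawElements)
  mcols(rawElements)$element_id <- sprintf("cne%05d",
                                           seq_along(rawElements))
  keep <- rawElements
  if (variant == "noOverlap_lt1kb")
    keep <- keep[width(keep) < 1000L]
  if (variant == "strict") {
    keep <- keep[!overlapsAny(keep, exons, ignore.strand = TRUE)]
    out <- keep
  } else {
    pieces <- lapply(seq_along(keep), function(i) {
      d <- GenomicRanges::setdiff(keep[i], exons, ignore.strand = TRUE)
      mcols(d)$element_id <- rep(mcols(keep)$element_id[i], length(d))
      d
    })
    out <- if (length(pieces)) do.call(c, pieces) else keep[0]
  }
  new("CNESet", intervals = sort(out), variant = variant)
}

#' Neutral flank reference intervals for a CNE set
#'
#' For a CNE of length L starting at s and ending at e (1-based closed),
#' the upstream flank is the ceiling(L/2) bases ending 501 bp before s
#' and the downstream flank the floor(L/2) bases starting 501 bp after e,
#' i.e. both flanks sit at an exact 500 bp gap from the element. Any
#' overlap with exons or with the full noOverlap CNE set is subtracted,
#' and flanks are clipped at the chromosome bounds.
#'
#' @param cnes a [CNESet-class] (or GRanges) whose elements get flanks.
#' @param exons GRanges of exons to mask out.
#' @param allCnes GRanges of the full noOverlap CNE set to mask out.
#' @param L chromosome length for clipping.
#' @return GRanges of flank intervals with metadata columns `element_id`
#'   and `side` ("up"/"down").
#' @export
buildCneFlankReference <- function(cnes, exons, allCnes, L) {
  gr <- if (is(cnes, "CNESet")) cnes@intervals else granges(cnes)
  if (!length(gr))
    return(GRanges())
  ids <- if (!is.null(mcols(gr)$element_id)) mcols(gr)$element_id
         else sprintf("cne%05d", seq_along(gr))
  widths <- width(gr)
  up <- IRanges(end = start(gr) - 501L, width = ceiling(widths / 2))
  down <- IRanges(start = end(gr) + 501L, width = floor(widths / 2))
  mask <- reduce(c(IRanges(start(exons), end(exons)),
                   IRanges(start(allCnes), end(allCnes))))
  clip <- function(ir) IRanges::restrict(ir, start = 1L, end = as.integer(L))
  pieces <- lapply(seq_along(gr), function(i) {
    u <- clip(IRanges::setdiff(clip(up[i]), mask))
    d <- clip(IRanges::setdiff(clip(down[i]), mask))
    if (length(u) + length(d) == 0L) return(GRanges())
    out <- GRanges(as.character(seqnames(gr))[1], c(u, d))
    mcols(out)$element_id <- ids[i]
    mcols(out)$side <- c(rep("up", length(u)), rep("down", length(d)))
    out
  })
  pieces <- pieces[lengths(pieces) > 0]
  if (!length(pieces)) return(GRanges())
  sort(do.call(c, pieces))
}

#' Assemble the full per-position class map
#'
#' Combines the degeneracy classification with CNE and CNE-flank
#' intervals. Exonic classes (including exclusions) take precedence,
#' then CNEs, then flanks; remaining positions are `none`.
#'
#' @param degenMap a [SiteClassMap-class] from [classifyDegeneracy()].
#' @param cnes a [CNESet-class] or GRanges.
#' @param flanks GRanges from [buildCneFlankReference()].
#' @return a [SiteClassMap-class].
#' @export
buildSiteClassMap <- function(degenMap, cnes, flanks) {
  classes <- as.character(degenMap@classes)
  reason <- degenMap@reason
  cneGr <- if (is(cnes, "CNESet")) cnes@intervals else granges(cnes)
  for (i in seq_along(cneGr)) {
    idx <- start(cneGr)[i]:end(cneGr)[i]
    free <- idx[classes[idx] == "none"]
    classes[free] <- "cne"
  }
  for (i in seq_along(flanks)) {
    idx <- start(flanks)[i]:end(flanks)[i]
    free <- idx[classes[idx] == "none"]
    classes[free] <- "cne_flank"
  }
  new("SiteClassMap", chrom = degenMap@chrom,
      classes = factor(classes, levels = .SITE_CLASS_LEVELS),
      reason = reason)
}

#' Write a site-class map as BED
#'
#' Runs of equal class are emitted as BED intervals (0-based half-open on
#' disk) with the class in the name column; `none` positions are omitted.
#'
#' @param map a [SiteClassMap-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSiteClassBed <- function(map, path) {
  cls <- as.character(map@classes)
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  gr <- GRanges(map@chrom, IRanges(starts[keep], ends[keep]),
                name = r$values[keep])
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
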