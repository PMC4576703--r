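# Per-class aggregation: pi, divergence, pi/d and Tajima's D with
# block-bootstrap confidence intervals (per transcript for exonic
# classes, per nonempty 1 Mb window for CNE and flank classes).

.classUnits <- function(pos, cls, transcripts, windowBp) {
  exonic <- cls %in% c("fold0", "fold2", "fold4")
  if (exonic && !is.null(transcripts) && length(transcripts)) {
    hits <- findOverlaps(GRanges(seqnames(transcripts)[1],
                                 IRanges(pos, pos)), transcripts,
                         select = "first")
    id <- mcols(transcripts)$transcript_id[hits]
    id[is.na(id)] <- "unassigned"
    id
  } else {
    sprintf("w%06d", (pos - 1L) %/% as.integer(windowBp))
  }
}

#' Per-class diversity, divergence and Tajima's D with bootstrap CIs
#'
#' For every requested class, computes per-site pi (monomorphic
#' accessible sites in the denominator), divergence of the ingroup major
#' allele from the outgroup, pi/d, and Tajima's D on the folded spectrum
#' projected to `nProj` alleles; 95% percentile bootstrap intervals
#' resample transcripts (exonic classes) or nonempty `windowBp` windows
#' (CNE/flank classes).
#'
#' @param counts data.frame from [alleleCounts()] restricted to filtered
#'   records.
#' @param outgroupBases character vector of outgroup bases, indexed by
#'   position (length L).
#' @param classMap a [SiteClassMap-class].
#' @param accessible integer positions passing all filters/masks.
#' @param classes classes to summarize.
#' @param nProj projected haploid sample size for the SFS and D.
#' @param nBoot bootstrap replicates (0 disables CIs).
#' @param seed integer seed for the bootstrap.
#' @param transcripts GRanges with `transcript_id` (exon-class units).
#' @param windowBp window size for CNE/flank bootstrap units.
#' @return data.frame with one row per class: n_sites, pi, d, pi_over_d,
#'   tajima_d and their CI bounds, n_div_sites, n_skipped.
#' @export
classSummary <- function(counts, outgroupBases, classMap, accessible,
                         classes = c("fold0", "fold2", "fold4", "cne",
                                     "cne_flank"),
                         nProj = 6L, nBoot = 1000L, seed = 1L,
                         transcripts = NULL, windowBp = 1e6) {
  res <- lapply(classes, function(cls) {
    sites <- intersect(sitesOfClass(classMap, cls), accessible)
    sites <- sites[sites %in% counts$pos]
    empty <- data.frame(class = cls, n_sites = 0L, pi = NA_real_,
      pi_lo = NA_real_, pi_hi = NA_real_, d = NA_real_, d_lo = NA_real_,
      d_hi = NA_real_, pi_over_d = NA_real_, pod_lo = NA_real_,
      pod_hi = NA_real_, tajima_d = NA_real_, D_lo = NA_real_,
      D_hi = NA_real_, n_div_sites = 0L, n_skipped = 0L,
      stringsAsFactors = FALSE)
    if (!length(sites)) return(empty)
    i <- match(sites, counts$pos)
    j <- counts$j[i]; n <- counts$n[i]; major <- counts$major[i]
    outB <- outgroupBases[sites]

    cp <- classPi(j, n)
    dv <- tryCatch(divergence(major, outB), error = function(e)
      list(d = NA_real_, nSites = 0L, nDiff = 0L))
    sfs <- projectFoldedSfs(j, n, nProj, label = cls)
    D <- tryCatch(tajimasDFromSfs(sfs), error = function(e) NA_real_)

    row <- empty
    row$n_sites <- cp$nSites
    row$pi <- cp$pi
    row$d <- dv$d
    row$n_div_sites <- dv$nSites
    row$pi_over_d <- if (!is.na(dv$d) && dv$d > 0) cp$pi / dv$d
                     else NA_real_
    row$tajima_d <- D
    row$n_skipped <- sfs@nSkipped

    if (nBoot > 0) {
      uid <- .classUnits(sites, cls, transcripts, windowBp)
      units <- lapply(split(seq_along(sites), uid), function(ii) {
        seg <- j[ii] > 0 & n[ii] >= 2
        usable <- outB[ii] %in% c("A", "C", "G", "T")
        usfs <- projectFoldedSfs(j[ii], n[ii], nProj)
        list(piSum = sum(sitePi(j[ii][seg], n[ii][seg])),
             nAcc = length(ii),
             nDiff = sum(major[ii][usable] != outB[ii][usable]),
             nCounted = sum(usable),
             sfs = usfs@counts)
      })
      if (length(units) >= 2L) {
        agg <- function(u, fld) Reduce(`+`, lapply(u, `[[`, fld))
        piF <- function(u) agg(u, "piSum") / agg(u, "nAcc")
        dF <- function(u) {
          nc <- agg(u, "nCounted")
          if (nc == 0) NA_real_ else agg(u, "nDiff") / nc
        }
        podF <- function(u) {
          d <- dF(u)
          if (is.na(d) || d == 0) NA_real_ else piF(u) / d
        }
        DF <- function(u) {
          cts <- agg(u, "sfs")
          tryCatch(tajimasDFromSfs(new("FoldedSFS",
            nProj = as.integer(nProj), counts = cts, label = "",
            nSkipped = 0L)), error = function(e) NA_real_)
        }
        ciOf <- function(f, off) tryCatch(
          bootstrapCi(f, units, nBoot, seed + off),
          error = function(e) c(lo = NA_real_, hi = NA_real_))
        ci <- ciOf(piF, 0L); row$pi_lo <- ci[1]; row$pi_hi <- ci[2]
        ci <- ciOf(dF, 1L); row$d_lo <- ci[1]; row$d_hi <- ci[2]
        ci <- ciOf(podF, 2L); row$pod_lo <- ci[1]; row$pod_hi <- ci[2]
        ci <- ciOf(DF, 3L); row$D_lo <- ci[1]; row$D_hi <- ci[2]
      }
    }
    row
  })
  do.call(rbind, res)
}
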