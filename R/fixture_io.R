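# Emission of a SimulatedCohort as standard files (VCF/FASTA/GFF3/BED +
# truth JSON) that round-trip through the package's readers.

.gtString <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Write a simulated cohort to disk as analysis-ready files
#'
#' Emits a multi-sample VCF v4.2 (all sites, GT:DP per sample, QUAL
#' column, INFO key `F` carrying the inbreeding coefficient where at
#' least 10 samples are called), reference and outgroup FASTA, exon CDS
#' features as GFF3 (with strand and phase), CNE intervals as BED, and a
#' truth JSON from which [replayCohort()] regenerates the identical
#' cohort.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ref = file.path(dir, "reference.fa"),
             outgroup = file.path(dir, "outgroup.fa"),
             gff3 = file.path(dir, "exons.gff3"),
             bed = file.path(dir, "cnes.bed"),
             truth = file.path(dir, "truth.json"))

  L <- nchar(cohort@reference)
  nS <- nrow(cohort@genotypes)
  samples <- sprintf("s%02d", seq_len(nS))
  refBases <- strsplit(cohort@reference, "", fixed = TRUE)[[1]]

  fVals <- apply(cohort@genotypes, 2, inbreedingCoefficient,
                 minSamples = 10L)
  info <- ifelse(is.na(fVals), ".", sprintf("F=%.4f", fVals))
  alt <- ifelse(is.na(cohort@altAllele), ".", cohort@altAllele)
  sampleCols <- lapply(seq_len(nS), function(i)
    paste0(.gtString(cohort@genotypes[i, ]), ":", cohort@depth[i, ]))
  body <- do.call(paste, c(list(cohort@chrom, seq_len(L), ".", refBases,
                                alt, sprintf("%.2f", cohort@qual), ".",
                                info, "GT:DP"), sampleCols,
                           list(sep = "\t")))
  header <- c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", cohort@chrom, L),
    "##INFO=<ID=F,Number=1,Type=Float,Description=\"Inbreeding coefficient\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), paths["vcf"])

  refSet <- DNAStringSet(setNames(cohort@reference, cohort@chrom))
  writeXStringSet(refSet, paths["ref"])
  outSet <- DNAStringSet(setNames(cohort@outgroup, cohort@chrom))
  writeXStringSet(outSet, paths["outgroup"])

  ex <- cohort@exons
  if (length(ex)) {
    mcols(ex) <- NULL
    mcols(ex)$source <- "driftscape"
    mcols(ex)$type <- "CDS"
    mcols(ex)$phase <- 0L
    mcols(ex)$ID <- mcols(cohort@exons)$transcript_id
  }
  rtracklayer::export(ex, paths["gff3"], format = "gff3")
  rtracklayer::export(cohort@cnes, paths["bed"], format = "bed")
  write_json(cohort@truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Read CDS transcripts from a GFF3 file
#'
#' @param path GFF3 with CDS features carrying an ID (or Parent)
#'   attribute naming the transcript.
#' @return GRanges of CDS intervals with a `transcript_id` metadata
#'   column, strand preserved.
#' @export
readCdsTranscripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  id <- if (!is.null(mcols(gr)$Parent) &&
            any(lengths(mcols(gr)$Parent) > 0))
    vapply(as.list(mcols(gr)$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  else mcols(gr)$ID
  out <- granges(gr)
  mcols(out)$transcript_id <- id
  out
}

#' Read CNE intervals from a BED file
#'
#' @param path BED3+ file (0-based half-open on disk; 1-based closed in
#'   the returned GRanges, per Bioconductor convention).
#' @return GRanges.
#' @export
readCneBed <- function(path) {
  granges(rtracklayer::import(path, format = "bed"))
}
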