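# Per-class population-genetic statistics: pi, divergence, folded SFS
# with hypergeometric projection, Tajima's D, block bootstrap CIs, Ne/mu
# estimation, and the PSMC / DFE-alpha export encodings.

#' Per-site heterozygosity
#'
#' pi at a single site with minor-allele count j among n called alleles:
#' 2 j (n - j) / (n (n - 1)).
#'
#' @param j minor-allele count(s), 0 <= j <= n/2.
#' @param n called allele count(s), n >= 2.
#' @return numeric vector of per-site pi.
#' @export
sitePi <- function(j, n) {
  if (any(n < 2)) stop("n must be >= 2")
  2 * j * (n - j) / (n * (n - 1))
}

#' Per-site allele summaries of a variant table
#'
#' @param vt a [VariantTable-class] (typically the filtered `records`
#'   from [applySiteFilters()]).
#' @return data.frame with one row per non-multiallelic site: `pos`,
#'   `n` (called alleles), `j` (minor-allele count), `major` (major
#'   allele base; ties resolved to the reference allele).
#' @export
alleleCounts <- function(vt) {
  keep <- !vt@multiallelic
  gt <- vt@gt[keep, , drop = FALSE]
  called <- rowSums(!is.na(gt))
  altC <- rowSums(gt, na.rm = TRUE)
  n <- 2L * called
  refC <- n - altC
  j <- pmin(altC, refC)
  alt <- vt@alt[keep]
  major <- ifelse(altC > refC & !is.na(alt), alt, vt@ref[keep])
  data.frame(pos = vt@pos[keep], n = n, j = j, major = major,
             stringsAsFactors = FALSE)
}

#' Per-site nucleotide diversity of a site class
#'
#' Sum of [sitePi()] over segregating sites divided by the total number
#' of accessible sites of the class (monomorphic sites count in the
#' denominator).
#'
#' @param j,n minor-allele and called-allele counts over the accessible
#'   sites of the class (monomorphic sites have j = 0).
#' @param nAccessible denominator; defaults to `length(j)`.
#' @return list with `pi` and `nSites`.
#' @export
classPi <- function(j, n, nAccessible = length(j)) {
  if (nAccessible < 1) stop("zero accessible sites")
  seg <- which(j > 0 & n >= 2)
  piSum <- if (length(seg)) sum(sitePi(j[seg], n[seg])) else 0
  list(pi = piSum / nAccessible, nSites = nAccessible)
}

#' Per-site divergence from an outgroup
#'
#' Fraction of counted sites at which the outgroup base differs from the
#' ingroup major allele (ties broken toward the reference allele). Sites
#' without a usable outgroup base (N) are dropped from numerator and
#' denominator.
#'
#' @param major ingroup major-allele base per site.
#' @param outgroupBase outgroup base per site (may contain "N").
#' @return list with `d`, `nSites` (counted sites) and `nDiff`.
#' @export
divergence <- function(major, outgroupBase) {
  usable <- outgroupBase %in% c("A", "C", "G", "T")
  if (!any(usable)) stop("no sites with outgroup base")
  nDiff <- sum(major[usable] != outgroupBase[usable])
  list(d = nDiff / sum(usable), nSites = sum(usable), nDiff = nDiff)
}

#' Project per-site allele counts onto a fixed sample size (folded)
#'
#' Each site with j minor alleles among n called contributes its
#' hypergeometric downsampling mass to counts at `nProj` alleles; folding
#' is applied after projection and expected counts accumulate as real
#' numbers. Sites with fewer than `nProj` called alleles are skipped and
#' counted in `nSkipped`.
#'
#' @param j,n per-site minor-allele and called-allele counts.
#' @param nProj projected haploid sample size (>= 4).
#' @param label class label stored with the spectrum.
#' @return a [FoldedSFS-class].
#' @export
projectFoldedSfs <- function(j, n, nProj, label = "") {
  stopifnot(nProj >= 4)
  nProj <- as.integer(nProj)
  nBins <- nProj %/% 2L + 1L
  counts <- numeric(nBins)
  usable <- n >= nProj
  grp <- paste(j[usable], n[usable])
  tab <- table(grp)
  for (g in names(tab)) {
    jn <- as.integer(strsplit(g, " ", fixed = TRUE)[[1]])
    mass <- dhyper(0:nProj, jn[1], jn[2] - jn[1], nProj)
    foldedBin <- pmin(0:nProj, nProj - (0:nProj)) + 1L
    for (k in seq_along(mass))
      counts[foldedBin[k]] <- counts[foldedBin[k]] +
        tab[[g]] * mass[k]
  }
  new("FoldedSFS", nProj = nProj, counts = counts, label = label,
      nSkipped = as.integer(sum(!usable)))
}

.tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1)) with pi_sum the sum of
#' per-site heterozygosities over the S segregating sites, using the
#' standard Tajima (1989) constants for a fixed allele count n.
#'
#' @param j minor-allele counts at segregating sites (entries with j = 0
#'   are ignored), all at the same n.
#' @param n haploid sample size (>= 4).
#' @return D. Errors when no site is segregating (D is undefined).
#' @export
tajimasD <- function(j, n) {
  stopifnot(n >= 4)
  j <- j[j > 0]
  S <- length(j)
  if (S == 0L) stop("Tajima's D undefined: no segregating sites")
  piSum <- sum(sitePi(j, n))
  k <- .tajimaConstants(n)
  (piSum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D from a projected folded spectrum
#'
#' @param sfs a [FoldedSFS-class]; bin 0 (monomorphic) is ignored.
#' @return D computed on the (possibly fractional) projected counts.
#' @export
tajimasDFromSfs <- function(sfs) {
  n <- sfs@nProj
  counts <- sfs@counts[-1]
  S <- sum(counts)
  if (S <= 0) stop("Tajima's D undefined: no segregating sites")
  ks <- seq_along(counts)
  piSum <- sum(counts * sitePi(ks, n))
  k <- .tajimaConstants(n)
  (piSum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Percentile bootstrap confidence interval over resampling units
#'
#' Units are resampled with replacement `nBoot` times and the statistic
#' recomputed on each replicate; the 2.5% and 97.5% percentiles are
#' returned. Exonic statistics resample per transcript; CNE and flank
#' statistics resample nonempty 1 Mb windows.
#'
#' @param statFn function taking a list of units and returning a scalar
#'   (may return NA when undefined on a replicate).
#' @param units list of resampling units (length >= 2).
#' @param nBoot number of replicates.
#' @param seed integer seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrapCi <- function(statFn, units, nBoot = 1000L, seed = 1L) {
  if (length(units) < 2L) stop("need at least 2 resampling units")
  set.seed(seed)
  vals <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(length(units), replace = TRUE)
    as.numeric(statFn(units[idx]))
  }, numeric(1))
  nBad <- sum(!is.finite(vals))
  if (nBad > 0.1 * nBoot)
    stop("statistic undefined in ", nBad, " of ", nBoot, " replicates")
  q <- quantile(vals[is.finite(vals)], c(0.025, 0.975), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Mutation rate from neutral divergence
#'
#' mu = d / (2 T g): per-generation mutation rate implied by a per-site
#' divergence d accumulated over two lineages of T years at g generations
#' per year.
#'
#' @param d per-site divergence at putatively neutral sites.
#' @param tSplitYears split time in years.
#' @param gensPerYear generations per year.
#' @return mu per bp per generation.
#' @export
estimateMu <- function(d, tSplitYears, gensPerYear) {
  if (d <= 0 || tSplitYears <= 0 || gensPerYear <= 0)
    stop("all inputs must be positive")
  d / (2 * tSplitYears * gensPerYear)
}

#' Effective population size from neutral diversity
#'
#' Equates pi at neutral sites to 4 Ne mu: Ne = pi / (4 mu).
#'
#' @param pi per-site neutral diversity.
#' @param mu mutation rate per bp per generation (> 0).
#' @return Ne (diploids).
#' @export
estimateNe <- function(pi, mu) {
  if (mu <= 0) stop("mu must be > 0")
  pi / (4 * mu)
}

#' Encode one diploid genome for PSMC
#'
#' Bins the region into `binBp` windows and encodes each as "K" (at
#' least one heterozygous site), "T" (no heterozygous site) or "N"
#' (fewer than `minCalledFrac` of the bin's sites called), producing a
#' fasta-like record wrapped at 60 characters.
#'
#' @param hetPositions positions with a heterozygous call in this sample
#'   (after upstream genotype-quality and cohort-calledness filtering).
#' @param calledPositions positions called and passing all filters.
#' @param L region length in bp.
#' @param binBp bin width (>= 1).
#' @param minCalledFrac called fraction below which a bin is "N".
#' @param chrom record name.
#' @return character vector of output lines (">chrom" then wrapped
#'   sequence).
#' @export
encodePsmcInput <- function(hetPositions, calledPositions, L,
                            binBp = 100L, minCalledFrac = 0.1,
                            chrom = "chr1") {
  stopifnot(binBp >= 1)
  nBins <- ceiling(L / binBp)
  binOf <- function(p) (as.integer(p) - 1L) %/% as.integer(binBp) + 1L
  calledPerBin <- tabulate(binOf(calledPositions), nBins)
  hetPerBin <- tabulate(binOf(hetPositions), nBins)
  binWidth <- c(rep(binBp, nBins - 1L), L - (nBins - 1L) * binBp)
  code <- ifelse(calledPerBin / binWidth < minCalledFrac, "N",
                 ifelse(hetPerBin > 0L, "K", "T"))
  seqStr <- paste(code, collapse = "")
  starts <- seq(1L, nchar(seqStr), 60L)
  c(paste0(">", chrom),
    substring(seqStr, starts, pmin(starts + 59L, nchar(seqStr))))
}

# round non-negative reals to integers preserving round(sum) exactly
# (largest-remainder apportionment)
.roundPreserveTotal <- function(x) {
  target <- round(sum(x))
  fl <- floor(x)
  rem <- as.integer(target - sum(fl))
  if (rem > 0) {
    frac <- x - fl
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[top] <- fl[top] + 1
  }
  as.integer(fl)
}

#' Write a selected/neutral folded SFS pair in DFE-alpha layout
#'
#' The text layout is: a dataset-count line ("1"), the haploid sample
#' size, the selected then neutral folded count vectors padded to n + 1
#' entries, and a divergence block of two "sites diffs" lines (selected,
#' neutral). Fractional projected counts are rounded with
#' largest-remainder apportionment so each vector's total is preserved.
#'
#' @param selected,neutral [FoldedSFS-class] objects at the same nProj.
#' @param divergences list with `selected` and `neutral`, each
#'   `c(sites, diffs)`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDfeAlphaSfs <- function(selected, neutral, divergences, path) {
  if (selected@nProj != neutral@nProj)
    stop("selected and neutral SFS have different nProj")
  n <- selected@nProj
  pad <- function(sfs) {
    v <- numeric(n + 1L)
    v[seq_along(sfs@counts)] <- .roundPreserveTotal(sfs@counts)
    v
  }
  selV <- pad(selected)
  if (sum(selV) == 0) warning("selected SFS is all zero")
  lines <- c("1", as.character(n),
             paste(selV, collapse = " "),
             paste(pad(neutral), collapse = " "),
             paste(divergences$selected, collapse = " "),
             paste(divergences$neutral, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a file written by [writeDfeAlphaSfs()]
#'
#' @param path file path.
#' @return list with `nProj`, `selected`, `neutral` (count vectors of
#'   length nProj + 1) and `divergences`.
#' @export
readDfeAlphaSfs <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[2])
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  list(nProj = n, selected = num(lines[3]), neutral = num(lines[4]),
       divergences = list(selected = num(lines[5]),
                          neutral = num(lines[6])))
}
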