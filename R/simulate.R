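# Forward Wright-Fisher simulator and synthetic-cohort generator.
#
# The population is held as a segregating-site x haplotype 0/1 matrix so a
# whole generation reduces to a few vectorized matrix operations; derived
# alleles that fix are moved to a `fixed` set (they matter for divergence),
# and a new mutation landing on a segregating or fixed position flips the
# allele there, keeping every site biallelic.

.BASES <- c("A", "C", "G", "T")

#' Forward Wright-Fisher simulation of a recombining region
#'
#' Simulates discrete non-overlapping generations with per-haplotype
#' mutation count ~ Poisson(mu L) at uniform positions, recombination as
#' Poisson(rec L) crossovers between the two parental haplotypes, and
#' multiplicative viability selection (diploid fitness
#' prod over sites of (1 - s dosage / 2), i.e. semidominance h = 0.5).
#' The population burns in for `burninMult` x N generations at the size of
#' the most ancient epoch before the epoch sequence is applied.
#'
#' @param L region length in bp.
#' @param demography a [DemographyModel-class], most ancient epoch first.
#' @param mu mutation rate per bp per generation, in `[0, 1)`.
#' @param rec recombination rate per bp per generation, in `[0, 1)`.
#' @param selection optional [SelectionMap-class] of length L.
#' @param seed integer seed; the same seed yields bit-identical output.
#' @param burninMult burn-in length in multiples of the oldest epoch size.
#' @return list with `hap` (2N x S integer 0/1 matrix of the final
#'   population, columns sorted by position), `pos` (segregating
#'   positions), `fixed` (positions where the derived allele has fixed),
#'   and the input parameters.
#' @export
simulateWrightFisher <- function(L, demography, mu, rec, selection = NULL,
                                 seed = 1L, burninMult = 10) {
  stopifnot(L >= 1)
  if (!is(demography, "DemographyModel"))
    stop("demography must be a DemographyModel")
  if (!is.finite(mu) || !is.finite(rec) || mu < 0 || mu >= 1 ||
      rec < 0 || rec >= 1)
    stop("mutation and recombination rates must be finite and in [0, 1)")
  sVec <- if (is.null(selection)) numeric(L) else selection@s
  if (length(sVec) != L) stop("selection map length must equal L")
  set.seed(seed)

  N0 <- demography@sizes[1]
  epochN <- c(N0, demography@sizes)
  epochGens <- c(ceiling(burninMult * N0), demography@durations)

  H <- matrix(0L, 0L, 2L * N0)   # segregating sites x haplotypes
  pos <- integer(0)
  fixed <- integer(0)
  anySel <- any(sVec > 0)

  for (ep in seq_along(epochGens)) {
    Nnew <- epochN[ep]
    twoN <- 2L * Nnew
    for (g in seq_len(epochGens[ep])) {
      S <- length(pos)
      nInd <- ncol(H) / 2L
      if (anySel && S) {
        selrows <- which(sVec[pos] > 0)
        if (length(selrows)) {
          dos <- H[selrows, seq(1L, ncol(H), 2L), drop = FALSE] +
                 H[selrows, seq(2L, ncol(H), 2L), drop = FALSE]
          w <- exp(colSums(log1p(-sVec[pos[selrows]] * dos / 2)))
        } else w <- rep(1, nInd)
      } else w <- NULL
      parents <- if (is.null(w) || all(w == w[1]))
        sample.int(nInd, twoN, replace = TRUE)
      else sample.int(nInd, twoN, replace = TRUE, prob = w)
      hapChoice <- sample.int(2L, twoN, replace = TRUE)
      nCross <- rpois(twoN, rec * L)
      if (S) {
        Hn <- H[, 2L * (parents - 1L) + hapChoice, drop = FALSE]
        for (i in which(nCross > 0L)) {
          cuts <- sort.int(sample.int(L, nCross[i], replace = TRUE))
          fromOther <- findInterval(pos, cuts) %% 2L == 1L
          if (any(fromOther)) {
            other <- 2L * (parents[i] - 1L) + (3L - hapChoice[i])
            Hn[fromOther, i] <- H[fromOther, other]
          }
        }
      } else Hn <- matrix(0L, 0L, twoN)
      nMut <- rpois(1L, mu * L * twoN)
      if (nMut > 0L) {
        mPos <- sample.int(L, nMut, replace = TRUE)
        mHap <- sample.int(twoN, nMut, replace = TRUE)
        newRows <- vector("list", nMut)
        newPos <- integer(nMut)
        nNew <- 0L
        for (k in seq_len(nMut)) {
          p <- mPos[k]
          j <- match(p, pos)
          if (!is.na(j)) {
            Hn[j, mHap[k]] <- 1L - Hn[j, mHap[k]]
          } else if (nNew > 0L && !is.na(jn <- match(p, newPos[seq_len(nNew)]))) {
            newRows[[jn]][mHap[k]] <- 1L - newRows[[jn]][mHap[k]]
          } else if (p %in% fixed) {
            fixed <- fixed[fixed != p]
            row <- rep(1L, twoN)
            row[mHap[k]] <- 0L
            nNew <- nNew + 1L
            newRows[[nNew]] <- row
            newPos[nNew] <- p
          } else {
            row <- rep(0L, twoN)
            row[mHap[k]] <- 1L
            nNew <- nNew + 1L
            newRows[[nNew]] <- row
            newPos[nNew] <- p
          }
        }
        if (nNew > 0L) {
          Hn <- rbind(Hn,
                      matrix(unlist(newRows[seq_len(nNew)]), nNew, twoN,
                             byrow = TRUE))
          pos <- c(pos, newPos[seq_len(nNew)])
        }
      }
      if (length(pos)) {
        cs <- rowSums(Hn)
        isFix <- cs == ncol(Hn)
        keep <- cs > 0L & !isFix
        if (any(isFix)) fixed <- c(fixed, pos[isFix])
        if (!all(keep)) {
          Hn <- Hn[keep, , drop = FALSE]
          pos <- pos[keep]
        }
      }
      H <- Hn
    }
  }
  ord <- order(pos)
  list(hap = t(H[ord, , drop = FALSE]), pos = pos[ord],
       fixed = sort.int(fixed), L = as.integer(L), mu = mu, rec = rec,
       demography = demography, seed = as.integer(seed))
}

#' Evolve an outgroup sequence from the reference
#'
#' Each position is substituted independently with probability
#' 1 - exp(-2 mu tSplit) (two lineages of length tSplit), the replacement
#' base drawn uniformly from the three alternatives.
#'
#' @param reference character scalar of A/C/G/T bases.
#' @param mu mutation rate per bp per generation.
#' @param tSplit split time in generations (>= 0).
#' @param seed integer seed.
#' @return character scalar of the same length.
#' @export
emitOutgroup <- function(reference, mu, tSplit, seed = 1L) {
  stopifnot(tSplit >= 0, mu >= 0)
  set.seed(seed)
  bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  pSub <- 1 - exp(-2 * mu * tSplit)
  hit <- which(runif(length(bases)) < pSub)
  if (length(hit)) {
    alt <- vapply(bases[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1), USE.NAMES = FALSE)
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

#' Synthesize exon and CNE annotation for a simulated region
#'
#' Exons are single-CDS transcripts (length a multiple of 3, random
#' strand) placed uniformly without overlap. CNEs are placed by drawing a
#' gap to a uniformly chosen exon edge: with probability `clusterWeight`
#' the gap is exponential with mean `clusterScale` (clustering near
#' exons), otherwise uniform on `[0, maxGap]`; `clusterWeight = 0` hence
#' gives uniform CNE-to-exon gaps over the admissible range.
#'
#' @param L region length in bp.
#' @param exonDensity,cneDensity target fraction of the region covered by
#'   each feature type, in (0, 1).
#' @param seed integer seed.
#' @param exonLenCodons integer range of internal codon counts per exon.
#' @param cneLenRange integer range of CNE lengths in bp.
#' @param clusterWeight fraction of CNEs placed with exponential gaps.
#' @param clusterScale mean of the exponential gap (bp).
#' @param maxGap upper bound of the uniform gap (bp).
#' @return list with `exons` (GRanges with strand and `transcript_id`)
#'   and `cnes` (GRanges), both sorted and non-overlapping within a set.
#' @export
synthesizeAnnotation <- function(L, exonDensity = 0.05, cneDensity = 0.03,
                                 seed = 1L, exonLenCodons = c(30L, 100L),
                                 cneLenRange = c(40L, 400L),
                                 clusterWeight = 0.5, clusterScale = 2000,
                                 maxGap = 10000) {
  stopifnot(exonDensity > 0, exonDensity < 1, cneDensity >= 0,
            cneDensity < 1)
  if ((exonDensity + cneDensity) > 0.6)
    stop("requested feature densities are infeasible for L")
  set.seed(seed)
  occ <- IRanges()   # occupied intervals (both feature types)

  placeUniform <- function(len) {
    for (i in 1:200) {
      s <- sample.int(L - len + 1L, 1L)
      cand <- IRanges(s, s + len - 1L)
      if (!overlapsAny(cand, occ)) return(cand)
    }
    NULL
  }

  exStarts <- integer(0); exEnds <- integer(0)
  targetEx <- exonDensity * L
  covered <- 0
  while (covered < targetEx) {
    nCodon <- sample(seq(exonLenCodons[1], exonLenCodons[2]), 1L)
    len <- 3L * (nCodon + 2L)      # ATG + codons + stop
    if (len >= L) stop("exon length infeasible for L")
    cand <- placeUniform(len)
    if (is.null(cand)) break
    occ <- reduce(c(occ, cand))
    exStarts <- c(exStarts, start(cand)); exEnds <- c(exEnds, end(cand))
    covered <- covered + len
  }
  if (!length(exStarts)) stop("could not place any exon")
  ordEx <- order(exStarts)
  exons <- GRanges("chr1", IRanges(exStarts[ordEx], exEnds[ordEx]),
    strand = sample(c("+", "-"), length(exStarts), replace = TRUE))
  mcols(exons)$transcript_id <- sprintf("tx%03d", seq_along(exons))

  cneStarts <- integer(0); cneEnds <- integer(0)
  if (cneDensity > 0) {
    targetCne <- cneDensity * L
    covered <- 0
    tries <- 0
    while (covered < targetCne && tries < 50000) {
      tries <- tries + 1
      len <- sample(seq(cneLenRange[1], cneLenRange[2]), 1L)
      i <- sample.int(length(exons), 1L)
      side <- sample(c(-1L, 1L), 1L)
      gap <- if (runif(1) < clusterWeight)
        round(rexp(1, 1 / clusterScale)) else round(runif(1, 0, maxGap))
      s <- if (side < 0L) start(exons)[i] - gap - len
           else end(exons)[i] + gap + 1L
      if (s < 1L || s + len - 1L > L) next
      cand <- IRanges(s, s + len - 1L)
      if (overlapsAny(cand, occ)) next
      occ <- reduce(c(occ, cand))
      cneStarts <- c(cneStarts, s); cneEnds <- c(cneEnds, s + len - 1L)
      covered <- covered + len
    }
  }
  cnes <- if (length(cneStarts)) {
    ordCne <- order(cneStarts)
    GRanges("chr1", IRanges(cneStarts[ordCne], cneEnds[ordCne]))
  } else GRanges()
  list(exons = exons, cnes = cnes)
}

# Rewrite reference bases inside each exon to a valid open reading frame
# (ATG ... sense codons ... stop) on the exon's strand.
.imprintOrfs <- function(bases, exons) {
  codons <- names(GENETIC_CODE)
  sense <- codons[GENETIC_CODE != "*"]
  stops <- codons[GENETIC_CODE == "*"]
  for (i in seq_along(exons)) {
    len <- width(exons)[i]
    nInternal <- len / 3L - 2L
    orf <- c("ATG", sample(sense, nInternal, replace = TRUE),
             sample(stops, 1L))
    seqc <- strsplit(paste(orf, collapse = ""), "", fixed = TRUE)[[1]]
    if (as.character(GenomicRanges::strand(exons))[i] == "-")
      seqc <- rev(c(A = "T", C = "G", G = "C", T = "A")[seqc])
    bases[start(exons)[i]:end(exons)[i]] <- seqc
  }
  bases
}

#' Build a selection map from annotation
#'
#' Exonic first and second codon positions (where most changes are
#' nonsynonymous) receive `sExon`; third positions are neutral, standing
#' in for the largely synonymous 4-fold class. CNE positions receive
#' `sCne`. Everything else is neutral.
#'
#' @param exons,cnes GRanges (exons stranded).
#' @param L region length.
#' @param sExon,sCne selection coefficients (>= 0).
#' @return a [SelectionMap-class].
#' @export
selectionFromAnnotation <- function(exons, cnes, L, sExon = 0.05,
                                    sCne = 0.05) {
  s <- numeric(L)
  lab <- rep("neutral", L)
  for (i in seq_along(exons)) {
    idx <- start(exons)[i]:end(exons)[i]
    codpos <- ((seq_along(idx) - 1L) %% 3L) + 1L
    if (as.character(GenomicRanges::strand(exons))[i] == "-")
      codpos <- rev(codpos)
    sel <- idx[codpos != 3L]
    s[sel] <- sExon
    lab[idx] <- "exon"
    lab[sel] <- "exon"
  }
  for (i in seq_along(cnes)) {
    idx <- start(cnes)[i]:end(cnes)[i]
    s[idx] <- sCne
    lab[idx] <- "cne"
  }
  lab[s == 0 & lab != "neutral"] <- "neutral"   # neutral 3rd positions
  SelectionMap(s, lab)
}

#' Sample a diploid cohort from a simulated population
#'
#' Draws `2 nSample` haplotypes without replacement, pairs them into
#' diploids, masks genotypes independently at `missingRate`, and attaches
#' per-sample depths (negative binomial, mean `depthMean`, dispersion
#' `depthDispersion`) and site quality scores (mixture: with probability
#' `qualLowProb` uniform on `qualLowRange`, else uniform on
#' `qualHighRange`) so that every downstream filter is exercisable.
#'
#' @param population result of [simulateWrightFisher()].
#' @param nSample number of diploid samples.
#' @param missingRate per-genotype missingness fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param reference optional character reference of length L (random if
#'   NULL).
#' @param outgroup optional outgroup sequence (defaults to the reference).
#' @param exons,cnes annotation GRanges stored with the cohort.
#' @param chrom chromosome name.
#' @param depthMean,depthDispersion negative-binomial depth model.
#' @param qualLowProb,qualLowRange,qualHighRange site-quality mixture.
#' @param truth extra truth entries to record.
#' @return a [SimulatedCohort-class].
#' @export
sampleCohort <- function(population, nSample, missingRate = 0, seed = 1L,
                         reference = NULL, outgroup = NULL,
                         exons = GRanges(), cnes = GRanges(),
                         chrom = "chr1", depthMean = 30,
                         depthDispersion = 5, qualLowProb = 0.03,
                         qualLowRange = c(5, 22),
                         qualHighRange = c(30, 1000), truth = list()) {
  nHapAvail <- nrow(population$hap)
  if (2L * nSample > nHapAvail)
    stop("n_sample too large: need ", 2L * nSample, " haplotypes, have ",
         nHapAvail)
  stopifnot(missingRate >= 0, missingRate <= 1)
  set.seed(seed)
  L <- population$L
  if (is.null(reference))
    reference <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
  if (is.null(outgroup)) outgroup <- reference
  refBases <- strsplit(reference, "", fixed = TRUE)[[1]]

  pick <- sample.int(nHapAvail, 2L * nSample)
  hap <- matrix(0L, 2L * nSample, L)
  if (length(population$pos))
    hap[, population$pos] <- population$hap[pick, , drop = FALSE]
  if (length(population$fixed)) hap[, population$fixed] <- 1L
  geno <- hap[seq(1L, 2L * nSample, 2L), , drop = FALSE] +
          hap[seq(2L, 2L * nSample, 2L), , drop = FALSE]
  if (missingRate > 0) {
    miss <- matrix(runif(nSample * L) < missingRate, nSample, L)
    geno[miss] <- NA_integer_
  }
  altAllele <- rep(NA_character_, L)
  varPos <- which(colSums(hap) > 0L)
  if (length(varPos))
    altAllele[varPos] <- vapply(refBases[varPos], function(b)
      sample(setdiff(.BASES, b), 1L), character(1), USE.NAMES = FALSE)
  depth <- matrix(
    as.integer(rnbinom(nSample * L, size = depthDispersion,
                       mu = depthMean)),
    nSample, L)
  low <- runif(L) < qualLowProb
  qual <- ifelse(low, runif(L, qualLowRange[1], qualLowRange[2]),
                 runif(L, qualHighRange[1], qualHighRange[2]))
  truth <- c(truth, list(seed = seed, missing_rate = missingRate,
    n_sample = nSample, mu = population$mu, rec = population$rec,
    demography_sizes = population$demography@sizes,
    demography_durations = population$demography@durations,
    sim_seed = population$seed, L = L))
  new("SimulatedCohort", chrom = chrom, reference = reference,
      outgroup = outgroup, haplotypes = hap, genotypes = geno,
      altAllele = altAllele, depth = depth, qual = qual,
      exons = exons, cnes = cnes, truth = truth)
}

#' One-call synthetic cohort with annotation, selection and outgroup
#'
#' Convenience wrapper that synthesizes annotation, imprints valid open
#' reading frames into a random reference, builds the selection map, runs
#' the Wright-Fisher simulation, evolves an outgroup, and samples a
#' cohort. All parameters are recorded in the cohort's `truth` list, and
#' `do.call(simulateCohort, truth_args)` replays the identical cohort.
#'
#' @param L region length (bp).
#' @param nSample diploid cohort size.
#' @param demographySizes,demographyDurations epoch vectors (most ancient
#'   first).
#' @param mu,rec per-bp per-generation rates.
#' @param tSplit outgroup split time in generations.
#' @param missingRate genotype missingness.
#' @param exonDensity,cneDensity,clusterWeight annotation parameters.
#' @param sExon,sCne selection coefficients for selected positions.
#' @param seed root seed; stage seeds are derived as seed + 1 ... seed + 5.
#' @param chrom chromosome name.
#' @return a [SimulatedCohort-class].
#' @export
simulateCohort <- function(L = 50000, nSample = 12,
                           demographySizes = 100,
                           demographyDurations = 200,
                           mu = 1e-5, rec = 1e-5, tSplit = 0,
                           missingRate = 0.02, exonDensity = 0.05,
                           cneDensity = 0.03, clusterWeight = 0.5,
                           sExon = 0.05, sCne = 0.05, seed = 1L,
                           chrom = "chr1") {
  args <- list(L = L, nSample = nSample,
    demographySizes = demographySizes,
    demographyDurations = demographyDurations, mu = mu, rec = rec,
    tSplit = tSplit, missingRate = missingRate,
    exonDensity = exonDensity, cneDensity = cneDensity,
    clusterWeight = clusterWeight, sExon = sExon, sCne = sCne,
    seed = seed, chrom = chrom)
  ann <- synthesizeAnnotation(L, exonDensity, cneDensity, seed = seed + 1L,
                              clusterWeight = clusterWeight)
  set.seed(seed + 2L)
  refBases <- sample(.BASES, L, replace = TRUE)
  refBases <- .imprintOrfs(refBases, ann$exons)
  reference <- paste(refBases, collapse = "")
  selection <- selectionFromAnnotation(ann$exons, ann$cnes, L, sExon, sCne)
  demo <- DemographyModel(demographySizes, demographyDurations)
  pop <- simulateWrightFisher(L, demo, mu, rec, selection, seed = seed + 3L)
  outgroup <- emitOutgroup(reference, mu, tSplit, seed = seed + 4L)
  sampleCohort(pop, nSample, missingRate, seed = seed + 5L,
               reference = reference, outgroup = outgroup,
               exons = ann$exons, cnes = ann$cnes, chrom = chrom,
               truth = list(args = args))
}

#' Replay a cohort from a truth record
#'
#' @param truth either the `truth` list of a [SimulatedCohort-class] or a
#'   path to a truth JSON written by [writeFixture()].
#' @return the identical [SimulatedCohort-class].
#' @export
replayCohort <- function(truth) {
  if (is.character(truth)) truth <- read_json(truth, simplifyVector = TRUE)
  args <- truth$args
  args$demographySizes <- unlist(args$demographySizes)
  args$demographyDurations <- unlist(args$demographyDurations)
  do.call(simulateCohort, args)
}
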