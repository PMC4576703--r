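# Configuration, validation and end-to-end orchestration:
# filter -> classify -> per-class statistics -> flank profiles ->
# LD decay -> Ne/mu -> exports, with a manifest of every output.

#' Default pipeline configuration
#'
#' @param vcf,ref,outgroup,gff3,cneBed input paths (a multi-sample VCF,
#'   reference FASTA, base-per-reference-position outgroup FASTA, CDS
#'   GFF3, CNE BED).
#' @param outDir output directory.
#' @param seed root seed; every stochastic stage derives its stream from
#'   it.
#' @param filter a [FilterConfig-class] or a named list of its fields.
#' @param cneVariant CNE set used for within-CNE statistics.
#' @param nProj projected haploid sample size for SFS/Tajima's D.
#' @param nBoot bootstrap replicates for class CIs.
#' @param windowBp bootstrap window for CNE/flank classes.
#' @param flankExonBin,flankExonMax,flankCneBin,flankCneMax flank profile
#'   bin widths and extents (bp).
#' @param kernelCap CNE-to-exon kernel cap (bp).
#' @param padRange distance range whose mean pi pads the convolution.
#' @param ldMaxDistance,ldBin,ldNMax LD-curve settings.
#' @param tSplitYears,gensPerYear divergence-time assumptions for the
#'   mutation-rate estimate.
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(vcf, ref, outgroup, gff3, cneBed, outDir,
                           seed = 1L, filter = FilterConfig(),
                           cneVariant = "noOverlap_lt1kb", nProj = 6L,
                           nBoot = 200L, windowBp = 1e6,
                           flankExonBin = 1000L, flankExonMax = 100000L,
                           flankCneBin = 100L, flankCneMax = 20000L,
                           kernelCap = 200000L,
                           padRange = c(60000, 100000),
                           ldMaxDistance = 40000L, ldBin = 20L,
                           ldNMax = 7500L, tSplitYears = 1.2e7,
                           gensPerYear = 2) {
  list(paths = list(vcf = vcf, ref = ref, outgroup = outgroup,
                    gff3 = gff3, cneBed = cneBed),
       outDir = outDir, seed = seed, filter = filter,
       cneVariant = cneVariant, nProj = nProj, nBoot = nBoot,
       windowBp = windowBp, flankExonBin = flankExonBin,
       flankExonMax = flankExonMax, flankCneBin = flankCneBin,
       flankCneMax = flankCneMax, kernelCap = kernelCap,
       padRange = padRange, ldMaxDistance = ldMaxDistance,
       ldBin = ldBin, ldNMax = ldNMax, tSplitYears = tSplitYears,
       gensPerYear = gensPerYear)
}

#' Validate a pipeline configuration
#'
#' Returns the full list of problems (empty character vector when the
#' configuration is valid) rather than failing at the first one.
#'
#' @param config list as from [pipelineConfig()].
#' @return character vector of error messages.
#' @export
validateConfig <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  for (nm in c("vcf", "ref", "outgroup", "gff3", "cneBed")) {
    p <- config$paths[[nm]]
    if (is.null(p) || !nzchar(p)) add(sprintf("missing path: %s", nm))
    else if (!file.exists(p)) add(sprintf("file not found (%s): %s", nm, p))
  }
  if (is.null(config$seed) || !is.finite(config$seed))
    add("seed must be set")
  f <- config$filter
  if (is.list(f)) {
    if (!is.null(f$proximityMd) && f$proximityMd < 0)
      add("proximity_md must be >= 0")
    if (!is.null(f$meanCovBounds) && diff(f$meanCovBounds) <= 0)
      add("meanCovBounds must be an increasing pair")
    if (!is.null(f$perSampleCovBounds) && diff(f$perSampleCovBounds) <= 0)
      add("perSampleCovBounds must be an increasing pair")
  } else if (is(f, "FilterConfig")) {
    v <- validObject(f, test = TRUE)
    if (!isTRUE(v)) add(paste(v, collapse = "; "))
  } else add("filter must be a FilterConfig or a named list")
  if (!is.null(config$nProj) && config$nProj < 4)
    add("nProj must be >= 4")
  if (!config$cneVariant %in% c("noOverlap", "strict", "noOverlap_lt1kb"))
    add("unknown cneVariant")
  if (!is.null(config$ldMaxDistance) && config$ldMaxDistance < 1)
    add("ldMaxDistance must be >= 1")
  errs
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.maskToBed <- function(mask, path) {
  r <- rle(mask@status)
  ends <- mask@pos[cumsum(r$lengths)]
  starts <- mask@pos[cumsum(r$lengths) - r$lengths + 1L]
  df <- data.frame(chrom = mask@chrom, start = starts - 1L, end = ends,
                   status = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes filter -> classify -> per-class statistics -> flank
#' profiles and convolution -> LD decay and fits -> Ne/mu estimation ->
#' PSMC and DFE-alpha exports, writing every declared output plus a
#' manifest into `config$outDir`. Reruns with the same configuration and
#' inputs produce identical outputs (all randomness derives from
#' `config$seed`).
#'
#' @param config list from [pipelineConfig()]; validated before any
#'   computation.
#' @return invisibly, a list with the in-memory results (`summary`,
#'   `mask`, `classMap`, `profiles`, `kernel`, `ldCurves`, `ldFits`,
#'   `neEstimate`, `paths`).
#' @export
runPipeline <- function(config) {
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  if (is.list(config$filter))
    config$filter <- do.call(FilterConfig, config$filter)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outPaths <- c()
  declare <- function(name, path) {
    outPaths[[name]] <<- path
    path
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- read inputs ---
  vt <- stage("read", readVariants(config$paths$vcf))
  refSeq <- stage("read",
    as.character(readDNAStringSet(config$paths$ref)[[1]]))
  outSeq <- stage("read",
    as.character(readDNAStringSet(config$paths$outgroup)[[1]]))
  transcripts <- stage("read", readCdsTranscripts(config$paths$gff3))
  cnesRaw <- stage("read", readCneBed(config$paths$cneBed))
  L <- nchar(refSeq)
  outBases <- strsplit(outSeq, "", fixed = TRUE)[[1]]

  # --- filter stack ---
  coverage <- stage("filter", computeModalCoverage(vt@dp))
  fr <- stage("filter", applySiteFilters(vt, coverage, config$filter))
  mask <- fr$mask
  failExtra <- function(positions, reason) {
    hit <- match(positions, mask@pos)
    hit <- hit[!is.na(hit)]
    hit <- hit[mask@status[hit] == "pass"]
    mask@status[hit] <<- paste0("fail:", reason)
  }
  md <- config$filter@proximityMd
  if (md > 0L) {
    varPos <- sort(c(variantPositions(vt), indelRecords(vt)$pos))
    kept <- proximityFilter(varPos, md)
    failExtra(setdiff(varPos, kept), "proximity")
  }
  im <- stage("filter", indelMask(indelRecords(vt), L))
  if (length(im))
    failExtra(unlist(lapply(seq_along(im), function(i)
      start(im)[i]:end(im)[i])), "indel")
  if (config$filter@cpgExclude)
    failExtra(which(cpgProneMask(c(refSeq, outSeq))), "cpg")

  # --- site classes ---
  degen <- stage("classify", classifyDegeneracy(transcripts, refSeq, L))
  exons <- granges(transcripts)
  cneSet <- stage("classify",
    buildCneSets(cnesRaw, exons, config$cneVariant))
  noOv <- stage("classify", buildCneSets(cnesRaw, exons, "noOverlap"))
  flanks <- stage("classify",
    buildCneFlankReference(cneSet, exons, noOv@intervals, L))
  classMap <- stage("classify", buildSiteClassMap(degen, cneSet, flanks))

  # --- per-class statistics ---
  counts <- alleleCounts(fr$records)
  accessible <- passPositions(mask)
  summary <- stage("stats", classSummary(counts, outBases, classMap,
    accessible, nProj = config$nProj, nBoot = config$nBoot,
    seed = config$seed, transcripts = transcripts,
    windowBp = config$windowBp))
  declare("summary", .writeTsv(summary,
    file.path(config$outDir, "class_summary.tsv")))

  # --- flank profiles ---
  cls <- as.character(classMap@classes)
  eligible <- accessible[cls[accessible] %in% c("none", "cne_flank")]
  ei <- match(eligible, counts$pos)
  segE <- counts$j[ei] > 0 & counts$n[ei] >= 2
  piC <- numeric(length(eligible))
  piC[segE] <- sitePi(counts$j[ei][segE], counts$n[ei][segE])
  outE <- outBases[eligible]
  divM <- ifelse(outE %in% c("A", "C", "G", "T"),
                 counts$major[ei] != outE, NA)
  profiles <- list()
  profiles$exon <- stage("flanks", binFlankStatistics(eligible, piC,
    divM, exons, config$flankExonBin, config$flankExonMax, "exon"))
  profiles$cne <- stage("flanks", binFlankStatistics(eligible, piC,
    divM, cneSet@intervals, config$flankCneBin, config$flankCneMax,
    "cne"))
  kernel <- tryCatch(cneExonDistanceKernel(noOv, exons,
    cap = min(config$kernelCap, L)), error = function(e) NULL)
  if (!is.null(kernel)) {
    exon100 <- stage("flanks", binFlankStatistics(eligible, piC, divM,
      exons, kernel@binBp, config$flankExonMax, "exon"))
    profiles$exon_blurred <- tryCatch(blurFlankProfile(exon100, kernel,
      padRange = config$padRange), error = function(e) NULL)
  }
  slopes <- list(
    cne = tryCatch(fitFarSlope(profiles$cne), error = function(e) NULL),
    exon_blurred = if (!is.null(profiles$exon_blurred))
      tryCatch(fitFarSlope(profiles$exon_blurred),
               error = function(e) NULL))
  for (nm in names(profiles))
    if (!is.null(profiles[[nm]]))
      declare(paste0("flanks_", nm), .writeTsv(profiles[[nm]]@stats,
        file.path(config$outDir, sprintf("flanks_%s.tsv", nm))))
  if (!is.null(kernel))
    declare("kernel", .writeTsv(binStats(kernel),
      file.path(config$outDir, "cne_exon_kernel.tsv")))

  # --- LD ---
  segPos <- counts$pos[counts$j > 0 & counts$n >= 4]
  ldSites <- intersect(segPos, accessible)
  ldCurves <- list(); ldFits <- list()
  if (length(ldSites) >= 10) {
    gtLd <- t(fr$records@gt[match(ldSites, vt@pos), , drop = FALSE])
    focalSets <- list(all = seq_along(ldSites),
      exon = which(overlapsAny(GRanges(vt@chrom,
        IRanges(ldSites, ldSites)), exons, ignore.strand = TRUE)),
      cne = which(overlapsAny(GRanges(vt@chrom,
        IRanges(ldSites, ldSites)), cneSet@intervals,
        ignore.strand = TRUE)))
    for (nm in names(focalSets)) {
      if (length(focalSets[[nm]]) < 2) next
      ldCurves[[nm]] <- stage("ld", ldDecayCurve(gtLd, ldSites,
        focal = focalSets[[nm]], maxDistance = config$ldMaxDistance,
        binBp = config$ldBin, nMax = config$ldNMax,
        seed = config$seed, focalSet = nm))
      declare(paste0("ld_", nm), .writeTsv(ldCurves[[nm]]@stats,
        file.path(config$outDir, sprintf("ld_curve_%s.tsv", nm))))
    }
    if (!is.null(ldCurves$all)) {
      ldFits$exponential <- tryCatch(
        fitOffsetExponential(ldCurves$all), error = function(e) NULL)
      ldFits$stretched <- tryCatch(
        fitStretchedExponential(ldCurves$all), error = function(e) NULL)
      ldFits$stretched_d05 <- tryCatch(
        fitStretchedExponential(ldCurves$all, fixD = 0.5),
        error = function(e) NULL)
    }
  }
  fitJson <- lapply(ldFits, function(f) if (is.null(f)) NULL else
    list(a = f@a, b = f@b, c = f@c, d = f@d, fixed_d = f@fixedD,
         residual_ss = f@residualSS, converged = f@converged))
  fitJson$r2_floor <- theoreticalR2Floor(ncol(vt@gt))
  declare("ld_fits", {
    p <- file.path(config$outDir, "ld_fits.json")
    write_json(fitJson, p, auto_unbox = TRUE, digits = NA, null = "null")
    p
  })

  # --- Ne / mu ---
  ne <- NULL
  s4 <- summary[summary$class == "fold4", ]
  if (nrow(s4) == 1 && !is.na(s4$d) && s4$d > 0) {
    muHat <- estimateMu(s4$d, config$tSplitYears, config$gensPerYear)
    ne <- list(mu_hat = muHat, ne_hat = estimateNe(s4$pi, muHat),
               d = s4$d, pi = s4$pi, t_split_years = config$tSplitYears,
               gens_per_year = config$gensPerYear, class = "fold4")
  }
  declare("ne_estimate", {
    p <- file.path(config$outDir, "ne_estimate.json")
    write_json(ne, p, auto_unbox = TRUE, digits = NA, null = "null")
    p
  })

  # --- exports ---
  declare("mask", .maskToBed(mask, file.path(config$outDir, "mask.bed")))
  declare("class_map", writeSiteClassBed(classMap,
    file.path(config$outDir, "site_classes.bed")))
  # PSMC encoding for the first sample: sites with >= 10 samples called
  nCalled <- rowSums(!is.na(fr$records@gt))
  psmcOk <- intersect(accessible, vt@pos[nCalled >= 10])
  i1 <- match(psmcOk, vt@pos)
  called1 <- psmcOk[!is.na(fr$records@gt[i1, 1])]
  het1 <- psmcOk[!is.na(fr$records@gt[i1, 1]) &
                 fr$records@gt[i1, 1] == 1L]
  declare("psmcfa", {
    p <- file.path(config$outDir, "sample1.psmcfa")
    writeLines(encodePsmcInput(het1, called1, L, chrom = vt@chrom), p)
    p
  })
  sel <- summary[summary$class == "fold0", ]
  neu <- summary[summary$class == "fold4", ]
  if (nrow(sel) == 1 && nrow(neu) == 1 && sel$n_sites > 0 &&
      neu$n_sites > 0) {
    i0 <- match(intersect(sitesOfClass(classMap, "fold0"), accessible),
                counts$pos)
    i4 <- match(intersect(sitesOfClass(classMap, "fold4"), accessible),
                counts$pos)
    sfs0 <- projectFoldedSfs(counts$j[i0], counts$n[i0], config$nProj,
                             "fold0")
    sfs4 <- projectFoldedSfs(counts$j[i4], counts$n[i4], config$nProj,
                             "fold4")
    declare("dfe_sfs", writeDfeAlphaSfs(sfs0, sfs4, list(
      selected = c(sel$n_div_sites, round(sel$d * sel$n_div_sites)),
      neutral = c(neu$n_div_sites, round(neu$d * neu$n_div_sites))),
      file.path(config$outDir, "dfe_alpha_sfs.txt")))
  }

  manifest <- list(
    inputs = config$paths,
    seed = config$seed,
    config = config[setdiff(names(config), c("paths", "filter"))],
    n_records = length(vt@pos),
    n_accessible = length(accessible),
    mask_summary = as.list(maskSummary(mask)),
    outputs = as.list(outPaths))
  p <- file.path(config$outDir, "manifest.json")
  write_json(manifest, p, auto_unbox = TRUE, digits = NA, null = "null")
  outPaths[["manifest"]] <- p

  invisible(list(summary = summary, mask = mask, classMap = classMap,
                 profiles = profiles, kernel = kernel, slopes = slopes,
                 ldCurves = ldCurves, ldFits = ldFits, neEstimate = ne,
                 coverage = coverage, paths = outPaths))
}
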