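# Shared, lazily computed simulation batches. Problem sizes are chosen
# so coalescent expectations are testable while the whole suite stays
# fast; everything is seed-fixed and cached across test files.

.simCache <- new.env(parent = emptyenv())

# constant-size neutral study conditions for replicate-locus checks
.neutralPars <- list(N = 100L, L = 2000L, theta = 0.004, nSample = 5L,
                     nRep = 200L)

.repStats <- function(pop, nSample, seed) {
  coh <- sampleCohort(pop, nSample, missingRate = 0, seed = seed)
  n <- 2L * nSample
  altC <- colSums(coh@haplotypes)
  seg <- altC > 0L & altC < n
  j <- pmin(altC[seg], n - altC[seg])
  list(j = j, n = n, S = length(j),
       piPerSite = if (length(j)) sum(sitePi(j, n)) / pop$L else 0,
       D = if (length(j)) tajimasD(j, n) else NA_real_)
}

neutralReps <- function() {
  if (!is.null(.simCache$neutral)) return(.simCache$neutral)
  p <- .neutralPars
  mu <- p$theta / (4 * p$N)
  reps <- lapply(seq_len(p$nRep), function(i) {
    pop <- simulateWrightFisher(p$L, DemographyModel(p$N, 100),
                                mu, mu, seed = 1000L + i)
    .repStats(pop, p$nSample, seed = 5000L + i)
  })
  .simCache$neutral <- reps
  reps
}

# recent 10-fold contraction lasting half the bottleneck size in
# generations (a short, sharp crash; sampled right at its end)
bottleneckReps <- function() {
  if (!is.null(.simCache$bottleneck)) return(.simCache$bottleneck)
  p <- .neutralPars
  mu <- p$theta / (4 * p$N)
  demo <- DemographyModel(c(p$N, p$N / 10L), c(50, p$N / 10L / 2))
  reps <- lapply(seq_len(p$nRep), function(i) {
    pop <- simulateWrightFisher(p$L, demo, mu, mu, seed = 1000L + i)
    .repStats(pop, p$nSample, seed = 5000L + i)
  })
  .simCache$bottleneck <- reps
  reps
}

# one moderate cohort reused by io/pipeline tests
smallCohort <- function() {
  if (!is.null(.simCache$cohort)) return(.simCache$cohort)
  .simCache$cohort <- simulateCohort(L = 12000, nSample = 12,
    demographySizes = 60, demographyDurations = 100, mu = 2e-5,
    rec = 2e-5, tSplit = 3000, missingRate = 0.03, exonDensity = 0.06,
    cneDensity = 0.04, clusterWeight = 0.5, sExon = 0.05, sCne = 0.05,
    seed = 11L)
  .simCache$cohort
}

smallFixtureDir <- function() {
  if (!is.null(.simCache$fixtureDir)) return(.simCache$fixtureDir)
  d <- file.path(tempdir(), "driftscape-fixture")
  writeFixture(smallCohort(), d)
  .simCache$fixtureDir <- d
  d
}
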