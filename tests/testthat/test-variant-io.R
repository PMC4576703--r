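# VCF reading and the post-call filter stack.

writeTestVcf <- function(lines, samples = c("s01", "s02", "s03")) {
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=F,Number=1,Type=Float,Description=\"F\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

test_that("VCF records parse into site records with matching fields", {
  p <- writeTestVcf(
    "chr1\t42\t.\tA\tG\t55.5\t.\tF=-0.25\tGT:DP\t0/1:20\t1/1:31\t./.:4")
  vt <- readVariants(p)
  expect_identical(vt@pos, 42L)
  expect_identical(vt@ref, "A")
  expect_identical(vt@alt, "G")
  expect_equal(vt@qual, 55.5)
  expect_equal(vt@f, -0.25)
  expect_identical(as.integer(vt@gt[1, ]), c(1L, 2L, NA))
  expect_identical(as.integer(vt@dp[1, ]), c(20L, 31L, 4L))
  expect_false(vt@multiallelic)
})

test_that("an empty VCF body yields an empty table without error", {
  p <- writeTestVcf(character(0))
  vt <- readVariants(p)
  expect_identical(length(vt@pos), 0L)
})

test_that("out-of-order positions are rejected naming the offender", {
  p <- writeTestVcf(c(
    "chr1\t100\t.\tA\tG\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30",
    "chr1\t90\t.\tC\tT\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30"))
  expect_error(readVariants(p), "record 2.*chr1:90")
})

test_that("multi-allelic SNVs are flagged and indels routed aside", {
  p <- writeTestVcf(c(
    "chr1\t10\t.\tA\tG,T\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30",
    "chr1\t20\t.\tACGT\tA\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30",
    "chr1\t30\t.\tT\tTAA\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30",
    "chr1\t40\t.\tG\tC\t50\t.\t.\tGT:DP\t0/1:20\t0/0:30\t0/0:30"))
  vt <- readVariants(p)
  expect_identical(vt@pos, c(10L, 40L))
  expect_identical(vt@multiallelic, c(TRUE, FALSE))
  ind <- indelRecords(vt)
  expect_identical(ind$type, c("del", "ins"))
  expect_identical(ind$pos, c(21L, 30L))  # first deleted base / anchor
  expect_identical(ind$len, c(3L, 2L))
})

test_that("modal coverage is the positive-depth argmax with smallest-
          depth tie-break", {
  expect_identical(
    modalCoverage(computeModalCoverage(list(a = c(`10` = 5, `20` = 50,
                                                  `30` = 3)))),
    c(a = 20L))
  expect_identical(
    modalCoverage(computeModalCoverage(list(a = c(`10` = 5, `20` = 5)))),
    c(a = 10L))
  expect_error(computeModalCoverage(list(a = c(`0` = 99))),
               "no usable coverage")
})

test_that("inbreeding coefficient follows 1 - Hobs/Hexp with the
          10-sample availability rule", {
  expect_equal(inbreedingCoefficient(rep(1L, 12)), -1)
  # Hardy-Weinberg proportions: p = 0.5, 12 samples 3/6/3
  expect_equal(inbreedingCoefficient(c(rep(0L, 3), rep(1L, 6),
                                       rep(2L, 3))), 0)
  expect_true(is.na(inbreedingCoefficient(rep(1L, 9))))
  expect_true(is.na(inbreedingCoefficient(rep(0L, 12))))  # Hexp = 0
})

test_that("each filter records its reason and failing depth samples are
          set missing rather than failing the site", {
  nS <- 12
  mkgt <- function(d) matrix(d, 1, nS)
  modal <- new("CoverageProfile",
               modal = setNames(rep(30L, nS), sprintf("s%02d", 1:nS)))
  base <- function(gt, dp, qual, f = NA_real_)
    new("VariantTable", chrom = "chr1", pos = 1L, ref = "A", alt = "G",
        qual = qual, f = f, gt = mkgt(gt), dp = mkgt(dp),
        multiallelic = FALSE,
        indels = data.frame(pos = integer(0), ref = character(0),
          alt = character(0), type = character(0), len = integer(0)))
  run <- function(vt) applySiteFilters(vt, modal)$mask@status

  expect_identical(run(base(rep(0L, nS), rep(30L, nS), qual = 22)),
                   "fail:qual")
  expect_identical(run(base(rep(1L, nS), rep(30L, nS), qual = 50)),
                   "fail:F")   # all het: F = -1 < -0.8
  expect_identical(run(base(c(0L, 1L, rep(NA, 10)), rep(30L, nS), 50)),
                   "fail:min_called")
  expect_identical(run(base(rep(0L, nS), rep(50L, nS), qual = 50)),
                   "fail:coverage")  # mean normalized 1.67 > 1.4
  # depth out of per-sample bounds masks the sample, then min_called
  gt <- c(rep(0L, 4), rep(NA, 8))
  dp <- c(5L, 5L, rep(30L, 10))    # 5 < 0.25 x 30
  r <- applySiteFilters(base(gt, dp, 50), modal)
  expect_identical(r$mask@status, "fail:min_called")
  expect_true(all(is.na(r$records@gt[1, 1:2])))
  ok <- base(rep(c(0L, 1L), 6), rep(30L, nS), 50)
  expect_identical(run(ok), "pass")
})

test_that("proximity filter removes by original positions without
          cascading and is idempotent", {
  expect_identical(proximityFilter(c(100L, 103L, 200L), 5), 200L)
  expect_identical(proximityFilter(c(100L, 104L, 109L), 5), 109L)
  pos <- c(10L, 30L, 50L)
  expect_identical(proximityFilter(pos, 0), pos)
  expect_error(proximityFilter(c(5L, 2L), 3), "sorted")
  set.seed(8)
  for (i in 1:20) {
    p <- sort(sample.int(500, 60))
    once <- proximityFilter(p, 7)
    expect_identical(proximityFilter(once, 7), once)
  }
})

test_that("indel masks span the stated windows and merge", {
  m <- indelMask(data.frame(pos = 100L, type = "del", len = 3L))
  expect_identical(IRanges::start(m), 99L)
  expect_identical(IRanges::end(m), 103L)
  m <- indelMask(data.frame(pos = 100L, type = "ins", len = 2L))
  expect_identical(IRanges::start(m), 98L)
  expect_identical(IRanges::end(m), 103L)
  m <- indelMask(data.frame(pos = c(100L, 104L), type = c("del", "del"),
                            len = c(3L, 2L)))
  expect_identical(length(m), 1L)
  expect_identical(IRanges::start(m), 99L)
  expect_identical(IRanges::end(m), 106L)
  expect_error(indelMask(data.frame(pos = 1L, type = "del", len = -1L)),
               "negative")
})

test_that("CpG-prone flags follow the any-sequence union rule", {
  expect_identical(cpgProneMask("ACGT"), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(cpgProneMask("AAAA"), rep(FALSE, 4))
  # union across sequences on shared coordinates: a position is prone
  # if any sequence has C before it or G after it
  expect_identical(cpgProneMask(c("AAA", "ACA")), c(FALSE, FALSE, TRUE))
  expect_identical(cpgProneMask(c("AAA", "ACG")), c(FALSE, TRUE, TRUE))
  expect_error(cpgProneMask(c("AAA", "AAAA")), "equal length")
})

test_that("filters are monotone and the mask partitions all positions", {
  d <- smallFixtureDir()
  vt <- readVariants(file.path(d, "cohort.vcf"))
  cov <- computeModalCoverage(vt@dp)
  loose <- FilterConfig(minQual = 0, fMin = -Inf,
                        perSampleCovBounds = c(0, Inf),
                        meanCovBounds = c(0, Inf), minCalled = 1L)
  strict <- FilterConfig()
  stricter <- FilterConfig(minQual = 60, meanCovBounds = c(0.9, 1.1))
  nPass <- function(cfg)
    length(passPositions(applySiteFilters(vt, cov, cfg)$mask))
  nl <- nPass(loose); ns <- nPass(strict); nt <- nPass(stricter)
  expect_true(nl >= ns && ns >= nt)
  mask <- applySiteFilters(vt, cov, strict)$mask
  expect_identical(length(mask@pos), length(vt@pos))
  expect_identical(sum(maskSummary(mask)), length(vt@pos))
})

test_that("a clean cohort with wide-open bounds passes every site", {
  pop <- simulateWrightFisher(3000, DemographyModel(40, 60), 4e-5, 4e-5,
                              seed = 31)
  coh <- sampleCohort(pop, 12, missingRate = 0, seed = 2,
                      qualLowProb = 0)
  d <- tempfile(); paths <- writeFixture(coh, d)
  vt <- readVariants(paths[["vcf"]])
  cov <- computeModalCoverage(vt@dp)
  cfg <- FilterConfig(minQual = 0, perSampleCovBounds = c(0, Inf),
                      meanCovBounds = c(0, Inf), minCalled = 1L)
  mask <- applySiteFilters(vt, cov, cfg)$mask
  expect_identical(passPositions(mask), vt@pos)
})
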