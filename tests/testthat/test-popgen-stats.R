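# pi, divergence, SFS projection, Tajima's D, bootstrap, Ne/mu and the
# export encodings.

test_that("per-site heterozygosity matches its closed form", {
  expect_equal(sitePi(1, 24), 1 / 12)
  expect_equal(sitePi(0, 24), 0)
  expect_equal(sitePi(12, 24), 12 / 23)
  expect_error(sitePi(0, 1), ">= 2")
})

test_that("class pi equals the pairwise-difference oracle exactly on
          small fixtures", {
  expect_equal(classPi(c(1, rep(0, 9)), rep(24, 10),
                       nAccessible = 1000)$pi, (1 / 12) / 1000,
               tolerance = 1e-12)
  expect_equal(classPi(rep(0, 5), rep(10, 5))$pi, 0)
  expect_error(classPi(numeric(0), numeric(0)), "zero accessible")
  set.seed(42)
  for (rep in 1:10) {
    nSites <- sample(10:50, 1)
    n <- sample(c(10L, 16L, 24L), 1)
    j <- sample(0:(n / 2), nSites, replace = TRUE)
    expect_equal(classPi(j, rep(n, nSites))$pi,
                 oracleClassPi(j, rep(n, nSites)), tolerance = 1e-14)
  }
})

test_that("divergence counts outgroup mismatches of the major allele
          and drops unusable outgroup bases", {
  major <- rep("A", 1000)
  out <- rep("A", 1000)
  expect_equal(divergence(major, out)$d, 0)
  out[1:142] <- "G"
  expect_equal(divergence(major, out)$d, 0.142)
  out[143:200] <- "N"
  dv <- divergence(major, out)
  expect_identical(dv$nSites, 942L)
  expect_equal(dv$d, 142 / 942)
  expect_error(divergence("A", "N"), "no sites")
})

test_that("folded projection reproduces exhaustive subsampling", {
  # identity when n equals the projection size
  sfs <- projectFoldedSfs(c(2, 0), c(8, 8), 8)
  expect_equal(sfsCounts(sfs), c(1, 0, 1, 0, 0))
  sfs0 <- projectFoldedSfs(0, 10, 6)
  expect_equal(sfsCounts(sfs0)[1], 1)
  for (case in list(c(2, 8, 6), c(3, 10, 6), c(1, 9, 4), c(4, 10, 8),
                    c(5, 10, 6))) {
    got <- sfsCounts(projectFoldedSfs(case[1], case[2], case[3]))
    want <- oracleProjectFolded(case[1], case[2], case[3])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # probability mass conserved per site
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    j <- sample(0:(n %/% 2), 1)
    expect_equal(sum(sfsCounts(projectFoldedSfs(j, n, 6))), 1,
                 tolerance = 1e-12)
  }
  # sites below the projection size are skipped and counted
  sk <- projectFoldedSfs(c(1, 1), c(4, 10), 6)
  expect_identical(sk@nSkipped, 1L)
})

test_that("Tajima's D agrees with an independently coded textbook
          implementation to 1e-12", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(c(10L, 24L), 1)
    j <- sample(1:(n / 2), sample(5:40, 1), replace = TRUE)
    expect_equal(tajimasD(j, n), oracleTajimaD(j, n),
                 tolerance = 1e-12)
  }
  expect_error(tajimasD(integer(0), 10), "undefined")
  expect_error(tajimasD(rep(0, 5), 10), "undefined")
  # projected-spectrum route agrees with the direct route at full n
  j <- c(1, 2, 3, 3, 5)
  sfs <- projectFoldedSfs(j, rep(10, 5), 10)
  expect_equal(tajimasDFromSfs(sfs), tajimasD(j, 10),
               tolerance = 1e-12)
})

test_that("bootstrap intervals are reproducible, degenerate on
          identical units, and attain nominal coverage", {
  units <- rep(list(list(x = 5)), 10)
  statFn <- function(u) mean(vapply(u, `[[`, numeric(1), "x"))
  ci <- bootstrapCi(statFn, units, 100, seed = 1)
  expect_equal(unname(ci[1]), unname(ci[2]))
  u2 <- lapply(1:20, function(i) list(x = i))
  expect_identical(bootstrapCi(statFn, u2, 200, seed = 5),
                   bootstrapCi(statFn, u2, 200, seed = 5))
  # nominal coverage of the 95% interval for a mean over blocks
  set.seed(99)
  hits <- 0L
  for (trial in 1:500) {
    vals <- rnorm(25)
    un <- lapply(vals, function(v) list(x = v))
    ci <- bootstrapCi(statFn, un, 200, seed = trial)
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
  # an error is raised when the statistic is mostly undefined
  bad <- function(u) if (length(unique(vapply(u, `[[`, numeric(1),
    "x"))) < 18) NA_real_ else 1
  expect_error(bootstrapCi(bad, u2, 100, seed = 2), "undefined")
})

test_that("mutation-rate and Ne estimators reproduce their defining
          relations", {
  mu <- estimateMu(0.142, 1.2e7, 2)
  expect_equal(mu, 0.142 / (2 * 1.2e7 * 2), tolerance = 1e-12)
  expect_equal(estimateMu(0.142, 1.2e7, 4), mu / 2)  # g doubled halves mu
  expect_error(estimateMu(0, 1, 1), "positive")
  expect_equal(estimateNe(0.00147, mu), 0.00147 / (4 * mu))
  expect_equal(estimateNe(0, mu), 0)
  expect_error(estimateNe(0.001, 0), "mu")
})

test_that("Ne estimation is scale invariant and pi/d unchanged under
          joint rescaling of pi and d", {
  d <- 0.142; pi <- 0.00147; Tg <- c(1.2e7, 2)
  ne1 <- estimateNe(pi, estimateMu(d, Tg[1], Tg[2]))
  k <- 3.7
  # scaling pi and d jointly leaves Ne (mu scales with d) and pi/d fixed
  ne2 <- estimateNe(k * pi, estimateMu(k * d, Tg[1], Tg[2]))
  expect_equal(ne2, ne1, tolerance = 1e-12)
  expect_equal((k * pi) / (k * d), pi / d, tolerance = 1e-12)
  # scaling pi alone scales Ne proportionally
  ne3 <- estimateNe(k * pi, estimateMu(d, Tg[1], Tg[2]))
  expect_equal(ne3, k * ne1, tolerance = 1e-12)
})

test_that("PSMC encoding emits K/T/N by bin with 60-column wrapping", {
  # 3 bins of 100 bp on a 300 bp region
  het <- c(55L)                       # bin 1
  called <- c(1:100, 101:104, 201:300)  # bin 2 only 4% called
  enc <- encodePsmcInput(het, called, 300, chrom = "tiny")
  expect_identical(enc[1], ">tiny")
  expect_identical(enc[2], "KNT")
  long <- encodePsmcInput(integer(0), 1:9000, 9000)
  expect_identical(nchar(long[2]), 60L)
  expect_identical(sum(nchar(long[-1])), 90L)
  expect_true(all(strsplit(paste(long[-1], collapse = ""), "")[[1]] ==
                  "T"))
})

test_that("DFE-alpha export round-trips and largest-remainder rounding
          preserves totals", {
  s <- new("FoldedSFS", nProj = 10L, counts = c(90.4, 4.3, 2.1, 1.7,
           0.8, 0.7), label = "sel", nSkipped = 0L)
  n <- new("FoldedSFS", nProj = 10L, counts = c(80.9, 9.1, 4.4, 3.2,
           1.6, 0.8), label = "neu", nSkipped = 0L)
  p <- tempfile()
  writeDfeAlphaSfs(s, n, list(selected = c(500, 12),
                              neutral = c(480, 60)), p)
  back <- readDfeAlphaSfs(p)
  expect_identical(back$nProj, 10L)
  expect_equal(sum(back$selected), round(sum(s@counts)))
  expect_equal(sum(back$neutral), round(sum(n@counts)))
  expect_equal(back$divergences$selected, c(500, 12))
  # rounding error is bounded by 1 per bin
  expect_true(all(abs(back$selected[1:6] - s@counts) < 1))
  expect_error(writeDfeAlphaSfs(s,
    new("FoldedSFS", nProj = 8L, counts = rep(1, 5), label = "x",
        nSkipped = 0L), list(), p), "nProj")
  set.seed(3)
  for (i in 1:20) {
    x <- runif(8, 0, 20)
    r <- driftscape:::.roundPreserveTotal(x)
    expect_identical(sum(r), as.integer(round(sum(x))))
  }
})
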