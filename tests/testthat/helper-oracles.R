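# Independent brute-force oracles, deliberately coded along different
# routes than the package implementations.

# pi at one site by enumerating all allele pairs
oracleSitePi <- function(j, n) {
  alleles <- c(rep(1L, j), rep(0L, n - j))
  prs <- utils::combn(n, 2)
  mean(alleles[prs[1, ]] != alleles[prs[2, ]])
}

# class pi: sum of pairwise-difference site values over accessible sites
oracleClassPi <- function(j, n, nAccessible = length(j)) {
  tot <- 0
  for (i in seq_along(j))
    if (j[i] > 0) tot <- tot + oracleSitePi(j[i], n[i])
  tot / nAccessible
}

# Tajima's D, textbook transcription (theta_pi vs theta_w route)
oracleTajimaD <- function(j, n) {
  j <- j[j > 0]
  S <- length(j)
  thetaPi <- sum(vapply(j, oracleSitePi, numeric(1), n = n))
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  thetaW <- S / a1
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  varD <- (c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1)
  (thetaPi - thetaW) / sqrt(varD)
}

# folded projection by exhaustive subsample enumeration
oracleProjectFolded <- function(j, n, nProj) {
  alleles <- c(rep(1L, j), rep(0L, n - j))
  subs <- utils::combn(n, nProj)
  counts <- numeric(nProj %/% 2 + 1)
  for (col in seq_len(ncol(subs))) {
    k <- sum(alleles[subs[, col]])
    kf <- min(k, nProj - k)
    counts[kf + 1] <- counts[kf + 1] + 1
  }
  counts / ncol(subs)
}

# weighted OLS through the normal equations
oracleWeightedSlope <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  as.numeric(beta[2])
}

# degeneracy of a codon position by substituting and translating
# (translation via Biostrings, a separate route from the package's
# lookup table construction)
oracleDegeneracy <- function(codon, cpos) {
  aa <- function(cd) as.character(Biostrings::translate(
    Biostrings::DNAString(cd), no.init.codon = TRUE))
  ref <- aa(codon)
  nSame <- 0L
  for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, cpos, cpos)) next
    mut <- codon
    substr(mut, cpos, cpos) <- b
    if (aa(mut) == ref) nSame <- nSame + 1L
  }
  nSame   # 0 -> fold0, 1 -> fold2, 2 -> threefold, 3 -> fold4
}
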