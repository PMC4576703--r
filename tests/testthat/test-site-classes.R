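# Transcript validation, degeneracy classification, CNE sets and
# neutral flank construction.

test_that("complete-transcript rules are enforced", {
  expect_true(validateTranscript("ATGAAATAA")$valid)
  v <- validateTranscript("ATGTAAAAA")
  expect_false(v$valid)
  expect_identical(v$reason, "premature_stop")
  v <- validateTranscript("ATGAAATA")
  expect_identical(v$reason, "length_not_multiple_of_3")
  expect_identical(validateTranscript("ATGANATAA")$reason,
                   "ambiguous_base")
  expect_identical(validateTranscript("CTGAAATAA")$reason,
                   "no_start_codon")
  expect_identical(validateTranscript("ATGAAAAAA")$reason,
                   "no_stop_codon")
})

test_that("degeneracy classes match a brute-force translating oracle
          over all codons and positions", {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*" & codons != "ATG"]
  for (cd in codons) {
    if (Biostrings::GENETIC_CODE[[cd]] == "*") next
    # transcript ATG | AAA | <codon> | AAA | TAA on a 15-bp genome
    ref <- paste0("ATG", "AAA", cd, "AAA", "TAA")
    tx <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(1, 15), strand = "+")
    S4Vectors::mcols(tx)$transcript_id <- "t1"
    map <- classifyDegeneracy(tx, ref, 15)
    got <- as.character(map@classes)[7:9]
    want <- vapply(1:3, function(p) {
      deg <- oracleDegeneracy(cd, p)
      c(`0` = "fold0", `1` = "fold2", `2` = "excluded",
        `3` = "fold4")[[as.character(deg)]]
    }, character(1))
    expect_identical(got, want)
    if (any(want == "excluded"))
      expect_identical(unique(map@reason[7:9][want == "excluded"]),
                       "threefold")
  }
})

test_that("known codons classify as the genetic code dictates and
          minus-strand transcripts agree with their forward twins", {
  # GGA (Gly): third position fold4; TGG (Trp): all fold0
  ref <- "ATGGGATGGTAA"
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                               strand = "+")
  S4Vectors::mcols(tx)$transcript_id <- "t1"
  map <- classifyDegeneracy(tx, ref, 12)
  expect_identical(as.character(map@classes)[6], "fold4")
  expect_identical(as.character(map@classes)[7:9],
                   rep("fold0", 3))
  # same CDS on the minus strand of the reverse-complemented genome
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref)))
  txm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12),
                                strand = "-")
  S4Vectors::mcols(txm)$transcript_id <- "t1"
  mapm <- classifyDegeneracy(txm, rc, 12)
  expect_identical(as.character(mapm@classes), rev(as.character(
    map@classes)))
})

test_that("transcripts with inconsistent degeneracy exclude the site and
          invalid transcripts exclude their private positions", {
  # two overlapping complete transcripts in different reading frames
  # (plus-strand [1,30] and minus-strand [7,24]); shared positions whose
  # codon roles disagree must be excluded
  ref <- "ATGCAACTAGTGTGCAGTCCTCATGTTTAA"
  tx <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 7), c(30, 24)), strand = c("+", "-"))
  S4Vectors::mcols(tx)$transcript_id <- c("t1", "t2")
  map <- classifyDegeneracy(tx, ref, 30)
  inc <- which(map@reason == "inconsistent_degeneracy")
  expect_true(length(inc) > 0)
  expect_true(all(as.character(map@classes)[inc] == "excluded"))
  # an invalid transcript alone marks its span invalid_transcript
  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 24),
                                strand = "+")
  S4Vectors::mcols(bad)$transcript_id <- "t3"
  map2 <- classifyDegeneracy(bad, paste(rep("A", 24), collapse = ""), 24)
  expect_identical(unique(map2@reason[20:24]), "invalid_transcript")
  expect_identical(unique(as.character(map2@classes)[20:24]),
                   "excluded")
})

test_that("CNE set variants trim, drop and length-filter as specified", {
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 250))
  raw <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 400, 2000), c(300, 420, 3500)))
  noOv <- buildCneSets(raw, exons, "noOverlap")
  iv <- cneIntervals(noOv)
  # the overlapped element splits into two segments sharing its id
  seg1 <- iv[S4Vectors::mcols(iv)$element_id == "cne00001"]
  expect_identical(IRanges::start(seg1), c(101L, 251L))
  expect_identical(IRanges::end(seg1), c(200L, 300L))
  strict <- buildCneSets(raw, exons, "strict")
  expect_identical(length(cneIntervals(strict)), 2L)
  expect_false(101 %in% IRanges::start(cneIntervals(strict)))
  lt <- buildCneSets(raw, exons, "noOverlap_lt1kb")
  # the 1501-bp element is dropped, the others keep their noOverlap form
  expect_false(any(IRanges::start(cneIntervals(lt)) == 2000))
  # subset relations as base sets of positions
  posOf <- function(set) unlist(lapply(seq_along(cneIntervals(set)),
    function(i) IRanges::start(cneIntervals(set))[i]:
                IRanges::end(cneIntervals(set))[i]))
  expect_true(all(posOf(strict) %in% posOf(noOv)))
  expect_true(all(posOf(lt) %in% posOf(noOv)))
  # untouched elements are identical across variants
  expect_true(all(c(400:420) %in% posOf(strict)))
})

test_that("CNE flanks sit at exactly 500 bp with ceil/floor halves,
          masked by exons and other CNEs", {
  cne <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200))
  fl <- buildCneFlankReference(cne, GenomicRanges::GRanges(),
                               GenomicRanges::GRanges(), 5000)
  expect_identical(IRanges::start(fl), c(401L, 1701L))
  expect_identical(IRanges::end(fl), c(500L, 1800L))
  # exon overlapping the upstream flank splits it
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(451, 480))
  fl2 <- buildCneFlankReference(cne, ex, GenomicRanges::GRanges(), 5000)
  up <- fl2[S4Vectors::mcols(fl2)$side == "up"]
  expect_identical(IRanges::start(up), c(401L, 481L))
  expect_identical(IRanges::end(up), c(450L, 500L))
  # odd length: ceil upstream, floor downstream
  cne5 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1005))
  fl5 <- buildCneFlankReference(cne5, GenomicRanges::GRanges(),
                                GenomicRanges::GRanges(), 5000)
  expect_identical(IRanges::width(fl5), c(3L, 2L))
})

test_that("flank totals never exceed the element length and never touch
          exons or CNEs on simulated annotation", {
  ann <- synthesizeAnnotation(60000, exonDensity = 0.05,
                              cneDensity = 0.03, seed = 17)
  noOv <- buildCneSets(ann$cnes, ann$exons, "noOverlap")
  fl <- buildCneFlankReference(noOv, ann$exons, cneIntervals(noOv),
                               60000)
  expect_false(any(IRanges::overlapsAny(fl, ann$exons,
                                        ignore.strand = TRUE)))
  expect_false(any(IRanges::overlapsAny(fl, cneIntervals(noOv),
                                        ignore.strand = TRUE)))
  ids <- S4Vectors::mcols(cneIntervals(noOv))$element_id
  w <- tapply(IRanges::width(cneIntervals(noOv)), ids, sum)
  fw <- tapply(IRanges::width(fl), S4Vectors::mcols(fl)$element_id, sum)
  for (id in names(fw))
    expect_lte(fw[[id]], w[[id]])
})

test_that("the assembled class map partitions every position exactly
          once", {
  coh <- smallCohort()
  L <- nchar(coh@reference)
  degen <- classifyDegeneracy(coh@exons, coh@reference, L)
  noOv <- buildCneSets(coh@cnes, coh@exons, "noOverlap")
  fl <- buildCneFlankReference(noOv, coh@exons, cneIntervals(noOv), L)
  map <- buildSiteClassMap(degen, noOv, fl)
  expect_identical(length(map@classes), L)
  tab <- table(map@classes)
  expect_identical(sum(tab), as.integer(L))
  expect_gt(tab[["fold0"]], 0)
  expect_gt(tab[["fold4"]], 0)
  expect_gt(tab[["cne"]], 0)
})
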