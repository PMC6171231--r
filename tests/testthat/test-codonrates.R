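test_that("Jukes-Cantor correction matches the closed form and its limits", {
  expect_identical(jcCorrect(0), 0)
  expect_equal(jcCorrect(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(jcCorrect(0.05), 0.0517, tolerance = 1e-3)
  # monotone increasing and always >= p
  p <- seq(0, 0.74, by = 0.02)
  d <- jcCorrect(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  # diverges approaching saturation, undefined at and beyond it
  expect_gt(jcCorrect(0.7499), 5)
  expect_error(jcCorrect(0.75), "saturation")
  expect_error(jcCorrect(0.9), "saturation")
  expect_error(jcCorrect(-0.01), "saturation")
})

test_that("every single-codon alignment yields S + N = 3 exactly", {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  for (codon in sense) {
    aln <- new("CodonAlignment", idA = "a", idB = "b",
               codonsA = codon, codonsB = codon, excluded = FALSE)
    est <- ng86(aln)
    expect_equal(est@S + est@N, 3, tolerance = 1e-12)
  }
})

test_that("identical sequences give zero differences and undefined omega", {
  seq <- randomCoding(40, seed = 11)
  cds <- inferFrame(seq, "x", minCodons = 10)
  aln <- codonAlign(cds, cds)
  est <- ng86(aln)
  expect_equal(est@Sd, 0)
  expect_equal(est@Nd, 0)
  expect_equal(est@Ka, 0)
  expect_equal(est@Ks, 0)
  expect_true(is.na(est@omega))
  expect_identical(est@flag, "undefined")
})

test_that("a 20-codon pair reproduces the exhaustive pathway oracle", {
  set.seed(42)
  a <- randomCoding(20)
  b <- mutateSeq(a, sample(60, 8))
  # keep only stop-free mutants in frame
  while (any(GC_TABLE[substring(b, seq(1, 58, 3), seq(3, 60, 3))] == "*")) {
    b <- mutateSeq(a, sample(60, 8))
  }
  aln <- new("CodonAlignment", idA = "a", idB = "b",
             codonsA = substring(a, seq(1, 58, 3), seq(3, 60, 3)),
             codonsB = substring(b, seq(1, 58, 3), seq(3, 60, 3)),
             excluded = rep(FALSE, 20))
  est <- ng86(aln)
  orc <- oracleNG86(a, b)
  expect_equal(est@S, orc$S, tolerance = 1e-10)
  expect_equal(est@N, orc$N, tolerance = 1e-10)
  expect_equal(est@Sd, orc$Sd, tolerance = 1e-10)
  expect_equal(est@Nd, orc$Nd, tolerance = 1e-10)
})

test_that("NG86 estimates are symmetric under swapping the sequences", {
  for (seed in 1:5) {
    sim <- simulateCodonPair(simulationConfig(
      seed = seed, nCodons = 120, ksTarget = 0.08, omega = 0.5))
    a <- inferFrame(sim$ancestral, "a", minCodons = 30)
    b <- inferFrame(sim$derived, "b", minCodons = 30)
    ab <- ng86(codonAlign(a, b))
    ba <- ng86(codonAlign(b, a))
    expect_equal(ab@Ks, ba@Ks, tolerance = 1e-12)
    expect_equal(ab@Ka, ba@Ka, tolerance = 1e-12)
    expect_equal(ab@S, ba@S, tolerance = 1e-12)
  }
})

test_that("frame inference recovers the generating frame and strand", {
  sim <- simulateCodonPair(simulationConfig(seed = 7, nCodons = 100,
                                            ksTarget = 0.02))
  cds <- inferFrame(sim$ancestral, "g1")
  expect_s4_class(cds, "CodingSequence")
  expect_identical(cds@strand, "+")
  expect_identical(cds@offset, 0L)
  expect_identical(cds@orf, sim$ancestral)
  # reverse complement carries the same ORF on the opposite strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$ancestral)))
  cdsRc <- inferFrame(rc, "g1rc")
  expect_identical(cdsRc@strand, "-")
  expect_identical(cdsRc@orf, cds@orf)
  expect_identical(cdsRc@protein, cds@protein)
})

test_that("stop-dense sequences are reported non-coding", {
  # random DNA carries stops every ~21 codons in every frame, so no frame
  # reaches a 100-codon open stretch
  expect_null(inferFrame(randomDna(400, seed = 2), minCodons = 100))
  # below the minimum ORF length
  expect_null(inferFrame(randomCoding(30, seed = 3), minCodons = 50))
})

test_that("codon alignment is gap-free on indel-free pairs and flags a
           terminal gap for a 3-nt extension", {
  sim <- simulateCodonPair(simulationConfig(seed = 5, nCodons = 80,
                                            ksTarget = 0.05))
  a <- inferFrame(sim$ancestral, "a", minCodons = 30)
  b <- inferFrame(sim$derived, "b", minCodons = 30)
  aln <- codonAlign(a, b)
  expect_equal(length(aln@codonsA), 80L)
  expect_false(any(aln@excluded))
  expect_false(any(aln@codonsA == "---"))
  # identical sequences: all columns identical
  alnAA <- codonAlign(a, a)
  expect_identical(alnAA@codonsA, alnAA@codonsB)
  # one leading extra codon forces exactly one terminal gap column
  ext <- paste0("GCT", sim$ancestral)
  aExt <- inferFrame(ext, "aext", minCodons = 30)
  alnExt <- codonAlign(aExt, a)
  expect_equal(sum(alnExt@codonsB == "---"), 1L)
  expect_true(alnExt@excluded[1L] || alnExt@excluded[length(alnExt@excluded)])
  expect_equal(sum(alnExt@excluded), 1L)
})

test_that("saturated pairs are flagged rather than corrected", {
  # hand-built alignment with most synonymous positions differing:
  # serine/leucine-rich columns drive ps beyond 3/4
  codA <- rep(c("TCT", "CTT", "GGT", "CGT"), each = 8)
  codB <- rep(c("TCG", "CTG", "GGG", "CGG"), each = 8)
  # every pair differs at a fully synonymous third position: ps = Sd/S large
  aln <- new("CodonAlignment", idA = "a", idB = "b",
             codonsA = codA, codonsB = codB,
             excluded = rep(FALSE, length(codA)))
  est <- ng86(aln)
  expect_identical(est@flag, "saturated")
  expect_true(is.na(est@Ks))
})
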