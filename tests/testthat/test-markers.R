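test_that("SSR class minima sit exactly at the published thresholds", {
  # mono: 12 repeats in, 11 out
  hit <- findSSRs(strrep("A", 12))
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$motif, "A")
  expect_equal(hit$repeats, 12L)
  expect_equal(nrow(findSSRs(strrep("A", 11))), 0L)
  # di: (AT)6 in, (AT)5 out
  expect_equal(nrow(findSSRs(strrep("AT", 6))), 1L)
  expect_equal(nrow(findSSRs(strrep("AT", 5))), 0L)
  # tri/tetra at 5, penta/hexa at 4
  expect_equal(findSSRs(strrep("ACG", 5))$unit, 3L)
  expect_equal(nrow(findSSRs(strrep("ACG", 4))), 0L)
  expect_equal(findSSRs(strrep("ACGT", 5))$unit, 4L)
  expect_equal(findSSRs(strrep("ACGTA", 4))$unit, 5L)
  expect_equal(findSSRs(strrep("ACGTAC", 4))$unit, 6L)
})

test_that("runs are reported once, under their smallest repeating unit", {
  # (ACG)5 is a tri repeat only, never a hexa report
  tri <- findSSRs(strrep("ACG", 5))
  expect_equal(nrow(tri), 1L)
  expect_identical(tri$motif, "ACG")
  # (AT)6 is a di repeat, not mono or tetra
  di <- findSSRs(strrep("AT", 6))
  expect_equal(nrow(di), 1L)
  expect_equal(di$unit, 2L)
  # a mono run long enough to satisfy the di threshold stays mono
  mono <- findSSRs(strrep("A", 14))
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$unit, 1L)
})

test_that("SSR loci satisfy the length identity and 1-based coordinates", {
  seq <- paste0("GCTGA", strrep("AGC", 6), "TTACG", strrep("TA", 7), "C")
  loci <- findSSRs(seq)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$end - loci$start + 1L, loci$unit * loci$repeats)
  expect_equal(loci$start[1], 6L)
  expect_identical(substr(seq, loci$start[1], loci$start[1] + 2), "AGC")
  # N breaks a run
  broken <- paste0(strrep("A", 6), "N", strrep("A", 6))
  expect_equal(nrow(findSSRs(broken)), 0L)
})

test_that("the exhaustive-scan oracle agrees on random 10 kb sequences", {
  for (seed in 1:3) {
    set.seed(seed)
    # random background plus implanted repeats and Ns
    parts <- c(randomDna(3000),
               strrep("AG", 8), randomDna(2000), strrep("TTG", 7),
               randomDna(2000), strrep("T", 15), randomDna(1500),
               strrep("ACGTC", 5), randomDna(1500))
    seq <- paste(parts, collapse = "")
    mine <- findSSRs(seq)[, c("motif", "unit", "repeats", "start", "end")]
    orc <- oracleFindSSRs(seq)
    rownames(mine) <- rownames(orc) <- NULL
    expect_equal(mine, orc)
    expect_gte(nrow(mine), 4L)  # the implanted repeats are found
  }
})

test_that("scanning the reversed sequence mirrors the loci", {
  set.seed(9)
  seq <- paste0(randomDna(200), strrep("CAG", 6), randomDna(100),
                strrep("A", 13), randomDna(50))
  fwd <- findSSRs(seq)
  rev <- findSSRs(paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$unit), sort(rev$unit))
  L <- nchar(seq)
  expect_setequal(L - fwd$end + 1L, rev$start)
  expect_setequal(L - fwd$start + 1L, rev$end)
})

test_that("motif normalization reports the smallest cycle rotation", {
  loci <- findSSRs(paste0("TT", strrep("GAC", 6), "TT"),
                   normalizeMotif = TRUE)
  expect_identical(loci$motif, "GAC")
  expect_identical(loci$canonical, "ACG")
})

test_that("SNP classification matches the purine/pyrimidine definition", {
  expect_identical(classifySNP("A", "G"), "transition")
  expect_identical(classifySNP("C", "T"), "transition")
  expect_identical(classifySNP("A", "T"), "transversion")
  expect_identical(classifySNP("G", "C"), "transversion")
  # symmetric
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in setdiff(bases, a))
    expect_identical(classifySNP(a, b), classifySNP(b, a))
  # exhaustive enumeration: 4 transitions, 8 transversions
  grid <- expand.grid(a = bases, b = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, ]
  klass <- classifySNP(grid$a, grid$b)
  expect_equal(sum(klass == "transition"), 4L)
  expect_equal(sum(klass == "transversion"), 8L)
  expect_error(classifySNP("A", "A"), "differ")
  expect_error(classifySNP("A", "N"), "alleles")
})

test_that("marker summaries tabulate classes and Ts/Tv fractions", {
  ssrs <- rbind(findSSRs(strrep("A", 12)), findSSRs(strrep("AT", 6)),
                findSSRs(strrep("ACG", 5)), findSSRs(strrep("ACGT", 5)),
                findSSRs(strrep("ACGTA", 4)), findSSRs(strrep("ACGTAC", 4)))
  snps <- data.frame(alleleA = c("A", "A", "G", "A"),
                     alleleB = c("G", "G", "A", "T"))
  s <- markerSummary(ssrs, snps)
  expect_equal(unname(s$ssrByUnit), rep(1L, 6))
  expect_equal(s$tsTv[["tsFraction"]], 0.75)
  expect_equal(unname(s$snpByPair["A/G"]), 3L, ignore_attr = TRUE)
  # empty inputs are well-defined
  empty <- markerSummary(NULL, NULL)
  expect_equal(sum(empty$ssrByUnit), 0L)
  expect_true(is.na(empty$tsTv[["tsFraction"]]))
})

test_that("a seeded SSR truth table survives the set-level scan", {
  truth <- data.frame(
    motif = c("AG", "TTG", "T"), unit = c(2L, 3L, 1L),
    repeats = c(8L, 7L, 15L))
  seq1 <- paste0(randomDna(120, seed = 51), strrep("AG", 8),
                 randomDna(80, seed = 52))
  seq2 <- paste0(randomDna(60, seed = 53), strrep("TTG", 7),
                 randomDna(40, seed = 54), strrep("T", 15),
                 randomDna(30, seed = 55))
  set <- transcriptSet("tax", c(u1 = seq1, u2 = seq2))
  found <- findSSRsInSet(set, normalizeMotif = TRUE)
  # match on cycle-rotation canonical motifs: a spacer that happens to end
  # in the repeat's period legitimately extends the run by a rotation
  canon <- pinediv:::.canonicalMotif(truth$motif)
  found <- found[order(match(found$canonical, canon)), ]
  expect_equal(found$canonical, canon)
  expect_equal(found$unit, truth$unit)
  expect_true(all(found$repeats >= truth$repeats))
})
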