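test_that("global identity handles the boundary cases", {
  expect_equal(globalIdentity("ACGTACGTAC", "ACGTACGTAC"), 1)
  expect_equal(globalIdentity("AAAA", "TTTT"), 0)
  expect_error(globalIdentity("", "ACGT"), "non-empty")
  # a 100-nt sequence with 5 substitutions aligns gap-free at 0.95
  x <- randomDna(100, seed = 2)
  y <- mutateSeq(x, c(10, 30, 50, 70, 90))
  expect_equal(globalIdentity(x, y), 0.95)
  # N never counts as a match, even against N
  expect_equal(globalIdentity("ACGN", "ACGN"), 0.75)
})

test_that("global identity is symmetric and bounded", {
  for (seed in 1:6) {
    set.seed(seed)
    a <- randomDna(sample(40:120, 1))
    b <- randomDna(sample(40:120, 1))
    ab <- globalIdentity(a, b)
    expect_equal(ab, globalIdentity(b, a), tolerance = 1e-12)
    expect_gte(ab, 0)
    expect_lte(ab, 1)
  }
})

test_that("the k-mer prefilter never rejects a pair at threshold identity", {
  # pairs constructed at >= 90% identity must always pass the bound
  for (seed in 1:10) {
    set.seed(seed)
    len <- sample(80:400, 1)
    a <- randomDna(len)
    nMut <- floor(0.09 * len)
    b <- mutateSeq(a, sample(len, nMut))
    ca <- pinediv:::.kmerCounts(a)
    cb <- pinediv:::.kmerCounts(b)
    expect_true(pinediv:::.pairCanReach(ca, cb, len, len, 0.90))
  }
})

test_that("redundancy collapse keeps the longest member of each class", {
  base <- randomDna(200, seed = 5)
  longer <- paste0(base, randomDna(8, seed = 6))  # identity ~0.96 to base
  far <- randomDna(200, seed = 7)
  set <- transcriptSet("tax", c(s1 = base, s2 = longer, s3 = far))
  out <- collapseRedundant(set, threshold = 0.95)
  expect_setequal(names(sequences(out)), c("s2", "s3"))
  # two identical records: one survivor
  twin <- transcriptSet("tax", c(a = base, b = base))
  expect_equal(length(collapseRedundant(twin)), 1L)
  # mutually dissimilar records pass through unchanged
  distinct <- transcriptSet("tax", c(
    a = randomDna(150, seed = 11), b = randomDna(150, seed = 12),
    c = randomDna(150, seed = 13)))
  expect_equal(length(collapseRedundant(distinct)), 3L)
})

test_that("redundancy classes form by single linkage", {
  # A~B at ~97%, B~C at ~97%, A~C at ~94%: one class of three
  a <- randomDna(300, seed = 21)
  b <- mutateSeq(a, sample(300, 9), seed = 22)
  cc <- mutateSeq(b, sample(300, 9), seed = 23)
  expect_gt(globalIdentity(a, b), 0.95)
  expect_gt(globalIdentity(b, cc), 0.95)
  expect_lt(globalIdentity(a, cc), 0.95)
  set <- transcriptSet("tax", c(A = a, B = b, C = cc))
  out <- collapseRedundant(set, threshold = 0.95)
  expect_equal(length(out), 1L)
  # longest member wins; equal lengths fall back to lexicographic id
  expect_identical(names(sequences(out)), "A")
})

test_that("redundancy collapse is idempotent", {
  set.seed(33)
  base <- replicate(4, randomDna(150))
  seqs <- c(base,
            vapply(base, function(s) mutateSeq(s, sample(150, 4)),
                   character(1)))
  names(seqs) <- paste0("t", seq_along(seqs))
  set <- transcriptSet("tax", seqs)
  once <- collapseRedundant(set)
  twice <- collapseRedundant(once)
  expect_identical(as.character(sequences(once)),
                   as.character(sequences(twice)))
})

test_that("orthologue pairing recovers simulated truth and rejects decoys", {
  tree <- ape::read.tree(text = "(A:0.01,B:0.01);")  # pairwise Ks 0.02
  clade <- simulateClade(simulationConfig(
    seed = 17, nCodons = 150, nGenes = 20, tree = tree, nDecoys = 5L))
  pairs <- pairOrthologues(clade$sets$A, clade$sets$B)
  # every true orthologue pair recovered, no decoy pairs
  expect_equal(sort(pairs$idA[pairs$idA == pairs$idB]),
               sprintf("g%04d", 1:20))
  expect_false(any(grepl("decoy", pairs$idA)))
  expect_false(any(grepl("decoy", pairs$idB)))
  expect_true(all(pairs$identity >= 0.90))
  # one-to-one matching
  expect_false(anyDuplicated(pairs$idA) > 0)
  expect_false(anyDuplicated(pairs$idB) > 0)
})

test_that("best-hit pairing prefers the higher-identity partner", {
  x <- randomDna(200, seed = 41)
  near <- mutateSeq(x, sample(200, 6), seed = 42)   # ~0.97
  mid <- mutateSeq(x, sample(200, 14), seed = 43)   # ~0.93
  setA <- transcriptSet("A", c(x = x))
  setB <- transcriptSet("B", c(pNear = near, pMid = mid))
  pairs <- pairOrthologues(setA, setB)
  expect_equal(nrow(pairs), 1L)
  expect_identical(pairs$idB, "pNear")
})

test_that("degenerate pairing inputs are handled explicitly", {
  a <- transcriptSet("A", c(x = randomDna(60, seed = 1)))
  empty <- new("TranscriptSet", taxon = "B",
               sequences = Biostrings::DNAStringSet())
  expect_warning(p <- pairOrthologues(a, empty), "empty")
  expect_equal(nrow(p), 0L)
  expect_error(pairOrthologues(a, a), "distinct")
})

test_that("pair tables round-trip through TSV", {
  tree <- ape::read.tree(text = "(A:0.005,B:0.005);")
  clade <- simulateClade(simulationConfig(
    seed = 3, nCodons = 60, nGenes = 5, tree = tree))
  pairs <- pairOrthologues(clade$sets$A, clade$sets$B)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePairsTsv(pairs, path)
  back <- readPairsTsv(path)
  expect_equal(back$idA, pairs$idA)
  expect_equal(back$identity, pairs$identity, tolerance = 1e-9)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writePairsTsv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
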