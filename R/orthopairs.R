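#' Construct a TranscriptSet
#'
#' @param taxon taxon name.
#' @param sequences a named character vector or \code{DNAStringSet} of
#'   transcripts (ids unique within the taxon, alphabet A/C/G/T/N).
#' @return a \linkS4class{TranscriptSet}.
#' @export
transcriptSet <- function(taxon, sequences) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  new("TranscriptSet", taxon = as.character(taxon), sequences = sequences)
}

#' Read a per-taxon FASTA into a TranscriptSet
#'
#' Record ids are the FASTA headers up to the first whitespace.
#'
#' @param path FASTA file path.
#' @param taxon taxon name; defaults to the file name without extension.
#' @return a \linkS4class{TranscriptSet}.
#' @export
readTranscripts <- function(path, taxon = NULL) {
  if (is.null(taxon))
    taxon <- sub("\\.(fa|fasta|fna)$", "", basename(path),
                 ignore.case = TRUE)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  transcriptSet(taxon, seqs)
}

# Scoring scheme for nucleotide global identity: match +1, mismatch -1
# (N matches nothing, not even N), linear gap cost 2 per column.
.dnaScoreMatrix <- function() {
  if (!is.null(.pinediv_cache$dnaScore)) return(.pinediv_cache$dnaScore)
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- 1
  m["N", "N"] <- -1
  .pinediv_cache$dnaScore <- m
  m
}

.globalAlnStats <- function(seqA, seqB) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "global", substitutionMatrix = .dnaScoreMatrix(),
    gapOpening = 0, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  matches <- sum(a == b & a %in% c("A", "C", "G", "T"))
  list(identity = matches / length(a), columns = length(a))
}

#' Global alignment identity of two nucleotide sequences
#'
#' End-to-end (Needleman--Wunsch) alignment with match +1, mismatch -1 and a
#' linear gap cost of 2 per column; identity is the fraction of alignment
#' columns that match exactly (gapped columns and columns involving N count
#' as mismatch). Symmetric in its arguments.
#'
#' @param seqA,seqB non-empty nucleotide sequences (character or
#'   \code{DNAString}).
#' @return identity fraction in [0, 1].
#' @examples
#' globalIdentity("ACGTACGT", "ACGTACGT")  # 1
#' globalIdentity("AAAA", "TTTT")          # 0
#' @export
globalIdentity <- function(seqA, seqB) {
  seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
  if (!nchar(seqA) || !nchar(seqB))
    stop("sequences must be non-empty")
  .globalAlnStats(seqA, seqB)$identity
}

# --- conservative 8-mer prefilter -----------------------------------------
# If two sequences align at identity >= t, then with La <= Lb the alignment
# has >= t * Lb matched columns, so sequence a has at most La - t*Lb
# unmatched positions; each unmatched position can destroy at most 8 of a's
# (La - 7) 8-mers, every other 8-mer of a occurs verbatim in b. A pair whose
# shared 8-mer count falls below that bound can therefore never reach the
# threshold and is skipped without alignment. The bound is conservative:
# it can only skip pairs that provably fail.

.kmerCounts <- function(seq, k = 8L) {
  d <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(d) - k + 1L
  if (n < 1L) return(integer(0))
  val <- numeric(n)
  for (j in seq_len(k))
    val <- val * 4 + d[j:(j + n - 1L)]
  val <- val[!is.na(val)]  # windows containing N drop out
  tab <- table(val)
  stats::setNames(as.integer(tab), names(tab))
}

.sharedKmers <- function(countsA, countsB) {
  common <- intersect(names(countsA), names(countsB))
  if (!length(common)) return(0L)
  sum(pmin(countsA[common], countsB[common]))
}

.pairCanReach <- function(countsA, countsB, lenA, lenB, threshold, k = 8L) {
  la <- min(lenA, lenB); lb <- max(lenA, lenB)
  if (la < threshold * lb) return(FALSE)
  bound <- (la - k + 1L) - k * (la - threshold * lb)
  if (bound <= 0) return(TRUE)
  .sharedKmers(countsA, countsB) >= bound
}

#' Collapse redundant transcripts within a taxon
#'
#' Greedy single-linkage clustering of transcripts at global identity
#' strictly above \code{threshold}; each class is represented by its longest
#' member (ties broken by lexicographically smallest id). Idempotent.
#'
#' @param set a \linkS4class{TranscriptSet}.
#' @param threshold similarity threshold, default 0.95 (strict \code{>}).
#' @return a \linkS4class{TranscriptSet} of class representatives, in input
#'   order.
#' @export
collapseRedundant <- function(set, threshold = 0.95) {
  stopifnot(is(set, "TranscriptSet"))
  n <- length(set)
  if (n <= 1L) return(set)
  seqs <- as.character(sequences(set))
  lens <- nchar(seqs)
  counts <- lapply(seqs, .kmerCounts)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (findRoot(i) == findRoot(j)) next
      if (!.pairCanReach(counts[[i]], counts[[j]], lens[i], lens[j],
                         threshold)) next
      if (globalIdentity(seqs[i], seqs[j]) > threshold)
        parent[findRoot(j)] <- findRoot(i)
    }
  }
  cls <- vapply(seq_len(n), findRoot, integer(1))
  ids <- names(sequences(set))
  keep <- logical(n)
  for (cl in unique(cls)) {
    members <- which(cls == cl)
    best <- members[order(-lens[members], ids[members])][1L]
    keep[best] <- TRUE
  }
  transcriptSet(taxon(set), sequences(set)[keep])
}

#' Identify putative orthologue pairs between two taxa
#'
#' Scores every cross-taxon transcript pair by global identity (a
#' conservative shared 8-mer bound skips pairs that provably cannot reach
#' the threshold) and reports a one-to-one best-hit matching among pairs at
#' identity \code{>= threshold}: pairs are accepted in order of decreasing
#' identity, then longer alignment, then lexicographic ids, each transcript
#' participating in at most one reported pair.
#'
#' @param setA,setB \linkS4class{TranscriptSet} objects for distinct taxa.
#' @param threshold identity threshold, default 0.90 (inclusive).
#' @return data.frame: taxonA, idA, taxonB, idB, identity, alnLength.
#'   Empty (with a warning) when either set is empty.
#' @export
pairOrthologues <- function(setA, setB, threshold = 0.90) {
  stopifnot(is(setA, "TranscriptSet"), is(setB, "TranscriptSet"))
  if (identical(taxon(setA), taxon(setB)))
    stop("orthologue pairing requires two distinct taxa")
  empty <- data.frame(taxonA = character(0), idA = character(0),
                      taxonB = character(0), idB = character(0),
                      identity = numeric(0), alnLength = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(setA) || !length(setB)) {
    warning("empty transcript set: no orthologue pairs reported")
    return(empty)
  }
  seqsA <- as.character(sequences(setA))
  seqsB <- as.character(sequences(setB))
  lensA <- nchar(seqsA); lensB <- nchar(seqsB)
  countsA <- lapply(seqsA, .kmerCounts)
  countsB <- lapply(seqsB, .kmerCounts)
  idsA <- names(seqsA); idsB <- names(seqsB)
  hits <- list()
  for (i in seq_along(seqsA)) {
    for (j in seq_along(seqsB)) {
      if (!.pairCanReach(countsA[[i]], countsB[[j]], lensA[i], lensB[j],
                         threshold)) next
      st <- .globalAlnStats(seqsA[i], seqsB[j])
      if (st$identity >= threshold)
        hits[[length(hits) + 1L]] <- data.frame(
          i = i, j = j, identity = st$identity, alnLength = st$columns)
    }
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  ord <- order(-hits$identity, -hits$alnLength, idsA[hits$i], idsB[hits$j])
  hits <- hits[ord, , drop = FALSE]
  usedA <- logical(length(seqsA)); usedB <- logical(length(seqsB))
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    if (usedA[hits$i[r]] || usedB[hits$j[r]]) next
    usedA[hits$i[r]] <- TRUE; usedB[hits$j[r]] <- TRUE
    keep[r] <- TRUE
  }
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(
    taxonA = taxon(setA), idA = idsA[hits$i],
    taxonB = taxon(setB), idB = idsB[hits$j],
    identity = hits$identity, alnLength = as.integer(hits$alnLength),
    stringsAsFactors = FALSE)
  out[order(out$idA), , drop = FALSE]
}

#' Write / read an orthologue-pair table
#'
#' Plain TSV with header columns taxonA, idA, taxonB, idB, identity,
#' alnLength.
#'
#' @param pairs data.frame as returned by \code{\link{pairOrthologues}}.
#' @param path file path.
#' @return \code{readPairsTsv} returns the data.frame;
#'   \code{writePairsTsv} returns \code{path} invisibly.
#' @export
writePairsTsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePairsTsv
#' @export
readPairsTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
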