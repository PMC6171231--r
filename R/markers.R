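.MIN_REPEATS <- c(12L, 6L, 5L, 5L, 4L, 4L)  # unit lengths 1..6

# Smallest cycle-rotation of a motif, for Fig.-2-style class grouping.
.canonicalMotif <- function(motif) {
  vapply(motif, function(m) {
    ch <- strsplit(m, "")[[1]]
    rots <- vapply(seq_along(ch), function(k)
      paste(c(ch[k:length(ch)], ch[seq_len(k - 1L)]), collapse = ""),
      character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE when the motif is itself periodic with some divisor period < unit,
# i.e. the run belongs to a smaller repeating unit.
.motifReducible <- function(motif) {
  u <- nchar(motif)
  ch <- strsplit(motif, "")[[1]]
  for (p in seq_len(u - 1L)) {
    if (u %% p != 0L) next
    if (all(ch == rep_len(ch[seq_len(p)], u))) return(TRUE)
  }
  FALSE
}

#' Scan a sequence for microsatellites (SSRs)
#'
#' Finds maximal perfect tandem repeats of 1--6 nt motifs meeting
#' class-specific minimum repeat counts (defaults 12 for mono-, 6 for di-,
#' 5 for tri- and tetra-, 4 for penta- and hexanucleotide motifs). Each run
#' is reported exactly once, under its smallest repeating unit; partial
#' trailing units are truncated so that \code{end - start + 1 = unit *
#' repeats}. N breaks a repeat run. Coordinates are 1-based inclusive.
#'
#' @param seq nucleotide sequence (character or \code{DNAString}) over
#'   A/C/G/T/N.
#' @param id sequence id recorded in the output.
#' @param minRepeats integer vector of length 6: minimum repeat count per
#'   unit length.
#' @param normalizeMotif logical; when TRUE, an extra column
#'   \code{canonical} holds the lexicographically smallest cycle rotation
#'   of each motif (for class grouping across strandless reports).
#' @return data.frame: id, motif, unit, repeats, start, end (+canonical).
#' @examples
#' findSSRs(strrep("A", 12))          # one mono-SSR
#' findSSRs(strrep("ACG", 5))$unit    # 3
#' @export
findSSRs <- function(seq, id = "seq", minRepeats = .MIN_REPEATS,
                     normalizeMotif = FALSE) {
  seq <- toupper(as.character(seq))
  stopifnot(length(minRepeats) == 6L)
  ch <- strsplit(seq, "")[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  L <- length(ch)
  rows <- list()
  for (u in 1:6) {
    if (L < u * minRepeats[u]) next
    idx <- seq_len(L - u)
    eq <- ch[idx] == ch[idx + u] & valid[idx] & valid[idx + u]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      span <- r$lengths[k] + u          # nt covered by the periodic region
      repeats <- span %/% u
      if (repeats < minRepeats[u]) next
      start <- starts[k]
      motif <- substr(seq, start, start + u - 1L)
      if (.motifReducible(motif)) next  # reported under its smaller unit
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, motif = motif, unit = u, repeats = repeats,
        start = start, end = start + u * repeats - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), motif = character(0), unit = integer(0),
               repeats = integer(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  if (normalizeMotif && nrow(out)) out$canonical <- .canonicalMotif(out$motif)
  else if (normalizeMotif) out$canonical <- character(0)
  out
}

#' Scan a whole TranscriptSet (or FASTA) for SSRs
#'
#' @param x a \linkS4class{TranscriptSet} or FASTA path.
#' @param ... passed to \code{\link{findSSRs}}.
#' @return combined data.frame over all sequences.
#' @export
findSSRsInSet <- function(x, ...) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- readTranscripts(x)
  stopifnot(is(x, "TranscriptSet"))
  seqs <- as.character(sequences(x))
  do.call(rbind, lapply(names(seqs), function(id)
    findSSRs(seqs[[id]], id = id, ...)))
}

#' Classify a SNP allele pair as transition or transversion
#'
#' Purine--purine (A/G) or pyrimidine--pyrimidine (C/T) substitutions are
#' transitions; all purine--pyrimidine substitutions are transversions.
#' Symmetric in its arguments; vectorised.
#'
#' @param a,b allele vectors over \{A, C, G, T\}, pairwise distinct.
#' @return character vector, \code{"transition"} or \code{"transversion"}.
#' @examples
#' classifySNP("A", "G")  # transition
#' classifySNP("A", "T")  # transversion
#' @export
classifySNP <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != length(b))
    stop("allele vectors must have equal length")
  if (any(!a %in% c("A", "C", "G", "T")) || any(!b %in% c("A", "C", "G", "T")))
    stop("alleles must be A, C, G or T")
  if (any(a == b))
    stop("SNP alleles must differ")
  purine <- c("A", "G")
  ifelse((a %in% purine) == (b %in% purine), "transition", "transversion")
}

#' Marker class-frequency summary
#'
#' Tabulates SSR loci by unit-length class and motif, and SNP records by
#' unordered allele pair with transition/transversion fractions -- the
#' standard marker-distribution summaries reported for transcriptome
#' surveys.
#'
#' @param ssrs data.frame from \code{\link{findSSRs}} (may be empty or
#'   NULL).
#' @param snps data.frame with columns \code{alleleA}, \code{alleleB} (may
#'   be empty or NULL).
#' @return list with \code{ssrByUnit} (named counts for units 1--6),
#'   \code{ssrByMotif} (table), \code{snpByPair} (table of unordered
#'   pairs), \code{tsTv} (counts and \code{tsFraction}).
#' @export
markerSummary <- function(ssrs = NULL, snps = NULL) {
  ssrByUnit <- stats::setNames(integer(6L), as.character(1:6))
  ssrByMotif <- table(character(0))
  if (!is.null(ssrs) && nrow(ssrs)) {
    tab <- table(factor(ssrs$unit, levels = 1:6))
    ssrByUnit[] <- as.integer(tab)
    ssrByMotif <- sort(table(ssrs$motif), decreasing = TRUE)
  }
  snpByPair <- table(character(0))
  tsTv <- c(transition = 0L, transversion = 0L, tsFraction = NA_real_)
  if (!is.null(snps) && nrow(snps)) {
    klass <- classifySNP(snps$alleleA, snps$alleleB)
    pair <- vapply(seq_len(nrow(snps)), function(i)
      paste(sort(c(toupper(snps$alleleA[i]), toupper(snps$alleleB[i]))),
            collapse = "/"), character(1))
    snpByPair <- sort(table(pair), decreasing = TRUE)
    nTs <- sum(klass == "transition")
    tsTv <- c(transition = nTs,
              transversion = sum(klass == "transversion"),
              tsFraction = nTs / length(klass))
  }
  list(ssrByUnit = ssrByUnit, ssrByMotif = ssrByMotif,
       snpByPair = snpByPair, tsTv = tsTv)
}
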