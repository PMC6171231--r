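#' Jukes--Cantor multiple-hit correction
#'
#' Converts an observed proportion of differing sites \code{p} into an
#' estimated number of substitutions per site,
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4p}{3})}. Monotone increasing and
#' always \eqn{\ge p}; diverges as \code{p} approaches 3/4, where the
#' correction is undefined (saturation).
#'
#' @param p numeric vector of difference proportions, each in [0, 3/4).
#' @return numeric vector of corrected distances.
#' @examples
#' jcCorrect(0)      # 0
#' jcCorrect(0.05)   # ~0.0517
#' @export
jcCorrect <- function(p) {
  if (!is.numeric(p) || anyNA(p))
    stop("p must be numeric without NAs")
  if (any(p < 0) || any(p >= 0.75))
    stop("saturation: p must lie in [0, 3/4)")
  -0.75 * log(1 - 4 * p / 3)
}

.translateCodons <- function(codons) {
  tab <- .codonTable()
  aa <- rep("X", length(codons))
  known <- codons %in% tab$codons
  aa[known] <- tab$aa[tab$index[codons[known]]]
  aa
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Infer the reading frame of a transcript
#'
#' Scans all six frames (three offsets on each strand) for the longest run
#' of stop-free codons and returns it as a \linkS4class{CodingSequence}.
#' This replaces database-guided directionality assignment with a
#' self-contained longest-ORF rule. Ties are broken deterministically:
#' forward strand first, then lower frame offset, then the earliest start.
#'
#' @param seq a nucleotide sequence (character or \code{DNAString});
#'   alphabet A, C, G, T, N. Codons containing N are treated as non-stop
#'   and translate to \code{"X"}.
#' @param id transcript id recorded on the result.
#' @param minCodons minimum ORF length in codons (default 50); sequences
#'   whose best stop-free run is shorter are reported non-coding.
#' @return a \linkS4class{CodingSequence}, or \code{NULL} when no stop-free
#'   run of at least \code{minCodons} codons exists (non-coding signal).
#' @export
inferFrame <- function(seq, id = "seq", minCodons = 50L) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) < 3L * minCodons) return(NULL)
  revcomp <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp
    for (offset in 0:2) {
      codons <- .splitCodons(substring(s, offset + 1L))
      if (!length(codons)) next
      isStop <- codons %in% c("TAA", "TAG", "TGA")
      runs <- rle(!isStop)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- which(runs$values)
      for (k in keep) {
        len <- runs$lengths[k]
        if (is.null(best) || len > best$len) {
          best <- list(len = len, strand = strand, offset = offset,
                       start = starts[k], codons = codons[starts[k]:ends[k]])
        }
      }
    }
  }
  if (is.null(best) || best$len < minCodons) return(NULL)
  orf <- paste(best$codons, collapse = "")
  new("CodingSequence",
      id = as.character(id), orf = orf, offset = as.integer(best$offset),
      strand = best$strand,
      protein = paste(.translateCodons(best$codons), collapse = ""))
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Aligns the translated proteins globally (Needleman--Wunsch via
#' \code{Biostrings::pairwiseAlignment}) and back-translates the alignment
#' onto the nucleotide codons. Columns where either side is a gap, or where
#' a codon contains an ambiguous base, are flagged excluded so that
#' substitution counting only ever sees clean sense-codon pairs.
#'
#' @param a,b \linkS4class{CodingSequence} objects (see
#'   \code{\link{inferFrame}}).
#' @param substitutionMatrix protein scoring matrix name (default
#'   \code{"BLOSUM62"}).
#' @param gapOpening,gapExtension gap penalties for the protein alignment.
#' @return a \linkS4class{CodonAlignment}, or \code{NULL} when no codon
#'   column survives exclusion (unalignable signal).
#' @export
codonAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                       gapOpening = 10, gapExtension = 0.5) {
  stopifnot(is(a, "CodingSequence"), is(b, "CodingSequence"))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a@protein), Biostrings::AAString(b@protein),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  alnA <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  alnB <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  codA <- .splitCodons(a@orf)
  codB <- .splitCodons(b@orf)
  iA <- cumsum(alnA != "-")
  iB <- cumsum(alnB != "-")
  colA <- ifelse(alnA == "-", "---", codA[iA])
  colB <- ifelse(alnB == "-", "---", codB[iB])
  hasN <- grepl("[^ACGT-]", colA) | grepl("[^ACGT-]", colB)
  excluded <- colA == "---" | colB == "---" | hasN
  if (all(excluded)) return(NULL)
  new("CodonAlignment", idA = a@id, idB = b@id,
      codonsA = colA, codonsB = colB, excluded = excluded)
}

#' Nei--Gojobori (1986) Ka/Ks estimation on a codon alignment
#'
#' Counting estimator: each codon contributes synonymous/nonsynonymous site
#' fractions (mutations to stop codons excluded position-wise, so S + N is
#' exactly 3 per counted codon, averaged over the two sequences); differences
#' within a codon pair are averaged over all minimal mutational pathways,
#' pathways crossing a stop codon excluded. The difference proportions
#' \code{ps = Sd/S} and \code{pn = Nd/N} are Jukes--Cantor corrected into
#' \code{Ks} and \code{Ka}.
#'
#' Flag conventions: \code{"undefined"} when no differences at all
#' (omega has no value), \code{"> 1"} when Ks = 0 but Ka > 0 (reported as
#' positive selection downstream), \code{"saturated"} when ps or pn reaches
#' 3/4 (the correction diverges; the pair is dropped downstream).
#'
#' @param aln a \linkS4class{CodonAlignment}.
#' @return a \linkS4class{RateEstimate}.
#' @seealso \code{\link{codonAlign}}, \code{\link{jcCorrect}},
#'   \code{\link{screenPositive}}
#' @export
ng86 <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  use <- !aln@excluded
  if (!any(use))
    stop("ng86 needs at least one gap-free codon column")
  codA <- aln@codonsA[use]
  codB <- aln@codonsB[use]
  tab <- .codonTable()
  synSites <- .synSitesPerCodon()
  iA <- tab$index[codA]
  iB <- tab$index[codB]
  nCodons <- length(iA)
  S <- (sum(synSites[iA]) + sum(synSites[iB])) / 2
  N <- 3 * nCodons - S
  counts <- .pairCountMatrices()
  Sd <- sum(counts$sd[cbind(iA, iB)])
  Nd <- sum(counts$nd[cbind(iA, iB)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  flag <- "ok"
  Ka <- Ks <- omega <- NA_real_
  if (Sd == 0 && Nd == 0) {
    Ka <- Ks <- 0
    flag <- "undefined"
  } else if (ps >= 0.75 || pn >= 0.75) {
    flag <- "saturated"
  } else {
    Ks <- jcCorrect(ps)
    Ka <- jcCorrect(pn)
    if (Ks == 0 && Ka > 0) {
      flag <- "> 1"
    } else {
      omega <- Ka / Ks
    }
  }
  new("RateEstimate", S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
      Ka = Ka, Ks = Ks, omega = omega, flag = flag)
}

#' Ka/Ks table for a set of orthologue pairs
#'
#' Runs frame inference, codon alignment and NG86 counting over a pair table
#' (as produced by \code{\link{pairOrthologues}}) and returns one row per
#' pair. Pairs that fail frame inference or alignment are reported with an
#' explanatory flag and NA rates; saturated pairs are kept but flagged.
#'
#' @param pairs data.frame with columns \code{taxonA}, \code{idA},
#'   \code{taxonB}, \code{idB} (extra columns are ignored).
#' @param sets named list of \linkS4class{TranscriptSet} objects covering
#'   every taxon in \code{pairs}.
#' @param minCodons minimum ORF length for \code{\link{inferFrame}}.
#' @return data.frame: taxonA, idA, taxonB, idB, S, N, Sd, Nd, Ka, Ks,
#'   omega, flag.
#' @export
estimatePairRates <- function(pairs, sets, minCodons = 50L) {
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  out <- data.frame(
    taxonA = character(n), idA = character(n),
    taxonB = character(n), idB = character(n),
    S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
    Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
    flag = character(n), stringsAsFactors = FALSE)
  cdsCache <- new.env(parent = emptyenv())
  getCds <- function(taxon, id) {
    key <- paste(taxon, id, sep = "\r")
    if (!is.null(cdsCache[[key]])) return(cdsCache[[key]])
    seqs <- sequences(sets[[taxon]])
    cds <- inferFrame(seqs[[id]], id = id, minCodons = minCodons)
    cdsCache[[key]] <- if (is.null(cds)) "noncoding" else cds
    cdsCache[[key]]
  }
  for (i in seq_len(n)) {
    out$taxonA[i] <- pairs$taxonA[i]; out$idA[i] <- pairs$idA[i]
    out$taxonB[i] <- pairs$taxonB[i]; out$idB[i] <- pairs$idB[i]
    a <- getCds(pairs$taxonA[i], pairs$idA[i])
    b <- getCds(pairs$taxonB[i], pairs$idB[i])
    if (identical(a, "noncoding") || identical(b, "noncoding")) {
      out$flag[i] <- "noncoding"
      next
    }
    aln <- codonAlign(a, b)
    if (is.null(aln)) {
      out$flag[i] <- "unalignable"
      next
    }
    est <- ng86(aln)
    out$S[i] <- est@S; out$N[i] <- est@N
    out$Sd[i] <- est@Sd; out$Nd[i] <- est@Nd
    out$Ka[i] <- est@Ka; out$Ks[i] <- est@Ks
    out$omega[i] <- est@omega; out$flag[i] <- est@flag
  }
  out
}
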