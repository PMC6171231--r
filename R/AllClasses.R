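#' @import methods
#' @importFrom Biostrings DNAStringSet
NULL

#' Simulation configuration for the codon-evolution generator
#'
#' Holds the parameters of the synthetic codon-evolution process: a seed,
#' gene length in codons, the nonsynonymous/synonymous rate ratio
#' \eqn{\omega = Ka/Ks}, the target synonymous divergence \eqn{Ks}
#' (substitutions per synonymous site), the number of genes, an optional
#' taxon tree (an \code{ape::phylo} with branch lengths in Ks units), and the
#' number of non-orthologous decoy sequences appended per taxon.
#'
#' @slot seed integer, RNG seed; identical configs give byte-identical output.
#' @slot nCodons integer, codons per simulated gene (>= 1).
#' @slot omega numeric, target Ka/Ks (>= 0).
#' @slot ksTarget numeric, expected synonymous substitutions per synonymous
#'   site between ancestor and derived sequence (>= 0).
#' @slot nGenes integer, number of independent genes.
#' @slot tree an \code{ape::phylo} object or \code{NULL}.
#' @slot nDecoys integer, random (non-orthologous) codon sequences appended to
#'   each taxon by \code{\link{simulateClade}}.
#'
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateCodonPair}},
#'   \code{\link{simulateClade}}
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nCodons = "integer",
    omega = "numeric",
    ksTarget = "numeric",
    nGenes = "integer",
    tree = "ANY",
    nDecoys = "integer"
  ),
  prototype(
    seed = 1L, nCodons = 300L, omega = 0.2, ksTarget = 0.05,
    nGenes = 100L, tree = NULL, nDecoys = 0L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@nCodons) != 1L || is.na(object@nCodons) ||
      object@nCodons < 1L)
    msg <- c(msg, "nCodons must be a single integer >= 1")
  if (length(object@omega) != 1L || is.na(object@omega) || object@omega < 0)
    msg <- c(msg, "omega must be a single nonnegative number")
  if (length(object@ksTarget) != 1L || is.na(object@ksTarget) ||
      object@ksTarget < 0)
    msg <- c(msg, "ksTarget must be a single nonnegative number")
  if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
      object@nGenes < 1L)
    msg <- c(msg, "nGenes must be a single integer >= 1")
  if (length(object@nDecoys) != 1L || is.na(object@nDecoys) ||
      object@nDecoys < 0L)
    msg <- c(msg, "nDecoys must be a single integer >= 0")
  if (!is.null(object@tree)) {
    if (!inherits(object@tree, "phylo"))
      msg <- c(msg, "tree must be NULL or an ape 'phylo' object")
    else if (is.null(object@tree$edge.length))
      msg <- c(msg, "tree must carry branch lengths (in Ks units)")
    else if (any(object@tree$edge.length < 0))
      msg <- c(msg, "tree branch lengths must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' A per-taxon set of transcript sequences
#'
#' A named collection of nucleotide transcripts for one taxon, the unit on
#' which redundancy collapsing and cross-taxon orthologue pairing operate.
#'
#' @slot taxon character, the taxon name.
#' @slot sequences a \code{DNAStringSet}; names are transcript ids, unique
#'   within the taxon; alphabet restricted to A, C, G, T, N.
#'
#' @seealso \code{\link{transcriptSet}}, \code{\link{collapseRedundant}},
#'   \code{\link{pairOrthologues}}
#' @export
setClass("TranscriptSet",
  representation(taxon = "character", sequences = "DNAStringSet")
)

setValidity("TranscriptSet", function(object) {
  msg <- character()
  if (length(object@taxon) != 1L || is.na(object@taxon) ||
      !nzchar(object@taxon))
    msg <- c(msg, "taxon must be a single non-empty name")
  ids <- names(object@sequences)
  if (length(object@sequences)) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all sequences must be named (transcript ids)")
    else if (anyDuplicated(ids))
      msg <- c(msg, "transcript ids must be unique within a taxon")
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "sequences must be non-empty")
    freq <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    bad <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
    if (sum(bad) > 0)
      msg <- c(msg, "sequence alphabet restricted to {A,C,G,T,N}")
  }
  if (length(msg)) msg else TRUE
})

#' A coding sequence with inferred reading frame
#'
#' The output of \code{\link{inferFrame}}: the longest stop-free open reading
#' region found across the six frames of a transcript, with its translation.
#'
#' @slot id character, transcript id.
#' @slot orf character, the in-frame nucleotide sequence (length divisible
#'   by 3, no internal stop codon).
#' @slot offset integer 0--2, offset of the ORF on the chosen strand.
#' @slot strand character, \code{"+"} or \code{"-"}.
#' @slot protein character, translated amino acids.
#' @export
setClass("CodingSequence",
  representation(
    id = "character", orf = "character", offset = "integer",
    strand = "character", protein = "character"
  )
)

setValidity("CodingSequence", function(object) {
  msg <- character()
  if (nchar(object@orf) %% 3L != 0L)
    msg <- c(msg, "orf length must be a multiple of 3")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!object@offset %in% 0:2)
    msg <- c(msg, "offset must be 0, 1 or 2")
  if (grepl("\\*", sub("\\*$", "", object@protein)))
    msg <- c(msg, "translated region contains an internal stop")
  if (length(msg)) msg else TRUE
})

#' A pairwise codon alignment
#'
#' Codon columns obtained by aligning two translated coding sequences at the
#' protein level and back-translating to nucleotide triplets. Columns in
#' which either side is a gap or contains an ambiguous base are flagged and
#' excluded from substitution counting.
#'
#' @slot idA,idB character, ids of the two coding sequences.
#' @slot codonsA,codonsB character vectors of equal length; each element a
#'   3-letter codon or \code{"---"} for a gap.
#' @slot excluded logical vector, \code{TRUE} for columns dropped from
#'   counting (gap or N-containing).
#' @seealso \code{\link{codonAlign}}, \code{\link{ng86}}
#' @export
setClass("CodonAlignment",
  representation(
    idA = "character", idB = "character",
    codonsA = "character", codonsB = "character",
    excluded = "logical"
  )
)

setValidity("CodonAlignment", function(object) {
  msg <- character()
  n <- length(object@codonsA)
  if (length(object@codonsB) != n || length(object@excluded) != n)
    msg <- c(msg, "codonsA, codonsB and excluded must have equal length")
  if (n) {
    used <- !object@excluded
    codons <- c(object@codonsA[used], object@codonsB[used])
    if (any(nchar(codons) != 3L))
      msg <- c(msg, "counted codons must be 3 nt")
    else if (any(.codonIsStop(codons)))
      msg <- c(msg, "counted codons must be stop-free")
    gapA <- object@codonsA == "---"
    gapB <- object@codonsB == "---"
    if (any((gapA | gapB) & used))
      msg <- c(msg, "gap columns must be flagged excluded")
  }
  if (length(msg)) msg else TRUE
})

#' Ka/Ks rate estimate for one codon-aligned pair
#'
#' Nei--Gojobori site and difference counts with Jukes--Cantor corrected
#' rates. \code{omega} is \code{NA} when flagged (saturated, undefined, or
#' the "> 1" convention for Ks = 0 with Ka > 0).
#'
#' @slot S,N numeric, synonymous and nonsynonymous site counts (S + N equals
#'   3 x counted codons).
#' @slot Sd,Nd numeric, synonymous and nonsynonymous difference counts.
#' @slot ps,pn numeric, difference proportions Sd/S and Nd/N.
#' @slot Ka,Ks numeric, Jukes--Cantor corrected rates.
#' @slot omega numeric, Ka/Ks; \code{NA} when not a finite ratio.
#' @slot flag character: \code{"ok"}, \code{"identical"}, \code{"> 1"}
#'   (Ks = 0, Ka > 0), \code{"undefined"} (Ka = Ks = 0), or
#'   \code{"saturated"} (ps or pn at or beyond 3/4; rates unusable).
#' @seealso \code{\link{ng86}}
#' @export
setClass("RateEstimate",
  representation(
    S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
    ps = "numeric", pn = "numeric", Ka = "numeric", Ks = "numeric",
    omega = "numeric", flag = "character"
  )
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (!object@flag %in% c("ok", "identical", "> 1", "undefined", "saturated"))
    msg <- c(msg, "unknown flag")
  if (!is.na(object@Ka) && object@Ka < 0) msg <- c(msg, "Ka must be >= 0")
  if (!is.na(object@Ks) && object@Ks < 0) msg <- c(msg, "Ks must be >= 0")
  if (object@S > 0 && abs(object@ps - object@Sd / object@S) > 1e-9)
    msg <- c(msg, "ps must equal Sd/S")
  if (object@N > 0 && abs(object@pn - object@Nd / object@N) > 1e-9)
    msg <- c(msg, "pn must equal Nd/N")
  if (length(msg)) msg else TRUE
})

#' Species-pair Ks-peak matrix
#'
#' A symmetric taxon-by-taxon table holding, for every species pair, the
#' modal synonymous divergence (Ks peak) and the number of orthologue pairs
#' behind it. This is the distance matrix the neighbour-joining phylogeny is
#' built from.
#'
#' @slot taxa character, ordered taxon names.
#' @slot peaks numeric matrix, Ks peaks; symmetric, \code{NA} diagonal.
#' @slot nPairs integer matrix, orthologue-pair counts; symmetric,
#'   \code{NA} diagonal.
#' @seealso \code{\link{peakMatrix}}, \code{\link{coniferKsPeaks}},
#'   \code{\link{njTree}}
#' @export
setClass("KsPeakMatrix",
  representation(taxa = "character", peaks = "matrix", nPairs = "matrix")
)

setValidity("KsPeakMatrix", function(object) {
  msg <- character()
  k <- length(object@taxa)
  for (slotname in c("peaks", "nPairs")) {
    m <- slot(object, slotname)
    if (!all(dim(m) == c(k, k))) {
      msg <- c(msg, sprintf("%s must be %d x %d", slotname, k, k))
      next
    }
    off <- row(m) != col(m)
    vals <- m[off]
    if (!isTRUE(all.equal(m[off], t(m)[off], tolerance = 1e-12,
                          check.attributes = FALSE)))
      msg <- c(msg, sprintf("%s must be symmetric", slotname))
    if (any(!is.na(diag(m))))
      msg <- c(msg, sprintf("%s diagonal must be NA", slotname))
    if (any(!is.na(vals) & vals < 0))
      msg <- c(msg, sprintf("%s entries must be nonnegative", slotname))
  }
  if (length(msg)) msg else TRUE
})

#' A rooted clade tree with branch-average Ks and clock ages
#'
#' A neighbour-joining tree in Ks-distance units rooted on an outgroup, with
#' a per-internal-node table of branch-average Ks (mean of all cross-clade
#' pairwise Ks-peak entries) and molecular-clock divergence ages.
#'
#' @slot tree an \code{ape::phylo}, rooted, branch lengths in Ks units.
#' @slot outgroup character, the outgroup taxon.
#' @slot nodes data.frame with columns \code{node}, \code{cladeA},
#'   \code{cladeB} (comma-separated taxon lists), \code{ks} (branch-average
#'   Ks, 3 decimals) and \code{ageMya}.
#' @slot rate numeric, synonymous substitutions per site per year.
#' @seealso \code{\link{rootWithOutgroup}}, \code{\link{cladeAges}}
#' @export
setClass("CladeTree",
  representation(
    tree = "ANY", outgroup = "character", nodes = "data.frame",
    rate = "numeric"
  )
)

setValidity("CladeTree", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo"))
    msg <- c(msg, "tree must be an ape 'phylo' object")
  else {
    if (!ape::is.rooted(object@tree))
      msg <- c(msg, "tree must be rooted")
    if (!object@outgroup %in% object@tree$tip.label)
      msg <- c(msg, "outgroup must be a tip of the tree")
  }
  if (length(object@rate) != 1L || is.na(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' All thresholds and inputs of the end-to-end chain: per-taxon FASTA paths,
#' the redundancy and orthology identity thresholds, Ks histogram bin width
#' and saturation cap, the molecular-clock rate, minimum ORF length, the
#' outgroup taxon, output directory and seed.
#'
#' @slot fastaFiles named character, one FASTA path per taxon.
#' @slot redundancyThreshold numeric in (0,1); within-taxon collapse uses
#'   strict \code{>} this value (default 0.95).
#' @slot orthologyThreshold numeric in (0,1); cross-taxon pairing uses
#'   \code{>=} this value (default 0.90).
#' @slot binWidth numeric, Ks histogram bin width (default 0.01).
#' @slot ksCap numeric, saturation cap on Ks values (default 2.0).
#' @slot clockRate numeric, synonymous substitutions/site/year
#'   (default 0.68e-9).
#' @slot minCodons integer, minimum ORF length in codons (default 50).
#' @slot outgroup character, outgroup taxon name (may be \code{NA} when no
#'   tree is requested).
#' @slot outDir character, output directory.
#' @slot seed integer.
#' @seealso \code{\link{runPipeline}}
#' @export
setClass("PipelineConfig",
  representation(
    fastaFiles = "character",
    redundancyThreshold = "numeric",
    orthologyThreshold = "numeric",
    binWidth = "numeric",
    ksCap = "numeric",
    clockRate = "numeric",
    minCodons = "integer",
    outgroup = "character",
    outDir = "character",
    seed = "integer"
  ),
  prototype(
    redundancyThreshold = 0.95, orthologyThreshold = 0.90,
    binWidth = 0.01, ksCap = 2.0, clockRate = 0.68e-9, minCodons = 50L,
    outgroup = NA_character_, outDir = ".", seed = 1L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && !is.na(x) && x > 0 && x < 1
  if (!inUnit(object@redundancyThreshold))
    msg <- c(msg, "redundancyThreshold must be in (0,1)")
  if (!inUnit(object@orthologyThreshold))
    msg <- c(msg, "orthologyThreshold must be in (0,1)")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (object@ksCap <= object@binWidth)
    msg <- c(msg, "ksCap must exceed binWidth")
  if (object@clockRate <= 0) msg <- c(msg, "clockRate must be positive")
  if (object@minCodons < 1L) msg <- c(msg, "minCodons must be >= 1")
  if (is.null(names(object@fastaFiles)) && length(object@fastaFiles))
    msg <- c(msg, "fastaFiles must be named by taxon")
  if (!is.na(object@outgroup) && length(object@fastaFiles) &&
      !object@outgroup %in% names(object@fastaFiles))
    msg <- c(msg, "outgroup must be one of the input taxa")
  if (length(msg)) msg else TRUE
})
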