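#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed; the whole simulation is a pure function of
#'   the config, so identical configs give byte-identical output.
#' @param nCodons codons per gene.
#' @param omega target Ka/Ks of the mutation process (>= 0).
#' @param ksTarget expected synonymous substitutions per synonymous site
#'   accumulated between ancestor and derived sequence (>= 0).
#' @param nGenes number of independently evolving genes.
#' @param tree optional \code{ape::phylo} with branch lengths in Ks units
#'   (required by \code{\link{simulateClade}}).
#' @param nDecoys random non-orthologous codon sequences appended per taxon.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nCodons = 200, omega = 0.2,
#'                         ksTarget = 0.05, nGenes = 10)
#' @export
simulationConfig <- function(seed = 1L, nCodons = 300L, omega = 0.2,
                             ksTarget = 0.05, nGenes = 100L, tree = NULL,
                             nDecoys = 0L) {
  if (length(omega) != 1L || is.na(omega) || omega < 0)
    stop("omega must be a single nonnegative number")
  if (length(ksTarget) != 1L || is.na(ksTarget) || ksTarget < 0)
    stop("ksTarget must be a single nonnegative number")
  new("SimulationConfig", seed = as.integer(seed),
      nCodons = as.integer(nCodons), omega = as.numeric(omega),
      ksTarget = as.numeric(ksTarget), nGenes = as.integer(nGenes),
      tree = tree, nDecoys = as.integer(nDecoys))
}

# Uniform random sense codons, as indices into the 64-codon table.
.randomSenseCodons <- function(n) {
  tab <- .codonTable()
  sample(which(tab$sense), n, replace = TRUE)
}

# Per-codon counts of available synonymous / nonsynonymous single-nt
# changes (stop-creating changes never available).
.classCandidateCounts <- function() {
  if (!is.null(.pinediv_cache$classCounts)) return(.pinediv_cache$classCounts)
  nb <- .neighbourTable()
  syn <- vapply(nb, function(d) sum(d$klass == "syn"), numeric(1))
  non <- vapply(nb, function(d) sum(d$klass == "nonsyn"), numeric(1))
  .pinediv_cache$classCounts <- list(syn = unname(syn), non = unname(non))
  .pinediv_cache$classCounts
}

# Evolve a codon-index vector by the target synonymous density `ks` and
# ratio `omega`. Event counts are Poisson with means ks*S and omega*ks*N
# (S, N = NG86 site counts of the starting sequence); events are applied in
# shuffled order, each picking uniformly among the single-nucleotide changes
# of its class available in the current sequence. Stop codons can never
# arise; multiple hits at a site occur naturally.
.evolveCodons <- function(codonIdx, ks, omega) {
  if (ks == 0) return(codonIdx)
  tab <- .codonTable()
  synSites <- .synSitesPerCodon()
  nb <- .neighbourTable()
  counts <- .classCandidateCounts()
  S <- sum(synSites[codonIdx])
  N <- 3 * length(codonIdx) - S
  nSyn <- stats::rpois(1L, ks * S)
  nNon <- stats::rpois(1L, omega * ks * N)
  events <- sample(c(rep("syn", nSyn), rep("nonsyn", nNon)))
  for (ev in events) {
    w <- if (ev == "syn") counts$syn[codonIdx] else counts$non[codonIdx]
    if (sum(w) == 0) next  # no change of this class available anywhere
    at <- sample.int(length(codonIdx), 1L, prob = w)
    cand <- nb[[codonIdx[at]]]
    cand <- cand[cand$klass == ev, , drop = FALSE]
    pick <- cand$target[sample.int(nrow(cand), 1L)]
    codonIdx[at] <- tab$index[[pick]]
  }
  codonIdx
}

.codonIdxToSeq <- function(codonIdx) {
  paste(.codonTable()$codons[codonIdx], collapse = "")
}

#' Simulate one ancestral--derived coding-sequence pair
#'
#' Draws a random stop-codon-free ancestral sequence and evolves a derived
#' copy under a per-codon single-nucleotide mutation process in which
#' synonymous changes accumulate at expected density \code{ksTarget} per
#' synonymous site and nonsynonymous changes at \code{omega * ksTarget} per
#' nonsynonymous site. No indels; no in-frame stop codon can arise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{ancestral} and \code{derived} (character
#'   nucleotide sequences, in frame) and \code{truth} (list: ksTarget,
#'   omega, nCodons, seed).
#' @examples
#' sim <- simulateCodonPair(simulationConfig(seed = 1, ksTarget = 0))
#' identical(sim$ancestral, sim$derived)  # TRUE at zero divergence
#' @export
simulateCodonPair <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  anc <- .randomSenseCodons(config@nCodons)
  der <- .evolveCodons(anc, config@ksTarget, config@omega)
  list(
    ancestral = .codonIdxToSeq(anc),
    derived = .codonIdxToSeq(der),
    truth = list(ksTarget = config@ksTarget, omega = config@omega,
                 nCodons = config@nCodons, seed = config@seed)
  )
}

#' Simulate transcript sets for a clade
#'
#' Evolves \code{nGenes} genes independently along \code{config@tree}
#' (branch lengths in Ks units): each gene starts from a random stop-free
#' ancestral sequence at the root and accumulates substitutions along every
#' branch under the \code{\link{simulateCodonPair}} process. Every taxon
#' receives one copy of each gene under a shared gene id for truth tracking,
#' plus \code{nDecoys} random non-orthologous codon sequences.
#'
#' @param config a \linkS4class{SimulationConfig} whose \code{tree} has at
#'   least 2 taxa.
#' @return list with \code{sets} (named list of \linkS4class{TranscriptSet})
#'   and \code{truth} (data.frame: gene, taxon, ksToRoot, omega).
#' @seealso \code{\link{writeCladeFasta}}
#' @export
simulateClade <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  tree <- config@tree
  if (is.null(tree) || length(tree$tip.label) < 2L)
    stop("simulateClade needs a tree with at least 2 taxa")
  set.seed(config@seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  nNode <- nTip + tree$Nnode
  taxa <- tree$tip.label
  perTaxon <- stats::setNames(
    rep(list(character(config@nGenes)), nTip), taxa)
  geneIds <- sprintf("g%04d", seq_len(config@nGenes))
  for (g in seq_len(config@nGenes)) {
    seqs <- vector("list", nNode)
    seqs[[root]] <- .randomSenseCodons(config@nCodons)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      seqs[[child]] <- .evolveCodons(seqs[[parent]],
                                     tree$edge.length[e], config@omega)
    }
    for (t in seq_len(nTip))
      perTaxon[[t]][g] <- .codonIdxToSeq(seqs[[t]])
  }
  sets <- lapply(taxa, function(tx) {
    sq <- perTaxon[[tx]]
    ids <- geneIds
    if (config@nDecoys > 0L) {
      decoys <- vapply(seq_len(config@nDecoys), function(i)
        .codonIdxToSeq(.randomSenseCodons(config@nCodons)), character(1))
      sq <- c(sq, decoys)
      ids <- c(ids, sprintf("decoy%03d", seq_len(config@nDecoys)))
    }
    transcriptSet(tx, stats::setNames(sq, ids))
  })
  names(sets) <- taxa
  depths <- ape::node.depth.edgelength(tree)[seq_len(nTip)]
  truth <- data.frame(
    gene = rep(geneIds, times = nTip),
    taxon = rep(taxa, each = config@nGenes),
    ksToRoot = rep(depths, each = config@nGenes),
    omega = config@omega,
    stringsAsFactors = FALSE)
  list(sets = sets, truth = truth)
}

#' Write a simulated clade to disk
#'
#' Writes one FASTA per taxon (record descriptions carry the seed), the
#' truth table as TSV (gene, taxon, ksToRoot, omega) and the configuration
#' as a flat key-value file.
#'
#' @param sim result of \code{\link{simulateClade}}.
#' @param config the \linkS4class{SimulationConfig} that produced it.
#' @param dir output directory (created if missing).
#' @return invisibly, the named character vector of files written.
#' @export
writeCladeFasta <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tx in names(sim$sets)) {
    path <- file.path(dir, paste0(tx, ".fasta"))
    seqs <- sequences(sim$sets[[tx]])
    names(seqs) <- paste0(names(seqs), " seed=", config@seed)
    Biostrings::writeXStringSet(seqs, path)
    files[tx] <- path
  }
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfgPath <- file.path(dir, "config.tsv")
  cfg <- c(seed = config@seed, nCodons = config@nCodons,
           omega = config@omega, ksTarget = config@ksTarget,
           nGenes = config@nGenes, nDecoys = config@nDecoys)
  writeLines(paste(names(cfg), cfg, sep = "\t"), cfgPath)
  invisible(c(files, truth = truthPath, config = cfgPath))
}
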