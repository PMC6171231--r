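.asDistanceMatrix <- function(m) {
  if (is(m, "KsPeakMatrix")) m <- peaks(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop("distance input must be a numeric matrix or KsPeakMatrix")
  if (is.null(rownames(m)))
    stop("distance matrix must carry taxon names")
  d <- m
  diag(d) <- 0
  if (anyNA(d) || any(!is.finite(d)))
    stop("distance matrix must be finite off the diagonal")
  if (any(d < 0))
    stop("distances must be nonnegative")
  if (max(abs(d - t(d))) > 1e-9)
    stop("distance matrix must be symmetric")
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical Saitou--Nei neighbour joining: at each step the pair minimising
#' the Q-criterion \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} is joined, with
#' ties broken deterministically by the lowest taxon-index pair. Negative
#' branch lengths (possible on non-additive input) are clamped to zero with
#' a warning. On an additive matrix the output tree reproduces the input
#' distances exactly.
#'
#' @param m a symmetric nonnegative distance matrix with taxon dimnames
#'   (zero or \code{NA} diagonal), or a \linkS4class{KsPeakMatrix}.
#' @return an unrooted \code{ape::phylo} tree with branch lengths in the
#'   input distance units.
#' @seealso \code{\link{rootWithOutgroup}}
#' @export
njTree <- function(m) {
  d <- .asDistanceMatrix(m)
  n <- nrow(d)
  if (n < 3L)
    stop("neighbour joining needs at least 3 taxa")
  frag <- rownames(d)
  clamp <- function(v) {
    if (v < 0) {
      warning("negative NJ branch length clamped to 0")
      return(0)
    }
    v
  }
  while (n > 3L) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    # ties on the Q-criterion break to the lowest (i, j) index pair
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      hit <- which(Q[i, (i + 1L):n] == qmin)
      if (length(hit)) { best <- c(i, i + hit[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    vi <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    newFrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], vi, frag[j], vj)
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dNew
    d[, i] <- dNew
    d[i, i] <- 0
    keep <- setdiff(seq_len(n), j)
    d <- d[keep, keep, drop = FALSE]
    frag[i] <- newFrag
    frag <- frag[-j]
    n <- n - 1L
  }
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = txt)
}

#' Root a tree on an outgroup taxon
#'
#' Places the root at the midpoint of the outgroup's pendant edge and
#' returns a \linkS4class{CladeTree} (node table empty until
#' \code{\link{cladeAges}} is applied). Re-rooting on the same taxon is
#' idempotent.
#'
#' @param tree an \code{ape::phylo}.
#' @param taxonName a tip label to use as outgroup.
#' @param rate molecular-clock rate recorded on the result (synonymous
#'   substitutions per site per year).
#' @return a \linkS4class{CladeTree}.
#' @export
rootWithOutgroup <- function(tree, taxonName, rate = 0.68e-9) {
  stopifnot(inherits(tree, "phylo"))
  if (!taxonName %in% tree$tip.label)
    stop("unknown outgroup taxon: ", taxonName)
  rooted <- ape::root(tree, outgroup = taxonName, resolve.root = TRUE)
  rootNode <- setdiff(rooted$edge[, 1L], rooted$edge[, 2L])
  childEdges <- which(rooted$edge[, 1L] == rootNode)
  stopifnot(length(childEdges) == 2L)
  # place the root at the midpoint of the outgroup's pendant edge: the two
  # root edges together carry that edge's full length (makes re-rooting on
  # the same taxon idempotent)
  total <- sum(rooted$edge.length[childEdges])
  rooted$edge.length[childEdges] <- total / 2
  new("CladeTree", tree = rooted, outgroup = taxonName,
      nodes = data.frame(), rate = rate)
}

#' Branch-average Ks between two clades
#'
#' The arithmetic mean of all cross-clade pairwise Ks-peak entries -- the
#' quantity fed to the molecular clock for the node where the two clades
#' meet. Reported to 3 decimals.
#'
#' @param m a \linkS4class{KsPeakMatrix} or named symmetric matrix.
#' @param cladeA,cladeB disjoint, non-empty character vectors of taxon
#'   names.
#' @return mean cross-clade Ks, rounded to 3 decimals.
#' @examples
#' m <- coniferKsPeaks()
#' branchAverageKs(m, setdiff(m@taxa, "Picea_glauca"), "Picea_glauca")
#' @export
branchAverageKs <- function(m, cladeA, cladeB) {
  pm <- if (is(m, "KsPeakMatrix")) peaks(m) else m
  if (!length(cladeA) || !length(cladeB))
    stop("clades must be non-empty")
  if (length(intersect(cladeA, cladeB)))
    stop("clades must be disjoint")
  missing <- setdiff(c(cladeA, cladeB), rownames(pm))
  if (length(missing))
    stop("taxa not in the matrix: ", paste(missing, collapse = ", "))
  round(mean(pm[cladeA, cladeB, drop = FALSE]), 3L)
}

#' Molecular-clock divergence time from Ks
#'
#' Converts a synonymous divergence into an age in million years (Mya) with
#' a strict molecular clock: \code{age = ks / (rate * 1e6)}. By default the
#' divergence is divided by the rate directly, the convention under which
#' the packaged conifer branch averages 0.146 / 0.078 / 0.035 date to about
#' 214.7 / 114.7 / 51.5 Mya at 0.68e-9 substitutions/site/year.
#' \code{perLineage = TRUE} applies the textbook \code{ks / (2 rate)}
#' instead (pairwise divergence split over the two lineages).
#'
#' @param ks nonnegative synonymous divergence (vectorised).
#' @param rate synonymous substitutions per site per year
#'   (default 0.68e-9).
#' @param perLineage logical; divide by \code{2 * rate} (default FALSE).
#' @return age(s) in Mya.
#' @examples
#' divergenceTime(0.146)  # ~214.7 Mya
#' @export
divergenceTime <- function(ks, rate = 0.68e-9, perLineage = FALSE) {
  if (any(is.na(ks)) || any(ks < 0))
    stop("ks must be nonnegative")
  if (rate <= 0)
    stop("clock rate must be positive")
  denom <- if (perLineage) 2 * rate else rate
  ks / (denom * 1e6)
}

.tipsBelow <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  out <- character(0)
  for (child in tree$edge[tree$edge[, 1L] == node, 2L])
    out <- c(out, .tipsBelow(tree, child))
  out
}

#' Date every split of a rooted tree
#'
#' For each internal node of a \linkS4class{CladeTree}, computes the
#' branch-average Ks between the two daughter clades from the Ks-peak
#' matrix and converts it to an age with the clock. Nodes with more than
#' two daughters (the unresolved root of a trifurcating tree) average over
#' all daughter-clade pairs.
#'
#' @param cladeTree a \linkS4class{CladeTree} from
#'   \code{\link{rootWithOutgroup}}.
#' @param m the \linkS4class{KsPeakMatrix} (or named matrix) the tree was
#'   built from.
#' @param perLineage passed to \code{\link{divergenceTime}}.
#' @return the \linkS4class{CladeTree} with its node table filled
#'   (columns: node, cladeA, cladeB, ks, ageMya).
#' @export
cladeAges <- function(cladeTree, m, perLineage = FALSE) {
  stopifnot(is(cladeTree, "CladeTree"))
  tree <- cladeTree@tree
  nTip <- length(tree$tip.label)
  rows <- list()
  for (node in (nTip + 1L):(nTip + tree$Nnode)) {
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (length(children) < 2L) next
    clades <- lapply(children, function(ch) .tipsBelow(tree, ch))
    ksVals <- c()
    for (a in seq_len(length(clades) - 1L))
      for (b in (a + 1L):length(clades))
        ksVals <- c(ksVals, branchAverageKs(m, clades[[a]], clades[[b]]))
    ks <- round(mean(ksVals), 3L)
    rows[[length(rows) + 1L]] <- data.frame(
      node = node,
      cladeA = paste(clades[[1L]], collapse = ","),
      cladeB = paste(unlist(clades[-1L]), collapse = ","),
      ks = ks,
      ageMya = round(divergenceTime(ks, cladeTree@rate,
                                    perLineage = perLineage), 1L),
      stringsAsFactors = FALSE)
  }
  cladeTree@nodes <- do.call(rbind, rows)
  validObject(cladeTree)
  cladeTree
}

#' Write a CladeTree to newick plus a node table TSV
#'
#' @param cladeTree a \linkS4class{CladeTree}.
#' @param newickPath path for the newick tree.
#' @param nodesPath path for the node table TSV (cladeA, cladeB, ks,
#'   ageMya, rate); skipped when \code{NULL} or the node table is empty.
#' @return invisibly, the paths written.
#' @export
writeCladeTree <- function(cladeTree, newickPath, nodesPath = NULL) {
  stopifnot(is(cladeTree, "CladeTree"))
  ape::write.tree(cladeTree@tree, file = newickPath)
  written <- newickPath
  if (!is.null(nodesPath) && nrow(cladeTree@nodes)) {
    tab <- cladeTree@nodes
    tab$rate <- cladeTree@rate
    utils::write.table(tab, nodesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, nodesPath)
  }
  invisible(written)
}
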