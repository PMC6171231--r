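# Internal genetic-code machinery shared by the estimator and the simulator.
# Everything is derived once from the standard genetic code and cached.

.pinediv_cache <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")

.codonTable <- function() {
  if (!is.null(.pinediv_cache$codons)) return(.pinediv_cache$codons)
  g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                   stringsAsFactors = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  tab <- list(codons = codons, aa = aa, sense = aa != "*",
              index = stats::setNames(seq_along(codons), codons))
  .pinediv_cache$codons <- tab
  tab
}

.codonIsStop <- function(codon) {
  tab <- .codonTable()
  !tab$sense[tab$index[codon]]
}

.codonAA <- function(codon) {
  tab <- .codonTable()
  tab$aa[tab$index[codon]]
}

# For each codon: the 9 single-nucleotide neighbours with position, new base
# and mutation class ("syn", "nonsyn", "stop").
.neighbourTable <- function() {
  if (!is.null(.pinediv_cache$neighbours)) return(.pinediv_cache$neighbours)
  tab <- .codonTable()
  out <- vector("list", 64L)
  for (i in seq_len(64L)) {
    codon <- tab$codons[i]
    from <- strsplit(codon, "")[[1]]
    pos <- integer(0); target <- character(0); klass <- character(0)
    for (p in 1:3) {
      for (b in setdiff(.BASES, from[p])) {
        to <- from
        to[p] <- b
        tc <- paste(to, collapse = "")
        cl <- if (.codonIsStop(tc)) "stop"
              else if (.codonAA(tc) == tab$aa[i]) "syn"
              else "nonsyn"
        pos <- c(pos, p); target <- c(target, tc); klass <- c(klass, cl)
      }
    }
    out[[i]] <- data.frame(pos = pos, target = target, klass = klass,
                           stringsAsFactors = FALSE)
  }
  names(out) <- tab$codons
  .pinediv_cache$neighbours <- out
  out
}

# Nei-Gojobori synonymous site count per codon: at each position the fraction
# of non-stop single-nucleotide changes that are synonymous; the position's
# nonsynonymous share is the complement, so every codon contributes exactly
# 3 sites (S + N = 3 per codon).
.synSitesPerCodon <- function() {
  if (!is.null(.pinediv_cache$synSites)) return(.pinediv_cache$synSites)
  tab <- .codonTable()
  nb <- .neighbourTable()
  s <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (!tab$sense[i]) next
    n <- nb[[i]]
    si <- 0
    for (p in 1:3) {
      at <- n[n$pos == p & n$klass != "stop", , drop = FALSE]
      if (nrow(at))
        si <- si + sum(at$klass == "syn") / nrow(at)
    }
    s[i] <- si
  }
  names(s) <- tab$codons
  .pinediv_cache$synSites <- s
  s
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons: enumerate every ordering of the differing positions, walk each
# mutational path, classify each step by the amino acids it joins, and
# average over paths whose intermediates are all sense codons. If every
# minimal path crosses a stop codon, all paths are used.
.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

.pairPathCounts <- function(codonA, codonB) {
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diffPos <- which(a != b)
  if (!length(diffPos)) return(c(sd = 0, nd = 0))
  paths <- .permutations(diffPos)
  sd <- nd <- ok <- numeric(length(paths))
  for (k in seq_along(paths)) {
    cur <- a
    s <- n <- 0
    valid <- TRUE
    for (p in paths[[k]]) {
      nxt <- cur
      nxt[p] <- b[p]
      curC <- paste(cur, collapse = "")
      nxtC <- paste(nxt, collapse = "")
      if (.codonIsStop(nxtC) && nxtC != codonB) valid <- FALSE
      if (.codonAA(curC) == .codonAA(nxtC)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    sd[k] <- s; nd[k] <- n; ok[k] <- valid
  }
  use <- if (any(ok == 1)) ok == 1 else rep(TRUE, length(paths))
  c(sd = mean(sd[use]), nd = mean(nd[use]))
}

# 64 x 64 lookup matrices of averaged path counts (NA where either codon is
# a stop), built lazily.
.pairCountMatrices <- function() {
  if (!is.null(.pinediv_cache$pairCounts)) return(.pinediv_cache$pairCounts)
  tab <- .codonTable()
  sd <- nd <- matrix(NA_real_, 64L, 64L,
                     dimnames = list(tab$codons, tab$codons))
  sense <- which(tab$sense)
  for (i in sense) {
    for (j in sense) {
      if (j < i) next
      counts <- .pairPathCounts(tab$codons[i], tab$codons[j])
      sd[i, j] <- sd[j, i] <- counts["sd"]
      nd[i, j] <- nd[j, i] <- counts["nd"]
    }
  }
  .pinediv_cache$pairCounts <- list(sd = sd, nd = nd)
  .pinediv_cache$pairCounts
}
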