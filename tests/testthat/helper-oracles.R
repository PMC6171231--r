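# Independent oracles used to cross-check the package's estimators.
# These deliberately share no code with the implementation beyond the
# standard genetic code itself.

GC_TABLE <- Biostrings::GENETIC_CODE

aaOf <- function(codon) unname(GC_TABLE[codon])
isStopCodon <- function(codon) aaOf(codon) == "*"

# --- Nei-Gojobori oracle ---------------------------------------------------

# Synonymous site count of one codon, by direct enumeration of the three
# alternative bases at each position; mutations to stop codons are removed
# from the denominator so each position contributes one full site.
oracleSynSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    syn <- 0L
    possible <- 0L
    for (b in setdiff(bases, ch[p])) {
      mut <- ch
      mut[p] <- b
      mutC <- paste(mut, collapse = "")
      if (isStopCodon(mutC)) next
      possible <- possible + 1L
      if (aaOf(mutC) == aaOf(codon)) syn <- syn + 1L
    }
    if (possible > 0L) total <- total + syn / possible
  }
  total
}

# All complete mutational paths from codonA to codonB, one single-base step
# per differing position, built by depth-first recursion (not permutation
# lists). Each path is scored for synonymous / nonsynonymous steps and
# whether it crosses a stop codon.
oraclePaths <- function(codonA, codonB) {
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- list(sd = sd, nd = nd,
                                           blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      curC <- paste(cur, collapse = "")
      nxtC <- paste(nxt, collapse = "")
      stepSyn <- aaOf(curC) == aaOf(nxtC)
      hitStop <- isStopCodon(nxtC) && !identical(nxt, b)
      recurse(nxt, setdiff(remaining, p),
              sd + as.integer(stepSyn), nd + as.integer(!stepSyn),
              blocked || hitStop)
    }
  }
  recurse(a, which(a != b), 0L, 0L, FALSE)
  paths
}

# Averaged difference counts; stop-crossing paths excluded unless every
# path is blocked (then all are used).
oraclePairDiffs <- function(codonA, codonB) {
  if (codonA == codonB) return(c(sd = 0, nd = 0))
  paths <- oraclePaths(codonA, codonB)
  blocked <- vapply(paths, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) paths else paths[!blocked]
  sd <- mean(vapply(use, `[[`, numeric(1), "sd"))
  nd <- mean(vapply(use, `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}

# Full NG86 estimate from two equal-length in-frame sequences.
oracleNG86 <- function(seqA, seqB) {
  codA <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  codB <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  S <- (sum(vapply(codA, oracleSynSites, numeric(1))) +
        sum(vapply(codB, oracleSynSites, numeric(1)))) / 2
  N <- 3 * length(codA) - S
  diffs <- mapply(function(x, y) oraclePairDiffs(x, y), codA, codB)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = Sd / S, pn = Nd / N)
}

# --- SSR oracle ------------------------------------------------------------

# Exhaustive microsatellite scan: every (start, unit) is tested by direct
# substring comparison; a locus is kept when its motif is aperiodic, the
# run cannot be extended left (not even partially) and the complete-copy
# count meets the class minimum.
oracleFindSSRs <- function(seq, minRepeats = c(12L, 6L, 5L, 5L, 4L, 4L)) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in 1:6) {
    for (start in seq_len(max(0L, L - u * minRepeats[u] + 1L))) {
      motif <- ch[start:(start + u - 1L)]
      if (!all(ok[start:(start + u - 1L)])) next
      aperiodic <- TRUE
      for (p in seq_len(u - 1L)) {
        if (u %% p == 0L &&
            all(motif == rep_len(motif[seq_len(p)], u))) {
          aperiodic <- FALSE
          break
        }
      }
      if (!aperiodic) next
      # leftmost: the position one base earlier must break the periodicity
      if (start > 1L && start - 1L + u <= L &&
          ok[start - 1L] && ok[start - 1L + u] &&
          ch[start - 1L] == ch[start - 1L + u]) next
      k <- 1L
      while (start + (k + 1L) * u - 1L <= L) {
        nxt <- ch[(start + k * u):(start + (k + 1L) * u - 1L)]
        if (!all(ok[(start + k * u):(start + (k + 1L) * u - 1L)]) ||
            !all(nxt == motif)) break
        k <- k + 1L
      }
      # partial right extension may add complete-period positions
      extra <- 0L
      repeat {
        pos <- start + (k * u) + extra
        if (pos > L || !ok[pos] || ch[pos] != ch[pos - u]) break
        extra <- extra + 1L
      }
      k <- (k * u + extra) %/% u
      if (k < minRepeats[u]) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = paste(motif, collapse = ""), unit = u, repeats = k,
        start = start, end = start + u * k - 1L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), unit = integer(0),
               repeats = integer(0), start = integer(0), end = integer(0))
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- misc helpers ----------------------------------------------------------

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random in-frame coding sequence without internal stops
randomCoding <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

mutateSeq <- function(seq, positions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  for (p in positions)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
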