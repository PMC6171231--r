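#' Modal synonymous divergence (Ks peak) of a value list
#'
#' Histograms the per-pair Ks values of one species pair over [0, cap) with
#' fixed-width bins and reports the left edge of the modal bin, the
#' convention used for species-pair distances. Ties go to the lower bin;
#' a modal first bin is displayed as e.g. \code{"< 0.01"} and carried as
#' 0.0 internally.
#'
#' @param values numeric vector of Ks values; entries outside [0, cap) (and
#'   NAs, e.g. flagged pairs) are dropped before binning.
#' @param binWidth histogram bin width (default 0.01, the reporting grid).
#' @param cap saturation cap excluding unalignable tails (default 2.0).
#' @return list with \code{peak} (numeric, multiple of \code{binWidth},
#'   2 decimals), \code{nPairs} (values retained) and \code{label}
#'   (display string).
#' @examples
#' ksPeak(rep(0.04, 10))$peak  # 0.04
#' @export
ksPeak <- function(values, binWidth = 0.01, cap = 2.0) {
  stopifnot(binWidth > 0, cap > binWidth)
  values <- values[!is.na(values) & values >= 0 & values < cap]
  if (!length(values))
    stop("no Ks values left after filtering to [0, cap)")
  nBins <- ceiling(cap / binWidth)
  bins <- pmin(floor(values / binWidth) + 1L, nBins)
  counts <- tabulate(bins, nbins = nBins)
  modal <- which.max(counts)  # ties resolve to the lower bin
  peak <- round((modal - 1L) * binWidth, 2L)
  label <- if (modal == 1L) sprintf("< %.2f", binWidth)
           else sprintf("%.2f", peak)
  list(peak = peak, nPairs = length(values), label = label)
}

#' Species-pair Ks-peak matrix from a per-pair rate table
#'
#' Aggregates a Ka/Ks rate table (as from \code{\link{estimatePairRates}})
#' by species pair and computes each pair's Ks peak, returning the
#' symmetric taxon-by-taxon matrix used as the phylogenetic distance
#' matrix. Taxon pairs absent from the table get \code{NA} entries (flagged
#' with a warning).
#'
#' @param rates data.frame with columns taxonA, taxonB, Ks (NAs ignored).
#' @param taxa taxon order for the matrix; default: order of first
#'   appearance in \code{rates}.
#' @param binWidth,cap passed to \code{\link{ksPeak}}.
#' @return a \linkS4class{KsPeakMatrix}.
#' @export
peakMatrix <- function(rates, taxa = NULL, binWidth = 0.01, cap = 2.0) {
  stopifnot(is.data.frame(rates),
            all(c("taxonA", "taxonB", "Ks") %in% names(rates)))
  if (is.null(taxa))
    taxa <- unique(c(rbind(rates$taxonA, rates$taxonB)))
  k <- length(taxa)
  pk <- matrix(NA_real_, k, k)
  np <- matrix(NA_integer_, k, k)
  missing <- character(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      sel <- (rates$taxonA == taxa[i] & rates$taxonB == taxa[j]) |
             (rates$taxonA == taxa[j] & rates$taxonB == taxa[i])
      vals <- rates$Ks[sel]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) {
        missing <- c(missing, paste(taxa[i], taxa[j], sep = " ~ "))
        next
      }
      p <- ksPeak(vals, binWidth = binWidth, cap = cap)
      pk[i, j] <- pk[j, i] <- p$peak
      np[i, j] <- np[j, i] <- p$nPairs
    }
  }
  if (length(missing))
    warning("no Ks values for taxon pair(s): ",
            paste(missing, collapse = ", "))
  new("KsPeakMatrix", taxa = taxa, peaks = pk, nPairs = np)
}

#' Construct a KsPeakMatrix from long-form entries
#'
#' @param taxa ordered taxon names.
#' @param entries data.frame with columns taxonA, taxonB, nPairs, peak (one
#'   row per unordered pair).
#' @return a \linkS4class{KsPeakMatrix}.
#' @export
ksPeakMatrix <- function(taxa, entries) {
  k <- length(taxa)
  pk <- matrix(NA_real_, k, k)
  np <- matrix(NA_integer_, k, k)
  ia <- match(entries$taxonA, taxa)
  ib <- match(entries$taxonB, taxa)
  if (anyNA(ia) || anyNA(ib))
    stop("entries mention taxa not in `taxa`")
  for (r in seq_len(nrow(entries))) {
    pk[ia[r], ib[r]] <- pk[ib[r], ia[r]] <- entries$peak[r]
    np[ia[r], ib[r]] <- np[ib[r], ia[r]] <- as.integer(entries$nPairs[r])
  }
  new("KsPeakMatrix", taxa = taxa, peaks = pk, nPairs = np)
}

#' Read / write a Ks-peak matrix as long-form TSV
#'
#' Columns: taxonA, taxonB, nPairs, peak; taxon order is order of first
#' appearance. The format round-trips losslessly.
#'
#' @param path TSV path.
#' @param x a \linkS4class{KsPeakMatrix}.
#' @return \code{readKsPeakMatrix} returns a \linkS4class{KsPeakMatrix};
#'   \code{writeKsPeakMatrix} returns \code{path} invisibly.
#' @export
readKsPeakMatrix <- function(path) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxa <- unique(c(rbind(entries$taxonA, entries$taxonB)))
  ksPeakMatrix(taxa, entries)
}

#' @rdname readKsPeakMatrix
#' @export
writeKsPeakMatrix <- function(x, path) {
  stopifnot(is(x, "KsPeakMatrix"))
  k <- length(x@taxa)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (is.na(x@peaks[i, j]) && is.na(x@nPairs[i, j])) next
      rows[[length(rows) + 1L]] <- data.frame(
        taxonA = x@taxa[i], taxonB = x@taxa[j],
        nPairs = x@nPairs[i, j], peak = x@peaks[i, j])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The published 13-conifer Ks-peak matrix
#'
#' The orthologue counts and Ks peaks for all pairs of 12 Pinus species and
#' Picea glauca, packaged as a fixture: the distance matrix behind the
#' genus phylogeny and its clock dating.
#'
#' @return a \linkS4class{KsPeakMatrix} over the 13 taxa in published
#'   order (P_kesiya first, Picea_glauca last).
#' @examples
#' m <- coniferKsPeaks()
#' peaks(m)["P_kesiya", "P_taeda"]  # 0.04
#' @export
coniferKsPeaks <- function() {
  path <- system.file("extdata", "conifer_ks_peaks.tsv", package = "pinediv",
                      mustWork = TRUE)
  readKsPeakMatrix(path)
}
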