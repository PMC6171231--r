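#' Screen orthologue pairs for positive selection (Ka/Ks > 1)
#'
#' Flags pairs whose Ka/Ks ratio strictly exceeds 1, including the
#' convention that Ks = 0 with Ka > 0 counts as positive selection (the
#' ratio is then reported as \code{"> 1"} rather than a number). Pairs with
#' Ka = Ks = 0 are never selected; omega = 1 exactly is not selected. This
#' is a raw-ratio screen with no significance test, mirroring how such
#' candidate lists are commonly assembled.
#'
#' @param rates data.frame from \code{\link{estimatePairRates}} (columns
#'   Ka, Ks, omega, flag at minimum).
#' @param keepAll logical; when TRUE, return every input row with a
#'   \code{selected} column instead of only the selected ones.
#' @return the input rows (selected only, unless \code{keepAll}) with
#'   columns \code{selected} (logical) and \code{omegaLabel} (formatted
#'   ratio, \code{"> 1"} for the Ks = 0 convention).
#' @seealso \code{\link{selectionCounts}}, \code{\link{annotateCandidates}}
#' @export
screenPositive <- function(rates, keepAll = FALSE) {
  stopifnot(is.data.frame(rates),
            all(c("Ka", "Ks", "omega", "flag") %in% names(rates)))
  finite <- !is.na(rates$omega)
  gtOne <- rates$flag == "> 1" |
    (!is.na(rates$Ks) & !is.na(rates$Ka) & rates$Ks == 0 & rates$Ka > 0)
  selected <- (finite & rates$omega > 1) | gtOne
  selected[is.na(selected)] <- FALSE
  out <- rates
  out$selected <- selected
  out$omegaLabel <- ifelse(gtOne, "> 1",
                           ifelse(finite, sprintf("%.4f", rates$omega), ""))
  if (keepAll) out else out[out$selected, , drop = FALSE]
}

#' Positive-selection counts per species pair
#'
#' @param rates data.frame from \code{\link{estimatePairRates}} with
#'   \code{taxonA}/\code{taxonB} columns.
#' @return data.frame: taxonA, taxonB, nPairs (rates computed), nSelected.
#' @export
selectionCounts <- function(rates) {
  calls <- screenPositive(rates, keepAll = TRUE)
  key <- paste(calls$taxonA, calls$taxonB, sep = "\t")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    parts <- strsplit(k, "\t")[[1]]
    data.frame(taxonA = parts[1L], taxonB = parts[2L],
               nPairs = sum(sel), nSelected = sum(calls$selected[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Join functional annotations onto selection calls
#'
#' Left-joins a precomputed annotation map (transcript id to accession and
#' functional label) onto either member of each call. Calls with no mapped
#' member keep empty labels; when both members map to conflicting labels,
#' both are retained (semicolon-separated) and the row is flagged.
#'
#' @param calls data.frame from \code{\link{screenPositive}} (columns idA,
#'   idB).
#' @param map data.frame with columns \code{id}, \code{accession},
#'   \code{label}; ids must be unique.
#' @return \code{calls} with columns \code{annotationAccession},
#'   \code{annotationLabel}, \code{annotationConflict}.
#' @export
annotateCandidates <- function(calls, map) {
  stopifnot(is.data.frame(calls), is.data.frame(map))
  if (nrow(map)) {
    stopifnot(all(c("id", "accession", "label") %in% names(map)))
    if (anyDuplicated(map$id))
      stop("duplicate ids in annotation map")
  }
  n <- nrow(calls)
  acc <- lab <- character(n)
  conflict <- logical(n)
  if (nrow(map)) {
    mA <- match(calls$idA, map$id)
    mB <- match(calls$idB, map$id)
    for (i in seq_len(n)) {
      hits <- stats::na.omit(c(mA[i], mB[i]))
      if (!length(hits)) next
      labs <- unique(map$label[hits])
      accs <- unique(map$accession[hits])
      lab[i] <- paste(labs, collapse = ";")
      acc[i] <- paste(accs, collapse = ";")
      conflict[i] <- length(labs) > 1L
    }
  }
  calls$annotationAccession <- acc
  calls$annotationLabel <- lab
  calls$annotationConflict <- conflict
  calls
}
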