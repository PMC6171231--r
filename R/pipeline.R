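#' Construct a PipelineConfig
#'
#' @param fastaFiles named character vector, one FASTA path per taxon.
#' @param outDir output directory for stage artifacts.
#' @param outgroup outgroup taxon for rooting (NA to skip the tree stage).
#' @param redundancyThreshold within-taxon collapse threshold (strict
#'   \code{>}, default 0.95).
#' @param orthologyThreshold cross-taxon pairing threshold (\code{>=},
#'   default 0.90).
#' @param binWidth,ksCap Ks histogram bin width and saturation cap.
#' @param clockRate synonymous substitutions/site/year (default 0.68e-9).
#' @param minCodons minimum ORF length in codons (default 50).
#' @param seed integer seed recorded in the manifest.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(fastaFiles, outDir = ".", outgroup = NA,
                           redundancyThreshold = 0.95,
                           orthologyThreshold = 0.90,
                           binWidth = 0.01, ksCap = 2.0,
                           clockRate = 0.68e-9, minCodons = 50L,
                           seed = 1L) {
  new("PipelineConfig", fastaFiles = fastaFiles,
      redundancyThreshold = redundancyThreshold,
      orthologyThreshold = orthologyThreshold,
      binWidth = binWidth, ksCap = ksCap, clockRate = clockRate,
      minCodons = as.integer(minCodons),
      outgroup = as.character(outgroup), outDir = outDir,
      seed = as.integer(seed))
}

.stageLog <- function(...) message("[pinediv] ", ...)

#' Run the end-to-end comparative-transcriptomics pipeline
#'
#' Executes the full chain: read per-taxon FASTA, collapse redundant
#' transcripts, pair orthologues for every taxon pair, estimate Ka/Ks,
#' aggregate Ks peaks into the species-pair distance matrix, build and root
#' the neighbour-joining tree, date its splits with the molecular clock,
#' and screen for positive selection. Every stage writes a plain TSV (or
#' newick) artifact into \code{outDir} plus a flat-key-value manifest, so a
#' rerun with the same config reproduces identical outputs.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return invisibly, a list: \code{sets} (collapsed transcript sets),
#'   \code{pairs}, \code{rates}, \code{peaks} (a
#'   \linkS4class{KsPeakMatrix}), \code{tree} (a \linkS4class{CladeTree}
#'   or NULL), \code{selection}, \code{files}.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  if (!length(config@fastaFiles))
    stop("pipeline: no input FASTA files configured")
  missing <- config@fastaFiles[!file.exists(config@fastaFiles)]
  if (length(missing))
    stop("pipeline: input not readable: ", paste(missing, collapse = ", "))
  set.seed(config@seed)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  taxa <- names(config@fastaFiles)

  sets <- lapply(taxa, function(tx) {
    s <- readTranscripts(config@fastaFiles[[tx]], taxon = tx)
    collapsed <- collapseRedundant(s, threshold = config@redundancyThreshold)
    .stageLog("collapse ", tx, ": ", length(s), " -> ", length(collapsed),
              " transcripts")
    collapsed
  })
  names(sets) <- taxa

  allPairs <- list()
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j <= i) next
      p <- pairOrthologues(sets[[i]], sets[[j]],
                           threshold = config@orthologyThreshold)
      .stageLog("pair ", taxa[i], " ~ ", taxa[j], ": ", nrow(p), " pairs")
      allPairs[[length(allPairs) + 1L]] <- p
    }
  }
  pairs <- do.call(rbind, allPairs)
  files["pairs"] <- file.path(config@outDir, "orthologue_pairs.tsv")
  writePairsTsv(pairs, files[["pairs"]])

  rates <- estimatePairRates(pairs, sets, minCodons = config@minCodons)
  nSat <- sum(rates$flag == "saturated")
  .stageLog("rates: ", nrow(rates), " pairs, ", nSat, " saturated dropped, ",
            sum(rates$flag %in% c("noncoding", "unalignable")),
            " unusable")
  files["rates"] <- file.path(config@outDir, "kaks_rates.tsv")
  utils::write.table(rates, files[["rates"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pm <- peakMatrix(rates, taxa = taxa, binWidth = config@binWidth,
                   cap = config@ksCap)
  files["peaks"] <- file.path(config@outDir, "ks_peaks.tsv")
  writeKsPeakMatrix(pm, files[["peaks"]])

  tree <- NULL
  if (!is.na(config@outgroup) && length(taxa) >= 3L) {
    nj <- njTree(pm)
    tree <- rootWithOutgroup(nj, config@outgroup, rate = config@clockRate)
    tree <- cladeAges(tree, pm)
    files["tree"] <- file.path(config@outDir, "nj_tree.nwk")
    files["nodes"] <- file.path(config@outDir, "node_ages.tsv")
    writeCladeTree(tree, files[["tree"]], files[["nodes"]])
    .stageLog("tree: ", length(taxa), " taxa rooted on ", config@outgroup)
  }

  selection <- screenPositive(rates)
  files["selection"] <- file.path(config@outDir, "positive_selection.tsv")
  utils::write.table(selection, files[["selection"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["selectionCounts"] <- file.path(config@outDir,
                                        "selection_counts.tsv")
  utils::write.table(selectionCounts(rates), files[["selectionCounts"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .stageLog("selection: ", nrow(selection), " candidate pairs")

  manifest <- c(
    package = "pinediv",
    version = as.character(utils::packageVersion("pinediv")),
    seed = config@seed,
    taxa = paste(taxa, collapse = ","),
    redundancyThreshold = config@redundancyThreshold,
    orthologyThreshold = config@orthologyThreshold,
    binWidth = config@binWidth, ksCap = config@ksCap,
    clockRate = config@clockRate, minCodons = config@minCodons,
    outgroup = config@outgroup,
    nPairs = nrow(pairs), nRates = nrow(rates),
    nSaturated = nSat, nSelected = nrow(selection))
  files["manifest"] <- file.path(config@outDir, "manifest.tsv")
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             files[["manifest"]])

  invisible(list(sets = sets, pairs = pairs, rates = rates, peaks = pm,
                 tree = tree, selection = selection, files = files))
}
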