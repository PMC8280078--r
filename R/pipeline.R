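#' Run the full promoter-tile differential-methylation pipeline
#'
#' Executes, in order: read + merge coverage files, per-sample depth
#' filter, blacklist exclusion, median coverage normalisation,
#' sliding-window tiling, promoter restriction, one DM contrast per
#' configured (control, experimental) pair, reversal classification of
#' the configured injury/treatment contrast pair, gene-level
#' aggregation, and gene-set over-representation. All result tables are
#' written as TSV (plus a JSON reversal summary and a run manifest) and
#' returned invisibly as a bundle.
#'
#' @param config a named list, or the path of a YAML file holding one,
#'   with entries:
#'   \describe{
#'     \item{samples}{data frame (or file path of a TSV) with columns
#'       `file`, `sample`, `group`.}
#'     \item{genes}{path of a BED6 gene table (TSS = strand-aware start).}
#'     \item{blacklist}{optional path of a BED file of excluded regions.}
#'     \item{geneSets}{optional named vector of gene-list file paths.}
#'     \item{outDir}{output directory.}
#'     \item{tiling}{optional list of [tilingParams()] overrides.}
#'     \item{dm}{optional list of [dmParams()] overrides.}
#'     \item{contrasts}{named list of `c(control=, experimental=)` pairs;
#'       the first two (by default named `injury` and `treatment`) feed
#'       the reversal step.}
#'   }
#' @param baseDir directory against which relative paths in `config` are
#'   resolved (default: the config file's directory, or `"."`).
#' @return Invisibly, a list with `tiles`, `contrasts`, `reversal`,
#'   `geneSummary`, `enrichment` and `manifest`.
#' @export
runPipeline <- function(config, baseDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (is.null(baseDir)) baseDir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(baseDir)) baseDir <- "."
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(baseDir, p))

  ## ---- validate before any computation
  samples <- config$samples
  if (is.character(samples)) samples <- readResultsTsv(resolve(samples))
  samples <- as.data.frame(samples)
  if (!all(c("file", "sample", "group") %in% names(samples)))
    .stopf("config$samples needs columns file, sample, group")
  if (anyDuplicated(samples$sample))
    .stopf("duplicated sample ids in config$samples")
  tp <- do.call(tilingParams, as.list(config$tiling))
  dp <- do.call(dmParams, as.list(config$dm))
  contrasts <- config$contrasts
  if (is.null(contrasts))
    contrasts <- list(
      injury = c(control = "Sham-Vehicle", experimental = "SNI-Vehicle"),
      treatment = c(control = "SNI-Vehicle", experimental = "SNI-SAM"))
  for (nm in names(contrasts)) {
    cc <- unlist(contrasts[[nm]])
    missing <- setdiff(cc[c("control", "experimental")], samples$group)
    if (length(missing))
      .stopf("contrast '%s' references undefined group(s): %s",
             nm, paste(missing, collapse = ", "))
  }
  if (is.null(config$outDir)) .stopf("config$outDir is required")
  outDir <- resolve(config$outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = as.character(packageVersion("methrev")),
                   config = config, counts = list())
  note <- function(stage, n) {
    manifest$counts[[stage]] <<- n
    message(sprintf("[%s] %d records", stage, n))
  }

  ## ---- stages
  mc <- readBismarkCoverage(resolve(samples$file),
                            sampleIds = samples$sample,
                            groups = samples$group)
  note("cpgs_raw", nrow(mc))
  mc <- filterByDepth(mc, tp$minDepth)
  note("cpgs_depth_filtered", nrow(mc))
  if (!is.null(config$blacklist)) {
    mc <- filterBlacklist(mc, readBed(resolve(config$blacklist)))
  }
  note("cpgs_blacklist_filtered", nrow(mc))
  mc <- normalizeCoverage(mc)
  tiles <- tileCounts(mc, tp)
  note("tiles", nrow(tiles))
  genes <- readGeneTable(resolve(config$genes))
  tiles <- restrictToPromoters(tiles, genes, tp)
  note("promoter_tiles", nrow(tiles))
  writeResultsTsv(tilesToTable(tiles), file.path(outDir, "tiles.tsv"))

  results <- list()
  for (nm in names(contrasts)) {
    cc <- unlist(contrasts[[nm]])
    results[[nm]] <- calculateDiffMeth(tiles, cc[["control"]],
                                       cc[["experimental"]], dp)
    note(paste0("dm_", nm),
         sum(results[[nm]]$status != "not_significant"))
    writeResultsTsv(results[[nm]],
                    file.path(outDir, paste0("contrast_", nm, ".tsv")))
  }

  rev <- NULL; geneSummary <- NULL
  if (length(results) >= 2L) {
    pairNames <- names(results)[1:2]
    pairs <- overlapContrasts(results[[pairNames[1]]], results[[pairNames[2]]])
    rev <- classifyReversal(pairs)
    note("reversal_pairs", nrow(rev$records))
    writeResultsTsv(rev$records, file.path(outDir, "reversal.tsv"))
    jsonlite::write_json(rev$summary, file.path(outDir,
                                                "reversal_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (nrow(rev$records)) {
      geneSummary <- summarizeGenes(rev$records)
      writeResultsTsv(geneSummary, file.path(outDir, "gene_summary.tsv"))
    }
  }

  enr <- NULL
  if (!is.null(config$geneSets)) {
    sets <- lapply(resolve(unlist(config$geneSets)), readGeneSet)
    names(sets) <- names(config$geneSets)
    population <- unique(unlist(strsplit(
      tilesToTable(tiles)$genes, ",", fixed = TRUE)))
    population <- population[nzchar(population)]
    hitLists <- lapply(results, function(r) unique(unlist(
      strsplit(r$genes[r$status != "not_significant"], ",", fixed = TRUE))))
    if (!is.null(rev)) {
      rr <- rev$records
      hitLists$reversal <- unique(unlist(strsplit(
        rr$genes[grepl("^reversal_of", rr$reversal_class)], ",",
        fixed = TRUE)))
    }
    enr <- do.call(rbind, lapply(names(hitLists), function(h) {
      e <- oraMulti(population, sets, intersect(hitLists[[h]], population))
      cbind(hits = h, e)
    }))
    writeResultsTsv(enr, file.path(outDir, "enrichment.tsv"))
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(tiles = tiles, contrasts = results, reversal = rev,
                 geneSummary = geneSummary, enrichment = enr,
                 manifest = manifest))
}

#' Volcano-plot table for one contrast
#'
#' Emits, per tile, the methylation difference against
#' `-log10(q_value)` with the usual five-way colouring: DM hyper / hypo,
#' non-significant tiles with large differences, significant tiles with
#' small differences, and the rest.
#'
#' @param contrast a contrast data frame from [calculateDiffMeth()].
#' @param params the [dmParams] used for calling.
#' @param maxNegLog10 cap for `-log10(q)` when q underflows to 0
#'   (default 350).
#' @return A data frame with `chrom`, `start`, `end`, `meth_diff`,
#'   `neg_log10_q` and `category`.
#' @export
makeVolcanoTable <- function(contrast, params = dmParams(),
                             maxNegLog10 = 350) {
  stopifnot(all(c("meth_diff", "q_value", "status") %in% names(contrast)))
  sig <- contrast$q_value < params$qThreshold
  big <- abs(contrast$meth_diff) > params$diffThreshold
  category <- ifelse(contrast$status == "hyper", "hyper",
              ifelse(contrast$status == "hypo", "hypo",
              ifelse(!sig & big, "nonsignificant_large_diff",
              ifelse(sig & !big, "significant_small_diff",
                     "not_different"))))
  data.frame(chrom = contrast$chrom, start = contrast$start,
             end = contrast$end, meth_diff = contrast$meth_diff,
             neg_log10_q = pmin(-log10(pmax(contrast$q_value,
                                            10^(-maxNegLog10))),
                                maxNegLog10),
             category = category)
}
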