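#' @rdname filterByDepth
#' @export
setMethod("filterByDepth", "MethylCounts", function(x, minDepth = 10L) {
  keep <- rowSums(totalCounts(x) >= minDepth) == ncol(x)
  if (!any(keep))
    .warnf("no site passes the depth filter (minDepth = %d)", minDepth)
  x[keep, ]
})

#' @rdname filterBlacklist
#' @export
setMethod("filterBlacklist", "MethylCounts", function(x, blacklist) {
  if (!is(blacklist, "GRanges"))
    .stopf("'blacklist' must be a GRanges")
  keep <- !IRanges::overlapsAny(rowRanges(x), blacklist, ignore.strand = TRUE)
  x[keep, ]
})

#' @rdname normalizeCoverage
#' @details
#' For each sample the median coverage over retained sites is computed;
#' the target is the median of those per-sample medians, and each
#' sample's counts are multiplied by target/median (rounded half away
#' from zero, floored at 1 read where coverage was nonzero). Methylated
#' counts are rescaled so each site's methylation proportion is
#' preserved, then clamped to the new coverage.
#' @export
setMethod("normalizeCoverage", "MethylCounts", function(x) {
  total <- totalCounts(x)
  meth <- methCounts(x)
  med <- apply(total, 2L, median)
  if (any(med == 0))
    .stopf("sample(s) with zero median coverage: %s",
           paste(colnames(x)[med == 0], collapse = ", "))
  target <- median(med)
  sf <- target / med
  prop <- ifelse(total > 0L, meth / total, 0)
  newTotal <- sweep(total, 2L, sf, `*`)
  newTotal <- roundHalfUp(newTotal)
  newTotal[total > 0L] <- pmax(1, newTotal[total > 0L])
  newMeth <- pmin(roundHalfUp(prop * newTotal), newTotal)
  out <- MethylCounts(newMeth, newTotal, rowRanges(x),
                      group = sampleGroups(x), sampleIds = colnames(x))
  metadata(out) <- metadata(x)
  metadata(out)$scaleFactors <- setNames(sf, colnames(x))
  out
})

#' @rdname tileCounts
#' @details
#' Candidate windows of width `tileSize` start at multiples of
#' `stepSize` from position 0 of each chromosome; a window becomes a
#' tile when it contains at least `minCpgs` retained CpGs, and
#' per-sample methylated/total counts are the sums over member CpGs.
#' With the 250/125 defaults every CpG feeds up to two tiles (exactly
#' one within `tileSize - stepSize` of the chromosome start).
#' @export
setMethod("tileCounts", "MethylCounts", function(x, params = tilingParams()) {
  stopifnot(inherits(params, "tilingParams"))
  tile <- params$tileSize; step <- params$stepSize
  p0 <- start(x) - 1L                       # 0-based site position
  chr <- as.character(seqnames(x))
  kmax <- p0 %/% step
  kmin <- pmax(0L, (p0 - tile) %/% step + 1L)
  nwin <- kmax - kmin + 1L
  row <- rep(seq_along(p0), nwin)
  k <- rep(kmin, nwin) + sequence(nwin) - 1L
  key <- paste(chr[row], k)
  methSum <- rowsum(methCounts(x)[row, , drop = FALSE], key)
  totalSum <- rowsum(totalCounts(x)[row, , drop = FALSE], key)
  nCpgs <- as.integer(rowsum(rep(1L, length(row)), key))
  keys <- rownames(methSum)
  sp <- regmatches(keys, regexpr(" \\d+$", keys))
  tChr <- substr(keys, 1L, nchar(keys) - nchar(sp))
  tK <- as.integer(sp)
  keep <- nCpgs >= params$minCpgs
  o <- order(tChr[keep], tK[keep])
  idx <- which(keep)[o]
  gr <- GRanges(tChr[idx],
                IRanges(start = tK[idx] * step + 1L, width = tile))
  out <- MethylCounts(methSum[idx, , drop = FALSE],
                      totalSum[idx, , drop = FALSE],
                      gr, group = sampleGroups(x), sampleIds = colnames(x))
  rowData(out)$n_cpgs <- nCpgs[idx]
  metadata(out) <- metadata(x)
  metadata(out)$tilingParams <- params
  out
})

#' Restrict tiles to promoter regions and annotate genes
#'
#' The promoter of a gene is the strand-aware window from
#' `promoterUpstream` bp upstream to `promoterDownstream` bp downstream
#' of its transcription start site. A tile is retained when it overlaps
#' at least one promoter and is annotated with every overlapping gene's
#' symbol.
#'
#' @param tiles a tile-level [MethylCounts-class] (from [tileCounts()]).
#' @param genes a stranded, named `GRanges` of genes (see
#'   [readGeneTable()]).
#' @param params a [tilingParams] list supplying the promoter extent.
#' @return The retained tiles with a `genes` `CharacterList` column in
#'   `rowData`.
#' @export
restrictToPromoters <- function(tiles, genes, params = tilingParams()) {
  stopifnot(is(tiles, "MethylCounts"), inherits(params, "tilingParams"))
  if (!is(genes, "GRanges") || any(strand(genes) == "*"))
    .stopf("'genes' must be a GRanges with '+'/'-' strand for every gene")
  if (is.null(names(genes)))
    names(genes) <- if (!is.null(genes$name)) genes$name else
      paste0("gene", seq_along(genes))
  # downstream counts the TSS base itself, hence + 1 for "N bp past TSS"
  prom <- suppressWarnings(
    promoters(genes, upstream = params$promoterUpstream,
              downstream = params$promoterDownstream + 1L))
  hits <- findOverlaps(rowRanges(tiles), prom, ignore.strand = TRUE)
  keep <- sort(unique(queryHits(hits)))
  sym <- unname(split(names(genes)[subjectHits(hits)],
                      factor(queryHits(hits), levels = keep)))
  out <- tiles[keep, ]
  rowData(out)$genes <- CharacterList(lapply(sym, unique))
  out
}

#' Export a tile-level MethylCounts as a flat table
#'
#' @param tiles a tile-level [MethylCounts-class].
#' @return A data frame with `chrom`, `start`, `end`, `n_cpgs`, `genes`
#'   (comma-joined), then `meth.<sample>` / `total.<sample>` columns.
#' @export
tilesToTable <- function(tiles) {
  meth <- methCounts(tiles); total <- totalCounts(tiles)
  colnames(meth) <- paste0("meth.", colnames(meth))
  colnames(total) <- paste0("total.", colnames(total))
  genes <- rowData(tiles)$genes
  df <- data.frame(chrom = as.character(seqnames(tiles)),
                   start = start(tiles), end = end(tiles),
                   n_cpgs = rowData(tiles)$n_cpgs,
                   genes = if (is.null(genes)) "" else
                     vapply(genes, paste, "", collapse = ","))
  cbind(df, meth, total)
}
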