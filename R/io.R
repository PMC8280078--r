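#' Read one Bismark coverage file
#'
#' The Bismark coverage dialect is a 6-column TSV: chromosome, 1-based
#' start, 1-based end, methylation percentage, methylated count,
#' unmethylated count. The percentage column is ignored and recomputed
#' from the counts; a mismatch beyond 0.5 points is reported as a warning
#' because the counts take precedence.
#'
#' @param path path to a coverage file.
#' @param sampleId sample identifier (default: file name without
#'   extension).
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `meth`,
#'   `cov`. Zero-coverage records are kept (the depth filter removes them
#'   downstream).
#' @seealso [readBismarkCoverage()] to read and merge a whole experiment.
#' @export
readCoverageFile <- function(path,
                             sampleId = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    .warnf("coverage file '%s' is empty", path)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), cov = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    .stopf("'%s': malformed line(s) (expected 6 tab-separated columns): %s",
           path, paste(utils::head(bad, 5L), collapse = ", "))
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2L]))
  pct <- suppressWarnings(as.numeric(m[, 4L]))
  meth <- suppressWarnings(as.numeric(m[, 5L]))
  unmeth <- suppressWarnings(as.numeric(m[, 6L]))
  nonnum <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(nonnum))
    .stopf("'%s': non-numeric position or count on line(s): %s",
           path, paste(utils::head(nonnum, 5L), collapse = ", "))
  if (any(meth < 0) || any(unmeth < 0))
    .stopf("'%s': negative counts", path)
  cov <- meth + unmeth
  chk <- cov > 0 & !is.na(pct)
  off <- which(chk & abs(pct - 100 * meth / cov) > 0.5)
  if (length(off))
    .warnf("'%s': methylation %% column disagrees with counts on %d line(s); counts used",
           path, length(off))
  data.frame(chrom = m[, 1L], pos = as.integer(pos),
             meth = as.integer(meth), cov = as.integer(cov))
}

#' Read and merge Bismark coverage files into a MethylCounts object
#'
#' Positions are taken as given (strand collapsing, if any, is assumed to
#' have happened upstream). The merged object covers the union of
#' positions across samples; a sample lacking a site gets coverage 0
#' there, which the depth filter later removes.
#'
#' @param files character vector of coverage file paths.
#' @param sampleIds sample identifiers, one per file.
#' @param groups group labels, one per file.
#' @return A [MethylCounts-class] with one row per distinct CpG position.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines("chr1\t101\t101\t80\t8\t2", file.path(dir, "a.cov"))
#' writeLines("chr1\t201\t201\t0\t0\t10", file.path(dir, "b.cov"))
#' mc <- readBismarkCoverage(file.path(dir, c("a.cov", "b.cov")),
#'                           sampleIds = c("a", "b"),
#'                           groups = c("ctl", "exp"))
#' totalCounts(mc)
#' @export
readBismarkCoverage <- function(files,
                                sampleIds = tools::file_path_sans_ext(basename(files)),
                                groups) {
  if (length(files) < 2L)
    .stopf("need at least 2 samples to build an experiment")
  if (length(sampleIds) != length(files) || anyDuplicated(sampleIds))
    .stopf("'sampleIds' must be unique, one per file")
  if (length(groups) != length(files))
    .stopf("'groups' must have one label per file")
  recs <- Map(readCoverageFile, files, sampleIds)
  names(recs) <- sampleIds
  mergeSamples(recs, groups)
}

#' Merge per-sample CpG records into one MethylCounts
#'
#' @param records named list (one element per sample) of data frames as
#'   returned by [readCoverageFile()].
#' @param groups group labels, one per sample.
#' @return A [MethylCounts-class] over the union of positions, rows sorted
#'   by chromosome then position.
#' @export
mergeSamples <- function(records, groups) {
  if (length(records) < 2L)
    .stopf("need at least 2 samples")
  sampleIds <- names(records)
  for (s in sampleIds) {
    key <- paste(records[[s]]$chrom, records[[s]]$pos)
    if (anyDuplicated(key))
      .stopf("sample '%s' has duplicated positions", s)
  }
  allChrom <- unlist(lapply(records, `[[`, "chrom"), use.names = FALSE)
  allPos <- unlist(lapply(records, `[[`, "pos"), use.names = FALSE)
  key <- paste(allChrom, allPos)
  keep <- !duplicated(key)
  uChrom <- allChrom[keep]
  uPos <- allPos[keep]
  o <- order(uChrom, uPos)
  uChrom <- uChrom[o]; uPos <- uPos[o]
  uKey <- paste(uChrom, uPos)
  n <- length(uKey)
  meth <- matrix(0L, n, length(records))
  total <- matrix(0L, n, length(records))
  for (j in seq_along(records)) {
    idx <- match(paste(records[[j]]$chrom, records[[j]]$pos), uKey)
    meth[idx, j] <- records[[j]]$meth
    total[idx, j] <- records[[j]]$cov
  }
  gr <- GRanges(uChrom, IRanges(uPos, width = 1L))
  MethylCounts(meth, total, gr, group = groups, sampleIds = sampleIds)
}

#' Write a MethylCounts object as Bismark coverage files
#'
#' One file per sample; rows with zero coverage in that sample are
#' omitted, matching what a methylation caller would emit.
#'
#' @param x a [MethylCounts-class] object (CpG level).
#' @param dir output directory (created if needed).
#' @param suffix file suffix (default `".cov"`).
#' @return Invisibly, the vector of file paths written.
#' @export
writeBismarkCoverage <- function(x, dir, suffix = ".cov") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- methCounts(x); total <- totalCounts(x)
  chrom <- as.character(seqnames(x)); pos <- start(x)
  paths <- file.path(dir, paste0(colnames(x), suffix))
  for (j in seq_len(ncol(x))) {
    keep <- total[, j] > 0L
    mj <- meth[keep, j]; tj <- total[keep, j]
    df <- data.frame(chrom[keep], pos[keep], pos[keep],
                     sprintf("%.6g", 100 * mj / tj), mj, tj - mj)
    write.table(df, paths[j], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read a BED file of genomic intervals
#'
#' Thin validating wrapper around `rtracklayer::import`; BED is 0-based
#' half-open on disk and arrives as a 1-based closed `GRanges`.
#'
#' @param path path to a BED3+ file.
#' @return A `GRanges`.
#' @export
readBed <- function(path) {
  raw <- read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(raw) >= 3L) {
    bad <- which(!(as.numeric(raw[[2L]]) < as.numeric(raw[[3L]])))
    if (length(bad))
      .stopf("'%s': interval with start >= end on line(s): %s",
             path, paste(utils::head(bad, 5L), collapse = ", "))
  }
  rtracklayer::import(path, format = "BED")
}

#' Read a stranded gene table (BED6)
#'
#' Column 4 is the gene symbol and column 6 the strand; every gene must
#' be stranded because the promoter window is strand-aware.
#'
#' @param path path to a 6-column BED file.
#' @return A named, stranded `GRanges` (names = gene symbols).
#' @export
readGeneTable <- function(path) {
  gr <- readBed(path)
  if (is.null(gr$name) || !length(gr$name))
    .stopf("'%s': gene table needs a name column (BED6)", path)
  if (any(strand(gr) == "*"))
    .stopf("'%s': every gene needs a strand ('+' or '-')", path)
  names(gr) <- gr$name
  gr
}

#' Read a gene set (one symbol per line)
#'
#' Symbols are case-preserved, trimmed, and de-duplicated.
#'
#' @param path path to a plain-text gene list.
#' @return Character vector of unique gene symbols.
#' @export
readGeneSet <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Write / read a results table as TSV
#'
#' Writers emit a header and a stable column order so that tables
#' round-trip exactly.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `writeResultsTsv` invisibly returns `path`; `readResultsTsv`
#'   returns the data frame.
#' @export
writeResultsTsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
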