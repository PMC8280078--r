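#' MethylCounts: per-sample bisulfite counts over genomic positions
#'
#' `MethylCounts` extends `RangedSummarizedExperiment` with two mandatory
#' assays, `meth` (methylated read counts) and `total` (total coverage),
#' holding one row per CpG site or per tile and one column per sample.
#' Group membership lives in `colData(x)$group`; tile-level objects carry
#' `n_cpgs` (and, after promoter annotation, `genes`) in `rowData`.
#'
#' @slot ... see `RangedSummarizedExperiment`.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<- colData colData<- rowRanges rowRanges<-
#' @importFrom S4Vectors metadata metadata<- DataFrame queryHits subjectHits
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#'   findOverlaps promoters resize
#' @importFrom IRanges IRanges CharacterList
#' @export
setClass("MethylCounts", contains = "RangedSummarizedExperiment")

setValidity("MethylCounts", function(object) {
  an <- assayNames(object)
  if (!all(c("meth", "total") %in% an))
    return("assays 'meth' and 'total' are both required")
  m <- assay(object, "meth")
  t <- assay(object, "total")
  if (any(m < 0) || any(t < 0))
    return("counts must be non-negative")
  if (any(m > t))
    return("methylated count exceeds total coverage")
  if (!"group" %in% colnames(colData(object)))
    return("colData must contain a 'group' column")
  TRUE
})

#' Construct a MethylCounts object
#'
#' @param meth,total integer matrices (rows = sites/tiles, columns =
#'   samples) of methylated and total read counts.
#' @param rowRanges a `GRanges` with one range per row.
#' @param group character vector of group labels, one per sample.
#' @param sampleIds optional sample identifiers (default: column names of
#'   `meth`).
#' @param ... further arguments passed to
#'   [SummarizedExperiment::SummarizedExperiment()].
#' @return A [MethylCounts-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 201), width = 1))
#' mc <- MethylCounts(meth = matrix(0:3, 2), total = matrix(10L, 2, 2),
#'                    rowRanges = gr, group = c("A", "B"))
#' mc
#' @export
MethylCounts <- function(meth, total, rowRanges, group,
                         sampleIds = colnames(meth), ...) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(meth)))
  colnames(meth) <- colnames(total) <- sampleIds
  se <- SummarizedExperiment(
    assays = list(meth = meth, total = total),
    rowRanges = rowRanges,
    colData = DataFrame(group = as.character(group), row.names = sampleIds),
    ...)
  new("MethylCounts", se)
}

#' @rdname methCounts
#' @export
setMethod("methCounts", "MethylCounts", function(x) assay(x, "meth"))

#' @rdname totalCounts
#' @export
setMethod("totalCounts", "MethylCounts", function(x) assay(x, "total"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "MethylCounts",
          function(x) setNames(colData(x)$group, colnames(x)))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups<-", "MethylCounts", function(x, value) {
  if (length(value) != ncol(x))
    .stopf("need one group label per sample (%d)", ncol(x))
  colData(x)$group <- as.character(value)
  x
})

#' @rdname methLevels
#' @export
setMethod("methLevels", "MethylCounts",
          function(x) methCounts(x) / totalCounts(x))

#' @describeIn MethylCounts compact display with per-group sample tallies.
#' @param object a `MethylCounts` object.
#' @export
setMethod("show", "MethylCounts", function(object) {
  kind <- if ("n_cpgs" %in% colnames(rowData(object))) "tiles" else "CpG sites"
  cat(sprintf("MethylCounts: %d %s x %d samples\n",
              nrow(object), kind, ncol(object)))
  grp <- table(colData(object)$group)
  cat("groups:",
      paste(sprintf("%s (n=%d)", names(grp), as.integer(grp)), collapse = ", "),
      "\n")
  sf <- metadata(object)$scaleFactors
  if (!is.null(sf))
    cat("coverage scale factors:",
        paste(sprintf("%s=%.3g", names(sf), sf), collapse = ", "), "\n")
  if (nrow(object)) {
    cov <- totalCounts(object)
    cat(sprintf("median coverage: %.0f\n", median(cov[cov > 0])))
  }
  invisible(NULL)
})

# sample ids for a group label, with validation
.groupSamples <- function(x, group) {
  ids <- colnames(x)[sampleGroups(x) == group]
  if (!length(ids)) .stopf("no samples with group label '%s'", group)
  ids
}
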