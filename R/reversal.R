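# Dual-contrast reversal analysis: overlap the injury contrast
# (SNI-Vehicle vs Sham-Vehicle) with the treatment contrast (SNI-SAM vs
# SNI-Vehicle) and ask, tile by tile, whether the treatment moved
# methylation back in the opposite direction.

.dmSubset <- function(x) x[x$status %in% c("hyper", "hypo"), , drop = FALSE]

.tileKey <- function(x) paste0(x$chrom, ":", x$start, "-", x$end)

#' Pair tiles differentially methylated in two contrasts
#'
#' Tiles called DM (hyper or hypo) in *both* contrasts are paired. The
#' default mode matches tiles by exact coordinates, which is correct when
#' both contrasts came from the same tiling; `mode = "overlap"`
#' additionally pairs an injury-DM tile with any overlapping
#' treatment-DM tiles, and when those overlapping tiles imply
#' contradictory classifications the record's treatment status is marked
#' `"conflicting"` (classified `"unclear"` downstream).
#'
#' @param injury,treatment contrast data frames from
#'   [calculateDiffMeth()].
#' @param mode `"exact"` (default) or `"overlap"`.
#' @return A data frame, one row per paired tile, with the injury and
#'   treatment effect and status side by side. Attributes `injuryOnly` /
#'   `treatmentOnly` count DM tiles present in only one contrast.
#' @export
overlapContrasts <- function(injury, treatment, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  needed <- c("chrom", "start", "end", "meth_diff", "status")
  stopifnot(all(needed %in% names(injury)), all(needed %in% names(treatment)))
  di <- .dmSubset(injury)
  dt <- .dmSubset(treatment)
  ki <- .tileKey(di); kt <- .tileKey(dt)
  shared <- intersect(ki, kt)
  if (mode == "exact" && !length(shared) && nrow(di) && nrow(dt)) {
    gi <- GRanges(di$chrom, IRanges(di$start, di$end))
    gt <- GRanges(dt$chrom, IRanges(dt$start, dt$end))
    nOv <- sum(IRanges::overlapsAny(gi, gt))
    if (nOv > 0.5 * min(nrow(di), nrow(dt)))
      .stopf(paste("no exact tile matches but %d partial overlaps:",
                   "the two contrasts appear to use different tiling",
                   "parameters"), nOv)
  }
  ii <- match(shared, ki); it <- match(shared, kt)
  pairs <- data.frame(
    chrom = di$chrom[ii], start = di$start[ii], end = di$end[ii],
    genes = if ("genes" %in% names(di)) di$genes[ii] else "",
    injury_diff = di$meth_diff[ii], injury_status = di$status[ii],
    injury_q = if ("q_value" %in% names(di)) di$q_value[ii] else NA_real_,
    treatment_diff = dt$meth_diff[it], treatment_status = dt$status[it],
    treatment_q = if ("q_value" %in% names(dt)) dt$q_value[it] else NA_real_)
  if (mode == "overlap" && nrow(di)) {
    unmatched <- setdiff(seq_len(nrow(di)), ii)
    if (length(unmatched)) {
      gi <- GRanges(di$chrom[unmatched], IRanges(di$start[unmatched],
                                                 di$end[unmatched]))
      gt <- GRanges(dt$chrom, IRanges(dt$start, dt$end))
      hits <- findOverlaps(gi, gt)
      if (length(hits)) {
        st <- split(dt$status[subjectHits(hits)], queryHits(hits))
        dfl <- split(dt$meth_diff[subjectHits(hits)], queryHits(hits))
        qh <- as.integer(names(st))
        one <- vapply(st, function(s) length(unique(s)) == 1L, TRUE)
        rows <- unmatched[qh]
        extra <- data.frame(
          chrom = di$chrom[rows], start = di$start[rows], end = di$end[rows],
          genes = if ("genes" %in% names(di)) di$genes[rows] else "",
          injury_diff = di$meth_diff[rows], injury_status = di$status[rows],
          injury_q = if ("q_value" %in% names(di)) di$q_value[rows] else
            NA_real_,
          treatment_diff = ifelse(one, vapply(dfl, mean, 0), NA_real_),
          treatment_status = ifelse(one, vapply(st, `[`, "", 1L),
                                    "conflicting"),
          treatment_q = NA_real_)
        pairs <- rbind(pairs, extra)
      }
    }
  }
  pairedInjury <- .tileKey(pairs)
  attr(pairs, "injuryOnly") <- sum(!ki %in% pairedInjury)
  attr(pairs, "treatmentOnly") <- if (mode == "exact")
    sum(!kt %in% pairedInjury) else NA_integer_
  pairs
}

#' Classify the reversal behaviour of paired DM tiles
#'
#' A tile hypermethylated by injury and hypomethylated by treatment is a
#' reversal of hypermethylation; the mirror case is a reversal of
#' hypomethylation; the same status in both contrasts is no reversal.
#' Records whose treatment status is `"conflicting"` (overlap-matching
#' mode only) are classified `"unclear"`.
#'
#' @param pairs paired-tile data frame from [overlapContrasts()].
#' @return A list with `records` (the pairs plus a `reversal_class`
#'   column) and `summary` (tile counts, percentages and unique-gene
#'   counts per class, plus the combined reversing tally).
#' @export
classifyReversal <- function(pairs) {
  cls <- with(pairs, ifelse(
    treatment_status == "conflicting", "unclear",
    ifelse(injury_status == "hyper" & treatment_status == "hypo",
           "reversal_of_hypermethylation",
    ifelse(injury_status == "hypo" & treatment_status == "hyper",
           "reversal_of_hypomethylation", "no_reversal"))))
  pairs$reversal_class <- cls
  levs <- c("reversal_of_hypermethylation", "reversal_of_hypomethylation",
            "no_reversal", "unclear")
  counts <- table(factor(cls, levels = levs))
  n <- nrow(pairs)
  geneCount <- function(class) {
    g <- unlist(strsplit(pairs$genes[cls == class], ",", fixed = TRUE))
    length(unique(g[nzchar(g)]))
  }
  reversing <- sum(counts[c("reversal_of_hypermethylation",
                            "reversal_of_hypomethylation")])
  revGenes <- {
    g <- unlist(strsplit(pairs$genes[cls %in% levs[1:2]], ",", fixed = TRUE))
    length(unique(g[nzchar(g)]))
  }
  summary <- list(
    n_pairs = n,
    counts = as.list(setNames(as.integer(counts), levs)),
    percents = as.list(setNames(
      if (n) 100 * as.integer(counts) / n else rep(0, length(levs)), levs)),
    genes = as.list(setNames(lapply(levs, geneCount), levs)),
    reversing_tiles = as.integer(reversing),
    reversing_percent = if (n) 100 * reversing / n else 0,
    reversing_genes = revGenes)
  list(records = pairs, summary = summary)
}

#' Gene-level aggregation of tile effects
#'
#' For each gene, the mean methylation difference over its tiles is
#' reported per contrast, with the standard error across tiles when a
#' gene has two or more (absent for single-tile genes). A tile annotated
#' to several genes contributes to each of them.
#'
#' @param records reversal records (or any data frame with `genes`,
#'   `injury_diff`, `treatment_diff` columns).
#' @return A data frame with one row per gene: `gene`, `n_tiles`,
#'   `injury_mean`, `injury_se`, `treatment_mean`, `treatment_se`.
#' @export
summarizeGenes <- function(records) {
  stopifnot(all(c("genes", "injury_diff", "treatment_diff") %in%
                  names(records)))
  gl <- strsplit(records$genes, ",", fixed = TRUE)
  rows <- rep(seq_len(nrow(records)), lengths(gl))
  gene <- unlist(gl)
  keep <- nzchar(gene)
  rows <- rows[keep]; gene <- gene[keep]
  byGene <- split(rows, gene)
  se <- function(x) if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_
  out <- data.frame(
    gene = names(byGene),
    n_tiles = lengths(byGene),
    injury_mean = vapply(byGene, function(i) mean(records$injury_diff[i]), 0),
    injury_se = vapply(byGene, function(i) se(records$injury_diff[i]), 0),
    treatment_mean = vapply(byGene,
                            function(i) mean(records$treatment_diff[i]), 0),
    treatment_se = vapply(byGene,
                          function(i) se(records$treatment_diff[i]), 0),
    row.names = NULL)
  out[order(out$gene), , drop = FALSE]
}
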