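#' Hypergeometric over-representation of one gene set
#'
#' Tests whether `hits` (e.g. differentially methylated or reversing
#' genes) over-represent `geneSet` relative to the `population` of genes
#' the pipeline could have detected (genes with at least one analysable
#' promoter tile). With `N` population genes, `K` of them in the set and
#' `n` hits of which `k` are in the set, the upper-tail p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` is obtained by exact
#' summation of the probability mass.
#'
#' @param population character vector: the measured-gene universe.
#' @param geneSet character vector of set members; members absent from
#'   the population are dropped (and reported with a message) before
#'   testing.
#' @param hits character vector of hit genes; must be a subset of the
#'   population.
#' @param name set label carried into the result.
#' @return A one-row data frame: `set`, `N`, `K`, `n`, `k`, `p_value`.
#' @examples
#' hypergeomEnrichment(letters[1:10], letters[1:4], letters[c(1:3, 9:10)])
#' @export
hypergeomEnrichment <- function(population, geneSet, hits, name = "set") {
  population <- unique(population)
  if (!length(population)) .stopf("empty population")
  hits <- unique(hits)
  if (!all(hits %in% population))
    .stopf("%d hit gene(s) are not in the population",
           sum(!hits %in% population))
  dropped <- setdiff(unique(geneSet), population)
  if (length(dropped))
    message(sprintf("gene set '%s': %d member(s) not in the population dropped",
                    name, length(dropped)))
  inSet <- intersect(unique(geneSet), population)
  N <- length(population)
  K <- length(inSet)
  n <- length(hits)
  k <- length(intersect(hits, inSet))
  p <- if (k == 0) 1 else
    sum(dhyper(k:min(K, n), m = K, n = N - K, k = n))
  data.frame(set = name, N = N, K = K, n = n, k = k,
             p_value = min(1, p))
}

#' Over-representation analysis of several gene sets
#'
#' Applies [hypergeomEnrichment()] to each set, adds a
#' Benjamini-Hochberg adjusted `q_value` across sets, and sorts by
#' p-value.
#'
#' @param population,hits as in [hypergeomEnrichment()].
#' @param geneSets named list of character vectors.
#' @return A data frame with one row per set, sorted by `p_value`.
#' @export
oraMulti <- function(population, geneSets, hits) {
  if (!length(geneSets)) .stopf("need at least one gene set")
  if (is.null(names(geneSets)))
    names(geneSets) <- paste0("set", seq_along(geneSets))
  res <- do.call(rbind, Map(function(gs, nm)
    hypergeomEnrichment(population, gs, hits, name = nm),
    geneSets, names(geneSets)))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
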