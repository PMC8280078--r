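#' Sliding-linear-model estimate of the null proportion (pi0)
#'
#' Above the signal-bearing region of a p-value distribution the
#' empirical CDF is approximately linear with slope pi0 (the proportion
#' of true null hypotheses). The estimator divides `[lambdaMin, 1]` into
#' `nSegments` consecutive lambda segments, fits a least-squares line to
#' the empirical CDF within each, and reports the slope of the most
#' stable segment — the one whose slope changes least from its left
#' neighbour, ties resolved towards larger lambda, where the null
#' component dominates.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambdaMin left edge of the lambda range scanned (default 0.1).
#' @param nSegments number of sliding segments (default 10).
#' @param pointsPerSegment CDF evaluation points per segment (default 11).
#' @return A single number in `(0, 1]`.
#' @examples
#' set.seed(1)
#' slimPi0(runif(5000))          # near 1 under the full null
#' @export
slimPi0 <- function(p, lambdaMin = 0.1, nSegments = 10L,
                    pointsPerSegment = 11L) {
  .checkPvalues(p)
  if (!length(p)) return(1)
  itv <- (1 - lambdaMin) / nSegments
  slopes <- vapply(seq_len(nSegments), function(i) {
    hi <- if (i == nSegments) 1 else lambdaMin + i * itv  # exact right edge
    lam <- seq(lambdaMin + (i - 1L) * itv, hi,
               length.out = pointsPerSegment)
    Fhat <- vapply(lam, function(l) mean(p <= l), 0)
    # closed-form OLS slope
    sum((lam - mean(lam)) * (Fhat - mean(Fhat))) / sum((lam - mean(lam))^2)
  }, 0)
  if (nSegments == 1L) {
    sel <- 1L
  } else {
    d <- abs(diff(slopes))
    sel <- max(which(d == min(d))) + 1L
  }
  cand <- slopes[sel]
  # degenerate distributions (e.g. point masses) leave the stable region
  # flat at slope 0; fall back to the steepest segment, which holds the
  # remaining mass
  if (cand <= 0) cand <- max(slopes)
  min(1, max(cand, 1e-3))
}

#' SLIM-style FDR adjustment of p-values
#'
#' Converts p-values to q-values by scaling the Benjamini-Hochberg
#' step-up adjustment with a sliding-linear-model estimate of the null
#' proportion pi0 (see [slimPi0()]); with `pi0 = 1` the result equals
#' Benjamini-Hochberg exactly. Output is order-preserving: `q[i] <= q[j]`
#' whenever `p[i] <= p[j]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"SLIM"` (pi0-scaled FDR) or `"BH"`.
#' @param pi0 optional fixed pi0 overriding the estimate (SLIM method
#'   only).
#' @return Numeric vector of q-values, same length as `p`, each in
#'   `[0, 1]`. The pi0 used is attached as `attr(, "pi0")`.
#' @export
slimAdjust <- function(p, method = c("SLIM", "BH"), pi0 = NULL) {
  method <- match.arg(method)
  .checkPvalues(p)
  if (!length(p)) return(numeric(0))
  if (method == "BH") {
    q <- p.adjust(p, method = "BH")
    attr(q, "pi0") <- 1
    return(q)
  }
  if (is.null(pi0)) pi0 <- slimPi0(p)
  .assertProportion(pi0, "pi0")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * (m / (m:1)) * p[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}

.checkPvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    .stopf("p-values must be numeric, non-missing, and within [0, 1]")
  invisible(p)
}
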