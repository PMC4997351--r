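#' Per-gene tissue-specificity p-values
#'
#' For every gene, compares expression in the target-tissue samples
#' against all other samples with a one-sided rank-sum test (alternative:
#' target expression greater). Genes with all-zero expression get p = 1
#' with a warning.
#'
#' @param se A [SummarizedExperiment::SummarizedExperiment] whose first
#'   assay holds non-negative expression values (RPKM-like) and whose
#'   `colData` has a tissue label column, or a plain numeric matrix with
#'   `tissues` given.
#' @param target Target tissue label.
#' @param tissues Character vector of per-sample tissue labels (required
#'   for a plain matrix; taken from `colData(se)[[tissueCol]]` otherwise).
#' @param tissueCol Name of the tissue column in `colData`.
#' @return Named numeric vector of p-values, one per gene.
#' @export
specificityPvalues <- function(se, target, tissues = NULL,
                               tissueCol = "tissue") {
  if (is(se, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(se)
    if (is.null(tissues))
      tissues <- SummarizedExperiment::colData(se)[[tissueCol]]
  } else mat <- as.matrix(se)
  if (is.null(tissues) || length(tissues) != ncol(mat))
    stop("need one tissue label per sample")
  in_target <- tissues == target
  if (!any(in_target)) stop("no samples with target tissue ", target)
  if (all(in_target)) stop("no non-target samples")
  n <- sum(in_target)
  m <- sum(!in_target)
  exact_ok <- choose(n + m, min(n, m)) <= 1e6
  zero_rows <- 0L
  p <- apply(mat, 1L, function(row) {
    if (all(row == 0)) {
      zero_rows <<- zero_rows + 1L
      return(1)
    }
    if (exact_ok)
      rankSumTest(row[in_target], row[!in_target],
                  alternative = "greater")$p.value
    else .rankSumGreaterApprox(row, in_target)
  })
  if (zero_rows > 0L)
    warning(zero_rows, " all-zero gene(s) assigned p = 1")
  p
}

## normal-approximation one-sided (greater) rank-sum p-value; same tie and
## continuity corrections as rankSumTest, without its bookkeeping overhead
.rankSumGreaterApprox <- function(row, in_target) {
  N <- length(row)
  n <- sum(in_target)
  r <- rank(row)
  W <- sum(r[in_target])
  mu <- n * (N + 1) / 2
  tie_tab <- tabulate(match(row, unique(row)))
  tie_adj <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma <- sqrt(n * (N - n) / 12 * ((N + 1) - tie_adj))
  if (sigma == 0) return(1)
  stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
}

#' Flag tissue-specific genes by p-value quantile
#'
#' Flags the most significant fraction of genes: those with p-values at
#' or below the empirical `quantile` of all p-values (type-1 quantile;
#' ties at the cutoff are all included).
#'
#' @param pvalues Named numeric vector of per-gene p-values.
#' @param quantile Fraction flagged (default 0.01, the upper 1% of
#'   significance).
#' @return data.frame with columns `gene`, `p`, `specific`; the cutoff
#'   used is attached as attribute `"cutoff"`.
#' @export
callSpecific <- function(pvalues, quantile = 0.01) {
  stopifnot(quantile > 0, quantile < 1)
  if (length(pvalues) < 1 / quantile)
    warning("fewer than 1/quantile genes; call set may be empty or noisy")
  cutoff <- stats::quantile(pvalues, probs = quantile, type = 1,
                            names = FALSE)
  out <- data.frame(
    gene = if (is.null(names(pvalues))) seq_along(pvalues)
           else names(pvalues),
    p = as.numeric(pvalues),
    specific = pvalues <= cutoff,
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "quantile") <- quantile
  out
}

#' Sliding gene-window counts of flagged genes
#'
#' Slides a fixed-size window (default 15 genes) along the chromosomal
#' gene order in steps of one gene and counts flagged genes per window.
#'
#' @param flags Logical vector of per-gene flags in chromosomal order
#'   (e.g. the `specific` column of [callSpecific()] output).
#' @param windowSize Number of genes per window.
#' @return Integer vector of counts, one per window, named/indexed by the
#'   first gene of each window.
#' @examples
#' windowScan(c(FALSE, FALSE, TRUE, TRUE, FALSE), windowSize = 3)
#' @export
windowScan <- function(flags, windowSize = 15L) {
  flags <- as.logical(flags)
  n <- length(flags)
  windowSize <- as.integer(windowSize)
  if (n < windowSize) stop("fewer genes than the window size")
  cs <- c(0L, cumsum(flags))
  counts <- cs[(windowSize + 1L):(n + 1L)] - cs[seq_len(n - windowSize + 1L)]
  names(counts) <- if (!is.null(names(flags)))
    names(flags)[seq_along(counts)] else as.character(seq_along(counts))
  counts
}

#' Report on a window scan around a focal gene
#'
#' Summarises the sliding-window scan: the maximum window count, the best
#' (highest-count) window covering the focal gene, a histogram of window
#' counts, and an enrichment p-value comparing the p-values of genes in
#' the focal window against all other genes (one-sided rank-sum,
#' alternative: focal-window p-values smaller). When no window contains
#' any flagged gene the enrichment p is 1 by convention.
#'
#' @param counts Window counts from [windowScan()].
#' @param calls data.frame from [callSpecific()] (same gene order used
#'   for the scan).
#' @param focal Focal gene name (must appear in `calls$gene`).
#' @param windowSize Window size used in the scan.
#' @return List with `maxCount`, `maxWindow` (first-gene index of the
#'   best window overall), `focalWindow` (first-gene index of the best
#'   window covering the focal gene), `focalCount`, `histogram`
#'   (table of window counts) and `enrichmentP`.
#' @export
scanReport <- function(counts, calls, focal, windowSize = 15L) {
  gi <- match(focal, calls$gene)
  if (is.na(gi)) stop("focal gene not found: ", focal)
  n <- nrow(calls)
  windowSize <- as.integer(windowSize)
  # windows covering gene gi start in [gi - windowSize + 1, gi]
  cov_start <- max(1L, gi - windowSize + 1L):min(gi, length(counts))
  focal_best <- cov_start[which.max(counts[cov_start])]
  enrich <- if (max(counts) == 0L) 1 else {
    in_win <- seq(focal_best, focal_best + windowSize - 1L)
    rankSumTest(calls$p[in_win], calls$p[setdiff(seq_len(n), in_win)],
                alternative = "less")$p.value
  }
  list(
    maxCount = max(counts),
    maxWindow = unname(which.max(counts)),
    focalWindow = unname(focal_best),
    focalCount = unname(counts[focal_best]),
    histogram = table(counts),
    enrichmentP = enrich
  )
}
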