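## Jensen-Shannon-divergence conservation scoring of protein alignments
## and per-segment synonymous/nonsynonymous variation summaries.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

## amino-acid background frequencies implied by the BLOSUM62 matrix
## (order A R N D C Q E G H I L K M F P S T W Y V), renormalised
.blosum62Background <- function() {
  f <- c(0.078, 0.051, 0.041, 0.052, 0.024, 0.034, 0.059, 0.083, 0.025,
         0.062, 0.092, 0.056, 0.024, 0.044, 0.043, 0.059, 0.055, 0.014,
         0.034, 0.072)
  names(f) <- AA20
  f / sum(f)
}

.background <- function(background) {
  if (is.numeric(background)) {
    stopifnot(setequal(names(background), AA20))
    return(background[AA20] / sum(background))
  }
  switch(match.arg(background, c("blosum62", "uniform")),
         blosum62 = .blosum62Background(),
         uniform = stats::setNames(rep(1 / 20, 20), AA20))
}

#' Jensen-Shannon divergence conservation score of one alignment column
#'
#' Scores a column by the Jensen-Shannon divergence (base-2 logs, equal
#' mixture weights) between the column's residue frequency distribution
#' (with pseudocounts) and a background distribution. The score is
#' bounded in `[0, 1]`: 0 when the column matches the background, larger
#' for more biased (conserved) columns.
#'
#' @param residues Character vector of residues in the column (single
#'   letters; gaps as `-` or `.`).
#' @param background `"blosum62"` (default), `"uniform"`, or a named
#'   numeric vector over the 20 amino acids.
#' @param pseudocount Added to each residue count; default `1/n` for `n`
#'   sequences.
#' @param gapThreshold Columns with a gap fraction above this return
#'   `NA`.
#' @return Numeric score in `[0, 1]`, or `NA` for gappy/empty columns.
#' @export
jsdColumnScore <- function(residues, background = "blosum62",
                           pseudocount = NULL, gapThreshold = 0.3) {
  residues <- toupper(residues)
  n <- length(residues)
  if (n == 0L) return(NA_real_)
  gap_frac <- mean(residues %in% c("-", "."))
  if (gap_frac > gapThreshold) return(NA_real_)
  res <- residues[residues %in% AA20]
  if (length(res) < 2L) return(NA_real_)
  if (is.null(pseudocount)) pseudocount <- 1 / n
  q <- .background(background)
  counts <- table(factor(res, levels = AA20)) + pseudocount
  p <- as.numeric(counts / sum(counts))
  names(p) <- AA20
  .jsd(p, q)
}

## base-2 Jensen-Shannon divergence between distributions p and q
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Per-column conservation profile of a protein alignment
#'
#' @param aln [Biostrings::AAStringSet] of aligned (equal-length)
#'   sequences, or a character vector.
#' @inheritParams jsdColumnScore
#' @return data.frame with columns `column`, `score`, `gap_fraction`.
#' @export
conservationProfile <- function(aln, background = "blosum62",
                                pseudocount = NULL, gapThreshold = 0.3) {
  seqs <- toupper(as.character(aln))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  ncol_aln <- ncol(mat)
  score <- numeric(ncol_aln)
  gapf <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    gapf[j] <- mean(col %in% c("-", "."))
    score[j] <- jsdColumnScore(col, background = background,
                               pseudocount = pseudocount,
                               gapThreshold = gapThreshold)
  }
  data.frame(column = seq_len(ncol_aln), score = score,
             gap_fraction = gapf)
}

#' Mean conservation score per functional segment
#'
#' @param profile data.frame from [conservationProfile()].
#' @param segments data.frame with columns `name`, `start`, `end`
#'   (1-based closed alignment-column intervals, non-overlapping).
#' @return Named numeric vector of per-segment means over non-missing
#'   columns; `NA` for fully missing segments.
#' @export
segmentConservation <- function(profile, segments) {
  .checkSegments(segments, max(profile$column))
  out <- vapply(seq_len(nrow(segments)), function(i) {
    sc <- profile$score[profile$column >= segments$start[i] &
                          profile$column <= segments$end[i]]
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) NA_real_ else mean(sc)
  }, numeric(1))
  names(out) <- segments$name
  out
}

.checkSegments <- function(segments, ncol_aln) {
  stopifnot(all(c("name", "start", "end") %in% names(segments)))
  if (any(segments$start < 1L) || any(segments$end > ncol_aln) ||
      any(segments$start > segments$end))
    stop("segment intervals must lie within the alignment")
  o <- order(segments$start)
  s <- segments[o, ]
  if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)]))
    stop("segments must not overlap")
  invisible(TRUE)
}

#' Normalized nonsynonymous/synonymous variation ratio per segment
#'
#' For each functional segment of a codon alignment, accumulates
#' Nei-Gojobori pathway-averaged synonymous and nonsynonymous differences
#' and fractional site counts over all sequence pairs and codon columns
#' (concatenated-count mode; `perPair = TRUE` averages per-pair ratios
#' instead), then forms `(nonsyn diffs / nonsyn sites) / (syn diffs /
#' syn sites)`. Codon columns containing gaps, ambiguity codes or stop
#' codons in either sequence of a pair are skipped. Segments whose name
#' matches `exclude` are dropped (by default the PTS-repeat region, whose
#' copy-number changes make alignment columns unreliable). With
#' `normalize = "whole"` each segment's ratio is divided by the ratio
#' over all retained segments; `"max"` divides by the largest segment
#' ratio; `"none"` reports raw ratios.
#'
#' @param codonAln [Biostrings::DNAStringSet] or character vector of
#'   aligned coding sequences (equal length, 3x the protein columns).
#' @param segments data.frame (`name`, `start`, `end`) in protein
#'   alignment columns.
#' @param normalize `"whole"` (default), `"max"`, or `"none"`.
#' @param exclude Regular expression for segment names to drop
#'   (default `"PTS"`; `NULL` keeps all).
#' @param perPair Average per-pair ratios instead of pooling counts.
#' @return Named numeric vector of per-segment ratios; `NA` when a
#'   segment has no synonymous differences (undefined ratio).
#' @export
segmentNsRatio <- function(codonAln, segments, normalize = "whole",
                           exclude = "PTS", perPair = FALSE) {
  normalize <- match.arg(normalize, c("whole", "max", "none"))
  seqs <- toupper(as.character(codonAln))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  if (nchar(seqs[1]) %% 3L != 0L)
    stop("codon alignment length must be divisible by 3")
  if (!is.null(exclude)) {
    keep <- !grepl(exclude, segments$name)
    segments <- segments[keep, , drop = FALSE]
  }
  if (nrow(segments) == 0L) stop("no segments left to score")
  .checkSegments(segments, nchar(seqs[1]) %/% 3L)
  codon_lists <- lapply(seqs, .codons)
  segCounts <- function(cols) {
    tot <- c(sd = 0, nd = 0, ss = 0, ns = 0)
    ratios <- numeric(0)
    for (i in seq_len(length(seqs) - 1L)) {
      for (j in seq(i + 1L, length(seqs))) {
        pair <- c(sd = 0, nd = 0, ss = 0, ns = 0)
        for (k in cols) {
          ca <- codon_lists[[i]][k]
          cb <- codon_lists[[j]][k]
          if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
          if (.isStopCodon(ca) || .isStopCodon(cb)) next
          sa <- codonSites(ca)
          sb <- codonSites(cb)
          pair["ss"] <- pair["ss"] + (sa[["syn"]] + sb[["syn"]]) / 2
          pair["ns"] <- pair["ns"] + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
          if (ca != cb) {
            d <- codonSynNonsyn(ca, cb)
            pair["sd"] <- pair["sd"] + d[["syn"]]
            pair["nd"] <- pair["nd"] + d[["nonsyn"]]
          }
        }
        tot <- tot + pair
        if (pair[["sd"]] > 0 && pair[["ss"]] > 0 && pair[["ns"]] > 0)
          ratios <- c(ratios,
                      (pair[["nd"]] / pair[["ns"]]) /
                        (pair[["sd"]] / pair[["ss"]]))
      }
    }
    list(tot = tot, ratios = ratios)
  }
  ratioOf <- function(cnt) {
    if (perPair) {
      if (length(cnt$ratios) == 0L) return(NA_real_)
      return(mean(cnt$ratios))
    }
    tot <- cnt$tot
    if (tot[["sd"]] == 0 || tot[["ss"]] == 0 || tot[["ns"]] == 0)
      return(NA_real_)
    (tot[["nd"]] / tot[["ns"]]) / (tot[["sd"]] / tot[["ss"]])
  }
  raw <- vapply(seq_len(nrow(segments)), function(i) {
    ratioOf(segCounts(seq(segments$start[i], segments$end[i])))
  }, numeric(1))
  names(raw) <- segments$name
  if (normalize == "none") return(raw)
  denom <- if (normalize == "whole") {
    all_cols <- unlist(lapply(seq_len(nrow(segments)), function(i)
      seq(segments$start[i], segments$end[i])))
    ratioOf(segCounts(all_cols))
  } else max(raw, na.rm = TRUE)
  if (is.na(denom) || denom == 0) {
    warning("normalization denominator undefined; returning raw ratios")
    return(raw)
  }
  raw / denom
}

#' Read a segment map from a BED-like TSV
#'
#' Columns: name, start, end over protein alignment columns (1-based
#' closed, header required).
#'
#' @param file TSV path.
#' @return data.frame with `name`, `start`, `end`.
#' @export
readSegmentMap <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
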