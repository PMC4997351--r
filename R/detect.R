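#' Detect in-frame subexonic tandem repeats in a coding sequence
#'
#' Frame-constrained seed-and-extend detector for tandem repeats made of
#' fixed-length, in-frame units (default 69 nt, i.e. 23 codons, the unit
#' length characteristic of mucin PTS-repeat domains). Candidate starts
#' are scanned codon-by-codon; a position seeds a run when the next two
#' adjacent windows match at or above the relaxed pairwise bound
#' `2*minIdentity - 1` (two units each within `1 - minIdentity` of their
#' consensus can differ from each other by up to twice that), and the run
#' is extended while further windows match the running majority-rule
#' consensus at the same bound. Each collected run is then re-verified:
#' only the maximal contiguous stretch of units with identity at least
#' `minIdentity` to the final consensus is kept, and among overlapping
#' candidate phases the run with most units (then highest mean identity,
#' then leftmost start) wins. A trailing copy shorter than one unit that
#' matches the consensus prefix is flagged separately and never counted.
#'
#' @param cds A [Biostrings::DNAString], character scalar, or named
#'   character of length 1 (DNA over A/C/G/T/N).
#' @param unitLength Unit length in nucleotides; must be divisible by 3.
#' @param minUnits Minimum number of full units to report a run (>= 2).
#' @param minIdentity Minimum per-unit identity to the running consensus,
#'   between 0.5 and 1.
#' @param sourceId,species Labels stored in the annotation.
#' @return A [RepeatAnnotation-class]; empty (zero units) when the CDS is
#'   shorter than two units or no run is found.
#' @examples
#' unit <- strrep("ACTTCA", 11)  # 66 nt; real use has 69-nt units
#' cds <- paste0(strrep("GAA", 10), strrep(unit, 3), strrep("GAT", 10))
#' detectRepeats(cds, unitLength = 66)
#' @export
detectRepeats <- function(cds, unitLength = 69L, minUnits = 2L,
                          minIdentity = 0.8, sourceId = "cds",
                          species = NA_character_) {
  if (is(cds, "DNAString")) cds <- as.character(cds)
  if (!is.character(cds) || length(cds) != 1L)
    stop("cds must be a single DNA sequence")
  unitLength <- as.integer(unitLength)
  if (unitLength %% 3L != 0L) stop("unitLength must be divisible by 3")
  if (minUnits < 2L) stop("minUnits must be >= 2")
  if (minIdentity < 0.5 || minIdentity > 1)
    stop("minIdentity must be in [0.5, 1]")
  s <- strsplit(toupper(cds), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T", "N")))
    stop("cds contains non-DNA characters")
  L <- length(s)
  U <- unitLength
  empty <- RepeatAnnotation(sourceId, species, unitLength = U)
  if (L < 2L * U) return(empty)

  ident <- function(a, b) mean(a == b & a != "N")
  window <- function(p) s[p:(p + U - 1L)]  # p is 1-based start

  # collect a candidate run from every frame-aligned seed; a tandem array
  # also matches itself at shifted phases (identity (U - shift)/U), so the
  # best phase is chosen afterwards by unit count, then mean identity
  loose <- max(0.5, 2 * minIdentity - 1)
  skip_seed <- logical(L)  # same-phase seeds inside an accepted run
  cands <- list()
  for (p in seq(1L, L - 2L * U + 1L, by = 3L)) {
    if (skip_seed[p]) next
    if (ident(window(p), window(p + U)) < loose) next
    run <- list(window(p), window(p + U))
    consensus <- .majorityConsensus(run)
    q <- p + 2L * U
    while (q + U - 1L <= L && ident(window(q), consensus) >= loose) {
      run[[length(run) + 1L]] <- window(q)
      consensus <- .majorityConsensus(run)
      q <- q + U
    }
    # re-verify against the final consensus: keep the maximal contiguous
    # stretch of units at or above minIdentity
    ok <- vapply(run, ident, 0, b = consensus) >= minIdentity
    rle_ok <- rle(ok)
    if (!any(rle_ok$values & rle_ok$lengths >= minUnits)) next
    best <- which(rle_ok$values & rle_ok$lengths ==
                    max(rle_ok$lengths[rle_ok$values]))[1L]
    from <- sum(rle_ok$lengths[seq_len(best - 1L)]) + 1L
    keep <- seq(from, from + rle_ok$lengths[best] - 1L)
    run <- run[keep]
    run_starts <- p + (keep - 1L) * U
    consensus <- .majorityConsensus(run)
    if (length(run) < minUnits) next
    skip_seed[run_starts[-1L]] <- TRUE
    run_end <- run_starts[length(run_starts)] + U - 1L
    # boundary-continuation penalty: a phase-shifted run leaves repeat
    # content just outside its span (the adjacent codon continues the
    # consensus), whereas a true maximal run is flanked by non-repeat
    # sequence; penalising boundary matches resolves phase ties
    p0 <- run_starts[1L]
    bnd <- 0L
    if (p0 >= 4L)
      bnd <- bnd + sum(s[(p0 - 3L):(p0 - 1L)] == consensus[(U - 2L):U])
    if (run_end + 3L <= L)
      bnd <- bnd + sum(s[(run_end + 1L):(run_end + 3L)] == consensus[1:3])
    k <- length(run)
    mean_ident <- mean(vapply(run, ident, 0, b = consensus))
    cands[[length(cands) + 1L]] <- list(
      starts = run_starts,
      seqs = vapply(run, paste, "", collapse = ""),
      consensus = consensus,
      k = k,
      meanIdent = mean_ident,
      # boundary term scaled below 1/6 so it breaks exact match-count
      # ties without ever overturning a strict one-match advantage
      score = k * U * mean_ident - bnd / 7,
      end = run_end
    )
  }
  if (length(cands) == 0L) return(empty)
  # greedy selection of non-overlapping runs: more units, then higher
  # boundary-penalised match score, then leftmost
  ord <- order(-vapply(cands, `[[`, 0L, "k"),
               -vapply(cands, `[[`, 0, "score"),
               vapply(cands, function(c) c$starts[1L], 0L))
  chosen <- list()
  occupied <- logical(L)
  for (i in ord) {
    span <- seq(cands[[i]]$starts[1L], cands[[i]]$end)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    chosen[[length(chosen) + 1L]] <- cands[[i]]
  }
  chosen <- chosen[order(vapply(chosen, function(c) c$starts[1L], 0L))]
  starts <- unlist(lapply(chosen, `[[`, "starts"))
  seqs <- unlist(lapply(chosen, `[[`, "seqs"))
  # trailing partial copy after the last run: < U nt matching the
  # consensus prefix
  partial <- IRanges::IRanges()
  last <- chosen[[length(chosen)]]
  q <- last$end + 1L
  rem <- L - q + 1L
  if (rem >= 3L && rem < U) {
    if (mean(s[q:L] == last$consensus[seq_len(rem)]) >= minIdentity)
      partial <- IRanges::IRanges(start = q, end = L)
  }
  RepeatAnnotation(
    sourceId, species, unitLength = U,
    units = IRanges::IRanges(start = starts, width = U),
    unitSeqs = Biostrings::DNAStringSet(seqs),
    partial = partial
  )
}

.majorityConsensus <- function(units) {
  m <- do.call(rbind, units)
  U <- ncol(m)
  b5 <- c("A", "C", "G", "T", "N")
  cnts <- vapply(b5, function(b) colSums(m == b), numeric(U))
  if (is.null(dim(cnts))) cnts <- matrix(cnts, nrow = U)
  mx <- do.call(pmax, as.data.frame(cnts))
  # ties resolved toward the earliest unit's base in each column
  cons <- rep(NA_character_, U)
  for (r in seq_len(nrow(m))) {
    b <- m[r, ]
    cb <- cnts[cbind(seq_len(U), match(b, b5))]
    fill <- is.na(cons) & cb == mx
    cons[fill] <- b[fill]
  }
  cons
}

#' Write repeat annotations as BED (0-based half-open)
#'
#' @param x A [RepeatAnnotation-class] or list of them.
#' @param file Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeRepeatBed <- function(x, file) {
  if (is(x, "RepeatAnnotation")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(a) {
    n <- unitCount(a)
    if (n == 0L) return(NULL)
    data.frame(
      chrom = sourceId(a),
      chromStart = IRanges::start(unitRanges(a)) - 1L,
      chromEnd = IRanges::end(unitRanges(a)),
      name = paste0(ifelse(is.na(repeatSpecies(a)), sourceId(a),
                           repeatSpecies(a)), "_", seq_len(n)),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) rows <- data.frame(chrom = character(),
                                        chromStart = integer(),
                                        chromEnd = integer(),
                                        name = character())
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(rows)
}

#' Write repeat unit sequences as TSV
#'
#' One row per unit: label (`Species_Index`, 5' to 3'), source id, start,
#' end (1-based closed) and sequence.
#'
#' @inheritParams writeRepeatBed
#' @return Invisibly, the data.frame written.
#' @export
writeUnitsTsv <- function(x, file) {
  if (is(x, "RepeatAnnotation")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(a) {
    n <- unitCount(a)
    if (n == 0L) return(NULL)
    data.frame(
      label = paste0(ifelse(is.na(repeatSpecies(a)), sourceId(a),
                            repeatSpecies(a)), "_", seq_len(n)),
      source = sourceId(a),
      start = IRanges::start(unitRanges(a)),
      end = IRanges::end(unitRanges(a)),
      sequence = as.character(unitSeqs(a)),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) rows <- data.frame(label = character(),
                                        source = character(),
                                        start = integer(), end = integer(),
                                        sequence = character())
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
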