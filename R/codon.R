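## Codon-level synonymous/nonsynonymous accounting (Nei-Gojobori 1986
## conventions: pathway averaging for differences, fractional site counts).

BASES <- c("A", "C", "G", "T")

#' Translate a codon with the standard genetic code
#'
#' @param codon Character scalar of three DNA bases (A/C/G/T).
#' @return Single-letter amino acid, or `"*"` for a stop codon.
#' @keywords internal
.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a valid codon: ", codon)
  aa
}

.isStopCodon <- function(codon) .translateCodon(codon) == "*"

#' Synonymous/nonsynonymous differences between two codons
#'
#' Counts the synonymous and nonsynonymous nucleotide differences between
#' two codons by enumerating every mutational pathway (every ordering of
#' the differing positions), scoring each single-base step as synonymous
#' when the encoded amino acid is unchanged, and averaging over pathways.
#' Pathways that pass through a stop codon are excluded from the average;
#' in the degenerate case where every pathway passes through a stop, all
#' pathways are used and the stop-crossing steps are scored by amino-acid
#' change.
#'
#' @param codonA,codonB Character scalars of three DNA bases each.
#' @return Named numeric vector with elements `syn` and `nonsyn`;
#'   `syn + nonsyn` equals the nucleotide Hamming distance exactly.
#' @examples
#' codonSynNonsyn("GCT", "GCC")  # synonymous Ala -> Ala
#' codonSynNonsyn("TTT", "GTA")  # averages the two pathways
#' @export
codonSynNonsyn <- function(codonA, codonB) {
  key <- paste0(codonA, codonB)
  memo <- .codonPairMemo()
  res <- memo[[key]]
  if (is.null(res)) stop("not valid sense codons: ", codonA, ", ", codonB)
  res
}

.pathwayCounts <- function(codonA, codonB) {
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diff <- which(a != b)
  nd <- length(diff)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- .permutations(diff)
  kept <- list()
  all_paths <- list()
  for (i in seq_len(nrow(perms))) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    via_stop <- FALSE
    for (pos in perms[i, ]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_from <- .translateCodon(paste(cur, collapse = ""))
      aa_to <- .translateCodon(paste(nxt, collapse = ""))
      if (aa_to == "*" && !identical(nxt, b)) via_stop <- TRUE
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    path <- c(syn = syn, nonsyn = nonsyn)
    all_paths[[length(all_paths) + 1L]] <- path
    if (!via_stop) kept[[length(kept) + 1L]] <- path
  }
  use <- if (length(kept) > 0) kept else all_paths
  m <- do.call(rbind, use)
  c(syn = mean(m[, "syn"]), nonsyn = mean(m[, "nonsyn"]))
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# Memoised 61x61 sense-codon pair table, built on first use.
.codonEnv <- new.env(parent = emptyenv())

.codonPairMemo <- function() {
  if (!is.null(.codonEnv$pairs)) return(.codonEnv$pairs)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  memo <- new.env(parent = emptyenv(), size = 4096L)
  for (a in sense) {
    for (b in sense) {
      assign(paste0(a, b), .pathwayCounts(a, b), envir = memo)
    }
  }
  .codonEnv$pairs <- memo
  memo
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' At each codon position the three possible single-base changes are
#' classified; changes creating a stop codon are discarded from the
#' denominator. The synonymous site count of the position is the fraction
#' of retained changes that preserve the amino acid; nonsynonymous sites
#' are the complement, so the two always sum to 3 per codon.
#'
#' @param codon Character scalar of three DNA bases (a sense codon).
#' @return Named numeric vector with elements `syn` and `nonsyn`.
#' @export
codonSites <- function(codon) {
  memo <- .codonSiteMemo()
  res <- memo[[codon]]
  if (is.null(res)) stop("not a valid sense codon: ", codon)
  res
}

.siteCounts <- function(codon) {
  a <- strsplit(codon, "")[[1]]
  aa0 <- .translateCodon(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    tot <- 0
    for (nt in setdiff(BASES, a[pos])) {
      alt <- a
      alt[pos] <- nt
      aa1 <- .translateCodon(paste(alt, collapse = ""))
      if (aa1 == "*") next
      tot <- tot + 1
      if (aa1 == aa0) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(syn = s, nonsyn = 3 - s)
}

.codonSiteMemo <- function() {
  if (!is.null(.codonEnv$sites)) return(.codonEnv$sites)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  memo <- new.env(parent = emptyenv(), size = 64L)
  for (a in sense) assign(a, .siteCounts(a), envir = memo)
  .codonEnv$sites <- memo
  memo
}

## split a DNA string into codons; returns character vector
.codons <- function(x) {
  x <- as.character(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}
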