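#' Fraction of threonine + serine residues in a protein
#'
#' The T+S fraction approximates the density of candidate O-glycosylation
#' sites, the defining feature of mucin PTS domains. Gap characters
#' (`-`, `.`) are excluded from the denominator; `X` counts as a residue.
#'
#' @param protein Character scalar or [Biostrings::AAString].
#' @return Fraction in `[0, 1]`.
#' @examples
#' tsFraction("PTSTSAP")  # 4/7
#' @export
tsFraction <- function(protein) {
  if (is(protein, "AAString") || is(protein, "AAStringSet"))
    protein <- as.character(protein)
  if (!is.character(protein) || length(protein) != 1L)
    stop("protein must be a single amino-acid sequence")
  res <- strsplit(toupper(protein), "")[[1]]
  res <- res[!res %in% c("-", ".")]
  if (length(res) == 0L) stop("empty or all-gap protein sequence")
  if (!all(res %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")))
    stop("non-standard residue in protein sequence")
  sum(res %in% c("T", "S")) / length(res)
}

#' Pairwise divergence between two equal-length, in-frame repeat units
#'
#' Computes the positionwise (Hamming) nucleotide difference count and
#' partitions it into synonymous and nonsynonymous fractional components
#' by Nei-Gojobori pathway averaging over each codon pair, plus the
#' amino-acid Hamming distance and the difference in T+S residue counts.
#' The two sequences are compared position by position without alignment;
#' in-frame units of equal length are assumed. Codon pairs containing an
#' internal stop are skipped from all counts with a warning, so that the
#' partition closure `syn + nonsyn == nt` always holds.
#'
#' @param unitA,unitB DNA sequences (character or
#'   [Biostrings::DNAString]) of equal length divisible by 3.
#' @param idA,idB,speciesA,speciesB Optional labels carried in the result.
#' @return A one-row data.frame with columns `id_a`, `id_b`, `species_a`,
#'   `species_b`, `nt_diffs`, `syn_diffs`, `nonsyn_diffs`, `aa_diffs`,
#'   `ts_count_diff`.
#' @examples
#' pairwiseDivergence("GCT", "GCC")  # one synonymous difference
#' @export
pairwiseDivergence <- function(unitA, unitB, idA = "a", idB = "b",
                               speciesA = NA_character_,
                               speciesB = NA_character_) {
  a <- toupper(as.character(unitA))
  b <- toupper(as.character(unitB))
  if (nchar(a) != nchar(b))
    stop("units have unequal lengths; pre-align them before comparison")
  if (nchar(a) %% 3L != 0L) stop("unit length must be divisible by 3")
  ca <- .codons(a)
  cb <- .codons(b)
  aa_a <- vapply(ca, .translateCodon, "")
  aa_b <- vapply(cb, .translateCodon, "")
  skip <- aa_a == "*" | aa_b == "*"
  if (any(skip))
    warning(sum(skip), " codon pair(s) with internal stop skipped")
  nt <- 0L
  syn <- 0
  nonsyn <- 0
  aad <- 0L
  for (i in which(!skip)) {
    d <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    if (d > 0L) {
      nt <- nt + d
      sn <- codonSynNonsyn(ca[i], cb[i])
      syn <- syn + sn[["syn"]]
      nonsyn <- nonsyn + sn[["nonsyn"]]
      if (aa_a[i] != aa_b[i]) aad <- aad + 1L
    }
  }
  tsA <- sum(aa_a[!skip] %in% c("T", "S"))
  tsB <- sum(aa_b[!skip] %in% c("T", "S"))
  data.frame(
    id_a = idA, id_b = idB, species_a = speciesA, species_b = speciesB,
    nt_diffs = nt, syn_diffs = syn, nonsyn_diffs = nonsyn,
    aa_diffs = aad, ts_count_diff = abs(tsA - tsB),
    stringsAsFactors = FALSE
  )
}

#' Pairwise divergence matrices over all repeat units
#'
#' Assembles the symmetric pairwise difference matrices (nucleotide,
#' synonymous, nonsynonymous, amino-acid, T+S count) over every full unit
#' in a set of repeat annotations. Units are labelled `Species_Index`,
#' indexed 5' to 3' within each source.
#'
#' @param annotations A [RepeatAnnotation-class], a list of them, or a
#'   named [Biostrings::DNAStringSet]/character vector of unit sequences
#'   (names used as labels, species taken as the part before the last
#'   underscore).
#' @return A [RepeatDivergence-class] object.
#' @export
divergenceMatrix <- function(annotations) {
  if (is(annotations, "RepeatAnnotation")) annotations <- list(annotations)
  if (is(annotations, "DNAStringSet") || is.character(annotations)) {
    nm <- names(annotations)
    seqs <- as.character(annotations)
    names(seqs) <- if (is.null(nm)) paste0("unit_", seq_along(seqs)) else nm
    labels <- names(seqs)
    species <- sub("_[^_]*$", "", labels)
  } else {
    seqs <- character()
    labels <- character()
    species <- character()
    for (a in annotations) {
      n <- unitCount(a)
      if (n == 0L) next
      sp <- if (is.na(repeatSpecies(a))) sourceId(a) else repeatSpecies(a)
      seqs <- c(seqs, as.character(unitSeqs(a)))
      labels <- c(labels, paste0(sp, "_", seq_len(n)))
      species <- c(species, rep(sp, n))
    }
  }
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 repeat units")
  if (length(unique(nchar(seqs))) != 1L)
    stop("mixed unit lengths; all units must be equal length")
  mk <- function() matrix(0, n, n, dimnames = list(labels, labels))
  nt <- mk(); syn <- mk(); nonsyn <- mk(); aa <- mk(); ts <- mk()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- pairwiseDivergence(seqs[i], seqs[j])
      nt[i, j] <- nt[j, i] <- r$nt_diffs
      syn[i, j] <- syn[j, i] <- r$syn_diffs
      nonsyn[i, j] <- nonsyn[j, i] <- r$nonsyn_diffs
      aa[i, j] <- aa[j, i] <- r$aa_diffs
      ts[i, j] <- ts[j, i] <- r$ts_count_diff
    }
  }
  new("RepeatDivergence", labels = labels, species = species,
      nt = nt, syn = syn, nonsyn = nonsyn, aa = aa, ts = ts)
}

#' Write a divergence matrix component as TSV
#'
#' @param x A [RepeatDivergence-class].
#' @param file Output path.
#' @param component Which matrix to write (default nucleotide differences).
#' @return Invisibly, the matrix written.
#' @export
writeDivergenceTsv <- function(x, file, component = "nt") {
  m <- divergenceComponent(x, component)
  utils::write.table(data.frame(label = rownames(m), m, check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Hierarchical clustering of repeat units
#'
#' Agglomerative clustering (UPGMA / average linkage by default) of the
#' pairwise nucleotide difference matrix, as used to order heatmaps of
#' repeat similarity. Deterministic given the input order; ties are
#' resolved by `stats::hclust`'s leftmost-first merging.
#'
#' @param x A [RepeatDivergence-class] or a symmetric numeric matrix.
#' @param k Optional number of flat clusters to cut.
#' @param method Linkage passed to [stats::hclust()].
#' @return A list with elements `tree` (an `hclust`) and, when `k` is
#'   given, `clusters` (named integer vector from [stats::cutree()]).
#' @export
clusterRepeats <- function(x, k = NULL, method = "average") {
  m <- if (is(x, "RepeatDivergence")) divergenceComponent(x, "nt") else x
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-9))
    stop("need a symmetric distance matrix")
  if (nrow(m) < 2L) stop("need at least 2 units to cluster")
  tree <- stats::hclust(stats::as.dist(m), method = method)
  out <- list(tree = tree)
  if (!is.null(k)) out$clusters <- stats::cutree(tree, k = k)
  out
}

#' Recurrence (species-private clustering) score per species
#'
#' For each species with at least two units, the fraction of its units
#' whose nearest neighbour (smallest pairwise distance) belongs to the
#' same species. Ties at the minimum distance are broken toward a
#' different-species neighbour, making the score conservative. A score of
#' 1 is the signature of a species-private duplication burst (recurrent
#' expansion); orthologous repeat correspondence gives 0.
#'
#' @param x A [RepeatDivergence-class] or symmetric distance matrix.
#' @param species Species label per unit (taken from `x` when it is a
#'   `RepeatDivergence`).
#' @return Named numeric vector of per-species scores in `[0, 1]`; `NA`
#'   for species with a single unit.
#' @export
recurrenceScore <- function(x, species = NULL) {
  if (is(x, "RepeatDivergence")) {
    m <- divergenceComponent(x, "nt")
    species <- unitSpecies(x)
  } else m <- x
  if (is.null(species) || length(species) != nrow(m))
    stop("species labels must be given, one per unit")
  if (length(unique(species)) < 2L) stop("need at least 2 species")
  n <- nrow(m)
  nn_same <- logical(n)
  for (i in seq_len(n)) {
    d <- m[i, -i]
    sp <- species[-i]
    mins <- which(d <= min(d) + 1e-12)
    # conservative tie-break: prefer a different-species neighbour
    nn_same[i] <- all(sp[mins] == species[i])
  }
  out <- vapply(unique(species), function(s) {
    idx <- species == s
    if (sum(idx) < 2L) return(NA_real_)
    mean(nn_same[idx])
  }, numeric(1))
  names(out) <- unique(species)
  out
}

#' Divergence regressions over repeat pairs and species
#'
#' Ordinary least squares fits of (i) nonsynonymous vs synonymous
#' pairwise differences, (ii) T+S count difference vs total nucleotide
#' differences, and (iii) total T+S residue count vs repeat copy number
#' per species. Under adaptive constraint on O-glycosylation density the
#' first regression tracks the mutational input (high R-squared) while
#' the second stays flat (R-squared near zero).
#'
#' @param pairs data.frame of pairwise records as from
#'   [divergencePairs()] (regressions i and ii). May be `NULL` to skip.
#' @param speciesSummary Optional data.frame with columns `copy_number`
#'   and `ts_total` per species (regression iii).
#' @return data.frame with rows per regression and columns `regression`,
#'   `slope`, `intercept`, `r_squared`, `n`. `r_squared` is `NA` when the
#'   response has zero variance; zero variance in the predictor is an
#'   error.
#' @export
divergenceRegressions <- function(pairs = NULL, speciesSummary = NULL) {
  fit1 <- function(y, x, label) {
    if (length(x) < 3L) stop("need at least 3 points for regression ", label)
    if (stats::var(x) == 0)
      stop("zero variance in predictor for regression ", label)
    co <- stats::coef(stats::lm(y ~ x))
    # simple OLS: R^2 is the squared correlation; undefined for a
    # zero-variance response
    r2 <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)^2
    data.frame(regression = label, slope = unname(co[2]),
               intercept = unname(co[1]), r_squared = r2,
               n = length(x), stringsAsFactors = FALSE)
  }
  out <- NULL
  if (!is.null(pairs)) {
    out <- rbind(out,
      fit1(pairs$nonsyn_diffs, pairs$syn_diffs, "nonsyn_vs_syn"),
      fit1(pairs$ts_count_diff, pairs$nt_diffs, "ts_diff_vs_nt"))
  }
  if (!is.null(speciesSummary)) {
    out <- rbind(out,
      fit1(speciesSummary$ts_total, speciesSummary$copy_number,
           "ts_total_vs_copy_number"))
  }
  if (is.null(out)) stop("nothing to regress")
  rownames(out) <- NULL
  out
}
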