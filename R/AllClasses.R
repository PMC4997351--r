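#' @import methods
#' @importFrom S4Vectors isConstant
NULL

#' RepeatAnnotation: in-frame tandem repeat units within a coding sequence
#'
#' Container for the location and sequence of full-length, frame-aligned
#' tandem repeat units detected within one coding sequence. Unit
#' coordinates follow the IRanges convention (1-based, closed); BED export
#' converts to 0-based half-open. A trailing partial copy (shorter than
#' one full unit) is kept separately and never counted as a unit.
#'
#' @slot sourceId Identifier of the source coding sequence.
#' @slot species Species label of the source sequence.
#' @slot unitLength Unit length in nucleotides (divisible by 3).
#' @slot units [IRanges::IRanges] of full unit coordinates, sorted.
#' @slot unitSeqs [Biostrings::DNAStringSet] of the unit sequences.
#' @slot partial [IRanges::IRanges] of length 0 or 1: trailing partial copy.
#'
#' @aliases RepeatAnnotation-class
#' @export
setClass("RepeatAnnotation",
  representation(
    sourceId = "character",
    species = "character",
    unitLength = "integer",
    units = "IRanges",
    unitSeqs = "DNAStringSet",
    partial = "IRanges"
  )
)

setValidity("RepeatAnnotation", function(object) {
  msg <- character()
  if (object@unitLength %% 3L != 0L)
    msg <- c(msg, "unitLength must be divisible by 3")
  n <- length(object@units)
  if (n != length(object@unitSeqs))
    msg <- c(msg, "units and unitSeqs must have equal length")
  if (n > 0) {
    if (any(IRanges::width(object@units) != object@unitLength))
      msg <- c(msg, "all full units must have width unitLength")
    st <- IRanges::start(object@units)
    if (is.unsorted(st))
      msg <- c(msg, "units must be sorted by start")
    if (n > 1 && any(st[-1] <= IRanges::end(object@units)[-n]))
      msg <- c(msg, "units must be non-overlapping")
    if (length(unique(st %% 3L)) > 1L)
      msg <- c(msg, "unit starts must share the CDS frame offset")
  }
  if (length(object@partial) > 1L)
    msg <- c(msg, "at most one trailing partial copy")
  if (length(msg)) msg else TRUE
})

#' Construct a RepeatAnnotation
#'
#' @param sourceId,species Identifiers for the source CDS.
#' @param unitLength Unit length in nucleotides.
#' @param units An [IRanges::IRanges] of unit coordinates (may be empty).
#' @param unitSeqs A [Biostrings::DNAStringSet] of unit sequences.
#' @param partial Optional [IRanges::IRanges] for a trailing partial copy.
#' @return A [RepeatAnnotation-class] object.
#' @export
RepeatAnnotation <- function(sourceId, species = NA_character_,
                             unitLength = 69L,
                             units = IRanges::IRanges(),
                             unitSeqs = Biostrings::DNAStringSet(),
                             partial = IRanges::IRanges()) {
  new("RepeatAnnotation", sourceId = as.character(sourceId),
      species = as.character(species), unitLength = as.integer(unitLength),
      units = units, unitSeqs = unitSeqs, partial = partial)
}

#' @describeIn RepeatAnnotation Number of full repeat units.
#' @param object,x A `RepeatAnnotation`.
#' @export
setGeneric("unitCount", function(x) standardGeneric("unitCount"))

#' @rdname RepeatAnnotation
#' @export
setMethod("unitCount", "RepeatAnnotation", function(x) length(x@units))

#' @rdname RepeatAnnotation
#' @export
setGeneric("unitRanges", function(x) standardGeneric("unitRanges"))

#' @rdname RepeatAnnotation
#' @export
setMethod("unitRanges", "RepeatAnnotation", function(x) x@units)

#' @rdname RepeatAnnotation
#' @export
setGeneric("unitSeqs", function(x) standardGeneric("unitSeqs"))

#' @rdname RepeatAnnotation
#' @export
setMethod("unitSeqs", "RepeatAnnotation", function(x) x@unitSeqs)

#' @rdname RepeatAnnotation
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname RepeatAnnotation
#' @export
setMethod("sourceId", "RepeatAnnotation", function(x) x@sourceId)

#' @rdname RepeatAnnotation
#' @export
setGeneric("repeatSpecies", function(x) standardGeneric("repeatSpecies"))

#' @rdname RepeatAnnotation
#' @export
setMethod("repeatSpecies", "RepeatAnnotation", function(x) x@species)

setMethod("show", "RepeatAnnotation", function(object) {
  cat("RepeatAnnotation for", object@sourceId,
      if (!is.na(object@species)) paste0("(", object@species, ")"), "\n")
  cat("  ", unitCount(object), "full unit(s) of", object@unitLength, "nt\n")
  if (unitCount(object) > 0) {
    st <- IRanges::start(object@units)
    en <- IRanges::end(object@units)
    cat("   spans", st[1], "-", en[length(en)], "\n")
  }
  if (length(object@partial) == 1L)
    cat("   trailing partial copy at",
        IRanges::start(object@partial), "-", IRanges::end(object@partial), "\n")
  invisible(object)
})

#' RepeatDivergence: pairwise divergence matrices over repeat units
#'
#' Symmetric, zero-diagonal matrices of pairwise divergence between repeat
#' units, labelled `Species_Index` with the index counting units 5' to 3'
#' within each source sequence. Nucleotide differences are Hamming
#' distances; synonymous/nonsynonymous components are Nei-Gojobori
#' pathway-averaged fractional counts, so `syn + nonsyn == nt` entrywise.
#'
#' @slot labels Unit labels (`Species_Index`).
#' @slot species Species label per unit.
#' @slot nt,syn,nonsyn,aa,ts Numeric matrices: nucleotide, synonymous,
#'   nonsynonymous, amino-acid differences and |T+S count| differences.
#'
#' @aliases RepeatDivergence-class
#' @export
setClass("RepeatDivergence",
  representation(
    labels = "character",
    species = "character",
    nt = "matrix",
    syn = "matrix",
    nonsyn = "matrix",
    aa = "matrix",
    ts = "matrix"
  )
)

setValidity("RepeatDivergence", function(object) {
  msg <- character()
  n <- length(object@labels)
  for (nm in c("nt", "syn", "nonsyn", "aa", "ts")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      msg <- c(msg, paste(nm, "matrix dimension mismatch"))
    else {
      if (any(abs(m - t(m)) > 1e-9)) msg <- c(msg, paste(nm, "not symmetric"))
      if (any(abs(diag(m)) > 1e-9)) msg <- c(msg, paste(nm, "nonzero diagonal"))
      if (any(m < -1e-9)) msg <- c(msg, paste(nm, "negative entries"))
    }
  }
  if (length(object@species) != n)
    msg <- c(msg, "species labels must match unit count")
  if (length(msg)) msg else TRUE
})

#' @describeIn RepeatDivergence Extract one component matrix.
#' @param x A `RepeatDivergence`.
#' @param component One of `"nt"`, `"syn"`, `"nonsyn"`, `"aa"`, `"ts"`.
#' @export
setGeneric("divergenceComponent",
           function(x, component = "nt") standardGeneric("divergenceComponent"))

#' @rdname RepeatDivergence
#' @export
setMethod("divergenceComponent", "RepeatDivergence", function(x, component = "nt") {
  component <- match.arg(component, c("nt", "syn", "nonsyn", "aa", "ts"))
  slot(x, component)
})

#' @rdname RepeatDivergence
#' @export
setGeneric("unitLabels", function(x) standardGeneric("unitLabels"))

#' @rdname RepeatDivergence
#' @export
setMethod("unitLabels", "RepeatDivergence", function(x) x@labels)

#' @rdname RepeatDivergence
#' @export
setGeneric("unitSpecies", function(x) standardGeneric("unitSpecies"))

#' @rdname RepeatDivergence
#' @export
setMethod("unitSpecies", "RepeatDivergence", function(x) x@species)

setMethod("show", "RepeatDivergence", function(object) {
  cat("RepeatDivergence over", length(object@labels), "units from",
      length(unique(object@species)), "species\n")
  cat("  mean pairwise nt differences:",
      round(mean(object@nt[upper.tri(object@nt)]), 3), "\n")
  invisible(object)
})

#' Long-format pair table from a RepeatDivergence
#'
#' @param x A [RepeatDivergence-class] object.
#' @return A data.frame with one row per unordered unit pair and columns
#'   `id_a`, `id_b`, `species_a`, `species_b`, `nt_diffs`, `syn_diffs`,
#'   `nonsyn_diffs`, `aa_diffs`, `ts_count_diff`.
#' @export
divergencePairs <- function(x) {
  stopifnot(is(x, "RepeatDivergence"))
  n <- length(x@labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(
    id_a = x@labels[idx[, 1]],
    id_b = x@labels[idx[, 2]],
    species_a = x@species[idx[, 1]],
    species_b = x@species[idx[, 2]],
    nt_diffs = x@nt[idx],
    syn_diffs = x@syn[idx],
    nonsyn_diffs = x@nonsyn[idx],
    aa_diffs = x@aa[idx],
    ts_count_diff = x@ts[idx],
    stringsAsFactors = FALSE
  )
}
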