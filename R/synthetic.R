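## Seed-reproducible synthetic-data generators with ground-truth sidecars.
## These emulate the raw inputs of a comparative mucin-repeat analysis
## (mammalian mucin CDS with in-frame
## 69-nt PTS-repeats, primate copy-number genotype panels, GTEx-like
## expression matrices) so that every pipeline stage is testable offline.

## codon pools: repeat units are T/S/P-biased (>= 40% T+S codons, the
## O-glycosylation signature); flanks are drawn from a disjoint low-TS pool
.TS_CODONS <- c("ACT", "ACC", "ACA", "ACG", "TCT", "TCC", "TCA", "AGC")
.P_CODONS <- c("CCT", "CCA", "CCG")
.OTHER_CODONS <- c("GCT", "GGT", "CAA", "GAA", "GTT")
.FLANK_CODONS <- c("GAT", "AAA", "CTG", "ATG", "TGG", "CGT", "GGC",
                   "GTG", "CAG")

.sampleUnitCodons <- function(nCodons) {
  pool <- c(.TS_CODONS, .P_CODONS, .OTHER_CODONS)
  w <- c(rep(2, length(.TS_CODONS)), rep(1.2, length(.P_CODONS)),
         rep(1, length(.OTHER_CODONS)))
  sample(pool, nCodons, replace = TRUE, prob = w)
}

.sampleFlank <- function(nCodons) {
  paste(sample(.FLANK_CODONS, nCodons, replace = TRUE), collapse = "")
}

## substitute at `pos` (1-based) avoiding stop codons; returns new base
.safeSubstitution <- function(chars, pos) {
  for (nt in sample(setdiff(BASES, chars[pos]))) {
    cand <- chars
    cand[pos] <- nt
    ci <- (pos - 1L) %/% 3L
    codon <- paste(cand[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (!.isStopCodon(codon)) return(nt)
  }
  NA_character_
}

#' Generate one coding sequence with planted in-frame tandem repeats
#'
#' Builds a CDS of `flankCodons` codons of low-T/S flank, `nUnits` copies
#' of a random T/S-rich unit (each copy optionally carrying its own
#' substitutions), and a matching 3' flank. Ground truth (unit
#' coordinates and copy number) is attached.
#'
#' @param nUnits Planted copy number (>= 2).
#' @param unitLength Unit length in nt (divisible by 3).
#' @param subsPerUnit Substitutions applied independently to each copy.
#'   Substitution positions avoid the first and last codon of each unit:
#'   together with flank codons drawn from a pool disjoint from the unit
#'   codon pool, this keeps the planted array boundaries
#'   phase-identifiable (a substitution in a boundary codon can make a
#'   phase-shifted annotation of the same array genuinely
#'   indistinguishable from the planted one).
#' @param flankCodons Codons of flank on each side.
#' @param seed Integer seed.
#' @return List with `cds` (character), `truth` (list: `nUnits`,
#'   `starts`, `ends` 1-based closed, `unitLength`, `baseUnit`).
#' @export
makeRepeatCds <- function(nUnits = 5L, unitLength = 69L, subsPerUnit = 0L,
                          flankCodons = 20L, seed = 1L) {
  stopifnot(nUnits >= 2L, unitLength %% 3L == 0L)
  if (subsPerUnit > unitLength %/% 2L)
    warning("substitution load may push units below detectable identity")
  set.seed(as.integer(seed))
  base <- paste(.sampleUnitCodons(unitLength %/% 3L), collapse = "")
  units <- vapply(seq_len(nUnits), function(i) {
    chars <- strsplit(base, "")[[1]]
    if (subsPerUnit > 0L) {
      for (pos in sample(4:(unitLength - 3L), subsPerUnit)) {
        nt <- .safeSubstitution(chars, pos)
        if (!is.na(nt)) chars[pos] <- nt
      }
    }
    paste(chars, collapse = "")
  }, "")
  flank5 <- .sampleFlank(flankCodons)
  flank3 <- .sampleFlank(flankCodons)
  starts <- nchar(flank5) + (seq_len(nUnits) - 1L) * unitLength + 1L
  list(
    cds = paste0(flank5, paste(units, collapse = ""), flank3),
    truth = list(nUnits = nUnits, starts = starts,
                 ends = starts + unitLength - 1L,
                 unitLength = unitLength, baseUnit = base)
  )
}

#' Generate an orthologous CDS family with known repeat history
#'
#' Evolves a T/S-rich repeat array along a dated species tree under
#' infinite-sites bookkeeping: every substitution event takes a unit
#' position never used before, so the pairwise nucleotide difference
#' between any two unit lineages equals the number of events separating
#' them. The ancestral array holds `nUnits` units (unit 1 is the base
#' unit; units 2..k each carry `ancestralDivergence` private events);
#' along every branch each unit independently gains `branchSubsPerUnit`
#' events. A species-private duplication burst can be planted on one tip:
#' its array is rewritten as `copies` duplicates of one source unit, each
#' new copy carrying `subs` fresh events, which produces the
#' species-private clustering signature of recurrent expansion.
#'
#' @param tree Ultrametric [ape::phylo]; branch lengths only set the
#'   topology/sharing structure here (event counts are per branch).
#' @param nUnits Ancestral repeat copy number.
#' @param ancestralDivergence Events separating each non-base ancestral
#'   unit from the base unit.
#' @param branchSubsPerUnit Events gained per unit per branch.
#' @param burst Optional list(`species`, `source`, `copies`, `subs`):
#'   rewrite that tip's array as a burst of duplications.
#' @param flankCodons Flank codons on each side (shared by all species).
#' @param unitLength Unit length in nt.
#' @param seed Integer seed.
#' @return List with `cds` (named [Biostrings::DNAStringSet]), `units`
#'   (named [Biostrings::DNAStringSet], labels `Species_Index`), and
#'   `truth` (list: `copyNumber`, `coords`, `eventSets`,
#'   `eventDistance`, `unitLength`, `flankLength`).
#' @export
makeCdsFamily <- function(tree = greatApeTree(), nUnits = 5L,
                          ancestralDivergence = 4L, branchSubsPerUnit = 1L,
                          burst = NULL, flankCodons = 20L, unitLength = 69L,
                          seed = 1L) {
  stopifnot(nUnits >= 2L, unitLength %% 3L == 0L)
  set.seed(as.integer(seed))
  U <- as.integer(unitLength)
  base_chars <- strsplit(paste(.sampleUnitCodons(U %/% 3L), collapse = ""),
                         "")[[1]]
  # infinite-sites position pool; boundary codons are spared so planted
  # unit coordinates stay phase-identifiable for detection round-trips
  pos_pool <- sample(4:(U - 3L))
  pool_i <- 0L
  event_pos <- integer()
  event_to <- character()
  ## an event = unused position + non-ancestral, non-stop-creating base
  newEvent <- function() {
    repeat {
      pool_i <<- pool_i + 1L
      if (pool_i > length(pos_pool))
        stop("substitution budget exceeds unit length; ",
             "lower divergence/substitution settings")
      p <- pos_pool[pool_i]
      nt <- .safeSubstitution(base_chars, p)
      if (!is.na(nt)) {
        event_pos[length(event_pos) + 1L] <<- p
        event_to[length(event_to) + 1L] <<- nt
        return(length(event_pos))
      }
    }
  }
  addEvents <- function(set, n) {
    for (i in seq_len(n)) set <- c(set, newEvent())
    set
  }
  # ancestral array: unit 1 is the base, others carry private events
  anc <- lapply(seq_len(nUnits), function(i) {
    if (i == 1L) integer() else addEvents(integer(), ancestralDivergence)
  })
  tree <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  arrays <- vector("list", ntip + tree$Nnode)
  arrays[[ntip + 1L]] <- anc
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    arrays[[child]] <- lapply(arrays[[parent]], addEvents,
                              n = branchSubsPerUnit)
  }
  tips <- stats::setNames(arrays[seq_len(ntip)], tree$tip.label)
  if (!is.null(burst)) {
    sp <- burst$species
    if (!sp %in% names(tips)) stop("burst species not a tree tip")
    src <- tips[[sp]][[if (is.null(burst$source)) 1L else burst$source]]
    copies <- if (is.null(burst$copies)) length(tips[[sp]]) else burst$copies
    subs <- if (is.null(burst$subs)) 1L else burst$subs
    tips[[sp]] <- c(list(src), lapply(seq_len(copies - 1L), function(i)
      addEvents(src, subs)))
  }
  unitSeq <- function(set) {
    chars <- base_chars
    chars[event_pos[set]] <- event_to[set]
    paste(chars, collapse = "")
  }
  flank5 <- .sampleFlank(flankCodons)
  flank3 <- .sampleFlank(flankCodons)
  labels <- unlist(lapply(names(tips), function(sp)
    paste0(sp, "_", seq_along(tips[[sp]]))))
  unit_seqs <- unlist(lapply(tips, function(a) vapply(a, unitSeq, "")))
  names(unit_seqs) <- labels
  cds <- vapply(tips, function(a)
    paste0(flank5, paste(vapply(a, unitSeq, ""), collapse = ""), flank3), "")
  coords <- lapply(tips, function(a) {
    st <- nchar(flank5) + (seq_along(a) - 1L) * U + 1L
    data.frame(start = st, end = st + U - 1L)
  })
  flat <- unlist(tips, recursive = FALSE)
  n <- length(flat)
  ed <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- length(union(flat[[i]], flat[[j]])) -
        length(intersect(flat[[i]], flat[[j]]))
      ed[i, j] <- ed[j, i] <- d
    }
  }
  list(
    cds = Biostrings::DNAStringSet(cds),
    units = Biostrings::DNAStringSet(unit_seqs),
    truth = list(
      copyNumber = vapply(tips, length, 1L),
      coords = coords,
      eventSets = stats::setNames(flat, labels),
      eventDistance = ed,
      unitLength = U,
      flankLength = nchar(flank5)
    )
  )
}

#' Default great-ape genotype configuration
#'
#' Allele sets mirror the observed haploid PTS-repeat copy numbers:
#' Human 5 or 6, Chimpanzee 5, Gorilla 4 or 5, Orangutan 6 or 7.
#'
#' @param n Individuals per species.
#' @return Named list of per-species configs (`alleles`, `n`).
#' @export
greatApeGenotypeConfig <- function(n = 4L) {
  list(
    Human = list(alleles = c(5, 6), n = n),
    Chimpanzee = list(alleles = 5, n = n),
    Gorilla = list(alleles = c(4, 5), n = n),
    Orangutan = list(alleles = c(6, 7), n = n)
  )
}

#' Generate a diploid copy-number genotype table
#'
#' Samples two alleles per individual uniformly from each species'
#' allele set. With `forceHet = TRUE` for a species (and exactly two
#' alleles) every individual is heterozygous, mimicking small
#' all-heterozygous panels.
#'
#' @param config Named list per species: `alleles` (non-empty numeric),
#'   `n` (individuals), optional `forceHet`.
#' @param seed Integer seed.
#' @return data.frame with columns `species`, `individual`, `allele1`,
#'   `allele2`.
#' @export
makeGenotypeTable <- function(config = greatApeGenotypeConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  rows <- lapply(names(config), function(sp) {
    cf <- config[[sp]]
    if (length(cf$alleles) == 0L) stop("empty allele set for ", sp)
    forceHet <- isTRUE(cf$forceHet)
    if (forceHet && length(cf$alleles) != 2L)
      stop("forceHet needs exactly two alleles for ", sp)
    draw <- function(k) cf$alleles[sample.int(length(cf$alleles), k,
                                              replace = TRUE)]
    a1 <- draw(cf$n)
    a2 <- if (forceHet) {
      vapply(a1, function(a) setdiff(cf$alleles, a)[1], numeric(1))
    } else draw(cf$n)
    data.frame(species = sp, individual = paste0(sp, "_", seq_len(cf$n)),
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a GTEx-like expression matrix with a planted specific cluster
#'
#' Gene-by-sample log-normal expression with one target tissue and many
#' other tissues. A contiguous block of genes is up-shifted by
#' `foldChange` in the target-tissue samples only, emulating a cluster of
#' tissue-specific genes at a known chromosomal location.
#'
#' @param nGenes Genes on the (single) simulated chromosome.
#' @param nTargetSamples Samples of the target tissue.
#' @param nOtherTissues Number of non-target tissues.
#' @param samplesPerOther Samples per non-target tissue.
#' @param clusterSize Planted cluster size in genes (0 disables).
#' @param clusterStart First gene of the cluster (default: centered).
#' @param foldChange Multiplicative up-shift in the target tissue.
#' @param meanlog,sdlogGene,sdlogNoise Log-normal baseline parameters:
#'   per-gene mean levels are `Lognormal(meanlog, sdlogGene)` and
#'   per-sample values scatter around them with `sdlogNoise`.
#' @param targetTissue Label of the target tissue.
#' @param chrom Chromosome label for all genes.
#' @param seed Integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `rpkm`, `rowData` columns `chrom`, `position`, `in_cluster`, and
#'   `colData` column `tissue`. Truth (cluster gene indices) is stored in
#'   `metadata(se)$truth`.
#' @export
makeExpressionMatrix <- function(nGenes = 2000L, nTargetSamples = 5L,
                                 nOtherTissues = 52L, samplesPerOther = 1L,
                                 clusterSize = 10L, clusterStart = NULL,
                                 foldChange = 5, meanlog = 1, sdlogGene = 1,
                                 sdlogNoise = 1,
                                 targetTissue = "minor_salivary_gland",
                                 chrom = "chr4", seed = 1L) {
  set.seed(as.integer(seed))
  if (clusterSize > nGenes) stop("cluster larger than the gene count")
  nSamples <- nTargetSamples + nOtherTissues * samplesPerOther
  tissues <- c(rep(targetTissue, nTargetSamples),
               rep(paste0("tissue_", seq_len(nOtherTissues)),
                   each = samplesPerOther))
  gene_mu <- stats::rnorm(nGenes, meanlog, sdlogGene)
  mat <- matrix(stats::rlnorm(nGenes * nSamples, meanlog = rep(gene_mu,
                nSamples), sdlog = sdlogNoise), nrow = nGenes)
  cluster <- integer(0)
  if (clusterSize > 0L) {
    if (is.null(clusterStart))
      clusterStart <- (nGenes - clusterSize) %/% 2L + 1L
    cluster <- seq(clusterStart, clusterStart + clusterSize - 1L)
    mat[cluster, tissues == targetTissue] <-
      mat[cluster, tissues == targetTissue] * foldChange
  }
  genes <- sprintf("gene_%05d", seq_len(nGenes))
  rownames(mat) <- genes
  colnames(mat) <- paste0("sample_", seq_len(nSamples))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat),
    rowData = S4Vectors::DataFrame(
      chrom = chrom, position = seq_len(nGenes) * 1000L,
      in_cluster = seq_len(nGenes) %in% cluster, row.names = genes),
    colData = S4Vectors::DataFrame(tissue = tissues,
                                   row.names = colnames(mat))
  )
  S4Vectors::metadata(se)$truth <- list(cluster = cluster,
                                        foldChange = foldChange,
                                        targetTissue = targetTissue)
  se
}
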