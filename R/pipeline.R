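#' Run the full synthetic-to-report analysis pipeline
#'
#' Orchestrates the package's stages on synthetic data with known ground
#' truth: (1) generate an orthologous CDS family with planted repeats,
#' (2) detect repeats per species and write BED/TSV annotations, (3)
#' build the pairwise divergence matrices, clustering and recurrence
#' scores, (4) run the random-walk neutrality test under the default
#' great-ape configuration, (5) run a small coalescent
#' observed-vs-null grid on a generated genotype table, (6) generate an
#' expression matrix and run the tissue-specificity window scan, and (7)
#' profile conservation over the synthetic protein alignment. All
#' outputs are plain TSV/JSON under `outDir`, together with a manifest
#' (seed, parameters, package version) from which the run can be
#' reproduced exactly.
#'
#' @param outDir Output directory (created if needed). Existing result
#'   files are only overwritten with `overwrite = TRUE`.
#' @param seed Integer seed; mandatory, every stochastic stage derives
#'   its stream from it.
#' @param config Optional named list overriding defaults: `rates`,
#'   `walkReps`, `thetas`, `coalescentReps`, `windowSize`, `quantile`,
#'   `maxCN`, `rootCN`, `nGenes`, `foldChange`, `clusterSize`.
#' @param overwrite Allow overwriting an existing manifest/outputs.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(outDir, seed, config = list(), overwrite = FALSE) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
    as.integer(seed))))
    stop("a global integer seed is required (pass seed = <int>)")
  seed <- as.integer(seed)
  defaults <- list(rates = c(0.5, 1, 1.5, 2), walkReps = 1000L,
                   thetas = c(0.2, 1, 5.5), coalescentReps = 100L,
                   windowSize = 15L, quantile = 0.01, maxCN = 12,
                   rootCN = 5L, nGenes = 600L, foldChange = 5,
                   clusterSize = 10L)
  cfg <- utils::modifyList(defaults, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outDir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("outputs already exist in ", outDir,
         "; pass overwrite = TRUE to replace them")
  message("stage 1/7: synthetic CDS family")
  fam <- makeCdsFamily(seed = seed)
  Biostrings::writeXStringSet(fam$cds, file.path(outDir, "family.fasta"))

  message("stage 2/7: repeat detection")
  ann <- lapply(names(fam$cds), function(sp)
    detectRepeats(as.character(fam$cds[[sp]]), sourceId = sp, species = sp))
  writeRepeatBed(ann, file.path(outDir, "repeats.bed"))
  writeUnitsTsv(ann, file.path(outDir, "repeat_units.tsv"))

  message("stage 3/7: divergence, clustering, recurrence")
  div <- divergenceMatrix(ann)
  writeDivergenceTsv(div, file.path(outDir, "divergence_nt.tsv"))
  rec <- recurrenceScore(div)
  utils::write.table(
    data.frame(species = names(rec), recurrence = unname(rec)),
    file.path(outDir, "recurrence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  message("stage 4/7: random-walk neutrality test")
  nt <- neutralityTest(rates = cfg$rates, reps = cfg$walkReps,
                       seed = seed + 1L)
  utils::write.table(nt, file.path(outDir, "walk_neutrality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("stage 5/7: coalescent observed-vs-null grid")
  geno <- makeGenotypeTable(seed = seed + 2L)
  utils::write.table(geno, file.path(outDir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  model <- popModel(tree = greatApeTree(),
                    samples = table(expandGenotypes(geno)$species),
                    Ne = c(Chimpanzee = 2e4), NeRef = 1e4)
  grid <- obsVsNullGrid(geno, model, thetas = cfg$thetas,
                        reps = cfg$coalescentReps,
                        groups = list(great_apes = names(fam$cds)),
                        rootCN = cfg$rootCN, maxCN = cfg$maxCN,
                        seed = seed + 3L)
  utils::write.table(
    data.frame(comparison = rownames(grid$ratio), grid$ratio,
               check.names = FALSE),
    file.path(outDir, "cn_variation_ratio.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  message("stage 6/7: expression window scan")
  se <- makeExpressionMatrix(nGenes = cfg$nGenes,
                             clusterSize = cfg$clusterSize,
                             foldChange = cfg$foldChange, seed = seed + 4L)
  p <- specificityPvalues(se, target = "minor_salivary_gland")
  calls <- callSpecific(p, quantile = cfg$quantile)
  counts <- windowScan(calls$specific, windowSize = cfg$windowSize)
  truth <- S4Vectors::metadata(se)$truth
  focal <- rownames(se)[truth$cluster[1L]]
  report <- scanReport(counts, calls, focal = focal,
                       windowSize = cfg$windowSize)
  utils::write.table(calls, file.path(outDir, "specificity_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(window = names(counts), count = as.integer(counts)),
    file.path(outDir, "window_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  message("stage 7/7: conservation profile")
  prot <- Biostrings::translate(fam$cds)
  profile <- conservationProfile(prot)
  utils::write.table(profile, file.path(outDir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flank_aa <- fam$truth$flankLength %/% 3L
  unit_aa <- fam$truth$unitLength %/% 3L
  n_units <- min(fam$truth$copyNumber)
  segs <- data.frame(
    name = c("flank5", "PTS_repeats", "flank3"),
    start = c(1L, flank_aa + 1L, flank_aa + n_units * unit_aa + 1L),
    end = c(flank_aa, flank_aa + n_units * unit_aa,
            flank_aa + n_units * unit_aa + flank_aa))
  segcons <- segmentConservation(profile, segs)
  utils::write.table(
    data.frame(segment = names(segcons), mean_score = unname(segcons)),
    file.path(outDir, "segment_conservation.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "mucinEvol",
    version = as.character(utils::packageVersion("mucinEvol")),
    seed = seed,
    config = cfg
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(family = fam, annotations = ann, divergence = div,
                 recurrence = rec, neutrality = nt, grid = grid,
                 calls = calls, windowCounts = counts, scan = report,
                 conservation = profile, segments = segcons,
                 manifest = manifest))
}
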