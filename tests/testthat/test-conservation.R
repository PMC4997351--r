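# Jensen-Shannon conservation profiling and segment dN/dS summaries.

test_that("JSD column scores hit their closed-form anchors", {
  # column distribution equal to the background scores 0
  bg <- stats::setNames(rep(0.05, 20), strsplit("ARNDCQEGHILKMFPSTWYV",
                                                "")[[1]])
  col <- rep(names(bg), times = 5)   # empirical = uniform = background
  expect_equal(jsdColumnScore(col, background = "uniform",
                              pseudocount = 1e-12), 0, tolerance = 1e-6)
  # point mass vs uniform background, computed directly
  m <- (1 + 0.05) / 2
  kl1 <- log2(1 / m)
  kl2 <- 0.05 * log2(0.05 / m) + 19 * 0.05 * log2(0.05 / 0.025)
  expect_equal(jsdColumnScore(rep("W", 10), background = "uniform",
                              pseudocount = 1e-12),
               0.5 * (kl1 + kl2), tolerance = 1e-6)
})

test_that("JSD scores are bounded and respect the gap threshold", {
  set.seed(8)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:300) {
    col <- sample(aas, sample(3:12, 1), replace = TRUE)
    s <- jsdColumnScore(col)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
  gappy <- c("A", "A", "-", "-", "-")   # 60% gaps
  expect_true(is.na(jsdColumnScore(gappy, gapThreshold = 0.3)))
  expect_false(is.na(jsdColumnScore(gappy, gapThreshold = 0.7)))
  expect_true(is.na(jsdColumnScore(character(0))))
})

test_that("JSD is invariant under residue relabelling of column and background", {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  perm <- stats::setNames(rev(aas), aas)
  set.seed(9)
  bg <- stats::setNames(as.numeric(stats::runif(20, 0.5, 2)), aas)
  bg <- bg / sum(bg)
  for (i in 1:20) {
    col <- sample(aas, 8, replace = TRUE)
    bg_perm <- stats::setNames(bg, unname(perm[names(bg)]))
    expect_equal(jsdColumnScore(col, background = bg),
                 jsdColumnScore(unname(perm[col]), background = bg_perm),
                 tolerance = 1e-12)
  }
})

test_that("segment means follow the per-column profile", {
  prof <- data.frame(column = 1:10,
                     score = c(rep(0.2, 5), rep(0.8, 5)),
                     gap_fraction = 0)
  segs <- data.frame(name = c("lo", "hi"), start = c(1, 6), end = c(5, 10))
  m <- segmentConservation(prof, segs)
  expect_equal(unname(m), c(0.2, 0.8))
  prof$score[6:10] <- NA
  m2 <- segmentConservation(prof, segs)
  expect_true(is.na(m2[["hi"]]))
  expect_error(segmentConservation(prof, data.frame(name = "x", start = 3,
                                                    end = 40)),
               "within the alignment")
})

test_that("a conserved block outscores a diverged block", {
  set.seed(10)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  conserved <- strrep("MKTLAEQ", 2)
  seqs <- vapply(1:6, function(i)
    paste0(conserved, paste(sample(aas, 14, replace = TRUE),
                            collapse = "")), "")
  prof <- conservationProfile(seqs)
  segs <- data.frame(name = c("conserved", "diverged"),
                     start = c(1, 15), end = c(14, 28))
  m <- segmentConservation(prof, segs)
  expect_gt(m[["conserved"]], m[["diverged"]])
})

test_that("segment NS ratios behave on constructed codon alignments", {
  # purely synonymous segment scores 0; identical segment is undefined
  aln <- c(s1 = "GGTGCTAAAACT", s2 = "GGCGCAAAAACT", s3 = "GGAGCGAAAACT")
  segs <- data.frame(name = c("syn", "mixed", "same"),
                     start = c(1, 2, 3), end = c(1, 2, 4))
  r <- segmentNsRatio(aln, segs, normalize = "none", exclude = NULL)
  expect_equal(unname(r[["syn"]]), 0)
  expect_true(is.na(r[["same"]]))
  # third-position (fourfold) variation vs first-position variation
  third <- c(a = "GGTGGTGGT", b = "GGCGGAGGG")
  first <- c(a = "CTTACTGAT", b = "ATTCCTGAC")
  s1 <- segmentNsRatio(third, data.frame(name = "x", start = 1, end = 3),
                       normalize = "none", exclude = NULL)
  s2 <- segmentNsRatio(first, data.frame(name = "x", start = 1, end = 3),
                       normalize = "none", exclude = NULL)
  expect_lt(s1[["x"]], s2[["x"]])
})

test_that("adding nonsynonymous change never lowers the segment ratio", {
  set.seed(11)
  base <- c(s1 = "ACTCCTGCTAAAGGT", s2 = "ACCCCAGCCAAAGGC")
  seg <- data.frame(name = "x", start = 1, end = 5)
  r0 <- segmentNsRatio(base, seg, normalize = "none", exclude = NULL)
  worse <- base
  substr(worse["s2"], 7, 7) <- "T"  # GCC -> TCC, Ala -> Ser
  r1 <- segmentNsRatio(worse, seg, normalize = "none", exclude = NULL)
  expect_gte(r1[["x"]], r0[["x"]])
})

test_that("segment NS ratios agree with a brute-force implementation", {
  set.seed(12)
  pool <- senseCodons()
  for (trial in 1:5) {
    nseq <- sample(3:5, 1)
    ncod <- sample(5:10, 1)
    base <- sample(pool, ncod, replace = TRUE)
    seqs <- vapply(seq_len(nseq), function(i) {
      cods <- base
      idx <- sample(ncod, 2)
      cods[idx] <- sample(pool, 2)
      paste(cods, collapse = "")
    }, "")
    names(seqs) <- paste0("s", seq_len(nseq))
    seg <- data.frame(name = "all", start = 1, end = ncod)
    ours <- segmentNsRatio(seqs, seg, normalize = "none", exclude = NULL)
    ref <- ngSegmentOracle(seqs, seq_len(ncod))
    if (is.na(ref)) expect_true(is.na(ours[["all"]]))
    else expect_equal(unname(ours[["all"]]), ref, tolerance = 1e-9)
  }
})

test_that("PTS-like segments are excluded and normalization modes differ", {
  aln <- c(s1 = "GGTGCTAAAACTACT", s2 = "GGCACAAAAACTTCT")
  segs <- data.frame(name = c("flank", "PTS_repeats", "tail"),
                     start = c(1, 3, 5), end = c(2, 4, 5))
  r <- segmentNsRatio(aln, segs)
  expect_false("PTS_repeats" %in% names(r))
  raw <- segmentNsRatio(aln, segs, normalize = "none")
  expect_equal(names(raw), c("flank", "tail"))
})
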