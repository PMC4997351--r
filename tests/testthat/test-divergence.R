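# Pairwise divergence partitioning, matrices, clustering, recurrence and
# regressions.

test_that("tsFraction counts T and S residues, excluding gaps", {
  expect_equal(tsFraction("TSTS"), 1)
  expect_equal(tsFraction("PTSTSAP"), 4 / 7)
  expect_equal(tsFraction("AAAA"), 0)
  expect_equal(tsFraction("T-S-"), 1)   # gaps out of the denominator
  expect_error(tsFraction("----"), "all-gap")
  expect_error(tsFraction(""), "all-gap")
})

test_that("pairwiseDivergence partitions the Hamming distance", {
  r <- pairwiseDivergence(strrep("ACT", 23), strrep("ACT", 23))
  expect_equal(r$nt_diffs, 0)
  expect_equal(r$syn_diffs + r$nonsyn_diffs, 0)
  r <- pairwiseDivergence("GCT", "GCC")
  expect_equal(r$nt_diffs, 1)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$nonsyn_diffs, 0)
  expect_equal(r$aa_diffs, 0)
  r <- pairwiseDivergence("TTT", "GTA")
  expect_equal(r$nt_diffs, 2)
  expect_equal(r$syn_diffs, 0.5)
  expect_equal(r$nonsyn_diffs, 1.5)
  expect_equal(r$aa_diffs, 1)
  # T vs S leaves the T+S count unchanged; T vs A changes it by one
  expect_equal(pairwiseDivergence("ACTACT", "TCTACT")$ts_count_diff, 0)
  expect_equal(pairwiseDivergence("ACTACT", "GCTACT")$ts_count_diff, 1)
  expect_error(pairwiseDivergence("ACT", "ACTACT"), "unequal")
  expect_warning(pairwiseDivergence("TAAACT", "TAAACG"), "stop")
})

test_that("divergence records are symmetric and close the partition", {
  set.seed(21)
  pool <- senseCodons()
  for (i in 1:25) {
    a <- paste(sample(pool, 8, replace = TRUE), collapse = "")
    b <- paste(sample(pool, 8, replace = TRUE), collapse = "")
    ab <- pairwiseDivergence(a, b)
    ba <- pairwiseDivergence(b, a)
    expect_equal(ab$syn_diffs + ab$nonsyn_diffs, ab$nt_diffs,
                 tolerance = 1e-9)
    expect_equal(ab[c("nt_diffs", "syn_diffs", "nonsyn_diffs",
                      "aa_diffs", "ts_count_diff")],
                 ba[c("nt_diffs", "syn_diffs", "nonsyn_diffs",
                      "aa_diffs", "ts_count_diff")])
  }
})

test_that("divergenceMatrix is symmetric, zero-diagonal, labelled, metric", {
  u <- strrep("ACTCCT", 6)
  u3 <- sub("^ACTCCT", "ACGCCG", u)  # two changed sites
  m <- divergenceMatrix(c(Sp1_1 = u, Sp1_2 = u, Sp2_1 = u3))
  nt <- divergenceComponent(m, "nt")
  expect_equal(nt, t(nt))
  expect_equal(diag(nt), c(Sp1_1 = 0, Sp1_2 = 0, Sp2_1 = 0))
  expect_equal(sort(nt[upper.tri(nt)]), c(0, 2, 2))
  expect_equal(unitLabels(m), c("Sp1_1", "Sp1_2", "Sp2_1"))
  # triangle inequality on a larger random family
  fam <- makeCdsFamily(seed = 31)
  big <- divergenceComponent(divergenceMatrix(fam$units), "nt")
  n <- nrow(big)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(big[i, j], big[i, k] + big[k, j] + 1e-9)
  }
})

test_that("sidecar mutation counts equal nt differences (infinite sites)", {
  fam <- makeCdsFamily(seed = 77)
  m <- divergenceMatrix(fam$units)
  expect_equal(divergenceComponent(m, "nt"), fam$truth$eventDistance)
})

test_that("clustering joins identical pairs first; outliers merge last", {
  m <- matrix(10, 4, 4)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  rownames(m) <- colnames(m) <- paste0("u", 1:4)
  cl <- clusterRepeats(m, k = 2)
  expect_equal(cl$tree$height[1:2], c(0, 0))
  expect_equal(unname(cl$clusters), c(1, 1, 2, 2))
  m2 <- matrix(2, 5, 5); diag(m2) <- 0
  m2[5, ] <- m2[, 5] <- 50; m2[5, 5] <- 0
  rownames(m2) <- colnames(m2) <- paste0("u", 1:5)
  tr <- clusterRepeats(m2)$tree
  expect_true(-5 %in% tr$merge[nrow(tr$merge), ])  # outlier joins last
  expect_error(clusterRepeats(matrix(0, 1, 1)), "at least 2")
})

test_that("recurrence score separates bursts from orthologous arrays", {
  orth <- makeCdsFamily(seed = 5)
  sc <- recurrenceScore(divergenceMatrix(orth$units))
  expect_equal(unname(sc[c("Human", "Chimpanzee", "Gorilla", "Orangutan")]),
               c(0, 0, 0, 0))
  burst <- makeCdsFamily(burst = list(species = "Orangutan", copies = 5,
                                      subs = 1), seed = 5)
  sb <- recurrenceScore(divergenceMatrix(burst$units))
  expect_equal(unname(sb[["Orangutan"]]), 1)
  expect_equal(unname(sb[c("Human", "Chimpanzee", "Gorilla")]), c(0, 0, 0))
  # species with a single unit gets NA
  m <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3)
  sc1 <- recurrenceScore(m, species = c("A", "A", "B"))
  expect_true(is.na(sc1[["B"]]))
})

test_that("regressions recover collinear fits and flag degenerate ones", {
  pairs <- data.frame(syn_diffs = 1:10, nonsyn_diffs = 2 * (1:10),
                      nt_diffs = 3 * (1:10), ts_count_diff = rep(1, 10))
  fit <- divergenceRegressions(pairs)
  r1 <- fit[fit$regression == "nonsyn_vs_syn", ]
  expect_equal(r1$slope, 2)
  expect_equal(r1$r_squared, 1)
  r2 <- fit[fit$regression == "ts_diff_vs_nt", ]
  expect_equal(r2$slope, 0)
  expect_true(is.na(r2$r_squared))   # constant response: undefined R^2
  expect_error(
    divergenceRegressions(data.frame(syn_diffs = rep(1, 5),
                                     nonsyn_diffs = 1:5,
                                     nt_diffs = rep(2, 5),
                                     ts_count_diff = 1:5)),
    "zero variance in predictor")
  sp <- data.frame(copy_number = c(2, 4, 6, 8), ts_total = c(20, 41, 59, 82))
  f3 <- divergenceRegressions(speciesSummary = sp)
  expect_gt(f3$r_squared, 0.99)
})

test_that("TS-preserving mutations decouple TS differences from distance", {
  # units diverge by synonymous and TS-neutral changes; occasional
  # TS-toggling substitutions add response variance unrelated to distance
  set.seed(55)
  base <- strsplit(strrep("ACTCCTTCAGCT", 6), "")[[1]]  # 72 nt, TS-rich
  syn_pos <- seq(3, 72, by = 3)
  units <- lapply(1:30, function(i) {
    u <- base
    for (p in sample(syn_pos, sample(1:8, 1))) {
      cod <- paste(u[(p - 2):p], collapse = "")
      alt <- c(ACT = "ACC", CCT = "CCA", TCA = "TCT", GCT = "GCC",
               ACC = "ACA", CCA = "CCG", TCT = "TCC", GCC = "GCA")[cod]
      if (!is.na(alt)) u[(p - 2):p] <- strsplit(alt[[1]], "")[[1]]
    }
    if (runif(1) < 0.3) u[1:3] <- strsplit("GCA", "")[[1]]  # T -> A toggle
    paste(u, collapse = "")
  })
  names(units) <- paste0("S_", 1:30)
  m <- divergenceMatrix(unlist(units))
  fit <- divergenceRegressions(divergencePairs(m))
  expect_lt(fit[fit$regression == "ts_diff_vs_nt", "r_squared"], 0.2)
})
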