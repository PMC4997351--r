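# Multispecies coalescent with stepwise copy-number mutation.

test_that("theta scaling follows 4 Ne mu", {
  expect_equal(thetaFromK(1), 1)
  expect_equal(thetaFromK(5.5), 5.5)
  expect_equal(thetaFromK(1, Ne = 2e4), 2)
  expect_equal(thetaFromK(0.2), 0.2)
})

test_that("single-population genealogies match coalescent closed forms", {
  m2 <- popModel(species = "A", samples = c(A = 2))
  set.seed(10)
  tmrca <- replicate(4000, max(simulateGenealogy(m2)$nodeTime))
  # E[T2] = 1 in units of 4 Ne generations; Var[T2] = 1
  expect_lt(abs(mean(tmrca) - 1), 3 * sqrt(1 / 4000))
  m10 <- popModel(species = "A", samples = c(A = 10))
  set.seed(11)
  tl <- replicate(2500, simulateGenealogy(m10)$totalLength)
  expected <- sum(2 / (1:9))
  expect_lt(abs(mean(tl) - expected), 3 * sd(tl) / sqrt(2500))
})

test_that("no cross-population coalescence precedes the divergence time", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  mod <- popModel(tree = tr, samples = c(A = 3, B = 3))
  # 5 Myr at 25-year generations and Ne_ref 1e4 is 5 coalescent units
  for (s in 1:10) {
    g <- simulateGenealogy(mod, seed = s)
    anc <- function(i) {
      out <- integer()
      while (g$parent[i] > 0L) { i <- g$parent[i]; out <- c(out, i) }
      out
    }
    for (i in which(g$species == "A")) {
      for (j in which(g$species == "B")) {
        mrca <- intersect(anc(i), anc(j))[1]
        expect_gte(g$nodeTime[mrca], 5)
      }
    }
  }
})

test_that("mutation dropping follows ms scaling", {
  m2 <- popModel(species = "A", samples = c(A = 2))
  set.seed(12)
  # theta -> 0 limit: essentially never a mutation
  g <- simulateGenealogy(m2)
  expect_equal(sum(dropMutations(g, 1e-9)), 0)
  # E[pairwise mutations] = theta
  set.seed(13)
  counts <- replicate(4000, {
    g <- simulateGenealogy(m2)
    sum(dropMutations(g, 2))
  })
  expect_lt(abs(mean(counts) - 2), 3 * sd(counts) / sqrt(4000))
  # doubling theta doubles the mean count on a fixed genealogy
  g <- simulateGenealogy(m2, seed = 14)
  set.seed(15)
  lo <- replicate(3000, sum(dropMutations(g, 1)))
  hi <- replicate(3000, sum(dropMutations(g, 2)))
  expect_lt(abs(mean(hi) - 2 * mean(lo)),
            3 * sqrt(var(hi) / 3000 + 4 * var(lo) / 3000))
})

test_that("stepwise states keep the martingale and dispersion anchors", {
  m2 <- popModel(species = "A", samples = c(A = 2))
  # zero mutations leave every tip at the root state
  set.seed(15)
  g <- simulateGenealogy(m2)
  mc <- dropMutations(g, 1e-9)
  expect_equal(stepwiseCopyNumber(g, mc, rootCN = 7)$cn, c(7, 7))
  # E[(CN_i - CN_j)^2] = theta for two samples in one population
  set.seed(16)
  d2 <- replicate(4000, {
    g <- simulateGenealogy(m2)
    cn <- stepwiseCopyNumber(g, dropMutations(g, 2), rootCN = 25)$cn
    diff(cn)^2
  })
  expect_lt(abs(mean(d2) - 2), 3 * sd(d2) / sqrt(4000))
  # martingale: E[CN] = root (root far from the 0 clip)
  set.seed(17)
  mcn <- replicate(3000, {
    g <- simulateGenealogy(m2)
    mean(stepwiseCopyNumber(g, dropMutations(g, 1), rootCN = 25)$cn)
  })
  expect_lt(abs(mean(mcn) - 25), 3 * sd(mcn) / sqrt(3000))
})

test_that("truncation selection rejects and records as specified", {
  mod <- popModel(species = "A", samples = c(A = 4))
  # tiny theta: nothing rejected, stream equals the unselected stream
  s1 <- simulateCopyNumbers(mod, theta = 0.01, reps = 30, rootCN = 5,
                            maxCN = 12, seed = 7)
  s2 <- simulateCopyNumbers(mod, theta = 0.01, reps = 30, rootCN = 5,
                            maxCN = Inf, seed = 7)
  expect_equal(attr(s1, "acceptance"), 1)
  expect_identical(s1$cn, s2$cn)
  # max_cn equal to root: every accepted replicate stays at or below it
  s3 <- simulateCopyNumbers(mod, theta = 3, reps = 30, rootCN = 5,
                            maxCN = 5, seed = 8)
  expect_true(all(s3$cn <= 5))
  expect_lt(attr(s3, "acceptance"), 1)
  # determinism including rejection history
  s4 <- simulateCopyNumbers(mod, theta = 3, reps = 30, rootCN = 5,
                            maxCN = 5, seed = 8)
  expect_identical(s3, s4)
})

test_that("variation summaries compute within and between components", {
  df <- data.frame(species = c("A", "A", "B", "B"), cn = c(4, 6, 5, 5))
  vs <- variationSummary(df, groups = list(AB = c("A", "B")))
  expect_equal(unname(vs$within["A"]), 2)
  expect_equal(unname(vs$within["B"]), 0)
  expect_equal(unname(vs$between["AB"]), 0)  # both means are 5
  expect_error(variationSummary(df, groups = list(solo = "A")),
               ">= 2 species")
  expect_error(variationSummary(data.frame(species = c("A", "B"),
                                           cn = c(1, 2))),
               "at least 2 haplotypes")
  # pooled alternative
  vp <- variationSummary(df, groups = list(AB = c("A", "B")), pooled = TRUE)
  expect_equal(unname(vp$between["AB"]), var(c(4, 6, 5, 5)))
})

test_that("within-species variation grows with theta", {
  m6 <- popModel(species = "A", samples = c(A = 6))
  meanWithin <- function(theta) {
    set.seed(20)
    mean(replicate(500, {
      g <- simulateGenealogy(m6)
      var(stepwiseCopyNumber(g, dropMutations(g, theta), rootCN = 25)$cn)
    }))
  }
  v <- vapply(c(0.2, 1, 5.5), meanWithin, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("observed-vs-null ratio is near 1 under self-consistency", {
  mod <- popModel(species = "A", samples = c(A = 6))
  set.seed(30)
  ratios <- vapply(1:10, function(i) {
    g <- simulateGenealogy(mod)
    obs <- stepwiseCopyNumber(g, dropMutations(g, 1), rootCN = 5)
    res <- obsVsNullGrid(obs, mod, thetas = 1, reps = 120, rootCN = 5,
                         maxCN = Inf, seed = 100 + i)
    res$ratio["within_A", 1]
  }, numeric(1))
  gm <- exp(mean(log(pmax(ratios, 0.02))))
  expect_gt(gm, 0.5)
  expect_lt(gm, 2)
})

test_that("ratio cells fall as theta grows for a fixed observation", {
  obs <- data.frame(species = "A", individual = paste0("i", 1:3),
                    allele1 = c(5, 5, 6), allele2 = c(5, 6, 6))
  mod <- popModel(species = "A", samples = c(A = 6))
  res <- obsVsNullGrid(obs, mod, thetas = c(0.2, 1, 5.5), reps = 150,
                       seed = 77)
  expect_true(all(diff(res$ratio["within_A", ]) < 0))
})

test_that("genotype tables expand to haplotypes and read back from TSV", {
  geno <- makeGenotypeTable(seed = 2)
  hap <- expandGenotypes(geno)
  expect_equal(nrow(hap), 2 * nrow(geno))
  expect_true(all(hap$cn[hap$species == "Chimpanzee"] == 5))
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(geno, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(readGenotypeTable(tmp), geno)
})
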