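# Copy-number random walk along the dated great-ape tree.

test_that("zero rate leaves every tip at the ancestral state", {
  st <- simulateWalk(greatApeTree(), rate = 0, reps = 20, seed = 1)
  expect_true(all(st == 5))
  expect_equal(colnames(st), c("Human", "Chimpanzee", "Gorilla",
                               "Orangutan"))
})

test_that("terminal states obey the parity and range forced by the rate", {
  # 11 steps of +/-2 from 5 without flooring: odd values in [-17, 27]
  st <- simulateWalk(greatApeTree(), rate = 2, reps = 500, floor = -Inf,
                     seed = 2)
  expect_true(all(st %% 2 == 1))
  expect_true(all(st >= -17 & st <= 27))
  # flooring keeps states non-negative
  stf <- simulateWalk(greatApeTree(), rate = 2, reps = 500, seed = 2)
  expect_true(all(stf >= 0))
})

test_that("lineages share history until divergence", {
  st <- simulateWalk(greatApeTree(), rate = 1, reps = 400, floor = -Inf,
                     seed = 3)
  # Human and Chimpanzee share 6 of 11 steps: differ by at most 10
  expect_true(all(abs(st[, "Human"] - st[, "Chimpanzee"]) <= 10))
  # shared drift makes sister covariances exceed distant ones
  expect_gt(cov(st[, "Human"], st[, "Chimpanzee"]),
            cov(st[, "Human"], st[, "Orangutan"]))
  expect_gt(cov(st[, "Human"], st[, "Gorilla"]),
            cov(st[, "Human"], st[, "Orangutan"]))
})

test_that("martingale mean and variance law hold within 3 SE", {
  tr <- ape::read.tree(text = "(A:8,B:8);")
  st <- simulateWalk(tr, ancestral = 5, rate = 1, reps = 4000,
                     floor = -Inf, seed = 4)
  # E[terminal] = ancestral; Var = steps * rate^2 = 8
  se_mean <- sqrt(8 / 4000)
  expect_lt(abs(mean(st[, "A"]) - 5), 3 * se_mean)
  se_var <- sqrt(2 * 64 / 3999)
  expect_lt(abs(var(st[, "A"]) - 8), 3 * se_var)
})

test_that("identical seed and config reproduce states bit for bit", {
  a <- simulateWalk(greatApeTree(), rate = 1.5, reps = 50, seed = 11)
  b <- simulateWalk(greatApeTree(), rate = 1.5, reps = 50, seed = 11)
  expect_identical(a, b)
  expect_error(simulateWalk(greatApeTree(), step = 2, seed = 1),
               "multiple of step")
  expect_error(simulateWalk(ape::read.tree(text = "(A:1,B:2);"), seed = 1),
               "ultrametric")
})

test_that("variation statistics match direct formulas", {
  expect_equal(variationStatistic(c(5, 5, 5, 5)), 0)
  expect_equal(variationStatistic(c(5, 6, 5, 4)), 2 / 3)
  expect_equal(variationStatistic(c(6, 5, 4, 7)), 5 / 3)
  expect_error(variationStatistic(5), "at least 2")
})

test_that("observed variation sets enumerate allele combinations", {
  expect_length(observedVariationSet(greatApeObservedStates()), 8L)
  expect_length(observedVariationSet(list(A = 1, B = 2, C = 3)), 1L)
  v <- observedVariationSet(list(A = c(1, 3), B = c(1, 3)))
  expect_equal(sort(v), c(0, 0, 2, 2))
  expect_error(observedVariationSet(list(A = numeric(0), B = 1)),
               "at least one")
})

test_that("neutrality test is calibrated when observations are neutral", {
  # draw the observation from the simulation itself: p should be uniform
  tr <- greatApeTree()
  set.seed(99)
  ps <- vapply(1:120, function(i) {
    obs_states <- simulateWalk(tr, rate = 1, reps = 1, floor = -Inf,
                               seed = 5000 + i)[1, ]
    sims <- simulateWalk(tr, rate = 1, reps = 200, floor = -Inf,
                         seed = 9000 + i)
    rankSumTest(variationStatistic(obs_states),
                apply(sims, 1, variationStatistic), "less")$p.value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("direction check: overdispersed observations give p near 1", {
  nt <- neutralityTest(obs = list(Human = 1, Chimpanzee = 1, Gorilla = 1,
                                  Orangutan = 25),
                       rates = 1, reps = 300, seed = 8)
  expect_gt(nt$p_value, 0.95)
})

test_that("observed states round-trip through the TSV reader", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("tip\talleles", "Human\t5,6", "Chimpanzee\t5",
               "Gorilla\t4,5", "Orangutan\t6,7"), tmp)
  obs <- readObservedStates(tmp)
  expect_equal(obs, greatApeObservedStates())
})
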