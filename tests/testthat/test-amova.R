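test_that("hamming distance counts differing sites", {
  expect_equal(hammingDistance(rep(1, 7), rep(1, 7)), 0)
  expect_equal(hammingDistance(rep(1, 7), rep(0, 7)), 7)
  expect_equal(hammingDistance(c("M","U","M","M","M","U","M"),
                               rep("M", 7)), 2)
  expect_error(hammingDistance(c(1, 0), c(1, 0, 1)), "lengths differ")
  expect_error(hammingDistance(c(1, NA), c(1, 0)), "complete")
})

test_that("decomposition matches the independent centroid-based oracle exactly", {
  set.seed(2024)
  for (rep in 1:25) {
    hs <- randomHaplotypeSet()
    res <- amovaDecompose(hs)
    orc <- amovaOracle(hs$h, hs$fish, hs$class)
    expect_equal(res@ss[names(orc$ss)], orc$ss, tolerance = 1e-9)
    expect_equal(res@sigma2, orc$sigma2, tolerance = 1e-9)
    expect_equal(res@phi, orc$phi, tolerance = 1e-9)
    # SS additivity, exact
    expect_equal(res@ss[["total"]],
                 sum(res@ss[c("among_groups", "among_fish_within_groups",
                              "within_fish")]),
                 tolerance = 1e-12)
  }
})

test_that("complete fixation gives Phi_ST = 1 and duplicated groups Phi_CT = 0", {
  # two groups, one fish each, clones all-M vs all-U: no within variation
  hs1 <- structure(list(
    h = rbind(matrix(1L, 5, 7), matrix(0L, 5, 7)),
    fish = rep(c("f1", "f2"), each = 5),
    class = rep(c("A", "B"), each = 5), locus = "all"),
    class = "HaplotypeSet")
  r1 <- amovaDecompose(hs1)
  expect_equal(r1@phi[["phi_st"]], 1)
  expect_equal(r1@phi[["phi_ct"]], 1)
  # one group duplicated into two identical groups: no between-group variance
  set.seed(3)
  block <- matrix(rbinom(40 * 4, 1, 0.5), 40, 4)
  hs2 <- structure(list(
    h = rbind(block, block),
    fish = c(rep(paste0("a", 1:4), each = 10), rep(paste0("b", 1:4), each = 10)),
    class = rep(c("A", "B"), each = 40), locus = "all"),
    class = "HaplotypeSet")
  r2 <- amovaDecompose(hs2)
  # identical groups: among-group SS is exactly zero; the Phi_CT
  # estimate is then slightly negative (the finite-sample offset that
  # lets fixation indices print below zero), never positive
  expect_equal(r2@ss[["among_groups"]], 0, tolerance = 1e-12)
  expect_lte(r2@phi[["phi_ct"]], 1e-12)
  expect_gt(r2@phi[["phi_ct"]], -0.1)
})

test_that("monomorphic data yields zero statistics with the flag set", {
  hs <- structure(list(h = matrix(1L, 8, 3),
                       fish = rep(c("f1", "f2"), each = 4),
                       class = rep(c("A", "B"), each = 4), locus = "all"),
                  class = "HaplotypeSet")
  r <- amovaDecompose(hs)
  expect_true(r@monomorphic)
  expect_equal(unname(r@phi), c(0, 0, 0))
})

test_that("three-level Phi_CT collapses to the two-level Phi_ST with one clone per fish", {
  set.seed(9)
  h <- matrix(rbinom(12 * 3, 1, 0.5), 12, 3)
  cls <- rep(c("A", "B"), each = 6)
  hs3 <- structure(list(h = h, fish = paste0("f", 1:12), class = cls,
                        locus = "all"), class = "HaplotypeSet")
  # two-level collapse: each class is one population, no group level above
  hs2 <- structure(list(h = h, fish = cls, class = cls, locus = "all"),
                   class = "HaplotypeSet")
  r3 <- amovaDecompose(hs3)
  r2 <- amovaDecompose(hs2)
  expect_equal(r3@phi[["phi_ct"]], r2@phi[["phi_st"]], tolerance = 1e-9)
})

test_that("a fixture with estimated sigma_b = 0 equates two- and three-level Phi_ST", {
  # engineered so MS(among fish within groups) = MS(within fish) exactly
  h <- matrix(c(0L, 1L, 0L, 0L, 1L, 0L, 1L, 1L), ncol = 1)
  fish <- rep(c("f1", "f2", "f3", "f4"), each = 2)
  cls <- rep(c("A", "B"), each = 4)
  hs3 <- structure(list(h = h, fish = fish, class = cls, locus = "all"),
                   class = "HaplotypeSet")
  r3 <- amovaDecompose(hs3)
  expect_equal(r3@sigma2[["b"]], 0, tolerance = 1e-12)
  hs2 <- structure(list(h = h, fish = cls, class = cls, locus = "all"),
                   class = "HaplotypeSet")
  r2 <- amovaDecompose(hs2)
  expect_equal(r3@phi[["phi_st"]], r2@phi[["phi_st"]], tolerance = 1e-9)
})

test_that("permutation test is deterministic, bounded below, and warns when underpowered", {
  hs <- structure(list(
    h = rbind(matrix(1L, 20, 7), matrix(0L, 20, 7)),
    fish = rep(paste0("f", 1:8), each = 5),
    class = rep(c("A", "B"), each = 20), locus = "all"),
    class = "HaplotypeSet")
  p1 <- amovaPermutationTest(hs, "phi_ct", nPerm = 199, seed = 5)
  p2 <- amovaPermutationTest(hs, "phi_ct", nPerm = 199, seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
  # fully separated groups: only permutations recreating the split tie it
  expect_lt(as.numeric(p1), 0.05)
  tiny <- structure(list(h = rbind(matrix(1L, 2, 2), matrix(0L, 2, 2)),
                         fish = c("f1", "f1", "f2", "f2"),
                         class = c("A", "A", "B", "B"), locus = "all"),
                    class = "HaplotypeSet")
  expect_warning(amovaPermutationTest(tiny, "phi_ct", nPerm = 19, seed = 1),
                 "underpowered")
  # p can never be exactly zero (add-one rule)
  expect_gte(as.numeric(p1), 1 / 200)
})

test_that("median Fst is non-decreasing in the between-class effect size", {
  set.seed(71)
  deltas <- c(0, 0.1, 0.2, 0.3, 0.4)
  med <- vapply(deltas, function(d) {
    fst <- vapply(1:40, function(i) {
      hA <- matrix(rbinom(50 * 7, 1, 0.5), 50, 7)
      hB <- matrix(rbinom(50 * 7, 1, 0.5 + d), 50, 7)
      hs <- structure(list(h = rbind(hA, hB),
                           fish = rep(paste0("f", 1:10), each = 10),
                           class = rep(c("A", "B"), each = 50),
                           locus = "all"), class = "HaplotypeSet")
      amovaDecompose(hs)@fst
    }, 0)
    median(fst)
  }, 0)
  expect_true(all(diff(med) > -0.01))
  expect_gt(med[5], med[1])
})

test_that("pairwiseFst separates classes that differ and flags monomorphic loci", {
  a <- cyp19aAssay()
  classes <- data.frame(class_id = c("FLT", "MLT"), sex = c("F", "M"),
                        temperature = "LT", n_fish = c(15L, 15L))
  probs <- rbind(siteProbsFromMean(0.37), siteProbsFromMean(0.77))
  cfg <- generatorConfig(a, classes, probs, seed = 6)
  sim <- simulateCloneDataset(cfg)
  set <- buildCallMatrix(a, sim$sequences, sim$sampleSheet)
  r <- pairwiseFst(set, "MLT", "FLT", nPerm = 199, seed = 2)
  expect_gt(r@fst, 0)
  expect_lt(r@pValues[["phi_ct"]], 0.05)
  # single-locus run uses length-1 haplotypes
  r1 <- pairwiseFst(set, "MLT", "FLT", loci = -13L, nPerm = 99, seed = 2)
  expect_equal(r1@locus, "-13")
  expect_false(is.na(r1@fst))
  # absent class errors
  expect_error(pairwiseFst(set, "MLT", "FHT", nPerm = 9, seed = 1), "absent")
  # monomorphic single locus
  calls <- matrix(1L, 8, 2)
  sheet <- rbind(mkSheet(c("x", "y"), sex = "F"), mkSheet(c("z", "w"), sex = "M"))
  set2 <- mkCallSet(calls, rep(c("x", "y", "z", "w"), each = 2), sheet)
  r2 <- pairwiseFst(set2, "FLT", "MLT", loci = 1L, nPerm = 9, seed = 1)
  expect_true(r2@monomorphic)
  expect_equal(r2@fst, 0)
})
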