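# The toy amplicon is ACGATCCATCAGCGTACGTT with declared loci at 0-based
# indices 1 and 12, non-CpG Cs at 5, 6, 9 and an undeclared CG at 16.

test_that("hand-counted toy clone gives calls (M, U) and efficiency 2/3", {
  a <- toyAssay()
  # convert non-CpG Cs at 5 and 6, leave 9 unconverted; locus1 C (M),
  # locus2 T (U); undeclared CpG C untouched
  clone <- "ACGATTTATCAGTGTACGTT"
  r <- callClone(a, clone)
  expect_equal(unname(r$calls), c("M", "U"))
  expect_equal(r$conversionEfficiency, 2 / 3)
  expect_equal(r$nNonCpGCovered, 3L)
})

test_that("fully methylated and fully unmethylated perfect conversions call cleanly", {
  a <- toyAssay()
  allM <- "ACGATTTATTAGCGTACGTT"   # all non-CpG C -> T, locus Cs kept
  rM <- callClone(a, allM)
  expect_equal(unname(rM$calls), c("M", "M"))
  expect_equal(rM$conversionEfficiency, 1)
  allU <- "ATGATTTATTAGTGTATGTT"   # every C (CpG or not) -> T
  rU <- callClone(a, allU)
  expect_equal(unname(rU$calls), c("U", "U"))
  expect_equal(rU$conversionEfficiency, 1)
})

test_that("reverse-complement clones are auto-detected and call identically", {
  a <- toyAssay()
  clone <- "ACGATTTATCAGTGTACGTT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clone)))
  fwd <- callClone(a, clone)
  rev <- callClone(a, rc)
  expect_equal(rev$calls, fwd$calls)
  expect_equal(rev$conversionEfficiency, fwd$conversionEfficiency)
  expect_equal(alignClone(a, rc)$orientation, "reverse")
})

test_that("clones exceeding the mismatch tolerance are rejected", {
  a <- cyp19aAssay()
  sim <- simulateCloneDataset(studyGeneratorConfig(a, seed = 21))
  clone <- sim$sequences[[1]]
  b <- strsplit(clone, "")[[1]]
  ctx <- epiclone:::.referenceContext(a)
  unamb <- setdiff(which(ctx$bases != "C"), ctx$locusPos)
  set.seed(1)
  hit <- sample(unamb, ceiling(0.10 * length(unamb)))
  b[hit] <- ifelse(ctx$bases[hit] == "A", "T", "A")   # non-C mismatches
  mut <- paste(b, collapse = "")
  expect_false(alignClone(a, mut, tolerance = 0.05)$accepted)
  expect_error(callClone(a, mut, tolerance = 0.05), "unalignable")
  expect_error(callClone(a, "ACGT"), "unalignable")   # length mismatch
})

test_that("noise-free generated clones are called back to the exact truth", {
  a <- cyp19aAssay()
  classes <- data.frame(class_id = c("FLT", "MHT"), sex = c("F", "M"),
                        temperature = c("LT", "HT"), n_fish = c(3L, 3L))
  probs <- rbind(siteProbsFromMean(0.3), siteProbsFromMean(0.8))
  cfg <- generatorConfig(a, classes, probs, conversionFailureRate = 0,
                        seed = 13)
  sim <- simulateCloneDataset(cfg)
  set <- suppressMessages(buildCallMatrix(a, sim$sequences, sim$sampleSheet))
  expect_equal(unname(callsMatrix(set)),
               unname(sim$truth$patterns + 0L))
  expect_true(all(cloneData(set)$complete))
  expect_true(all(cloneData(set)$conversion_efficiency == 1))
})

test_that("per-fish means follow the hand-computed missing-robust rule", {
  # clone1: M,U,M; clone2: M,M,missing -> locus means (1, 0.5, 1), fish 5/6
  m <- rbind(c(1L, 0L, 1L), c(1L, 1L, NA))
  r <- clonesMeanMethylation(m)
  expect_equal(unname(r$locus_means), c(1, 0.5, 1))
  expect_equal(r$fish_mean, 5 / 6)
  # character form agrees
  mc <- rbind(c("M", "U", "M"), c("M", "M", NA))
  expect_equal(clonesMeanMethylation(mc)$fish_mean, 5 / 6)
  # all-missing locus flagged and excluded
  m2 <- rbind(c(1L, NA), c(0L, NA))
  r2 <- clonesMeanMethylation(m2)
  expect_equal(r2$undefined_loci, c(`3` = 2L), ignore_attr = TRUE)
  expect_equal(r2$fish_mean, 0.5)
  expect_error(clonesMeanMethylation(matrix(NA_integer_, 2, 2)), "non-missing")
})

test_that("call-set grouping, symmetry means, and clone-order invariance hold", {
  a <- cyp19aAssay()
  classes <- data.frame(class_id = "FLT", sex = "F", temperature = "LT",
                        n_fish = 4L)
  cfg <- generatorConfig(a, classes, matrix(0.5, 1, 7), seed = 2)
  sim <- simulateCloneDataset(cfg)
  set <- buildCallMatrix(a, sim$sequences, sim$sampleSheet)
  expect_equal(dim(callsMatrix(set)), c(40L, 7L))
  expect_equal(nrow(qcReport(set)), 4L)
  # clone order must not matter
  perm <- sample(length(sim$sequences))
  set2 <- buildCallMatrix(a, sim$sequences[perm], sim$sampleSheet)
  expect_equal(sort(fishMeanMethylation(set)), sort(fishMeanMethylation(set2)))
  # 5 all-M + 5 all-U clones -> 0.5 everywhere
  h <- rbind(matrix(1L, 5, 7), matrix(0L, 5, 7))
  sym <- clonesMeanMethylation(h)
  expect_true(all(sym$locus_means == 0.5))
  expect_equal(sym$fish_mean, 0.5)
})

test_that("fish with few clones are noted, none are filtered by default", {
  a <- toyAssay()
  classes <- data.frame(class_id = "FLT", sex = "F", temperature = "LT",
                        n_fish = 2L)
  cfg <- generatorConfig(a, classes, matrix(0.5, 1, 2), clonesPerFish = 7L,
                        seed = 8)
  sim <- simulateCloneDataset(cfg)
  # 7 clones is the study minimum: the fish passes with a logged note
  expect_message(
    set <- buildCallMatrix(a, sim$sequences, sim$sampleSheet),
    "fewer than 10")
  expect_equal(nrow(cloneData(set)), 14L)
  expect_equal(unname(table(cloneData(set)$fish_id)), c(7L, 7L),
               ignore_attr = TRUE)
})
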