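test_that("arcsine square-root transform is exact and strictly increasing", {
  expect_equal(arcsinSqrt(0), 0)
  expect_equal(arcsinSqrt(1), pi / 2)
  expect_equal(arcsinSqrt(0.5), pi / 4)
  expect_error(arcsinSqrt(1.2), "outside")
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsinSqrt(p)) > 0))
  expect_equal(arcsinSqrtInverse(arcsinSqrt(p)), p)
})

test_that("pooled t-test matches the hand formula and handles degeneracy", {
  r <- pooledTTest(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  # pooled s^2 = 0.01, se = 0.1 * sqrt(2/3)
  expect_equal(r$t, -0.3 / (0.1 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  same <- pooledTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(pooledTTest(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(pooledTTest(1, c(1, 2)), ">= 2 values")
})

test_that("two-way ANOVA uses Type II and reduces to Type I when balanced", {
  set.seed(12)
  d <- data.frame(sex = rep(c("F", "M"), each = 8),
                  temperature = rep(rep(c("LT", "HT"), each = 4), 2))
  d$transformed <- 0.5 + 0.4 * (d$sex == "M") + 0.1 * (d$temperature == "HT") +
    rnorm(16, 0, 0.05)
  tab <- twoWayAnova(d)
  expect_setequal(tab$term, c("sex", "temperature", "sex:temperature"))
  t1 <- anova(lm(transformed ~ factor(sex) * factor(temperature), d))
  expect_equal(tab$sum_sq[tab$term == "sex"], t1["factor(sex)", "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "temperature"],
               t1["factor(temperature)", "Sum Sq"], tolerance = 1e-9)
  # degenerate response handled by convention
  d0 <- d; d0$transformed <- 0.3
  tab0 <- twoWayAnova(d0)
  expect_true(attr(tab0, "degenerate"))
  expect_true(all(tab0$p_value == 1))
  # empty cell errors
  dbad <- d[!(d$sex == "F" & d$temperature == "HT"), ]
  expect_error(twoWayAnova(dbad), "incomplete design")
})

test_that("a simulated sex effect is detected and temperature stays null", {
  a <- cyp19aAssay()
  hits <- 0; falseTemp <- 0
  nrun <- 60
  for (i in seq_len(nrun)) {
    classes <- data.frame(class_id = c("FLT", "FHT", "MLT", "MHT"),
                          sex = c("F", "F", "M", "M"),
                          temperature = c("LT", "HT", "LT", "HT"),
                          n_fish = 6L)
    pF <- plogis(qlogis(0.35))
    pM <- plogis(qlogis(0.35) + 1.5)
    probs <- rbind(siteProbsFromMean(pF), siteProbsFromMean(pF),
                   siteProbsFromMean(pM), siteProbsFromMean(pM))
    cfg <- generatorConfig(a, classes, probs, seed = 1000 + i)
    sim <- simulateCloneDataset(cfg)
    set <- buildCallMatrix(a, sim$sequences, sim$sampleSheet)
    tab <- twoWayAnova(fishSummaries(set))
    if (tab$p_value[tab$term == "sex"] < 0.01) hits <- hits + 1
    if (tab$p_value[tab$term == "temperature"] < 0.05) {
      falseTemp <- falseTemp + 1
    }
  }
  expect_gte(hits / nrun, 0.9)
  expect_lte(falseTemp / nrun, 0.2)
})

test_that("sex threshold sits midway for zero-variance groups and flags overlap", {
  thr <- sexThreshold(rep(0.2, 5), rep(0.8, 5))
  expect_equal(thr$threshold, 0.5, tolerance = 1e-12)
  expect_false(thr$overlap)
  set.seed(4)
  ov <- sexThreshold(runif(10, 0.3, 0.7), runif(10, 0.3, 0.7))
  expect_true(ov$overlap)
  expect_true(ov$threshold > 0 && ov$threshold < 1)
  expect_error(sexThreshold(c(0.1, 0.2), rep(0.8, 5)), ">= 3 fish")
})

test_that("sex classification is threshold-based with the boundary assigned to M", {
  expect_equal(classifySex(0.619, 0.67), "F")
  expect_equal(classifySex(0.67, 0.67), "M")
  expect_equal(classifySex(0.90, 0.67), "M")
  expect_equal(classifySex(c(0.1, 0.9), 0.5), c("F", "M"))
  expect_error(classifySex(0.5, 1.2), "threshold")
  # invariant under the transform
  m <- runif(50)
  thr <- 0.67
  expect_equal(classifySex(m, thr),
               ifelse(arcsinSqrt(m) < arcsinSqrt(thr), "F", "M"))
})

test_that("methylation-expression regression reports r2, F and slope sign", {
  d <- data.frame(transformed = seq(0.2, 1.2, length.out = 10))
  d$logRQ <- 3 - 2 * d$transformed
  # perfect fit: summary.lm warns about the essentially zero residual
  r <- suppressWarnings(methExpressionCorrelation(d))
  expect_equal(r$r2, 1)
  expect_equal(r$slope_sign, -1)
  set.seed(2)
  d$logRQ <- d$logRQ + rnorm(10, 0, 0.2)
  r2 <- methExpressionCorrelation(d)
  expect_lt(r2$r2, 1)
  expect_equal(r2$df, c(1, 8))
  d0 <- data.frame(transformed = rep(0.5, 5), logRQ = rnorm(5))
  expect_error(methExpressionCorrelation(d0), "zero variance")
  expect_error(methExpressionCorrelation(d[1:2, ]), ">= 3 fish")
})

test_that("sex-ratio chi-square equals the closed 2x2 Pearson formula", {
  even <- sexRatioTest(group1 = c(10, 10), group2 = c(10, 10))
  expect_equal(even$chi2, 0)
  r <- sexRatioTest(group1 = c(28, 12), group2 = c(22, 18))
  # N (ad - bc)^2 / (r1 r2 c1 c2), no continuity correction
  expect_equal(r$chi2, 80 * (28 * 18 - 12 * 22)^2 / (40 * 40 * 50 * 30))
  expect_equal(r$df, 1)
  sep <- sexRatioTest(group1 = c(40, 0), group2 = c(0, 40))
  expect_equal(sep$chi2, 80)   # fully separated table: chi2 = N
  expect_error(sexRatioTest(group1 = c(0, 0), group2 = c(1, 2)), "zero margin")
})

test_that("tukey letters separate clearly distinct cell means", {
  set.seed(6)
  d <- data.frame(sex = rep(c("F", "F", "M", "M"), each = 6),
                  temperature = rep(c("LT", "HT", "LT", "HT"), each = 6))
  mu <- c(FLT = 0.4, FHT = 0.6, MLT = 1.0, MHT = 1.1)
  d$transformed <- mu[paste0(d$sex, d$temperature)] + rnorm(24, 0, 0.03)
  tk <- tukeyCellMeans(d)
  lett <- tk$letters
  expect_false(lett[["FLT"]] == lett[["MHT"]])
  # cells sharing no letter differ significantly in the HSD table
  expect_true(all(nchar(lett) >= 1))
})
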