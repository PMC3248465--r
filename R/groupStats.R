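#' Arcsine square-root transform for proportions
#'
#' The variance-stabilising analysis scale used for every group statistic
#' on methylation proportions: `asin(sqrt(p))`, in radians, mapping
#' `[0, 1]` onto `[0, pi/2]` strictly monotonically.
#'
#' @param p proportions in `[0, 1]`.
#' @return radians in `[0, pi/2]`.
#' @examples
#' arcsinSqrt(c(0, 0.5, 1))   # 0, pi/4, pi/2
#' @export
arcsinSqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportion outside [0, 1]")
  asin(sqrt(p))
}

#' @rdname arcsinSqrt
#' @param x radians; the inverse transform `sin(x)^2`.
#' @export
arcsinSqrtInverse <- function(x) sin(x)^2

#' Two-way ANOVA on transformed per-fish means
#'
#' Fixed-effects sex x temperature ANOVA with interaction on the arcsine
#' square-root transformed per-fish methylation means.  Type-II sums of
#' squares accommodate the unbalanced cell sizes of the study design
#' (3-15 fish per cell); with balanced cells Type II equals Type I.
#'
#' @param summaries data.frame from [fishSummaries()] (needs the factor
#'   columns and the response).
#' @param response response column (default `"transformed"`).
#' @param factorA,factorB factor columns (default sex and temperature).
#' @return data.frame: term, sum_sq, df, statistic (F), p_value.  When
#'   the response is constant the F statistics are 0 and p 1 by
#'   convention, with attribute `degenerate = TRUE`.
#' @export
twoWayAnova <- function(summaries, response = "transformed",
                        factorA = "sex", factorB = "temperature") {
  a <- factor(summaries[[factorA]])
  b <- factor(summaries[[factorB]])
  y <- summaries[[response]]
  if (nlevels(a) < 2L || nlevels(b) < 2L) stop("need >= 2 levels per factor")
  cellN <- table(a, b)
  if (any(cellN == 0L)) stop("incomplete design: empty cell")
  if (any(cellN < 2L)) stop("need >= 2 fish per cell")
  terms <- c(factorA, factorB, paste0(factorA, ":", factorB))
  if (stats::sd(y) == 0) {
    out <- data.frame(term = terms, sum_sq = 0, df = NA_real_,
                      statistic = 0, p_value = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::lm(y ~ a * b)
  tab <- car::Anova(fit, type = 2)
  tab <- tab[rownames(tab) != "Residuals", , drop = FALSE]
  rn <- rownames(tab)
  rn <- sub("^a:b$", paste0(factorA, ":", factorB), rn)
  rn <- sub("^a$", factorA, rn)
  rn <- sub("^b$", factorB, rn)
  out <- data.frame(term = rn, sum_sq = tab[["Sum Sq"]], df = tab[["Df"]],
                    statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]])
  attr(out, "degenerate") <- FALSE
  out
}

#' Tukey HSD on the 2x2 cell means with letter display
#'
#' Post-hoc comparison of the sex-by-temperature cell means of the
#' transformed response, with a compact letters display (cells sharing a
#' letter do not differ at `level`).
#'
#' @inheritParams twoWayAnova
#' @param level family-wise confidence level.
#' @return list with `tukey` (the [stats::TukeyHSD()] table) and
#'   `letters` (named character vector per cell).
#' @export
tukeyCellMeans <- function(summaries, response = "transformed",
                           factorA = "sex", factorB = "temperature",
                           level = 0.95) {
  cell <- factor(paste0(summaries[[factorA]], summaries[[factorB]]))
  y <- summaries[[response]]
  fit <- stats::aov(y ~ cell)
  tk <- stats::TukeyHSD(fit, conf.level = level)$cell
  means <- sort(tapply(y, cell, mean))
  k <- length(means)
  differs <- function(x1, x2) {
    key <- paste(x1, x2, sep = "-")
    alt <- paste(x2, x1, sep = "-")
    p <- if (key %in% rownames(tk)) tk[key, "p adj"] else tk[alt, "p adj"]
    p < 1 - level
  }
  # greedy insertion letters display over cells ordered by mean
  groups <- list()
  for (nm in names(means)) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], differs, TRUE, x2 = nm))) {
        groups[[gi]] <- c(groups[[gi]], nm); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- nm
  }
  lett <- stats::setNames(rep("", k), names(means))
  for (gi in seq_along(groups)) {
    for (nm in groups[[gi]]) lett[nm] <- paste0(lett[nm], letters[gi])
  }
  list(tukey = tk, letters = lett)
}

#' Pooled-variance Student's t-test
#'
#' Two-sample t on the analysis scale with the classical pooled-variance
#' formulation (sign convention: x minus y); Welch's unequal-variance
#' form is available via `welch = TRUE`.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param twoTailed two-sided p-value (default) or one-sided (greater).
#' @param welch use Welch's t instead of the pooled form.
#' @return list with `t`, `df`, `p`.
#' @export
pooledTTest <- function(x, y, twoTailed = TRUE, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  if (!welch && stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1))
    stop("zero pooled variance")
  }
  ht <- stats::t.test(x, y, var.equal = !welch,
                      alternative = if (twoTailed) "two.sided" else "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Methylation threshold separating female and male distributions
#'
#' Computes the level-% confidence interval of each sex's mean on the
#' arcsine square-root scale and places the threshold at the
#' back-transformed midpoint between the female CI upper bound and the
#' male CI lower bound.  When the intervals overlap the threshold falls
#' back to the midpoint of the two means and the `overlap` flag is set.
#' In the study this construction yields the 67% threshold used to sex
#' fish from methylation alone.
#'
#' @param femaleMeans,maleMeans per-fish mean methylation proportions
#'   (>= 3 fish per sex).
#' @param level confidence level (default 0.95).
#' @return list with `threshold` (proportion), `overlap`, `femaleCI` and
#'   `maleCI` (back-transformed intervals).
#' @export
sexThreshold <- function(femaleMeans, maleMeans, level = 0.95) {
  if (length(femaleMeans) < 3L || length(maleMeans) < 3L) {
    stop("need >= 3 fish per sex")
  }
  ci <- function(p) {
    t <- arcsinSqrt(p)
    n <- length(t)
    half <- stats::qt((1 + level) / 2, n - 1) * stats::sd(t) / sqrt(n)
    c(mean = mean(t), lower = mean(t) - half, upper = mean(t) + half)
  }
  f <- ci(femaleMeans); m <- ci(maleMeans)
  overlap <- f[["upper"]] >= m[["lower"]]
  mid <- if (overlap) (f[["mean"]] + m[["mean"]]) / 2 else
    (f[["upper"]] + m[["lower"]]) / 2
  list(threshold = arcsinSqrtInverse(mid), overlap = overlap,
       femaleCI = arcsinSqrtInverse(f[c("lower", "upper")]),
       maleCI = arcsinSqrtInverse(m[c("lower", "upper")]))
}

#' Classify sex from a per-fish methylation mean
#'
#' Means below the threshold are female, at or above it male (the
#' boundary is assigned to M).  Because the transform is strictly
#' increasing, classification is identical on the raw and transformed
#' scales.
#'
#' @param fishMean per-fish mean methylation proportion(s).
#' @param threshold threshold proportion in (0, 1).
#' @return character vector of "F"/"M".
#' @examples
#' classifySex(0.619, 0.67)   # "F"
#' @export
classifySex <- function(fishMean, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ifelse(fishMean < threshold, "F", "M")
}

#' Methylation-expression regression
#'
#' Ordinary least squares of log relative expression on transformed
#' methylation, reporting the determination coefficient, the regression
#' F-test and the slope sign — the study's test of the inverse
#' methylation-expression relationship.
#'
#' @param summaries data.frame with `transformed` and `logRQ` columns
#'   (>= 3 complete rows).
#' @return list with `r2`, `F`, `df` (c(1, n-2)), `p`, `slope`,
#'   `slope_sign`.
#' @export
methExpressionCorrelation <- function(summaries) {
  d <- summaries[stats::complete.cases(summaries[c("transformed", "logRQ")]), ]
  if (nrow(d) < 3L) stop("need >= 3 fish with both values")
  if (stats::sd(d$transformed) == 0) stop("zero variance in predictor")
  fit <- stats::lm(logRQ ~ transformed, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r2 = sm$r.squared, F = unname(fstat[1]),
       df = unname(fstat[2:3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       slope = unname(stats::coef(fit)[2]),
       slope_sign = sign(unname(stats::coef(fit)[2])))
}

#' Chi-square test for sex-ratio differences between two groups
#'
#' Pearson chi-square without continuity correction on the 2x2 table of
#' female/male counts per group.
#'
#' @param counts 2x2 matrix (rows = groups, columns = F/M counts), or two
#'   vectors via `group1`/`group2`.
#' @param group1,group2 alternative input: c(females, males) per group.
#' @return list with `chi2`, `df`, `p`.
#' @export
sexRatioTest <- function(counts = NULL, group1 = NULL, group2 = NULL) {
  if (is.null(counts)) counts <- rbind(group1, group2)
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
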