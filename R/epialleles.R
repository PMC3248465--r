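#' Size of the methylation pattern space
#'
#' With L assayed CpG loci there are 2^L theoretically possible
#' methylation patterns (epialleles); 7 loci give 128.
#'
#' @param L number of CpG loci (or a [PromoterAssay-class] /
#'   [MethCallSet-class], whose locus count is used).
#' @return 2^L as a numeric (exact for any practical panel size).
#' @examples
#' patternSpaceSize(7)   # 128
#' @export
patternSpaceSize <- function(L) {
  if (is(L, "PromoterAssay") || is(L, "MethCallSet")) L <- nLoci(L)
  if (L < 0) stop("L must be >= 0")
  2^L
}

# Complete-clone pattern strings ("M"/"U" per locus) and their class labels.
.patternStrings <- function(x, classBy = c("sex", "temperature")) {
  calls <- callsMatrix(x)
  cd <- cloneData(x)
  complete <- cd$complete
  calls <- calls[complete, , drop = FALSE]
  pat <- apply(calls, 1L, function(r) paste(c("U", "M")[r + 1L], collapse = ""))
  if (nrow(calls) == 0L) pat <- character(0)
  if (ncol(calls) == 0L) pat <- rep("", nrow(calls))
  sheet <- sampleSheet(x)
  cls <- classLabels(sheet, classBy)[match(cd$fish_id[complete], sheet$fish_id)]
  data.frame(fish_id = cd$fish_id[complete], pattern = pat, class = cls,
             stringsAsFactors = FALSE)
}

#' Tabulate epiallele frequencies by treatment class
#'
#' Counts complete clones (no missing call) per methylation pattern per
#' class.  Rows are sorted by total count descending, ties broken
#' lexicographically by pattern.
#'
#' @param x a [MethCallSet-class].
#' @param classBy sample-sheet columns defining the classes (default
#'   sex x temperature: FLT, FHT, MLT, MHT).
#' @return data.frame: `pattern`, one count column per class, `total`.
#'   The number of excluded incomplete clones is attached as attribute
#'   `n_incomplete`.
#' @export
tabulatePatterns <- function(x, classBy = c("sex", "temperature")) {
  ps <- .patternStrings(x, classBy)
  tab <- table(ps$pattern, factor(ps$class))
  counts <- as.data.frame.matrix(tab)
  out <- data.frame(pattern = rownames(counts), counts,
                    total = rowSums(counts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_incomplete") <- sum(!cloneData(x)$complete)
  attr(out, "class_totals") <- colSums(counts)
  out
}

#' Patterns eligible for contingency testing
#'
#' A pattern can be tested only when its expected count per class is at
#' least `minExpected`; under equal allocation across `nClasses` classes
#' this is a total observed count of `minExpected * nClasses` or higher
#' (with four classes: 20 or higher, boundary inclusive).
#'
#' @param table an epiallele table from [tabulatePatterns()].
#' @param nClasses number of classes (default: count columns in `table`).
#' @param minExpected minimum expected per-class count (default 5).
#' @return the eligible subset of `table`.
#' @export
eligiblePatterns <- function(table, nClasses = NULL, minExpected = 5) {
  if (is.null(nClasses)) {
    nClasses <- ncol(table) - 2L   # pattern + total
  }
  if (nClasses < 2L) stop("need at least 2 classes")
  table[table$total >= minExpected * nClasses, , drop = FALSE]
}

#' Chi-square contingency test for one epiallele
#'
#' Goodness-of-fit chi-square of a pattern's per-class counts against
#' expectations proportional to each class's total complete-clone count
#' (equal expectations when clone totals are balanced); df = classes - 1.
#'
#' @param counts integer vector of the pattern's count per class.
#' @param classTotals total complete clones per class (same order).
#' @return list with `chi2`, `df`, `p`.
#' @examples
#' patternChisqTest(c(40, 0, 0, 0), rep(100, 4))   # chi2 = 120, df = 3
#' @export
patternChisqTest <- function(counts, classTotals) {
  if (length(counts) != length(classTotals)) {
    stop("counts and classTotals must align")
  }
  p <- classTotals / sum(classTotals)
  if (any(p == 0)) stop("degenerate margins: a class has zero clones")
  ht <- suppressWarnings(stats::chisq.test(counts, p = p))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Epiallele table with eligibility and tests
#'
#' Adds the eligibility flag and, for eligible patterns, the per-pattern
#' chi-square test to an epiallele table.  No multiple-testing correction
#' is applied by default; `correct = "bonferroni"` adjusts the p-values
#' across the tested patterns.
#'
#' @param x a [MethCallSet-class].
#' @param classBy class-defining columns.
#' @param minExpected eligibility rule (see [eligiblePatterns()]).
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return the table from [tabulatePatterns()] with columns `eligible`,
#'   `chi2`, `df`, `p`.
#' @export
epialleleTests <- function(x, classBy = c("sex", "temperature"),
                           minExpected = 5, correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  tab <- tabulatePatterns(x, classBy)
  totals <- attr(tab, "class_totals")
  k <- length(totals)
  tab$eligible <- tab$total >= minExpected * k
  tab$chi2 <- tab$df <- tab$p <- NA_real_
  for (i in which(tab$eligible)) {
    tt <- patternChisqTest(as.numeric(tab[i, names(totals)]), totals)
    tab$chi2[i] <- tt$chi2; tab$df[i] <- tt$df; tab$p[i] <- tt$p
  }
  if (correct == "bonferroni") {
    sel <- tab$eligible
    tab$p[sel] <- stats::p.adjust(tab$p[sel], method = "bonferroni")
  }
  tab
}

#' Per-fish epiallele diversity (PCR-bias diagnostic)
#'
#' The number of distinct complete methylation patterns among a fish's
#' clones; with 10 clones per fish the theoretical range is 1-10.  A
#' diversity that collapses to 1-2 for many fish would indicate PCR bias
#' towards particular epialleles.
#'
#' @param x a [MethCallSet-class].
#' @return data.frame per fish: `fish_id`, `n_complete`,
#'   `n_patterns`, `ratio` (patterns per complete clone).
#' @export
patternDiversity <- function(x) {
  ps <- .patternStrings(x)
  if (nrow(ps) == 0L) stop("no complete clones")
  sp <- split(ps$pattern, ps$fish_id)
  out <- data.frame(
    fish_id = names(sp),
    n_complete = lengths(sp),
    n_patterns = vapply(sp, function(p) length(unique(p)), 0L)
  )
  out$ratio <- out$n_patterns / out$n_complete
  rownames(out) <- NULL
  out
}

#' Class-level diversity summary
#'
#' Mean per-fish pattern diversity per class and the correlation of
#' per-fish diversity with per-fish mean methylation (a diversity that
#' tracks methylation level would also hint at amplification bias).
#'
#' @param x a [MethCallSet-class].
#' @param classBy class-defining columns.
#' @return list with `by_class` (data.frame class, n_fish,
#'   mean_patterns) and `methylation_correlation` (list r, p).
#' @export
diversitySummary <- function(x, classBy = c("sex", "temperature")) {
  div <- patternDiversity(x)
  sheet <- sampleSheet(x)
  div$class <- classLabels(sheet, classBy)[match(div$fish_id, sheet$fish_id)]
  byClass <- do.call(rbind, lapply(split(div, div$class), function(d) {
    data.frame(class = d$class[1], n_fish = nrow(d),
               mean_patterns = mean(d$n_patterns))
  }))
  rownames(byClass) <- NULL
  means <- fishMeanMethylation(x)[div$fish_id]
  corr <- list(r = NA_real_, p = NA_real_)
  if (nrow(div) >= 3L && stats::sd(div$n_patterns) > 0 &&
      stats::sd(means, na.rm = TRUE) > 0) {
    ct <- stats::cor.test(div$n_patterns, means)
    corr <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(by_class = byClass, methylation_correlation = corr)
}

#' Render a pattern string with circle glyphs
#'
#' @param pattern character vector of M/U strings.
#' @return character vector with filled circles for methylated and open
#'   circles for unmethylated positions.
#' @export
patternGlyphs <- function(pattern) {
  vapply(strsplit(pattern, ""), function(p) {
    paste(ifelse(p == "M", "●", "○"), collapse = "")
  }, "")
}
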