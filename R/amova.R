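#' Build a haplotype set for AMOVA
#'
#' Extracts binary methylation haplotypes from a call set: clones within
#' fish (the populations) within treatment classes (the groups).  For the
#' whole promoter (`loci = "all"`) only complete clones contribute; a
#' single-locus run (`loci = <tss label>`) uses length-1 haplotypes from
#' every clone with a call at that locus.
#'
#' @param x a [MethCallSet-class].
#' @param classBy sample-sheet columns defining the groups.
#' @param loci `"all"` or one TSS-relative label.
#' @param classes optional character vector restricting to these class
#'   labels.
#' @return a `HaplotypeSet`: list with the 0/1 matrix `h`, and per-row
#'   `fish` and `class` labels.
#' @export
haplotypeSet <- function(x, classBy = c("sex", "temperature"),
                         loci = "all", classes = NULL) {
  calls <- callsMatrix(x)
  cd <- cloneData(x)
  sheet <- sampleSheet(x)
  cls <- classLabels(sheet, classBy)[match(cd$fish_id, sheet$fish_id)]
  if (identical(loci, "all")) {
    keep <- cd$complete
    h <- calls[keep, , drop = FALSE]
  } else {
    j <- match(as.integer(loci), as.integer(colnames(calls)))
    if (is.na(j)) stop("unknown locus: ", loci)
    keep <- !is.na(calls[, j])
    h <- calls[keep, j, drop = FALSE]
  }
  fish <- cd$fish_id[keep]
  cls <- cls[keep]
  if (!is.null(classes)) {
    miss <- setdiff(classes, unique(cls))
    if (length(miss)) stop("class absent: ", paste(miss, collapse = ", "))
    sel <- cls %in% classes
    h <- h[sel, , drop = FALSE]; fish <- fish[sel]; cls <- cls[sel]
  }
  structure(list(h = h, fish = fish, class = cls,
                 locus = if (identical(loci, "all")) "all" else
                   as.character(loci)),
            class = "HaplotypeSet")
}

#' Hamming distance between two methylation haplotypes
#'
#' The count of differing sites; on 0/1 vectors this equals the squared
#' Euclidean distance, the metric underlying all AMOVA sums of squares
#' here (methylation states have no substitution model to weight).
#'
#' @param h1,h2 equal-length 0/1 vectors (or "M"/"U" characters).
#' @return non-negative integer.
#' @examples
#' hammingDistance(c(1, 0, 1), c(1, 1, 1))   # 1
#' @export
hammingDistance <- function(h1, h2) {
  if (is.character(h1)) h1 <- as.integer(h1 == "M")
  if (is.character(h2)) h2 <- as.integer(h2 == "M")
  if (length(h1) != length(h2)) stop("haplotype lengths differ")
  if (anyNA(h1) || anyNA(h2)) stop("haplotypes must be complete")
  sum(h1 != h2)
}

# Fish-level aggregated squared-distance matrix: B[f, g] = sum of
# pairwise squared distances between all clones of fish f and fish g
# (both orders; diagonal blocks include both orders too).
.fishBlockSums <- function(h, fish) {
  f <- factor(fish, levels = unique(fish))
  s <- rowSums(h)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(h)
  B <- rowsum(t(rowsum(d2, f)), f)
  sizes <- as.vector(table(f))
  list(B = B, sizes = sizes, fishLevels = levels(f))
}

# Three-level AMOVA from fish-block sums.  groupOfFish: integer/character
# group label per fish (order of fishLevels).
.amovaFromB <- function(B, sizes, groupOfFish) {
  N <- sum(sizes)
  P <- length(sizes)
  grp <- factor(groupOfFish)
  G <- nlevels(grp)
  Ng <- as.vector(rowsum(sizes, grp))
  ssTotal <- sum(B) / (2 * N)
  ssWithinFish <- sum(diag(B) / (2 * sizes))
  BG <- rowsum(t(rowsum(B, grp)), grp)
  ssWithinGroups <- sum(diag(BG) / (2 * Ng))
  ssB <- ssWithinGroups - ssWithinFish        # among fish within groups
  ssA <- ssTotal - ssWithinGroups             # among groups
  dfA <- G - 1; dfB <- P - G; dfC <- N - P
  msA <- if (dfA > 0) ssA / dfA else 0
  msB <- if (dfB > 0) ssB / dfB else 0
  msC <- if (dfC > 0) ssWithinFish / dfC else 0
  # unbalanced-design coefficients
  s1 <- sum(rowsum(sizes^2, grp) / Ng)
  s2 <- sum(sizes^2) / N
  n1 <- if (dfB > 0) (N - s1) / dfB else 0
  n2 <- if (dfA > 0) (s1 - s2) / dfA else 0
  n3 <- if (dfA > 0) (N - sum(Ng^2) / N) / dfA else 0
  sigC <- msC
  sigB <- if (dfB > 0 && n1 > 0) (msB - sigC) / n1 else 0
  sigA <- if (dfA > 0 && n3 > 0) (msA - sigC - n2 * sigB) / n3 else 0
  total <- sigA + sigB + sigC
  mono <- !(total > 1e-12)
  phi <- if (mono) {
    c(phi_ct = 0, phi_sc = 0, phi_st = 0)
  } else {
    c(phi_ct = sigA / total,
      phi_sc = if (sigB + sigC > 0) sigB / (sigB + sigC) else 0,
      phi_st = (sigA + sigB) / total)
  }
  list(
    ss = c(among_groups = ssA, among_fish_within_groups = ssB,
           within_fish = ssWithinFish, total = ssTotal),
    df = c(among_groups = dfA, among_fish_within_groups = dfB,
           within_fish = dfC),
    sigma2 = c(a = sigA, b = sigB, c = sigC),
    phi = phi, monomorphic = mono, nHaplotypes = N
  )
}

.newAmovaResult <- function(core, pValues = c(phi_ct = NA_real_,
                                              phi_st = NA_real_),
                            nPerm = 0L, seed = NA_integer_,
                            comparison = "", locus = "all") {
  new("AmovaResult", ss = core$ss, df = core$df, sigma2 = core$sigma2,
      phi = core$phi, fst = unname(core$phi[["phi_ct"]]),
      pValues = pValues, nPermutations = as.integer(nPerm),
      seed = as.integer(seed), monomorphic = core$monomorphic,
      nHaplotypes = as.integer(core$nHaplotypes),
      comparison = comparison, locus = locus)
}

#' Hierarchical AMOVA decomposition (no permutation test)
#'
#' Decomposes the squared-Hamming distance variance of the haplotypes
#' into among-group, among-fish-within-group and within-fish components
#' (Excoffier's three-level framework), and derives the Phi statistics:
#' Phi_CT (among groups), Phi_SC (among fish within groups) and Phi_ST
#' (among fish overall).  Components may be negative; when the total
#' variance is zero the statistics are reported as 0 with the
#' `monomorphic` flag set.  The reported `fst` is Phi_CT, the
#' among-classes fixation index with fish as populations.
#'
#' @param hset a `HaplotypeSet` from [haplotypeSet()].
#' @return an [AmovaResult-class] with `pValues` set to NA.
#' @export
amovaDecompose <- function(hset) {
  if (length(unique(hset$class)) < 2L) stop("need >= 2 groups")
  fb <- .fishBlockSums(hset$h, hset$fish)
  groupOfFish <- hset$class[match(fb$fishLevels, hset$fish)]
  core <- .amovaFromB(fb$B, fb$sizes, groupOfFish)
  .newAmovaResult(core, locus = hset$locus)
}

#' Permutation test for a Phi statistic
#'
#' For Phi_CT whole fish (with all their clones) are permuted among
#' groups preserving group sizes — fish, not clones, are the independent
#' units.  For Phi_ST clones are permuted among fish across groups.  The
#' p-value uses the add-one rule p = (1 + #\{perm >= observed\}) /
#' (1 + nPerm), so it is never exactly zero; deterministic given the seed.
#'
#' @param hset a `HaplotypeSet`.
#' @param statistic `"phi_ct"` (default) or `"phi_st"`.
#' @param nPerm number of permutations (study convention: 10000).
#' @param seed integer seed.
#' @return the p-value, with the observed statistic and the number of
#'   permutations as attributes.
#' @export
amovaPermutationTest <- function(hset, statistic = c("phi_ct", "phi_st"),
                                 nPerm = 10000L, seed) {
  statistic <- match.arg(statistic)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  fb <- .fishBlockSums(hset$h, hset$fish)
  groupOfFish <- hset$class[match(fb$fishLevels, hset$fish)]
  obs <- .amovaFromB(fb$B, fb$sizes, groupOfFish)$phi[[statistic]]
  P <- length(fb$sizes)
  if (statistic == "phi_ct") {
    sizesPerGroup <- table(groupOfFish)
    nDistinct <- exp(lgamma(P + 1) - sum(lgamma(sizesPerGroup + 1)))
    if (nDistinct < 20) warning("underpowered permutation")
  }
  set.seed(as.integer(seed))
  exceed <- 0L
  if (statistic == "phi_ct") {
    for (b in seq_len(nPerm)) {
      permGrp <- sample(groupOfFish)
      stat <- .amovaFromB(fb$B, fb$sizes, permGrp)$phi[["phi_ct"]]
      if (stat >= obs - 1e-12) exceed <- exceed + 1L
    }
  } else {
    h <- hset$h
    f <- factor(hset$fish, levels = unique(hset$fish))
    s <- rowSums(h)
    d2 <- outer(s, s, "+") - 2 * tcrossprod(h)
    for (b in seq_len(nPerm)) {
      pf <- sample(f)
      B <- rowsum(t(rowsum(d2, pf)), pf)
      stat <- .amovaFromB(B, fb$sizes, groupOfFish)$phi[["phi_st"]]
      if (stat >= obs - 1e-12) exceed <- exceed + 1L
    }
  }
  p <- (1 + exceed) / (1 + nPerm)
  attr(p, "observed") <- obs
  attr(p, "nPerm") <- nPerm
  p
}

#' Full AMOVA: decomposition plus permutation p-values
#'
#' @inheritParams amovaPermutationTest
#' @param comparison optional description stored in the result.
#' @return an [AmovaResult-class] with permutation p-values for Phi_CT
#'   and Phi_ST.
#' @export
amova <- function(hset, nPerm = 10000L, seed, comparison = "") {
  res <- amovaDecompose(hset)
  pCt <- amovaPermutationTest(hset, "phi_ct", nPerm, seed)
  pSt <- amovaPermutationTest(hset, "phi_st", nPerm, seed + 1L)
  .newAmovaResult(
    list(ss = res@ss, df = res@df, sigma2 = res@sigma2, phi = res@phi,
         monomorphic = res@monomorphic, nHaplotypes = res@nHaplotypes),
    pValues = c(phi_ct = as.numeric(pCt), phi_st = as.numeric(pSt)),
    nPerm = nPerm, seed = seed, comparison = comparison, locus = res@locus)
}

#' Pairwise class differentiation (whole promoter or single CpG)
#'
#' Restricts the haplotype set to two classes and the requested loci and
#' returns the AMOVA with a permutation p-value for the reported Fst
#' (= Phi_CT, fish permuted among the two classes).  Single-locus runs
#' use length-1 haplotypes from every clone informative at that locus.
#'
#' @param x a [MethCallSet-class].
#' @param classA,classB class labels (e.g. "MLT", "FLT").
#' @param loci `"all"` or one TSS label.
#' @param classBy class-defining sample-sheet columns.
#' @param nPerm permutations for the p-value.
#' @param seed integer seed.
#' @return an [AmovaResult-class].
#' @export
pairwiseFst <- function(x, classA, classB, loci = "all",
                        classBy = c("sex", "temperature"),
                        nPerm = 10000L, seed) {
  hset <- haplotypeSet(x, classBy, loci, classes = c(classA, classB))
  res <- amovaDecompose(hset)
  p <- if (res@monomorphic) NA_real_ else
    as.numeric(amovaPermutationTest(hset, "phi_ct", nPerm, seed))
  .newAmovaResult(
    list(ss = res@ss, df = res@df, sigma2 = res@sigma2, phi = res@phi,
         monomorphic = res@monomorphic, nHaplotypes = res@nHaplotypes),
    pValues = c(phi_ct = p, phi_st = NA_real_),
    nPerm = nPerm, seed = seed,
    comparison = paste(classA, "vs", classB), locus = hset$locus)
}

#' Per-CpG and whole-promoter Fst grid
#'
#' Convenience wrapper producing the table-style report: for each class
#' comparison, the whole-promoter Fst and one row per CpG locus.
#'
#' @param x a [MethCallSet-class].
#' @param comparisons list of length-2 character vectors of class labels.
#' @param classBy class-defining columns.
#' @param nPerm permutations.
#' @param seed integer seed.
#' @return data.frame: comparison, locus, fst, p, monomorphic, n_perm.
#' @export
fstTable <- function(x, comparisons, classBy = c("sex", "temperature"),
                     nPerm = 1000L, seed) {
  rows <- list()
  s <- as.integer(seed)
  for (cmp in comparisons) {
    for (loc in c("all", as.character(tssLabels(x)))) {
      r <- pairwiseFst(x, cmp[1], cmp[2], loci = loc, classBy = classBy,
                       nPerm = nPerm, seed = s)
      s <- s + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = r@comparison, locus = r@locus, fst = r@fst,
        p = r@pValues[["phi_ct"]], monomorphic = r@monomorphic,
        n_perm = nPerm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname AmovaResult-accessors
#' @export
setGeneric("phiStatistics", function(x) standardGeneric("phiStatistics"))
#' @rdname AmovaResult-accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @rdname AmovaResult-accessors
#' @export
setGeneric("fstReported", function(x) standardGeneric("fstReported"))
#' @rdname AmovaResult-accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))

#' Accessors for AmovaResult
#'
#' @param x an [AmovaResult-class].
#' @return `phiStatistics` the named Phi vector; `varianceComponents` the
#'   sigma^2 vector; `fstReported` the reported fixation index (Phi_CT);
#'   `permutationP` the named p-value vector.
#' @name AmovaResult-accessors
#' @aliases phiStatistics varianceComponents fstReported permutationP
NULL

#' @rdname AmovaResult-accessors
setMethod("phiStatistics", "AmovaResult", function(x) x@phi)
#' @rdname AmovaResult-accessors
setMethod("varianceComponents", "AmovaResult", function(x) x@sigma2)
#' @rdname AmovaResult-accessors
setMethod("fstReported", "AmovaResult", function(x) x@fst)
#' @rdname AmovaResult-accessors
setMethod("permutationP", "AmovaResult", function(x) x@pValues)

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA", if (nzchar(object@comparison))
    paste0("(", object@comparison, ", locus ", object@locus, ")"), "\n")
  cat("  n =", object@nHaplotypes, "haplotypes\n")
  tab <- data.frame(df = object@df, SS = object@ss[names(object@df)],
                    sigma2 = object@sigma2)
  print(round(tab, 6))
  cat("  Phi_CT =", sprintf("%.4f", object@phi[["phi_ct"]]),
      " Phi_SC =", sprintf("%.4f", object@phi[["phi_sc"]]),
      " Phi_ST =", sprintf("%.4f", object@phi[["phi_st"]]), "\n")
  if (object@monomorphic) cat("  (monomorphic: total variance is zero)\n")
  if (!all(is.na(object@pValues))) {
    cat("  permutation p:",
        paste(names(object@pValues),
              sprintf("%.4g", object@pValues), collapse = ", "),
        sprintf("(%d permutations)", object@nPermutations), "\n")
  }
})
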