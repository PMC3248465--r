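#' Generator configuration for synthetic bisulfite clone data
#'
#' Describes a simulated clone-sequencing experiment: treatment classes
#' with fish counts, per-class per-CpG methylation probabilities, a shared
#' fish-level random intercept on the log-odds scale (within-fish
#' correlation), an explicit all-or-none epiallele mixture (the bimodal
#' all-methylated / all-unmethylated patterns that dominate real clone
#' data), bisulfite conversion failure at non-CpG cytosines, and optional
#' sequencing error and call dropout.
#'
#' @param assay a [PromoterAssay-class].
#' @param classes data.frame with columns `class_id`, `sex`, `temperature`,
#'   `n_fish` and optionally `treatment` (default "none").
#' @param siteMethProbs numeric matrix, classes x loci, of per-CpG
#'   methylation probabilities in `[0, 1]`; row names must match
#'   `classes$class_id`.
#' @param clonesPerFish integer, clones sequenced per fish (study design: 10).
#' @param fishEffectSd sigma_fish >= 0, SD of the per-fish intercept on the
#'   log-odds scale, shared across sites.
#' @param allOrNoneWeight rho in `[0, 1]`: probability that a clone is drawn
#'   as an all-M or all-U epiallele rather than site-independent.
#' @param conversionFailureRate epsilon in `[0, 1]`: probability a non-CpG C
#'   escapes conversion and is read as C (study estimate: 0.0202).
#' @param sequencingErrorRate per-base substitution probability (default 0).
#' @param dropoutRate probability a CpG call is masked as missing (default 0).
#' @param seed integer seed; the generator is deterministic given the
#'   config and seed.
#' @return a `GeneratorConfig` (a validated list).
#' @seealso [simulateCloneDataset()], [studyGeneratorConfig()]
#' @export
generatorConfig <- function(assay, classes, siteMethProbs,
                            clonesPerFish = 10L,
                            fishEffectSd = 0.5,
                            allOrNoneWeight = 0.5,
                            conversionFailureRate = 0.0202,
                            sequencingErrorRate = 0,
                            dropoutRate = 0,
                            seed) {
  stopifnot(is(assay, "PromoterAssay"))
  if (missing(seed) || is.null(seed)) {
    stop("seed is required: the generator must be reproducible")
  }
  if (is.null(classes$treatment)) classes$treatment <- "none"
  if (!all(c("class_id", "sex", "temperature", "n_fish") %in% names(classes))) {
    stop("classes needs columns class_id, sex, temperature, n_fish")
  }
  if (any(classes$n_fish < 1L)) stop("n_fish must be >= 1")
  if (clonesPerFish < 1L) stop("clonesPerFish must be >= 1")
  siteMethProbs <- as.matrix(siteMethProbs)
  if (nrow(siteMethProbs) != nrow(classes) ||
      ncol(siteMethProbs) != nLoci(assay)) {
    stop("siteMethProbs must be classes x loci")
  }
  if (is.null(rownames(siteMethProbs))) {
    rownames(siteMethProbs) <- classes$class_id
  }
  probs <- c(siteMethProbs, allOrNoneWeight, conversionFailureRate, dropoutRate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (fishEffectSd < 0 || sequencingErrorRate < 0) {
    stop("rates and standard deviations must be non-negative")
  }
  structure(list(
    assay = assay, classes = classes, siteMethProbs = siteMethProbs,
    clonesPerFish = as.integer(clonesPerFish), fishEffectSd = fishEffectSd,
    allOrNoneWeight = allOrNoneWeight,
    conversionFailureRate = conversionFailureRate,
    sequencingErrorRate = sequencingErrorRate, dropoutRate = dropoutRate,
    seed = as.integer(seed)
  ), class = "GeneratorConfig")
}

#' Per-CpG probabilities with a fixed across-site profile
#'
#' Spreads a target class mean over L sites with a fixed, centred
#' site-profile (linear from -spread to +spread), so the across-site
#' average equals the class mean while sites differ, as they do in real
#' promoter data.  Values are clamped to `[0.001, 0.999]`.
#'
#' @param classMean target across-site mean methylation in `[0, 1]`.
#' @param L number of loci.
#' @param spread half-range of the site profile.
#' @return numeric vector of length L.
#' @export
siteProbsFromMean <- function(classMean, L = 7L, spread = 0.1) {
  if (L == 1L) return(pmin(pmax(classMean, 0.001), 0.999))
  p <- classMean + seq(-spread, spread, length.out = L)
  pmin(pmax(p, 0.001), 0.999)
}

#' The study-design generator configuration
#'
#' Default synthetic experiment mirroring the one-year-old gonad design:
#' four classes (females and males at low and high temperature) with the
#' published fish counts (FLT 14, FHT 8, MLT 15, MHT 15), 10 clones per
#' fish, and per-CpG probabilities whose across-site averages equal the
#' published class means (FLT 37.1%, FHT 53.9%, MLT 77.0%, MHT 85.3%).
#'
#' @param assay a [PromoterAssay-class] (default the packaged cyp19a
#'   fixture).
#' @param seed integer seed.
#' @param ... overrides passed to [generatorConfig()].
#' @return a `GeneratorConfig`.
#' @export
studyGeneratorConfig <- function(assay = cyp19aAssay(), seed, ...) {
  classes <- data.frame(
    class_id = c("FLT", "FHT", "MLT", "MHT"),
    sex = c("F", "F", "M", "M"),
    temperature = c("LT", "HT", "LT", "HT"),
    n_fish = c(14L, 8L, 15L, 15L)
  )
  means <- c(FLT = 0.371, FHT = 0.539, MLT = 0.770, MHT = 0.853)
  probs <- t(vapply(means, siteProbsFromMean, numeric(nLoci(assay)),
                    L = nLoci(assay)))
  generatorConfig(assay, classes, probs, seed = seed, ...)
}

.clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Simulate a clone-based bisulfite sequencing dataset
#'
#' For each fish i in class g, the per-site methylation propensity is
#' `logit(theta[i, j]) = logit(p[g, j]) + u_i` with a fish intercept
#' `u_i ~ Normal(0, sigma_fish^2)` shared across sites.  Each clone is,
#' with probability rho, an all-or-none epiallele (all-M with probability
#' `mean_j theta[i, j]`, otherwise all-U) and otherwise has independent
#' `Bernoulli(theta[i, j])` states per site.  The clone sequence is the
#' amplicon read through bisulfite: a CpG-locus C stays C when methylated
#' and reads T otherwise; every non-CpG C reads T except that with
#' probability epsilon it escapes conversion and stays C; sequencing
#' errors substitute random bases; dropout masks locus bases as N.
#' Deterministic given config and seed.
#'
#' @param config a `GeneratorConfig` from [generatorConfig()].
#' @return list with `sequences` (named character vector, names
#'   `fishID|cloneID`), `sampleSheet` (data.frame), and `truth` (list with
#'   the per-fish propensity matrix `theta`, the pre-noise binary clone
#'   `patterns`, and the clone-to-fish map).
#' @export
simulateCloneDataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  assay <- config$assay
  ctx <- .referenceContext(assay)
  L <- nLoci(assay)
  cls <- config$classes
  nFishTotal <- sum(cls$n_fish)
  fishClass <- rep(seq_len(nrow(cls)), cls$n_fish)
  fishId <- unlist(lapply(seq_len(nrow(cls)), function(k) {
    sprintf("%s_f%02d", cls$class_id[k], seq_len(cls$n_fish[k]))
  }))

  # fish propensities
  u <- stats::rnorm(nFishTotal, 0, config$fishEffectSd)
  logitP <- stats::qlogis(.clamp01(config$siteMethProbs))
  theta <- stats::plogis(logitP[fishClass, , drop = FALSE] + u)
  rownames(theta) <- fishId

  # clone patterns
  m <- config$clonesPerFish
  nClones <- nFishTotal * m
  cloneFish <- rep(seq_len(nFishTotal), each = m)
  patterns <- matrix(FALSE, nClones, L)
  if (L > 0L) {
    aon <- stats::runif(nClones) < config$allOrNoneWeight
    thetaBar <- rowMeans(theta)
    allM <- stats::runif(nClones) < thetaBar[cloneFish]
    patterns[aon, ] <- allM[aon]
    ind <- which(!aon)
    if (length(ind)) {
      patterns[ind, ] <- stats::runif(length(ind) * L) <
        theta[cloneFish[ind], , drop = FALSE]
    }
  }

  # bisulfite-space sequences
  seqMat <- matrix(rep(ctx$bases, each = nClones), nClones, ctx$n)
  if (length(ctx$nonCpGCPos)) {
    conv <- matrix("T", nClones, length(ctx$nonCpGCPos))
    conv[stats::runif(length(conv)) < config$conversionFailureRate] <- "C"
    seqMat[, ctx$nonCpGCPos] <- conv
  }
  if (L > 0L) {
    seqMat[, ctx$locusPos] <- ifelse(patterns, "C", "T")
  }
  if (config$sequencingErrorRate > 0) {
    hit <- which(stats::runif(length(seqMat)) < config$sequencingErrorRate)
    if (length(hit)) {
      alphabet <- c("A", "C", "G", "T")
      cur <- match(seqMat[hit], alphabet)
      seqMat[hit] <- alphabet[(cur - 1L +
        sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L]
    }
  }
  if (config$dropoutRate > 0 && L > 0L) {
    drop <- matrix(stats::runif(nClones * L) < config$dropoutRate, nClones, L)
    sub <- seqMat[, ctx$locusPos, drop = FALSE]
    sub[drop] <- "N"
    seqMat[, ctx$locusPos] <- sub
  }
  sequences <- do.call(paste0, asplit(seqMat, 2))
  names(sequences) <- paste0(fishId[cloneFish], "|c",
                             sprintf("%02d", rep(seq_len(m), nFishTotal)))

  sheet <- data.frame(
    fish_id = fishId,
    sex = cls$sex[fishClass],
    temperature = cls$temperature[fishClass],
    treatment = cls$treatment[fishClass],
    tissue = "gonad",
    family = "sim",
    class_id = cls$class_id[fishClass],
    stringsAsFactors = FALSE
  )
  list(
    sequences = sequences,
    sampleSheet = sheet,
    truth = list(theta = theta, patterns = patterns,
                 clone_fish = fishId[cloneFish])
  )
}

#' Write simulated clones to FASTA
#'
#' @param sequences named character vector as returned by
#'   [simulateCloneDataset()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writeCloneFasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate a qPCR Ct table
#'
#' Emulates the expression arm of the study: per fish, replicate Ct values
#' for the target gene (cyp19a) and the reference gene (18S) with Normal
#' noise.  True females receive the lower target Ct (higher expression);
#' the default 5-cycle separation mirrors the clear two-mode split seen in
#' the study's expression data.  Default design: 16 fish per temperature
#' group, half of each group female.
#'
#' @param nFishPerGroup fish per temperature group (default 16).
#' @param groups temperature groups.
#' @param nFemalePerGroup true females per group (default half, rounded up).
#' @param targetCtFemale,targetCtMale mean target-gene Ct by true sex.
#' @param referenceCt mean reference-gene Ct.
#' @param ctSd replicate noise SD in cycles.
#' @param duplicates replicates per gene per fish (study: duplicate wells).
#' @param seed integer seed.
#' @return list with `ctTable` (data.frame `fish_id`, `temperature`,
#'   `gene`, `replicate`, `ct`) and `truth` (data.frame `fish_id`,
#'   `temperature`, `true_sex`).
#' @export
simulateExpressionTable <- function(nFishPerGroup = 16L,
                                    groups = c("LT", "HT"),
                                    nFemalePerGroup = ceiling(nFishPerGroup / 2),
                                    targetCtFemale = 24,
                                    targetCtMale = 29,
                                    referenceCt = 12,
                                    ctSd = 0.25,
                                    duplicates = 2L,
                                    seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (ctSd < 0) stop("ctSd must be >= 0")
  set.seed(as.integer(seed))
  rows <- list(); truths <- list()
  for (g in groups) {
    sexes <- rep(c("F", "M"), c(nFemalePerGroup, nFishPerGroup - nFemalePerGroup))
    fid <- sprintf("%s_x%02d", g, seq_len(nFishPerGroup))
    truths[[g]] <- data.frame(fish_id = fid, temperature = g, true_sex = sexes)
    mu <- ifelse(sexes == "F", targetCtFemale, targetCtMale)
    for (r in seq_len(duplicates)) {
      rows[[paste(g, r, "t")]] <- data.frame(
        fish_id = fid, temperature = g, gene = "cyp19a", replicate = r,
        ct = stats::rnorm(nFishPerGroup, mu, ctSd))
      rows[[paste(g, r, "r")]] <- data.frame(
        fish_id = fid, temperature = g, gene = "18S", replicate = r,
        ct = stats::rnorm(nFishPerGroup, referenceCt, ctSd))
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  ct <- ct[order(ct$fish_id, ct$gene, ct$replicate), ]
  rownames(ct) <- NULL
  list(ctTable = ct, truth = do.call(rbind, c(truths, make.row.names = FALSE)))
}
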