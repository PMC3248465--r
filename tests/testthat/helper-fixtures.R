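# Shared fixtures and the independent AMOVA oracle.

# 20-bp toy amplicon: declared CpG loci at 0-based indices 1 and 12,
# three non-CpG cytosines (5, 6, 9), plus one UNdeclared CG at 16 (the
# panel is partial, as in real assays).
toyAssay <- function() {
  PromoterAssay("toy", "ACGATCCATCAGCGTACGTT",
                data.frame(tss_label = c(-5L, 3L),
                           amplicon_index = c(1L, 12L)))
}

mkSheet <- function(fishIds, sex = "F", temperature = "LT",
                    treatment = "none", tissue = "gonad", family = "fam") {
  data.frame(fish_id = fishIds, sex = sex, temperature = temperature,
             treatment = treatment, tissue = tissue, family = family,
             stringsAsFactors = FALSE)
}

# Build a MethCallSet directly from an integer 0/1/NA matrix.
mkCallSet <- function(calls, fish, sheet, assay = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(assay)) {
    # synthetic assay with the right number of loci
    L <- ncol(calls)
    seq <- paste(rep("CGA", max(L, 1L)), collapse = "")
    assay <- PromoterAssay("adhoc", seq,
                           data.frame(tss_label = seq_len(L) * 2L - 1L,
                                      amplicon_index = (seq_len(L) - 1L) * 3L))
  }
  colnames(calls) <- tssLabels(assay)
  cd <- data.frame(fish_id = fish,
                   clone_id = paste0("c", seq_along(fish)),
                   conversion_efficiency = NA_real_,
                   n_nonCpG_C = 0L,
                   orientation = "forward",
                   complete = !apply(is.na(calls), 1L, any),
                   stringsAsFactors = FALSE)
  rownames(calls) <- paste0(cd$fish_id, "|", cd$clone_id)
  methods::new("MethCallSet", assay = assay, calls = calls, cloneData = cd,
               sampleSheet = sheet)
}

# Independent AMOVA oracle.  Sums of squares via the per-site ANOVA
# identity (deviations from centroids, no pairwise distances anywhere);
# variance components from the expected-mean-square equations written
# out from the group sizes.
amovaOracle <- function(h, fish, class) {
  h <- as.matrix(h)
  N <- nrow(h)
  fishLv <- unique(fish)
  grpOfFish <- class[match(fishLv, fish)]
  grpLv <- unique(class)
  devSS <- function(rows) {
    if (length(rows) < 2L) return(0)
    x <- h[rows, , drop = FALSE]
    sum(sweep(x, 2L, colMeans(x))^2)
  }
  ssTot <- devSS(seq_len(N))
  ssWP <- sum(vapply(fishLv, function(f) devSS(which(fish == f)), 0))
  ssWG <- sum(vapply(grpLv, function(g) devSS(which(class == g)), 0))
  ssB <- ssWG - ssWP
  ssA <- ssTot - ssWG
  P <- length(fishLv); G <- length(grpLv)
  sizes <- vapply(fishLv, function(f) sum(fish == f), 0)
  Ng <- vapply(grpLv, function(g) sum(class == g), 0)
  dfA <- G - 1; dfB <- P - G; dfC <- N - P
  msA <- if (dfA > 0) ssA / dfA else 0
  msB <- if (dfB > 0) ssB / dfB else 0
  msC <- if (dfC > 0) ssWP / dfC else 0
  s1 <- sum(vapply(grpLv, function(g) {
    sum(sizes[grpOfFish == g]^2) / sum(sizes[grpOfFish == g])
  }, 0))
  s2 <- sum(sizes^2) / N
  n1 <- if (dfB > 0) (N - s1) / dfB else 0
  n2 <- if (dfA > 0) (s1 - s2) / dfA else 0
  n3 <- if (dfA > 0) (N - sum(Ng^2) / N) / dfA else 0
  sigC <- msC
  sigB <- if (dfB > 0 && n1 > 0) (msB - sigC) / n1 else 0
  sigA <- if (dfA > 0 && n3 > 0) (msA - sigC - n2 * sigB) / n3 else 0
  tot <- sigA + sigB + sigC
  phi <- if (tot > 1e-12) {
    c(phi_ct = sigA / tot,
      phi_sc = if (sigB + sigC > 0) sigB / (sigB + sigC) else 0,
      phi_st = (sigA + sigB) / tot)
  } else c(phi_ct = 0, phi_sc = 0, phi_st = 0)
  list(ss = c(among_groups = ssA, among_fish_within_groups = ssB,
              within_fish = ssWP, total = ssTot),
       sigma2 = c(a = sigA, b = sigB, c = sigC), phi = phi)
}

# Random small haplotype layout for oracle-equivalence checks.
randomHaplotypeSet <- function(maxHap = 12L) {
  G <- sample(2:3, 1)
  fishPerGroup <- sample(1:3, G, replace = TRUE)
  L <- sample(2:4, 1)
  fish <- character(0); class <- character(0)
  f <- 0L
  for (g in seq_len(G)) {
    for (k in seq_len(fishPerGroup[g])) {
      f <- f + 1L
      nc <- sample(1:3, 1)
      fish <- c(fish, rep(paste0("f", f), nc))
      class <- c(class, rep(paste0("g", g), nc))
    }
  }
  if (length(fish) > maxHap) {
    keep <- seq_len(maxHap)
    fish <- fish[keep]; class <- class[keep]
  }
  h <- matrix(rbinom(length(fish) * L, 1L, 0.5), length(fish), L)
  structure(list(h = h, fish = fish, class = class, locus = "all"),
            class = "HaplotypeSet")
}
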