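#' Relative quantification (delta-delta-Ct) from a qPCR Ct table
#'
#' Per fish, delta-Ct is the mean target-gene Ct minus the mean
#' reference-gene Ct over replicates.  Following the study's calibrator
#' rule, the sample with the highest delta-Ct (lowest target expression;
#' ties broken by lexicographically smallest fish id) is the calibrator,
#' so its RQ is exactly 1, and RQ = 2^(-delta-delta-Ct) for every fish
#' (amplification efficiency fixed at perfect doubling).  Fish missing
#' either gene are flagged and excluded with a warning.
#'
#' @param ctTable data.frame with columns `fish_id`, `gene`, `replicate`,
#'   `ct` (extra per-fish constant columns such as `temperature` are
#'   carried through).
#' @param referenceGene reference gene name (default "18S").
#' @param targetGene target gene name; by default the single other gene
#'   present.
#' @return data.frame per fish: `fish_id`, carried columns, `delta_ct`,
#'   `delta_delta_ct`, `rq`, `log2_rq`, `calibrator`.
#' @examples
#' sim <- simulateExpressionTable(seed = 1, ctSd = 0)
#' rq <- computeRQ(sim$ctTable)
#' rq$rq[rq$calibrator]   # exactly 1
#' @export
computeRQ <- function(ctTable, referenceGene = "18S", targetGene = NULL) {
  genes <- unique(ctTable$gene)
  if (!referenceGene %in% genes) stop("reference gene absent: ", referenceGene)
  if (is.null(targetGene)) {
    targetGene <- setdiff(genes, referenceGene)
    if (length(targetGene) != 1L) {
      stop("specify targetGene; found: ", paste(genes, collapse = ", "))
    }
  }
  fishIds <- unique(ctTable$fish_id)
  carry <- setdiff(names(ctTable), c("fish_id", "gene", "replicate", "ct"))
  rows <- lapply(fishIds, function(f) {
    d <- ctTable[ctTable$fish_id == f, ]
    tc <- d$ct[d$gene == targetGene]
    rc <- d$ct[d$gene == referenceGene]
    if (!length(tc) || !length(rc)) return(NULL)
    out <- data.frame(fish_id = f, delta_ct = mean(tc) - mean(rc))
    for (cc in carry) out[[cc]] <- d[[cc]][1]
    out
  })
  dropped <- fishIds[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("fish missing a gene, excluded: ", paste(dropped, collapse = ", "))
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec) || nrow(rec) == 0L) stop("no fish with both genes")
  ord <- order(-rec$delta_ct, rec$fish_id)
  calib <- rec$fish_id[ord[1]]
  rec$delta_delta_ct <- rec$delta_ct - rec$delta_ct[rec$fish_id == calib]
  rec$rq <- 2^(-rec$delta_delta_ct)
  rec$log2_rq <- -rec$delta_delta_ct
  rec$calibrator <- rec$fish_id == calib
  rec[c("fish_id", carry, "delta_ct", "delta_delta_ct", "rq", "log2_rq",
        "calibrator")]
}

# Exact 1-D two-means: the optimal 2-partition of sorted values is a
# threshold split, so all n-1 splits are scored and the minimum
# within-cluster sum of squares wins.  Deterministic.
.twoMeans1d <- function(v) {
  o <- order(v)
  x <- v[o]
  n <- length(x)
  csum <- cumsum(x); csq <- cumsum(x^2)
  tot <- csum[n]; totsq <- csq[n]
  wss <- vapply(seq_len(n - 1L), function(k) {
    (csq[k] - csum[k]^2 / k) +
      ((totsq - csq[k]) - (tot - csum[k])^2 / (n - k))
  }, 0)
  k <- which.min(wss)
  cl <- integer(n)
  cl[o] <- rep(1:2, c(k, n - k))   # 1 = low cluster, 2 = high cluster
  cl
}

.meanSilhouette <- function(v, cl) {
  n <- length(v)
  s <- vapply(seq_len(n), function(i) {
    own <- v[cl == cl[i]]; other <- v[cl != cl[i]]
    if (length(own) < 2L) return(0)
    a <- sum(abs(own - v[i])) / (length(own) - 1L)
    b <- mean(abs(other - v[i]))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Two-cluster presumptive-sex assignment from expression
#'
#' Classifies sexually undifferentiated fish as presumptive females or
#' males from gonadal target-gene RQ: within each group (by default each
#' temperature treatment, matching the study's per-treatment runs), the
#' log2(RQ) values are split into two clusters by exact one-dimensional
#' 2-means; the cluster with the higher mean expression is labelled
#' presumptive F.  The mean silhouette width of the split is reported.
#' When all values in a group are identical the fish stay `"unassigned"`
#' with a warning.
#'
#' @param records RQ table from [computeRQ()].
#' @param by grouping column (default `"temperature"`); `NULL` pools all
#'   fish into a single clustering.
#' @return `records` with columns `presumptive_sex` and `silhouette`.
#' @export
clusterPresumptiveSex <- function(records, by = "temperature") {
  grp <- if (is.null(by)) rep("all", nrow(records)) else records[[by]]
  records$presumptive_sex <- "unassigned"
  records$silhouette <- NA_real_
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) < 4L) {
      warning("group ", g, ": fewer than 4 records, left unassigned")
      next
    }
    v <- records$log2_rq[i]
    if (max(v) - min(v) < 1e-12) {
      warning("group ", g, ": all RQ identical, left unassigned")
      next
    }
    cl <- .twoMeans1d(v)
    hi <- which.max(c(mean(v[cl == 1L]), mean(v[cl == 2L])))
    records$presumptive_sex[i] <- ifelse(cl == hi, "F", "M")
    records$silhouette[i] <- .meanSilhouette(v, cl)
  }
  records
}
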