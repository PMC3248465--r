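#' @importFrom stats setNames
NULL

.seqCharMatrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

.revComp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Vectorised calling core.  Gapless anchored comparison in bisulfite
# space: at reference non-C positions the clone must match the reference;
# at C-derived positions both C and T are acceptable.  A clone is accepted
# when its mismatch fraction at the unambiguous (non-C) positions is at
# most `tolerance`; reverse-complement orientation is auto-detected.
.callClones <- function(assay, seqs, tolerance = 0.05) {
  ctx <- .referenceContext(assay)
  nSeq <- length(seqs)
  L <- nLoci(assay)
  unamb <- which(ctx$bases != "C")
  res <- list(
    calls = matrix(NA_integer_, nSeq, L,
                   dimnames = list(names(seqs), tssLabels(assay))),
    conversion = rep(NA_real_, nSeq),
    nNonCpGCovered = rep(0L, nSeq),
    aligned = rep(FALSE, nSeq),
    orientation = rep(NA_character_, nSeq),
    mismatchFraction = rep(NA_real_, nSeq)
  )
  lenOk <- !is.na(seqs) & nchar(seqs) == ctx$n
  if (!any(lenOk)) return(res)

  mismFrac <- function(mat) {
    if (length(unamb) == 0L) return(rep(0, nrow(mat)))
    exp <- matrix(ctx$bases[unamb], nrow(mat), length(unamb), byrow = TRUE)
    rowSums(mat[, unamb, drop = FALSE] != exp) / length(unamb)
  }

  idx <- which(lenOk)
  mat <- .seqCharMatrix(toupper(seqs[idx]))
  frac <- mismFrac(mat)
  orient <- rep("forward", length(idx))
  retry <- which(frac > tolerance)
  if (length(retry)) {
    rcMat <- .seqCharMatrix(.revComp(seqs[idx[retry]]))
    rcFrac <- mismFrac(rcMat)
    better <- rcFrac <= tolerance
    if (any(better)) {
      mat[retry[better], ] <- rcMat[better, , drop = FALSE]
      frac[retry[better]] <- rcFrac[better]
      orient[retry[better]] <- "reverse"
    }
  }
  ok <- frac <= tolerance
  res$aligned[idx] <- ok
  res$mismatchFraction[idx] <- frac
  res$orientation[idx[ok]] <- orient[ok]

  keep <- idx[ok]
  if (length(keep) == 0L) return(res)
  kmat <- mat[ok, , drop = FALSE]
  if (L > 0L) {
    sub <- kmat[, ctx$locusPos, drop = FALSE]
    calls <- matrix(NA_integer_, nrow(sub), ncol(sub))
    calls[sub == "C"] <- 1L
    calls[sub == "T"] <- 0L
    res$calls[keep, ] <- calls
  }
  if (length(ctx$nonCpGCPos)) {
    nc <- kmat[, ctx$nonCpGCPos, drop = FALSE]
    nT <- rowSums(nc == "T")
    nC <- rowSums(nc == "C")
    covered <- nT + nC
    res$nNonCpGCovered[keep] <- as.integer(covered)
    res$conversion[keep] <- ifelse(covered > 0, nT / covered, NA_real_)
  }
  res
}

#' Anchored alignment of one clone to the assay amplicon
#'
#' Gapless comparison in bisulfite space: the clone must have the amplicon
#' length; reference C positions (CpG or not) accept either C or T, and
#' the mismatch fraction at the remaining unambiguous positions must not
#' exceed `tolerance`.  Reverse-complement input is auto-detected.
#'
#' @param assay a [PromoterAssay-class].
#' @param cloneSequence a single clone sequence (character).
#' @param tolerance maximum mismatch fraction at unambiguous positions.
#' @return list with `accepted`, `orientation` ("forward"/"reverse"),
#'   `mismatchFraction`.
#' @export
alignClone <- function(assay, cloneSequence, tolerance = 0.05) {
  r <- .callClones(assay, setNames(as.character(cloneSequence)[1], "clone"),
                   tolerance)
  list(accepted = r$aligned[1], orientation = r$orientation[1],
       mismatchFraction = r$mismatchFraction[1])
}

#' Call methylation states of one clone
#'
#' At each CpG locus the reference C read as C is methylated (`"M"`), read
#' as T unmethylated (`"U"`), and any other base missing (`NA`).  The
#' conversion efficiency is the fraction of covered reference non-CpG C
#' positions read as T, the standard QC for bisulfite completeness.
#'
#' @inheritParams alignClone
#' @return list with `calls` (character vector M/U/NA named by TSS label),
#'   `conversionEfficiency`, and `nNonCpGCovered`.
#' @examples
#' a <- cyp19aAssay()
#' sim <- simulateCloneDataset(studyGeneratorConfig(a, seed = 1))
#' callClone(a, sim$sequences[[1]])$conversionEfficiency
#' @export
callClone <- function(assay, cloneSequence, tolerance = 0.05) {
  r <- .callClones(assay, setNames(as.character(cloneSequence)[1], "clone"),
                   tolerance)
  if (!r$aligned[1]) stop("unalignable clone")
  calls <- c("U", "M")[r$calls[1, ] + 1L]
  names(calls) <- colnames(r$calls)
  list(calls = calls, conversionEfficiency = r$conversion[1],
       nNonCpGCovered = r$nNonCpGCovered[1])
}

#' Build the methylation call set for a clone FASTA
#'
#' Calls every clone against the assay, groups clones by fish via the
#' `fishID|cloneID` record naming, and assembles a [MethCallSet-class].
#' Unalignable clones are excluded with a warning; fish with no alignable
#' clone are dropped from the set (also with a warning).  By default no
#' conversion-efficiency filtering is applied (efficiencies are reported
#' as QC only); `minConversion` excludes clones below the given
#' efficiency.
#'
#' @param assay a [PromoterAssay-class].
#' @param clones clone sequences: a named character vector, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file; names must
#'   parse as `fishID|cloneID`.
#' @param sampleSheet data.frame with at least `fish_id`, `sex`,
#'   `temperature`, `treatment`; every fish referenced by a clone must
#'   appear.
#' @param tolerance alignment mismatch tolerance (see [alignClone()]).
#' @param minConversion minimum per-clone conversion efficiency to retain
#'   a clone (default 0: report only, exclude nothing).
#' @return a [MethCallSet-class].
#' @export
buildCallMatrix <- function(assay, clones, sampleSheet,
                            tolerance = 0.05, minConversion = 0) {
  if (is.character(clones) && length(clones) == 1L && file.exists(clones) &&
      !grepl("[|]", clones)) {
    clones <- Biostrings::readDNAStringSet(clones)
  }
  if (is(clones, "DNAStringSet")) {
    clones <- setNames(as.character(clones), sub("\\s.*", "", names(clones)))
  }
  if (is.null(names(clones)) || !all(grepl("|", names(clones), fixed = TRUE))) {
    stop("clone names must parse as fishID|cloneID")
  }
  ids <- strsplit(names(clones), "|", fixed = TRUE)
  fish <- vapply(ids, `[[`, "", 1L)
  cloneId <- vapply(ids, function(x) paste(x[-1], collapse = "|"), "")
  unknown <- setdiff(unique(fish), sampleSheet$fish_id)
  if (length(unknown)) {
    stop("fish not in sample sheet: ", paste(unknown, collapse = ", "))
  }

  r <- .callClones(assay, clones, tolerance)
  if (any(!r$aligned)) {
    warning(sum(!r$aligned), " unalignable clone(s) excluded: ",
            paste(utils::head(names(clones)[!r$aligned], 5), collapse = ", "))
  }
  keep <- r$aligned
  if (minConversion > 0) {
    keep <- keep & (is.na(r$conversion) | r$conversion >= minConversion)
  }
  if (!any(keep)) stop("no alignable clones")
  calls <- r$calls[keep, , drop = FALSE]
  cloneData <- data.frame(
    fish_id = fish[keep],
    clone_id = cloneId[keep],
    conversion_efficiency = r$conversion[keep],
    n_nonCpG_C = r$nNonCpGCovered[keep],
    orientation = r$orientation[keep],
    complete = !apply(is.na(calls), 1L, any),
    stringsAsFactors = FALSE
  )
  if (ncol(calls) == 0L) cloneData$complete <- TRUE
  lost <- setdiff(unique(fish), cloneData$fish_id)
  if (length(lost)) {
    warning("fish with no alignable clones excluded: ",
            paste(lost, collapse = ", "))
  }
  few <- names(which(table(cloneData$fish_id) < 10L))
  if (length(few)) {
    message("note: fish with fewer than 10 clones (study design allows 7-10): ",
            paste(few, collapse = ", "))
  }
  sheet <- sampleSheet[sampleSheet$fish_id %in% cloneData$fish_id, ,
                       drop = FALSE]
  rownames(calls) <- paste0(cloneData$fish_id, "|", cloneData$clone_id)
  new("MethCallSet", assay = assay, calls = calls, cloneData = cloneData,
      sampleSheet = sheet)
}

#' @rdname MethCallSet-accessors
#' @export
setGeneric("callsMatrix", function(x) standardGeneric("callsMatrix"))
#' @rdname MethCallSet-accessors
#' @export
setGeneric("cloneData", function(x) standardGeneric("cloneData"))
#' @rdname MethCallSet-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' Accessors for MethCallSet
#'
#' @param x a [MethCallSet-class].
#' @return `callsMatrix` the clones x loci 0/1/NA integer matrix;
#'   `cloneData` the per-clone QC data.frame; `sampleSheet` the fish
#'   metadata; `cpgLoci`/`nLoci`/`tssLabels` delegate to the assay.
#' @name MethCallSet-accessors
#' @aliases callsMatrix cloneData
NULL

#' @rdname MethCallSet-accessors
setMethod("callsMatrix", "MethCallSet", function(x) x@calls)
#' @rdname MethCallSet-accessors
setMethod("cloneData", "MethCallSet", function(x) x@cloneData)
#' @rdname MethCallSet-accessors
setMethod("sampleSheet", "MethCallSet", function(x) x@sampleSheet)
#' @rdname MethCallSet-accessors
setMethod("nLoci", "MethCallSet", function(x) nLoci(x@assay))
#' @rdname MethCallSet-accessors
setMethod("tssLabels", "MethCallSet", function(x) tssLabels(x@assay))
#' @rdname MethCallSet-accessors
setMethod("cpgLoci", "MethCallSet", function(x) cpgLoci(x@assay))

setMethod("show", "MethCallSet", function(object) {
  cd <- object@cloneData
  cat("MethCallSet on", object@assay@name, "\n")
  cat(" ", nrow(cd), "clones from", length(unique(cd$fish_id)), "fish;",
      sum(cd$complete), "complete\n")
  conv <- cd$conversion_efficiency
  if (any(!is.na(conv))) {
    cat("  mean conversion efficiency:",
        sprintf("%.2f%%", 100 * mean(conv, na.rm = TRUE)), "\n")
  }
})

#' Per-fish and per-locus mean methylation
#'
#' Per-locus means are M/(M+U) ignoring missing calls; the per-fish mean
#' is the average over loci of the per-locus means (equal locus
#' weighting), skipping loci with no informative call.
#'
#' @param x a [MethCallSet-class].
#' @return `fishLocusMeans`: numeric matrix fish x loci (NaN where a fish
#'   has no call at a locus).  `fishMeanMethylation`: named numeric vector
#'   of per-fish means.
#' @export
fishLocusMeans <- function(x) {
  calls <- callsMatrix(x)
  f <- factor(cloneData(x)$fish_id, levels = unique(cloneData(x)$fish_id))
  m <- rowsum(ifelse(is.na(calls), 0L, calls), f)
  n <- rowsum((!is.na(calls)) + 0L, f)
  out <- m / n   # NaN where n == 0
  colnames(out) <- colnames(calls)
  out
}

#' @rdname fishLocusMeans
#' @export
fishMeanMethylation <- function(x) {
  lm <- fishLocusMeans(x)
  res <- rowMeans(lm, na.rm = TRUE)
  res[is.nan(res)] <- NA_real_
  res
}

#' Mean methylation of a single clone-by-locus call matrix
#'
#' Convenience for a hand-assembled matrix of calls for one fish: values
#' may be 0/1/NA integers or "M"/"U"/NA characters.  Loci with no
#' informative call are flagged and excluded from the fish mean.
#'
#' @param calls a clones x loci matrix.
#' @return list with `locus_means`, `fish_mean`, and `undefined_loci`
#'   (indices of loci with no call).
#' @examples
#' m <- rbind(c(1, 0, 1), c(1, 1, NA))
#' clonesMeanMethylation(m)$fish_mean  # (1 + 0.5 + 1)/3
#' @export
clonesMeanMethylation <- function(calls) {
  if (is.character(calls)) {
    calls <- matrix(match(calls, c("U", "M")) - 1L, nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  }
  if (all(is.na(calls))) stop("at least one non-missing call is required")
  lm <- colSums(calls == 1L, na.rm = TRUE) / colSums(!is.na(calls))
  undef <- which(is.nan(lm))
  list(locus_means = lm, fish_mean = mean(lm[!is.nan(lm)]),
       undefined_loci = undef)
}

#' Per-fish summary table for group statistics
#'
#' One row per fish with class labels, the per-fish mean methylation and
#' its arcsine square-root transform (the analysis scale for all group
#' statistics).
#'
#' @param x a [MethCallSet-class].
#' @param classBy sample-sheet columns defining the treatment classes.
#' @return data.frame `fish_id`, the class columns, `class`,
#'   `mean_methylation`, `transformed`.
#' @export
fishSummaries <- function(x, classBy = c("sex", "temperature")) {
  means <- fishMeanMethylation(x)
  sheet <- sampleSheet(x)
  out <- sheet[match(names(means), sheet$fish_id), , drop = FALSE]
  out$class <- classLabels(out, classBy)
  out$mean_methylation <- unname(means)
  out$transformed <- arcsinSqrt(out$mean_methylation)
  rownames(out) <- NULL
  out
}

#' Group mean methylation
#'
#' Class-level summaries of the per-fish means (the primary aggregation),
#' with the pooled-call mean per class also reported.
#'
#' @inheritParams fishSummaries
#' @param by column(s) of the sample sheet to group by (default the
#'   sex x temperature class).
#' @return data.frame with `n_fish`, `mean_methylation` (mean of fish
#'   means), `sem`, and `pooled_mean` (all calls pooled).
#' @export
groupMeanMethylation <- function(x, by = c("sex", "temperature")) {
  fs <- fishSummaries(x, classBy = by)
  calls <- callsMatrix(x)
  sheet <- sampleSheet(x)
  cl <- classLabels(sheet, by)[match(cloneData(x)$fish_id, sheet$fish_id)]
  pooled <- vapply(split(seq_len(nrow(calls)), cl), function(i) {
    mean(calls[i, , drop = FALSE], na.rm = TRUE)
  }, 0)
  agg <- do.call(rbind, lapply(split(fs, fs$class), function(d) {
    data.frame(class = d$class[1], n_fish = nrow(d),
               mean_methylation = mean(d$mean_methylation, na.rm = TRUE),
               sem = stats::sd(d$mean_methylation, na.rm = TRUE) /
                 sqrt(sum(!is.na(d$mean_methylation))))
  }))
  agg$pooled_mean <- pooled[agg$class]
  rownames(agg) <- NULL
  agg
}

#' QC report for a call set
#'
#' Per-fish clone counts, complete-clone counts and mean conversion
#' efficiency, plus mean conversion per tissue as an attribute
#' (`tissue_conversion`).
#'
#' @param x a [MethCallSet-class].
#' @return data.frame, one row per fish.
#' @export
qcReport <- function(x) {
  cd <- cloneData(x)
  sheet <- sampleSheet(x)
  sp <- split(cd, cd$fish_id)
  rep <- do.call(rbind, lapply(sp, function(d) {
    data.frame(fish_id = d$fish_id[1], n_clones = nrow(d),
               n_complete = sum(d$complete),
               mean_conversion = mean(d$conversion_efficiency, na.rm = TRUE))
  }))
  rep <- merge(sheet[c("fish_id", "sex", "temperature", "treatment", "tissue")],
               rep, by = "fish_id")
  tconv <- tapply(cd$conversion_efficiency,
                  sheet$tissue[match(cd$fish_id, sheet$fish_id)],
                  mean, na.rm = TRUE)
  attr(rep, "tissue_conversion") <- tconv
  rep
}

#' Text lollipop rendering of a fish's call matrix
#'
#' One line per clone: filled circle = methylated, open circle =
#' unmethylated, dot = missing, in locus order.
#'
#' @param x a [MethCallSet-class].
#' @param fishId the fish to render.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
lollipopText <- function(x, fishId) {
  cd <- cloneData(x)
  rows <- which(cd$fish_id == fishId)
  if (!length(rows)) stop("unknown fish: ", fishId)
  calls <- callsMatrix(x)[rows, , drop = FALSE]
  glyph <- matrix(".", nrow(calls), ncol(calls))
  glyph[!is.na(calls) & calls == 1L] <- "●"
  glyph[!is.na(calls) & calls == 0L] <- "○"
  lines <- paste(cd$clone_id[rows],
                 apply(glyph, 1L, paste, collapse = " "))
  header <- paste(c("clone", colnames(calls)), collapse = " ")
  out <- c(header, lines)
  cat(out, sep = "\n")
  invisible(out)
}

#' Write the calls table to TSV
#'
#' Columns: `fish_id`, `clone_id`, one M/U/NA column per TSS label, and
#' `conversion_efficiency`.
#'
#' @param x a [MethCallSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCallsTable <- function(x, path) {
  calls <- callsMatrix(x)
  mu <- matrix(c("U", "M")[calls + 1L], nrow(calls), ncol(calls))
  colnames(mu) <- paste0("cpg_", colnames(calls))
  cd <- cloneData(x)
  out <- data.frame(fish_id = cd$fish_id, clone_id = cd$clone_id, mu,
                    conversion_efficiency = cd$conversion_efficiency,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
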