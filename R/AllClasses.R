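#' @import methods
NULL

#' PromoterAssay: a bisulfite amplicon with declared CpG loci
#'
#' A `PromoterAssay` anchors every downstream computation: it holds the
#' sense-strand reference sequence of the sequenced amplicon and the ordered
#' set of CpG loci assayed on it.  Loci are labelled by their position
#' relative to the transcription start site (TSS) using the signed
#' convention in which -1 abuts +1 and there is no position 0; internally
#' each locus is stored as a 0-based index of the C of the CG dinucleotide
#' on the amplicon.  The panel is declarative: an assay may cover only a
#' subset of the CG dinucleotides present in the sequence.
#'
#' @slot name character(1), assay name.
#' @slot referenceSequence character(1), sense-strand amplicon sequence
#'   (A/C/G/T).
#' @slot cpgLoci data.frame with integer columns `tss_label` (signed,
#'   strictly increasing, never 0) and `amplicon_index` (0-based index of
#'   the locus C).
#'
#' @seealso [loadAssay()], [cyp19aAssay()], [mapLabelToIndex()]
#' @exportClass PromoterAssay
setClass("PromoterAssay",
  representation(
    name = "character",
    referenceSequence = "character",
    cpgLoci = "data.frame"
  )
)

setValidity("PromoterAssay", function(object) {
  seq <- object@referenceSequence
  loci <- object@cpgLoci
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    return("referenceSequence must be a single non-empty string")
  }
  if (grepl("[^ACGT]", seq)) {
    return("referenceSequence may contain only A/C/G/T")
  }
  if (!all(c("tss_label", "amplicon_index") %in% names(loci))) {
    return("cpgLoci needs columns tss_label and amplicon_index")
  }
  if (nrow(loci) == 0L) return(TRUE)
  if (any(loci$tss_label == 0L)) {
    return("invalid coordinate convention: no position 0 exists")
  }
  if (any(diff(loci$tss_label) <= 0L)) {
    return("tss_labels must be strictly increasing")
  }
  n <- nchar(seq)
  idx <- loci$amplicon_index
  if (any(idx < 0L | idx > n - 2L)) {
    return("invalid locus: amplicon_index outside [0, len - 2]")
  }
  dinuc <- substring(seq, idx + 1L, idx + 2L)
  if (any(dinuc != "CG")) {
    bad <- loci$tss_label[dinuc != "CG"]
    return(sprintf("invalid locus: no CG dinucleotide at label %s",
                   paste(bad, collapse = ", ")))
  }
  TRUE
})

#' MethCallSet: methylation calls for a set of clones
#'
#' Container for the per-clone methylation call matrix produced by
#' [buildCallMatrix()].  Rows are clones (from all fish), columns are the
#' CpG loci of the assay in label order.  Calls are coded 1 (methylated,
#' C retained), 0 (unmethylated, C read as T) or `NA` (missing: locus not
#' readable on that clone).  Per-clone bisulfite conversion efficiency is
#' carried alongside as QC.
#'
#' @slot assay the [PromoterAssay-class] the calls were made against.
#' @slot calls integer matrix, clones x loci, values 0/1/NA; column names
#'   are the TSS-relative labels, row names the clone identifiers.
#' @slot cloneData data.frame, one row per clone: `fish_id`, `clone_id`,
#'   `conversion_efficiency`, `n_nonCpG_C` (non-CpG cytosine positions
#'   informing the efficiency) and `complete` (no missing call).
#' @slot sampleSheet data.frame mapping `fish_id` to `sex`, `temperature`,
#'   `treatment`, `tissue`, `family`.
#'
#' @seealso [buildCallMatrix()], [fishMeanMethylation()], [qcReport()]
#' @exportClass MethCallSet
setClass("MethCallSet",
  representation(
    assay = "PromoterAssay",
    calls = "matrix",
    cloneData = "data.frame",
    sampleSheet = "data.frame"
  )
)

setValidity("MethCallSet", function(object) {
  if (nrow(object@calls) != nrow(object@cloneData)) {
    return("calls and cloneData disagree on the number of clones")
  }
  if (ncol(object@calls) != nrow(object@assay@cpgLoci)) {
    return("calls must have one column per assay locus")
  }
  vals <- object@calls
  if (!all(vals %in% c(0L, 1L, NA_integer_))) {
    return("calls must be 0, 1 or NA")
  }
  need <- c("fish_id", "clone_id", "conversion_efficiency", "complete")
  if (!all(need %in% names(object@cloneData))) {
    return(sprintf("cloneData needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(object@cloneData$fish_id %in% object@sampleSheet$fish_id)) {
    return("every clone's fish must appear in the sample sheet")
  }
  TRUE
})

#' AmovaResult: hierarchical variance decomposition of methylation haplotypes
#'
#' Result of a three-level analysis of molecular variance on binary
#' methylation haplotypes: clones within fish (populations) within
#' treatment classes (groups).  Sums of squares are computed from pairwise
#' Hamming distances (equal to squared Euclidean distance on 0/1 vectors);
#' variance components use the standard unbalanced-design coefficient
#' equations and may be negative.  `fst` is the reported fixation index,
#' defined as Phi_CT (differentiation among classes with fish as
#' populations); Phi_ST and Phi_SC are also available.
#'
#' @slot ss named numeric: `among_groups`, `among_fish_within_groups`,
#'   `within_fish`, `total`.
#' @slot df named numeric degrees of freedom for the three levels.
#' @slot sigma2 named numeric variance components `a` (among groups),
#'   `b` (among fish within groups), `c` (within fish).
#' @slot phi named numeric: `phi_ct`, `phi_sc`, `phi_st`.
#' @slot fst numeric(1), the reported fixation index (= Phi_CT).
#' @slot pValues named numeric permutation p-values (NA when no
#'   permutation test was run).
#' @slot nPermutations integer(1).
#' @slot seed integer(1) seed used for permutations (NA if none).
#' @slot monomorphic logical(1), TRUE when the total variance is zero and
#'   the Phi statistics are returned as 0 by convention.
#' @slot nHaplotypes integer(1) number of haplotypes analysed.
#' @slot comparison character(1) description of the classes compared.
#' @slot locus character(1), `"all"` or a single TSS label.
#'
#' @seealso [amovaDecompose()], [amova()], [pairwiseFst()]
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(
    ss = "numeric",
    df = "numeric",
    sigma2 = "numeric",
    phi = "numeric",
    fst = "numeric",
    pValues = "numeric",
    nPermutations = "integer",
    seed = "integer",
    monomorphic = "logical",
    nHaplotypes = "integer",
    comparison = "character",
    locus = "character"
  )
)

setValidity("AmovaResult", function(object) {
  tot <- object@ss[["total"]]
  parts <- object@ss[["among_groups"]] +
    object@ss[["among_fish_within_groups"]] + object@ss[["within_fish"]]
  if (abs(tot - parts) > 1e-9 * max(1, abs(tot))) {
    return("sums of squares do not add up to the total")
  }
  if (any(object@phi > 1 + 1e-12, na.rm = TRUE)) {
    return("Phi statistics cannot exceed 1")
  }
  TRUE
})
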