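#' Construct a PromoterAssay
#'
#' Low-level constructor; most users will call [loadAssay()] on files or
#' [cyp19aAssay()] for the packaged synthetic cyp19a fixture.
#'
#' @param name assay name.
#' @param referenceSequence sense-strand amplicon sequence (character or
#'   [Biostrings::DNAString]).
#' @param cpgLoci data.frame with columns `tss_label` (signed integer,
#'   no 0) and `amplicon_index` (0-based index of the locus C), or NULL /
#'   zero rows for an empty panel.
#' @return a validated [PromoterAssay-class].
#' @examples
#' PromoterAssay("toy", "ACGTTACGTT",
#'               data.frame(tss_label = c(-2L, 3L),
#'                          amplicon_index = c(1L, 6L)))
#' @export
PromoterAssay <- function(name, referenceSequence, cpgLoci = NULL) {
  if (is(referenceSequence, "DNAString") || is(referenceSequence, "DNAStringSet")) {
    referenceSequence <- as.character(referenceSequence)[1]
  }
  referenceSequence <- toupper(referenceSequence)
  if (is.null(cpgLoci) || nrow(cpgLoci) == 0L) {
    cpgLoci <- data.frame(tss_label = integer(0), amplicon_index = integer(0))
  }
  cpgLoci$tss_label <- as.integer(cpgLoci$tss_label)
  cpgLoci$amplicon_index <- as.integer(cpgLoci$amplicon_index)
  cpgLoci <- cpgLoci[order(cpgLoci$tss_label), , drop = FALSE]
  rownames(cpgLoci) <- NULL
  new("PromoterAssay", name = name, referenceSequence = referenceSequence,
      cpgLoci = cpgLoci)
}

#' Load a promoter assay from a FASTA file and a locus table
#'
#' The reference amplicon is given as FASTA (first record used) and the
#' CpG panel as a sidecar TSV with header `tss_label`, `amplicon_index`
#' (0-based index of the C of each CG).  All assay invariants are checked:
#' each locus must sit on a CG dinucleotide, labels must be strictly
#' increasing and position 0 does not exist.
#'
#' @param fastaFile path to the amplicon FASTA.
#' @param lociFile path to the locus TSV.
#' @param name assay name; defaults to the FASTA record id.
#' @return a validated [PromoterAssay-class].
#' @export
loadAssay <- function(fastaFile, lociFile, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaFile)
  if (length(seqs) == 0L) stop("no sequence in ", fastaFile)
  if (is.null(name)) name <- sub("\\s.*", "", names(seqs)[1])
  loci <- utils::read.delim(lociFile, sep = "\t", stringsAsFactors = FALSE)
  PromoterAssay(name, seqs[[1]], loci)
}

#' The packaged synthetic cyp19a promoter assay
#'
#' A 520-bp synthetic amplicon carrying seven CpG loci at the TSS-relative
#' positions assayed in the sea bass cyp19a promoter study (-431, -56,
#' -49, -33, -13, +9, +60).  The sequence itself is synthetic (the study
#' amplicon was not deposited): it shares the locus count, label spacing
#' and a realistic non-CpG cytosine density (113 non-CpG Cs), and contains
#' no CG dinucleotide outside the declared panel.
#'
#' @return a [PromoterAssay-class] with L = 7.
#' @examples
#' nLoci(cyp19aAssay())
#' @export
cyp19aAssay <- function() {
  loadAssay(
    system.file("extdata", "cyp19a_synthetic_amplicon.fa", package = "epiclone"),
    system.file("extdata", "cyp19a_synthetic_loci.tsv", package = "epiclone"),
    name = "cyp19a_promoter_synthetic"
  )
}

#' @rdname PromoterAssay-accessors
#' @export
setGeneric("assayName", function(x) standardGeneric("assayName"))
#' @rdname PromoterAssay-accessors
#' @export
setGeneric("referenceSequence", function(x) standardGeneric("referenceSequence"))
#' @rdname PromoterAssay-accessors
#' @export
setGeneric("cpgLoci", function(x) standardGeneric("cpgLoci"))
#' @rdname PromoterAssay-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname PromoterAssay-accessors
#' @export
setGeneric("tssLabels", function(x) standardGeneric("tssLabels"))

#' Accessors for PromoterAssay
#'
#' @param x a [PromoterAssay-class].
#' @return `assayName` the name; `referenceSequence` the amplicon as a
#'   [Biostrings::DNAString]; `cpgLoci` the locus table; `nLoci` the number
#'   of loci L; `tssLabels` the signed locus labels.
#' @name PromoterAssay-accessors
#' @aliases assayName referenceSequence cpgLoci nLoci tssLabels
NULL

#' @rdname PromoterAssay-accessors
setMethod("assayName", "PromoterAssay", function(x) x@name)
#' @rdname PromoterAssay-accessors
setMethod("referenceSequence", "PromoterAssay",
          function(x) Biostrings::DNAString(x@referenceSequence))
#' @rdname PromoterAssay-accessors
setMethod("cpgLoci", "PromoterAssay", function(x) x@cpgLoci)
#' @rdname PromoterAssay-accessors
setMethod("nLoci", "PromoterAssay", function(x) nrow(x@cpgLoci))
#' @rdname PromoterAssay-accessors
setMethod("tssLabels", "PromoterAssay", function(x) x@cpgLoci$tss_label)

setMethod("show", "PromoterAssay", function(object) {
  cat("PromoterAssay:", object@name, "\n")
  cat("  amplicon length:", nchar(object@referenceSequence), "bp\n")
  cat("  CpG loci (L =", nrow(object@cpgLoci), "):",
      paste(object@cpgLoci$tss_label, collapse = ", "), "\n")
})

#' Map a TSS-relative label to its amplicon index (and back)
#'
#' The label/index mapping is a bijection over the declared loci;
#' `mapLabelToIndex` and `mapIndexToLabel` are exact inverses.
#'
#' @param assay a [PromoterAssay-class].
#' @param tssLabel signed integer locus label (no 0 exists).
#' @param ampliconIndex 0-based index of a locus C.
#' @return the 0-based amplicon index (resp. the signed label).
#' @examples
#' a <- cyp19aAssay()
#' mapIndexToLabel(a, mapLabelToIndex(a, -13L))
#' @export
mapLabelToIndex <- function(assay, tssLabel) {
  if (any(tssLabel == 0L)) stop("invalid coordinate convention: no position 0")
  hit <- match(as.integer(tssLabel), assay@cpgLoci$tss_label)
  if (anyNA(hit)) {
    stop("unknown locus: ", paste(tssLabel[is.na(hit)], collapse = ", "))
  }
  assay@cpgLoci$amplicon_index[hit]
}

#' @rdname mapLabelToIndex
#' @export
mapIndexToLabel <- function(assay, ampliconIndex) {
  hit <- match(as.integer(ampliconIndex), assay@cpgLoci$amplicon_index)
  if (anyNA(hit)) {
    stop("unknown locus index: ",
         paste(ampliconIndex[is.na(hit)], collapse = ", "))
  }
  assay@cpgLoci$tss_label[hit]
}

# Internal: positions (1-based) of reference cytosines by context.
# A non-CpG C is a C not followed by G (the conversion-efficiency
# denominator); Cs of undeclared CG dinucleotides belong to neither set
# (their methylation state is unknown and they carry no conversion signal).
.referenceContext <- function(assay) {
  bases <- strsplit(assay@referenceSequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  locusPos <- assay@cpgLoci$amplicon_index + 1L
  cPos <- which(bases == "C")
  followedByG <- cPos < n & bases[pmin(cPos + 1L, n)] == "G"
  nonCpG <- cPos[!followedByG]
  list(bases = bases, n = n, locusPos = locusPos, nonCpGCPos = nonCpG)
}
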