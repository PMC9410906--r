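# Central S4 containers. Tabular stage outputs (hits, operons, association
# records, IR calls) are ordinary data.frames; the classes below hold the
# objects with internal consistency worth enforcing.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

#' AnnotatedGenome: contig sequences plus CDS features
#'
#' A minimal annotated-genome container: a [Biostrings::DNAStringSet] of
#' contigs and a [GenomicRanges::GRanges] of CDS features whose metadata
#' columns carry `cds_id`, `translation` and `product`. Coordinates are
#' 1-based inclusive throughout (the GFF3 convention).
#'
#' @slot sequences A named `DNAStringSet`, one entry per contig.
#' @slot features A `GRanges` of CDS features on those contigs.
#' @export
setClass("AnnotatedGenome",
  representation(sequences = "DNAStringSet", features = "GRanges"))

setValidity("AnnotatedGenome", function(object) {
  msgs <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "contig sequences must have unique names")
  if (length(object@features)) {
    f <- object@features
    if (!all(as.character(GenomicRanges::seqnames(f)) %in% nm))
      msgs <- c(msgs, "features reference unknown contigs")
    w <- setNames(Biostrings::width(object@sequences), nm)
    bad <- GenomicRanges::start(f) < 1L |
      GenomicRanges::end(f) > w[as.character(GenomicRanges::seqnames(f))]
    if (any(bad))
      msgs <- c(msgs, "feature intervals outside contig bounds")
    need <- c("cds_id", "translation")
    if (!all(need %in% names(S4Vectors::mcols(f))))
      msgs <- c(msgs, "features need mcols cds_id and translation")
    else if (anyDuplicated(S4Vectors::mcols(f)$cds_id))
      msgs <- c(msgs, "duplicated cds_id")
    if (!all(as.character(GenomicRanges::strand(f)) %in% c("+", "-")))
      msgs <- c(msgs, "feature strand must be + or -")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of contigs.
#' @param features `GRanges` of CDS features with `cds_id`, `translation` and
#'   optionally `product` metadata columns; sorted by contig then start.
#' @return An [AnnotatedGenome-class] object.
#' @export
annotatedGenome <- function(sequences, features = GenomicRanges::GRanges()) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (length(features)) {
    if (is.null(S4Vectors::mcols(features)$product))
      S4Vectors::mcols(features)$product <- "hypothetical protein"
    sl <- setNames(Biostrings::width(sequences), names(sequences))
    GenomeInfoDb::seqlevels(features) <- names(sequences)
    GenomeInfoDb::seqlengths(features) <- sl
    features <- GenomicRanges::sort(features, ignore.strand = TRUE)
  }
  new("AnnotatedGenome", sequences = sequences, features = features)
}

#' @describeIn AnnotatedGenome-class contig sequences
#' @param genome An `AnnotatedGenome`.
#' @export
genomeSequences <- function(genome) genome@sequences

#' @describeIn AnnotatedGenome-class CDS features
#' @export
genomeFeatures <- function(genome) genome@features

#' @describeIn AnnotatedGenome-class contig names
#' @export
contigNames <- function(genome) names(genome@sequences)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@sequences), "contig(s),",
      sum(Biostrings::width(object@sequences)), "bp,",
      length(object@features), "CDS feature(s)\n")
})

#' FamilyProfile: position-specific log-odds profile of a protein family
#'
#' Column scores are `log2` odds of the (pseudocounted) column frequency over
#' a background amino-acid distribution, in bits. Built by [buildProfile()]
#' from an aligned family seed set; used by [scanGenome()].
#'
#' @slot familyName Family label.
#' @slot logOdds `width x 20` numeric matrix, columns of the profile in rows,
#'   amino acids in columns (bits).
#' @slot background Length-20 amino-acid background frequency vector (sums
#'   to 1).
#' @slot reference Ungapped reference protein for identity reporting
#'   (profile consensus unless supplied).
#' @slot scoreThreshold Minimum bit score for [scanGenome()] hits.
#' @slot minCoverage Minimum fraction of profile columns aligned.
#' @export
setClass("FamilyProfile",
  representation(familyName = "character", logOdds = "matrix",
                 background = "numeric", reference = "character",
                 scoreThreshold = "numeric", minCoverage = "numeric"))

setValidity("FamilyProfile", function(object) {
  msgs <- character()
  if (abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must sum to 1 (tolerance 1e-9)")
  if (!all(is.finite(object@logOdds)))
    msgs <- c(msgs, "log-odds cells must all be finite (use pseudocounts)")
  if (!identical(colnames(object@logOdds), AA20))
    msgs <- c(msgs, "log-odds columns must be the 20 standard amino acids")
  if (object@minCoverage < 0 || object@minCoverage > 1)
    msgs <- c(msgs, "minCoverage must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FamilyProfile-class number of profile columns
#' @param profile A `FamilyProfile`.
#' @export
profileWidth <- function(profile) nrow(profile@logOdds)

#' @describeIn FamilyProfile-class consensus protein (per-column best-scoring
#'   residue; ties resolved alphabetically)
#' @export
profileConsensus <- function(profile) {
  paste(AA20[apply(profile@logOdds, 1L, which.max)], collapse = "")
}

#' @describeIn FamilyProfile-class family label
#' @export
familyName <- function(profile) profile@familyName

setMethod("show", "FamilyProfile", function(object) {
  cat("FamilyProfile", object@familyName, "-", nrow(object@logOdds),
      "columns, score threshold", format(object@scoreThreshold, digits = 4),
      "bits, min coverage", object@minCoverage, "\n")
})

#' Motif: a DNA motif with counts, log-odds and contributing sites
#'
#' Produced by [discoverMotif()]; scanned with [scanMotif()] and compared
#' with [compareMotifs()].
#'
#' @slot counts `4 x width` integer site-count matrix (rows A,C,G,T).
#' @slot logOdds `4 x width` log2-odds matrix vs background, with
#'   pseudocounts (bits).
#' @slot background Length-4 base background frequencies.
#' @slot sites data.frame of contributing sites: `promoter_id`, `offset`
#'   (1-based on the promoter's coding strand), `strand`.
#' @slot ic Total information content in bits (uniform-background
#'   definition `sum_col (2 + sum_b p log2 p)`).
#' @export
setClass("Motif",
  representation(counts = "matrix", logOdds = "matrix",
                 background = "numeric", sites = "data.frame",
                 ic = "numeric"))

setValidity("Motif", function(object) {
  msgs <- character()
  if (!identical(rownames(object@counts), DNA4))
    msgs <- c(msgs, "count rows must be A,C,G,T")
  n <- nrow(object@sites)
  if (n > 0 && any(abs(colSums(object@counts) - n) > 1e-9))
    msgs <- c(msgs, "each count column must sum to the number of sites")
  if (ncol(object@counts) != ncol(object@logOdds))
    msgs <- c(msgs, "counts and logOdds widths differ")
  p <- sweep(object@counts, 2L, pmax(colSums(object@counts), 1), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- sum(2 + colSums(plogp))
  if (n > 0 && abs(ic - object@ic) > 1e-9)
    msgs <- c(msgs, "stored information content inconsistent with counts")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Motif-class motif width in columns
#' @param motif A `Motif`.
#' @export
motifWidth <- function(motif) ncol(motif@counts)

#' @describeIn Motif-class consensus sequence (per-column most frequent base,
#'   ties resolved alphabetically)
#' @export
motifConsensus <- function(motif) {
  paste(DNA4[apply(motif@counts, 2L, which.max)], collapse = "")
}

#' @describeIn Motif-class contributing sites
#' @export
motifSites <- function(motif) motif@sites

#' @describeIn Motif-class total information content (bits)
#' @export
motifIC <- function(motif) motif@ic

setMethod("show", "Motif", function(object) {
  cat("Motif:", motifConsensus(object), "- width", ncol(object@counts),
      ", sites", nrow(object@sites),
      ", IC", format(object@ic, digits = 4), "bits\n")
})
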