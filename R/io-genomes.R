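# Genome I/O and coordinate plumbing. FASTA/GFF3 reading and writing goes
# through Biostrings and rtracklayer; only the cds_id <-> ID attribute mapping
# lives here.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translateCds <- function(nt) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# CDS nucleotide sequence on the coding strand for one feature row.
featureSequence <- function(genome, feature) {
  s <- as.character(Biostrings::subseq(
    genome@sequences[[as.character(GenomicRanges::seqnames(feature))]],
    GenomicRanges::start(feature), GenomicRanges::end(feature)))
  if (as.character(GenomicRanges::strand(feature)) == "-") s <- revcomp(s)
  s
}

#' Write an annotated genome set to FASTA + GFF3 (+ protein FASTA)
#'
#' @param genome An [AnnotatedGenome-class].
#' @param prefix Output path prefix; writes `<prefix>.fna`, `<prefix>.gff3`
#'   and `<prefix>.faa`.
#' @return Invisibly, the three file paths.
#' @export
writeGenomeSet <- function(genome, prefix) {
  fna <- paste0(prefix, ".fna")
  gff <- paste0(prefix, ".gff3")
  faa <- paste0(prefix, ".faa")
  Biostrings::writeXStringSet(genome@sequences, fna)
  f <- genome@features
  if (length(f)) {
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(f),
      IRanges::IRanges(GenomicRanges::start(f), GenomicRanges::end(f)),
      strand = GenomicRanges::strand(f))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "acaScan", type = "CDS", phase = 0L,
      ID = S4Vectors::mcols(f)$cds_id,
      product = S4Vectors::mcols(f)$product,
      translation = S4Vectors::mcols(f)$translation)
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  prot <- Biostrings::AAStringSet(setNames(
    as.character(S4Vectors::mcols(f)$translation),
    as.character(S4Vectors::mcols(f)$cds_id)))
  Biostrings::writeXStringSet(prot, faa)
  invisible(c(fna = fna, gff3 = gff, faa = faa))
}

#' Read an annotated genome set from FASTA + GFF3
#'
#' CDS features are taken from the GFF3 `type == "CDS"` records; if a feature
#' lacks a `translation` attribute it is translated from the genome sequence.
#'
#' @param fasta Path to the nucleotide FASTA.
#' @param gff3 Path to the GFF3 annotation.
#' @return An [AnnotatedGenome-class].
#' @export
readGenomeSet <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                 error = function(e) GenomicRanges::GRanges())
  if (length(gr)) {
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    mc <- S4Vectors::mcols(gr)
    cds_id <- if (!is.null(mc$ID)) as.character(mc$ID) else
      paste0("cds", seq_along(gr))
    product <- if (!is.null(mc$product)) as.character(mc$product) else
      rep("hypothetical protein", length(gr))
    translation <- if (!is.null(mc$translation)) as.character(mc$translation)
      else rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      cds_id = cds_id, translation = translation, product = product)
    gn <- annotatedGenome(seqs, gr)
    miss <- which(is.na(S4Vectors::mcols(gn@features)$translation))
    for (i in miss) {
      S4Vectors::mcols(gn@features)$translation[i] <-
        translateCds(featureSequence(gn, gn@features[i]))
    }
    gn
  } else {
    annotatedGenome(seqs)
  }
}

#' Reverse-complement a genome set, flipping features accordingly
#'
#' Each contig is reverse-complemented and every feature's coordinates and
#' strand are mirrored; translations are untouched. Used for strand-symmetry
#' checks: all coding-strand-aware results (operons, promoters, IR sets,
#' association labels) are invariant under this transform.
#'
#' @param genome An [AnnotatedGenome-class].
#' @return The mirrored [AnnotatedGenome-class].
#' @export
reverseComplementGenome <- function(genome) {
  seqs <- Biostrings::reverseComplement(genome@sequences)
  f <- genome@features
  if (length(f)) {
    L <- setNames(Biostrings::width(genome@sequences), names(genome@sequences))
    cl <- L[as.character(GenomicRanges::seqnames(f))]
    ns <- cl - GenomicRanges::end(f) + 1L
    ne <- cl - GenomicRanges::start(f) + 1L
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(f),
      IRanges::IRanges(ns, ne),
      strand = ifelse(as.character(GenomicRanges::strand(f)) == "+", "-", "+"))
    S4Vectors::mcols(gr) <- S4Vectors::mcols(f)
    annotatedGenome(seqs, gr)
  } else {
    annotatedGenome(seqs)
  }
}
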