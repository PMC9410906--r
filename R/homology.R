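# Family-profile construction and protein scanning: the desk-scale analogue
# of building per-family HMMs and searching annotated genomes with them,
# plus blastp-style pairwise identity and CD-HIT-style greedy clustering.

encodeAA <- function(s) {
  i <- match(strsplit(s, "")[[1]], AA20)
  if (anyNA(i)) stop("non-standard amino-acid symbol in sequence")
  i
}

#' Build a position-specific log-odds profile from an aligned family seed set
#'
#' Per-column residue frequencies are blended with background-proportional
#' pseudocounts, `(count / n + pseudocount * background) / (1 + pseudocount)`
#' where `n` is the number of non-gap residues in the column, and converted
#' to log2 odds over the background. Working on relative frequencies makes
#' the profile invariant to sequence copy number. Columns in which more than
#' half the sequences are gapped are dropped.
#'
#' @param aligned Character vector of equal-length gapped protein strings
#'   (`-` for gaps).
#' @param pseudocount Total pseudocount weight (default 1).
#' @param background Length-20 amino-acid background frequencies (uniform by
#'   default); must sum to 1.
#' @param familyName Family label.
#' @param reference Ungapped reference protein used for identity reporting;
#'   defaults to the first seed sequence with gaps removed.
#' @param scoreThreshold Bit-score threshold stored on the profile (set it
#'   from [calibrateProfileThresholds()] for genome scans).
#' @param minCoverage Minimum aligned fraction of profile columns.
#' @return A [FamilyProfile-class].
#' @export
buildProfile <- function(aligned, pseudocount = 1,
                         background = rep(1 / 20, 20),
                         familyName = "family", reference = NULL,
                         scoreThreshold = 0, minCoverage = 0.5) {
  if (length(aligned) < 1L) stop("empty alignment")
  aligned <- toupper(aligned)
  if (length(unique(nchar(aligned))) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWY.-]*$", aligned)))
    stop("non-amino-acid symbol in alignment")
  aligned <- gsub("\\.", "-", aligned)
  mat <- do.call(rbind, strsplit(aligned, ""))
  gapFrac <- colMeans(mat == "-")
  keep <- which(gapFrac <= 0.5)
  if (!length(keep)) stop("no columns retained (all majority-gap)")
  background <- background / sum(background)
  lo <- matrix(0, nrow = length(keep), ncol = 20,
               dimnames = list(NULL, AA20))
  for (j in seq_along(keep)) {
    col <- mat[, keep[j]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA20))
    freq <- (as.numeric(cnt) / length(col) + pseudocount * background) /
      (1 + pseudocount)
    lo[j, ] <- unname(log2(freq / background))
  }
  ref <- if (is.null(reference)) gsub("-", "", aligned[1]) else reference
  new("FamilyProfile", familyName = familyName, logOdds = lo,
      background = background, reference = ref,
      scoreThreshold = scoreThreshold, minCoverage = minCoverage)
}

# Best ungapped placement of a profile against one protein. For proteins at
# least as long as the profile, all full-width windows are scored; shorter
# proteins are slid inside the profile (partial column coverage).
bestProfileScore <- function(lo, aaIdx) {
  w <- nrow(lo)
  L <- length(aaIdx)
  if (L >= w) {
    n <- L - w + 1L
    sc <- numeric(n)
    for (k in seq_len(w)) sc <- sc + lo[cbind(k, aaIdx[k:(k + n - 1L)])]
    list(score = max(sc), coverage = 1)
  } else {
    n <- w - L + 1L
    sc <- numeric(n)
    for (j in seq_len(n)) {
      sc[j] <- sum(lo[cbind(j:(j + L - 1L), aaIdx)])
    }
    list(score = max(sc), coverage = L / w)
  }
}

#' Scan a genome's CDS translations with family profiles
#'
#' Each profile is slid ungapped along every CDS translation; the best-window
#' bit score is kept. A hit is reported for every (CDS, family) pair with
#' score at or above the family's `scoreThreshold` and coverage at or above
#' its `minCoverage`; one CDS may hit several families.
#'
#' @param profiles A list of [FamilyProfile-class] objects.
#' @param genome An [AnnotatedGenome-class].
#' @return data.frame with `cds_id`, `contig`, `family`, `score` (bits),
#'   `coverage`, `identity` (to the profile reference), `aa_length`,
#'   sorted by descending score (ties by family then cds_id).
#' @export
scanGenome <- function(profiles, genome) {
  f <- genome@features
  out <- list()
  if (length(f)) {
    prots <- as.character(S4Vectors::mcols(f)$translation)
    ids <- as.character(S4Vectors::mcols(f)$cds_id)
    contigs <- as.character(GenomicRanges::seqnames(f))
    enc <- lapply(prots, encodeAA)
    for (p in profiles) {
      for (i in seq_along(enc)) {
        if (!length(enc[[i]])) next
        b <- bestProfileScore(p@logOdds, enc[[i]])
        if (b$score >= p@scoreThreshold && b$coverage >= p@minCoverage) {
          idn <- pairwiseIdentity(p@reference, prots[i])
          out[[length(out) + 1L]] <- data.frame(
            cds_id = ids[i], contig = contigs[i], family = p@familyName,
            score = b$score, coverage = b$coverage,
            identity = idn["identity"], aa_length = nchar(prots[i]),
            stringsAsFactors = FALSE, row.names = NULL)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(cds_id = character(), contig = character(),
               family = character(), score = numeric(), coverage = numeric(),
               identity = numeric(), aa_length = integer(),
               stringsAsFactors = FALSE)
  hits[order(-hits$score, hits$family, hits$cds_id), , drop = FALSE]
}

#' Calibrate per-family score thresholds on background-only genomes
#'
#' Scores every background CDS with every profile (no thresholding) and
#' returns, per family, the given quantile of per-CDS best scores. Intended
#' to be run on synthetic genomes that contain no planted family members,
#' giving an empirical null analogous to tuning a database-search bit-score
#' cutoff.
#'
#' @param profiles List of [FamilyProfile-class] objects.
#' @param genome A background-only [AnnotatedGenome-class].
#' @param probs Quantile of the null score distribution (default 0.999).
#' @param margin Bits added above the quantile (default 10): the extreme-tail
#'   quantile estimated from a few hundred null scores is noisy, and true
#'   family members sit hundreds of bits above the null, so a generous
#'   safety margin buys specificity at no sensitivity cost.
#' @return Named numeric vector of thresholds, one per family.
#' @export
calibrateProfileThresholds <- function(profiles, genome, probs = 0.999,
                                       margin = 10) {
  f <- genome@features
  if (!length(f)) stop("calibration genome has no CDS features")
  enc <- lapply(as.character(S4Vectors::mcols(f)$translation), encodeAA)
  vapply(profiles, function(p) {
    sc <- vapply(enc, function(e) bestProfileScore(p@logOdds, e)$score,
                 numeric(1))
    as.numeric(quantile(sc, probs, names = FALSE, type = 7)) + margin
  }, numeric(1)) |>
    setNames(vapply(profiles, familyName, character(1)))
}

#' Pairwise global identity and coverage of two protein sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1. Identity is matches over alignment columns inside the
#' mutually aligned span (both-residue columns plus internal gap columns;
#' terminal overhangs excluded); coverage is the number of both-residue
#' columns over the length of the reference `a`. The alignment is computed
#' in a canonical argument order, so identity is exactly symmetric.
#'
#' @param a Reference protein (coverage denominator).
#' @param b Query protein.
#' @return Named numeric vector `c(identity=, coverage=)`.
#' @export
#' @examples
#' pairwiseIdentity("AAAA", "AATT")
pairwiseIdentity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  swap <- (nchar(b) < nchar(a)) || (nchar(b) == nchar(a) && b < a)
  x <- if (swap) b else a
  y <- if (swap) a else b
  letters_xy <- sort(unique(strsplit(paste0(x, y), "")[[1]]))
  sm <- diag(1, length(letters_xy))
  dimnames(sm) <- list(letters_xy, letters_xy)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(x), Biostrings::BString(y), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
  va <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  vb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- va != "-" & vb != "-"
  if (!any(both)) {
    return(c(identity = 0, coverage = 0))
  }
  span <- range(which(both))
  cols <- span[1]:span[2]
  matches <- sum(va[cols] == vb[cols] & both[cols])
  c(identity = matches / length(cols),
    coverage = sum(both) / nchar(a))
}

#' Greedy incremental clustering by pairwise identity
#'
#' CD-HIT-style greedy rule: sequences are processed longest-first (ties by
#' id); each either joins the first established representative to which its
#' [pairwiseIdentity()] is at least `threshold`, or founds a new cluster.
#' Works on protein or nucleotide strings alike.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @return A list of class `ClusterSet`: `representatives` (ids in founding
#'   order), `membership` (named character: member id -> representative id)
#'   and `threshold`.
#' @export
greedyCluster <- function(seqs, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  membership <- setNames(character(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      if (pairwiseIdentity(seqs[[r]], seqs[[id]])["identity"] >= threshold) {
        membership[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      membership[id] <- id
    }
  }
  structure(list(representatives = reps, membership = membership,
                 threshold = threshold), class = "ClusterSet")
}

#' Write homolog hits or cluster membership as TSV
#'
#' @param x A hits data.frame from [scanGenome()] or a `ClusterSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeHitsTsv <- function(x, path) {
  if (inherits(x, "ClusterSet")) {
    x <- data.frame(member = names(x$membership),
                    representative = unname(x$membership),
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
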