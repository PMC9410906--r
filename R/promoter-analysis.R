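# Promoter dissection: strand-aware upstream extraction, sigma70 -35/-10
# consensus-matrix scanning, mismatch-tolerant inverted-repeat detection with
# IR1/IR2 classification, Gibbs-sampling motif discovery, motif scanning and
# motif-motif comparison.

encodeDNA <- function(s) {
  i <- match(strsplit(toupper(s), "")[[1]], DNA4)
  i[is.na(i)] <- 1L  # ambiguous bases scored as A; rare in practice
  i
}

# log2-odds hexamer matrix from a consensus: consensus base 0.7, others 0.1.
consensusMatrix6 <- function(hexamer, pMatch = 0.7) {
  b <- strsplit(hexamer, "")[[1]]
  m <- matrix(log2(((1 - pMatch) / 3) / 0.25), nrow = 4, ncol = 6,
              dimnames = list(DNA4, NULL))
  for (k in seq_len(6)) m[b[k], k] <- log2(pMatch / 0.25)
  m
}

scoreWindows <- function(x, mat) {
  w <- ncol(mat)
  n <- length(x) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) sc <- sc + mat[cbind(x[k:(k + n - 1L)], k)]
  sc
}

#' Extract promoter regions upstream of operon leaders
#'
#' For a `+` strand operon the `length` bases ending immediately before the
#' leader start are returned as-is; for a `-` strand operon the `length`
#' bases starting immediately after the leader end are returned
#' reverse-complemented. Either way the returned sequence reads 5' to 3' on
#' the coding strand and its last base is position -1 relative to the start
#' codon. Regions are clipped (and flagged) at contig edges; a leader flush
#' with the edge yields an empty, flagged region.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param operons Operon table from [callOperons()].
#' @param length Extraction length in bases (default 400).
#' @param operonIds Optional subset of operon ids.
#' @return data.frame: `operon_id`, `leader_cds`, `contig`, `strand`,
#'   `start`, `end` (genomic, NA when empty), `sequence`, `clipped`.
#' @export
extractPromoters <- function(genome, operons, length = 400,
                             operonIds = unique(operons$operon_id)) {
  cl <- setNames(Biostrings::width(genome@sequences), names(genome@sequences))
  rows <- lapply(operonIds, function(opId) {
    m <- operons[operons$operon_id == opId, , drop = FALSE]
    ld <- m[m$is_leader, , drop = FALSE]
    L <- cl[[ld$contig]]
    if (ld$strand == "+") {
      e <- ld$start - 1L
      s <- max(1L, ld$start - as.integer(length))
      clipped <- (ld$start - as.integer(length)) < 1L
    } else {
      s <- ld$end + 1L
      e <- min(L, ld$end + as.integer(length))
      clipped <- (ld$end + as.integer(length)) > L
    }
    if (s > e || e < 1L || s > L) {
      return(data.frame(operon_id = opId, leader_cds = ld$cds_id,
                        contig = ld$contig, strand = ld$strand,
                        start = NA_integer_, end = NA_integer_,
                        sequence = "", clipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    seq <- as.character(Biostrings::subseq(genome@sequences[[ld$contig]], s, e))
    if (ld$strand == "-") seq <- revcomp(seq)
    data.frame(operon_id = opId, leader_cds = ld$cds_id, contig = ld$contig,
               strand = ld$strand, start = s, end = e, sequence = seq,
               clipped = clipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan a promoter for a sigma70 -35/-10 core element pair
#'
#' Every (-35 position, -10 position) pair with a spacer in `spacerRange`
#' and both hexamers inside the 3'-most `searchWindow` bases is scored with
#' log-odds consensus matrices built from TTGACA and TATAAT (consensus base
#' probability 0.7) plus a spacer penalty of 0.5 bits per base deviation
#' from the 17-base optimum. The maximal-score pair is returned; ties are
#' broken towards the 3'-most -10 element, then the longest spacer.
#'
#' @param sequence Promoter sequence (coding-strand oriented), or one row of
#'   [extractPromoters()] output.
#' @param searchWindow Only the 3'-most this-many bases are searched
#'   (default 150).
#' @param spacerRange Allowed spacer lengths (default 15-19).
#' @param threshold Optional significance threshold in bits; when supplied
#'   the `significant` flag is `total_score >= threshold`, otherwise `NA`.
#'   Calibrate with [calibrateCoreThreshold()].
#' @param pMatch Consensus-base probability of the scoring matrices.
#' @return One-row data.frame (`m35_start`, `m35_end`, `m35_seq`,
#'   `m35_score`, `m10_start`, `m10_end`, `m10_seq`, `m10_score`, `spacer`,
#'   `total_score`, `significant`; positions 1-based on the promoter), or
#'   `NULL` if the region cannot hold the minimal footprint.
#' @export
scanCorePromoter <- function(sequence, searchWindow = 150,
                             spacerRange = c(15, 19), threshold = NULL,
                             pMatch = 0.7) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  L <- nchar(sequence)
  minFoot <- 12L + spacerRange[1]
  if (L < minFoot) return(NULL)
  x <- encodeDNA(sequence)
  m35 <- consensusMatrix6("TTGACA", pMatch)
  m10 <- consensusMatrix6("TATAAT", pMatch)
  s35 <- scoreWindows(x, m35)
  s10 <- scoreWindows(x, m10)
  lo <- max(1L, L - as.integer(searchWindow) + 1L)
  best <- NULL
  for (sp in spacerRange[1]:spacerRange[2]) {
    # m10 start = m35 start + 6 + sp
    if (L - 11L - sp < lo) next
    p35 <- seq(lo, L - 11L - sp, by = 1L)
    p35 <- p35[p35 + 6L + sp + 5L <= L & p35 + 6L + sp >= lo]
    if (!length(p35)) next
    p10 <- p35 + 6L + sp
    tot <- s35[p35] + s10[p10] - 0.5 * abs(sp - 17L)
    for (j in seq_along(p35)) {
      cand <- c(tot[j], p10[j], sp, p35[j])
      better <- is.null(best) ||
        cand[1] > best[1] + 1e-12 ||
        (abs(cand[1] - best[1]) <= 1e-12 &&
           (cand[2] > best[2] || (cand[2] == best[2] && cand[3] > best[3])))
      if (better) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  p35 <- best[4]; p10 <- best[2]; sp <- best[3]
  data.frame(
    m35_start = p35, m35_end = p35 + 5L,
    m35_seq = substr(sequence, p35, p35 + 5L), m35_score = s35[p35],
    m10_start = p10, m10_end = p10 + 5L,
    m10_seq = substr(sequence, p10, p10 + 5L), m10_score = s10[p10],
    spacer = sp, total_score = best[1],
    significant = if (is.null(threshold)) NA else best[1] >= threshold,
    stringsAsFactors = FALSE)
}

#' Calibrate a core-promoter significance threshold on background sequences
#'
#' @param n Number of background promoters to score.
#' @param length Background promoter length.
#' @param gc Background GC fraction.
#' @param probs Null-score quantile (default 0.99).
#' @param seed Integer seed.
#' @param ... Passed to [scanCorePromoter()].
#' @return Threshold in bits.
#' @export
calibrateCoreThreshold <- function(n = 200, length = 150, gc = 0.5,
                                   probs = 0.99, seed = 1, ...) {
  scores <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      scanCorePromoter(randomDna(length, gc), ...)$total_score
    }, numeric(1))
  })
  as.numeric(quantile(scores, probs, names = FALSE))
}

#' Find maximal mismatch-tolerant inverted repeats
#'
#' An inverted repeat is a pair of equal-length arms where the left arm and
#' the reverse complement of the right arm differ at no more than
#' `maxMismatch` positions. All candidates with arm length and spacer in the
#' given ranges are enumerated; a candidate is reported only if it is
#' maximal, i.e. neither extension by one base pair - outward (spacer
#' unchanged) or inward (spacer reduced by 2) - stays within the arm,
#' spacer, sequence and mismatch bounds. Results are sorted by descending
#' arm length, then ascending mismatches, position and spacer.
#'
#' @param sequence DNA string.
#' @param armRange Arm length bounds (default `c(4, 10)`; minimum >= 2).
#' @param spacerRange Spacer bounds (default `c(0, 12)`).
#' @param maxMismatch Maximum mismatches per arm pair (default 1).
#' @return data.frame: `left_start`, `left_end`, `right_start`, `right_end`,
#'   `arm_length`, `spacer`, `mismatches` (1-based positions).
#' @export
findInvertedRepeats <- function(sequence, armRange = c(4, 10),
                                spacerRange = c(0, 12), maxMismatch = 1) {
  stopifnot(armRange[1] >= 2, spacerRange[1] >= 0, maxMismatch >= 0)
  x <- encodeDNA(sequence)
  L <- length(x)
  xc <- 5L - x  # complement encoding
  cand <- list()
  for (a in armRange[1]:armRange[2]) {
    for (s in spacerRange[1]:spacerRange[2]) {
      n <- L - 2L * a - s + 1L
      if (n < 1L) next
      i <- seq_len(n)
      mm <- integer(n)
      for (k in seq_len(a)) {
        # left arm pos k pairs with right arm pos a+1-k
        mm <- mm + (x[i + k - 1L] != xc[i + 2L * a + s - k])
      }
      keep <- mm <= maxMismatch
      if (any(keep)) {
        cand[[length(cand) + 1L]] <- data.frame(
          left_start = i[keep], arm_length = a, spacer = s,
          mismatches = mm[keep])
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), spacer = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, cand)
  i <- d$left_start; a <- d$arm_length; s <- d$spacer
  # outward extension: (i-1, a+1, s); adds pair (i-1, i+2a+s)
  outOk <- i - 1L >= 1L & a + 1L <= armRange[2] & i + 2L * a + s <= L
  outMm <- d$mismatches + ifelse(outOk & i > 1L & i + 2L * a + s <= L,
                                 x[pmax(i - 1L, 1L)] !=
                                   xc[pmin(i + 2L * a + s, L)], NA)
  outValid <- outOk & !is.na(outMm) & outMm <= maxMismatch
  # inward extension: (i, a+1, s-2); adds pair (i+a, i+a+s-1)
  inOk <- s - 2L >= spacerRange[1] & a + 1L <= armRange[2]
  inMm <- d$mismatches + ifelse(inOk, x[i + a] != xc[i + a + s - 1L], NA)
  inValid <- inOk & !is.na(inMm) & inMm <= maxMismatch
  d <- d[!outValid & !inValid, , drop = FALSE]
  d$left_end <- d$left_start + d$arm_length - 1L
  d$right_start <- d$left_end + d$spacer + 1L
  d$right_end <- d$right_start + d$arm_length - 1L
  d <- d[order(-d$arm_length, d$mismatches, d$left_start, d$spacer), ,
         drop = FALSE]
  rownames(d) <- NULL
  d[, c("left_start", "left_end", "right_start", "right_end", "arm_length",
        "spacer", "mismatches")]
}

#' Find inverted repeats in a promoter's 3'-most search window
#'
#' Runs [findInvertedRepeats()] on the 3'-most `searchWindow` bases (the
#' region where Aca operator sites concentrate) and reports coordinates in
#' the full promoter frame. Set `fullRegion = TRUE` to search everything.
#'
#' @inheritParams findInvertedRepeats
#' @param searchWindow Window size in bases (default 150).
#' @param fullRegion Search the whole promoter instead.
#' @return As [findInvertedRepeats()].
#' @export
findPromoterIRs <- function(sequence, searchWindow = 150, fullRegion = FALSE,
                            armRange = c(4, 10), spacerRange = c(0, 12),
                            maxMismatch = 1) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  L <- nchar(sequence)
  off <- if (fullRegion || L <= searchWindow) 0L else L - as.integer(searchWindow)
  irs <- findInvertedRepeats(substr(sequence, off + 1L, L), armRange,
                             spacerRange, maxMismatch)
  for (cn in c("left_start", "left_end", "right_start", "right_end"))
    irs[[cn]] <- irs[[cn]] + off
  irs
}

#' Classify inverted repeats relative to a core promoter call
#'
#' `IR1` when the IR span (left arm start to right arm end) overlaps the
#' core promoter span (-35 start to -10 end) by at least one base, `IR2`
#' when disjoint, `unclassified` when no core call is available. Both must
#' be in the same promoter coordinate frame.
#'
#' @param irs IR table from [findInvertedRepeats()]/[findPromoterIRs()].
#' @param core Core call from [scanCorePromoter()], or `NULL`.
#' @return `irs` with a `classification` column appended.
#' @export
classifyInvertedRepeats <- function(irs, core = NULL) {
  if (is.null(core) || !nrow(irs)) {
    irs$classification <- rep("unclassified", nrow(irs))
    return(irs)
  }
  coreSpan <- c(core$m35_start, core$m10_end)
  overlaps <- irs$left_start <= coreSpan[2] & irs$right_end >= coreSpan[1]
  irs$classification <- ifelse(overlaps, "IR1", "IR2")
  irs
}

revcompLogOdds <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

#' Discover a shared motif across promoters by Gibbs sampling
#'
#' Site-sampling Gibbs motif discovery on both strands: one sequence's site
#' is resampled at a time from the posterior given the motif built (with
#' 0.25/base pseudocounts) from the remaining sequences' sites. In `zoops`
#' mode a sequence may hold no site (background option with prior
#' `1 - sitePrior`); in `oops` mode every sequence holds exactly one. A
#' deterministic phase-shift move is applied periodically, and each restart
#' ends with a deterministic argmax polish. The best restart by (total
#' information content x site count) wins. Fully reproducible for a fixed
#' seed.
#'
#' @param promoters Named character vector of promoter sequences, or
#'   [extractPromoters()] output.
#' @param width Motif width in columns (default 18).
#' @param mode `"zoops"` (default) or `"oops"`.
#' @param nRestarts Independent restarts (default 4).
#' @param iterations Gibbs sweeps per restart (default 80).
#' @param seed Integer seed.
#' @param pseudocount Per-base pseudocount (default 0.25).
#' @param background Length-4 background base frequencies.
#' @param sitePrior Prior probability that a sequence holds a site (zoops).
#' @param shiftEvery Apply the phase-shift move every this many sweeps.
#' @return A [Motif-class].
#' @export
discoverMotif <- function(promoters, width = 18, mode = c("zoops", "oops"),
                          nRestarts = 4, iterations = 80, seed = 1,
                          pseudocount = 0.25, background = rep(0.25, 4),
                          sitePrior = 0.9, shiftEvery = 10) {
  mode <- match.arg(mode)
  if (is.data.frame(promoters))
    promoters <- setNames(promoters$sequence, promoters$operon_id)
  promoters <- promoters[nchar(promoters) > 0]
  if (length(promoters) < 2L) stop("need at least 2 non-empty promoters")
  if (any(nchar(promoters) < width))
    stop("motif width exceeds the shortest promoter")
  if (is.null(names(promoters)))
    names(promoters) <- paste0("seq", seq_along(promoters))
  w <- as.integer(width)
  ns <- length(promoters)
  enc <- lapply(promoters, function(s) {
    list(encodeDNA(s), encodeDNA(revcomp(s)))
  })
  lens <- nchar(promoters)
  nOff <- lens - w + 1L
  background <- background / sum(background)

  siteWindow <- function(i, st, off) enc[[i]][[st]][off:(off + w - 1L)]

  # Precomputed linear indices into a 4 x w matrix for every window of every
  # sequence/strand: one vectorised lookup scores all windows at once.
  lin <- lapply(seq_len(ns), function(i) lapply(1:2, function(st) {
    x <- enc[[i]][[st]]
    pos <- outer(seq_len(w), 0:(nOff[i] - 1L), "+")
    matrix(x[pos] + 4L * (seq_len(w) - 1L), nrow = w)
  }))

  scoreAll <- function(lo, i, st) colSums(matrix(lo[lin[[i]][[st]]], nrow = w))

  countsOf <- function(strands, offs, has, excl = 0L) {
    cnt <- matrix(0, 4L, w)
    for (i in seq_len(ns)) {
      if (i == excl || !has[i]) next
      win <- siteWindow(i, strands[i], offs[i])
      cnt[cbind(win, seq_len(w))] <- cnt[cbind(win, seq_len(w))] + 1
    }
    cnt
  }

  logOddsOf <- function(cnt) {
    n <- sum(cnt[, 1])
    freq <- (cnt + pseudocount) / (n + 4 * pseudocount)
    log2(freq / background)
  }

  llOf <- function(cnt) {
    n <- sum(cnt[, 1])
    if (n == 0) return(-Inf)
    freq <- (cnt + pseudocount) / (n + 4 * pseudocount)
    sum(cnt * log2(freq / background))
  }

  icOf <- function(cnt) {
    n <- max(colSums(cnt)[1], 1)
    p <- cnt / n
    plogp <- ifelse(p > 0, p * log2(p), 0)
    sum(2 + colSums(plogp))
  }

  addSite <- function(cnt, i, st, off, sign = 1) {
    win <- siteWindow(i, st, off)
    idx <- cbind(win, seq_len(w))
    cnt[idx] <- cnt[idx] + sign
    cnt
  }

  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      strands <- sample(1:2, ns, replace = TRUE)
      offs <- vapply(nOff, function(n) sample.int(n, 1L), integer(1))
      has <- rep(TRUE, ns)
      cntAll <- countsOf(strands, offs, has)
      for (it in seq_len(iterations)) {
        for (i in seq_len(ns)) {
          cnt <- if (has[i]) addSite(cntAll, i, strands[i], offs[i], -1) else
            cntAll
          if (sum(cnt[, 1]) == 0) { has[i] <- TRUE; next }
          lo <- logOddsOf(cnt)
          lr <- 2^pmin(c(scoreAll(lo, i, 1L), scoreAll(lo, i, 2L)), 500)
          m <- length(lr)
          if (mode == "oops") {
            pick <- sample.int(m, 1L, prob = lr)
            has[i] <- TRUE
          } else {
            wts <- c(lr * sitePrior / m, 1 - sitePrior)
            pick <- sample.int(m + 1L, 1L, prob = wts)
            if (pick == m + 1L) { has[i] <- FALSE; cntAll <- cnt; next }
            has[i] <- TRUE
          }
          if (pick <= nOff[i]) {
            strands[i] <- 1L; offs[i] <- pick
          } else {
            strands[i] <- 2L; offs[i] <- pick - nOff[i]
          }
          cntAll <- addSite(cnt, i, strands[i], offs[i])
        }
        if (it %% shiftEvery == 0L && sum(has) >= 2L) {
          bestDelta <- 0L
          bestLL <- llOf(cntAll)
          for (delta in c(-2L, -1L, 1L, 2L)) {
            sh <- offs + delta
            if (any(sh[has] < 1L | sh[has] > nOff[has])) next
            ll <- llOf(countsOf(strands, sh, has))
            if (ll > bestLL + 1e-9) { bestLL <- ll; bestDelta <- delta }
          }
          if (bestDelta != 0L) {
            offs <- offs + bestDelta
            cntAll <- countsOf(strands, offs, has)
          }
        }
      }
      # deterministic polish: argmax site per sequence
      for (i in seq_len(ns)) {
        cnt <- countsOf(strands, offs, has, excl = i)
        if (sum(cnt[, 1]) == 0) next
        lo <- logOddsOf(cnt)
        sc <- c(scoreAll(lo, i, 1L), scoreAll(lo, i, 2L))
        j <- which.max(sc)
        if (mode == "zoops") {
          lrBest <- 2^min(sc[j], 500) * sitePrior / length(sc)
          if (lrBest < (1 - sitePrior)) { has[i] <- FALSE; next }
        }
        has[i] <- TRUE
        if (j <= nOff[i]) { strands[i] <- 1L; offs[i] <- j }
        else { strands[i] <- 2L; offs[i] <- j - nOff[i] }
      }
      cnt <- countsOf(strands, offs, has)
      score <- icOf(cnt) * sum(has)
      if (is.null(best) || score > best$score + 1e-12) {
        best <- list(score = score, strands = strands, offs = offs, has = has)
      }
    }
  })

  cnt <- countsOf(best$strands, best$offs, best$has)
  rownames(cnt) <- DNA4
  keep <- which(best$has)
  fwdOff <- ifelse(best$strands == 1L, best$offs,
                   lens - best$offs - w + 2L)
  sites <- data.frame(
    promoter_id = names(promoters)[keep],
    offset = as.integer(fwdOff[keep]),
    strand = c("+", "-")[best$strands[keep]],
    stringsAsFactors = FALSE)
  lo <- logOddsOf(cnt)
  dimnames(lo) <- dimnames(cnt)
  new("Motif", counts = cnt, logOdds = lo, background = background,
      sites = sites, ic = icOf(cnt))
}

#' Select a motif width by information content per column
#'
#' Runs [discoverMotif()] over a width sweep and returns the motif with the
#' highest information content per column.
#'
#' @inheritParams discoverMotif
#' @param widths Candidate widths (default 10 to 24, step 2).
#' @return The winning [Motif-class].
#' @export
sweepMotifWidth <- function(promoters, widths = seq(10, 24, by = 2), ...,
                            seed = 1) {
  cand <- lapply(widths, function(w)
    discoverMotif(promoters, width = w, seed = deriveSeed(seed, paste0("w", w)),
                  ...))
  perCol <- vapply(cand, function(m) motifIC(m) / motifWidth(m), numeric(1))
  cand[[which.max(perCol)]]
}

#' Scan a sequence with a motif
#'
#' Scores every window on both strands with the motif's log-odds matrix and
#' reports windows at or above `threshold`. Offsets are 1-based on the
#' forward (coding) strand of the scanned sequence for both strand hits.
#'
#' @param motif A [Motif-class].
#' @param sequence DNA string (or one row of [extractPromoters()] output).
#' @param threshold Score threshold in bits.
#' @return data.frame: `offset`, `strand`, `score`, sorted by offset.
#' @export
scanMotif <- function(motif, sequence, threshold = 0) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  w <- motifWidth(motif)
  if (nchar(sequence) < w)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  x <- encodeDNA(sequence)
  sf <- scoreWindows(x, motif@logOdds)
  sr <- scoreWindows(x, revcompLogOdds(motif@logOdds))
  hits <- rbind(
    data.frame(offset = seq_along(sf), strand = "+", score = sf,
               stringsAsFactors = FALSE),
    data.frame(offset = seq_along(sr), strand = "-", score = sr,
               stringsAsFactors = FALSE))
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

motifFreq <- function(motif, pseudocount = 0.25) {
  n <- sum(motif@counts[, 1])
  (motif@counts + pseudocount) / (n + 4 * pseudocount)
}

colCorrelation <- function(u, v) {
  if (stats::sd(u) > 0 && stats::sd(v) > 0) return(stats::cor(u, v))
  if (max(abs(u - v)) < 1e-12) 1 else 0
}

#' Align and compare two motifs by mean per-column Pearson correlation
#'
#' All relative offsets with at least `minOverlap` aligned columns are
#' enumerated in both orientations (`b` optionally reverse-complemented);
#' the alignment maximising the mean per-column Pearson correlation of the
#' frequency vectors is returned. Ties prefer the forward orientation, then
#' the smallest absolute offset.
#'
#' @param a,b [Motif-class] objects.
#' @param minOverlap Minimum aligned columns (default 4).
#' @return list(`offset` = position of b's first column relative to a's,
#'   `orientation` = "forward"/"reverse", `correlation`).
#' @export
compareMotifs <- function(a, b, minOverlap = 4) {
  fa <- motifFreq(a)
  fb <- motifFreq(b)
  wa <- ncol(fa); wb <- ncol(fb)
  stopifnot(wa >= minOverlap, wb >= minOverlap)
  best <- NULL
  for (orient in c("forward", "reverse")) {
    fo <- if (orient == "forward") fb else fb[4:1, rev(seq_len(wb)), drop = FALSE]
    for (delta in (minOverlap - wb):(wa - minOverlap)) {
      ja <- max(1L, 1L + delta):min(wa, wb + delta)
      if (length(ja) < minOverlap) next
      cc <- mean(vapply(ja, function(j) colCorrelation(fa[, j], fo[, j - delta]),
                        numeric(1)))
      better <- is.null(best) || cc > best$correlation + 1e-12 ||
        (abs(cc - best$correlation) <= 1e-12 &&
           orient == "forward" && best$orientation == "reverse") ||
        (abs(cc - best$correlation) <= 1e-12 &&
           orient == best$orientation && abs(delta) < abs(best$offset))
      if (better) best <- list(offset = delta, orientation = orient,
                               correlation = cc)
    }
  }
  best
}

#' Write / read a motif in MEME minimal text format
#'
#' @param motif A [Motif-class].
#' @param path Output path.
#' @param name Motif name in the file.
#' @return `writeMemeMotif()` the path invisibly; `readMemeMotif()` a
#'   [Motif-class] (site list is not stored in the format and comes back
#'   empty).
#' @export
writeMemeMotif <- function(motif, path, name = "motif1") {
  n <- nrow(motif@sites)
  freq <- motifFreq(motif)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA4, motif@background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(freq), n)), con)
  for (j in seq_len(ncol(freq)))
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", freq[1, j], freq[2, j],
                       freq[3, j], freq[4, j]), con)
  invisible(path)
}

#' @rdname writeMemeMotif
#' @export
readMemeMotif <- function(path) {
  lines <- readLines(path)
  bgLine <- lines[grep("^Background letter frequencies", lines) + 1L]
  bg <- as.numeric(strsplit(trimws(bgLine), "\\s+")[[1]][c(2, 4, 6, 8)])
  hdr <- grep("^letter-probability matrix:", lines)
  wd <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + wd)]
  freq <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(4)))
  cnt <- t(freq) * max(nsites, 1)
  dimnames(cnt) <- list(DNA4, NULL)
  lo <- log2(t(freq) / bg)
  dimnames(lo) <- dimnames(cnt)
  p <- t(freq)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  new("Motif", counts = cnt, logOdds = lo, background = bg,
      sites = data.frame(promoter_id = character(), offset = integer(),
                         strand = character(), stringsAsFactors = FALSE),
      ic = sum(2 + colSums(plogp)))
}
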