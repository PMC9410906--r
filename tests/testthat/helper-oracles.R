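# Independent oracles and small generators used across the suite. These
# deliberately re-derive results with naive code paths (loops, enumeration)
# so they stay independent of the package implementations they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

randDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
randProt <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rcStr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
hammingStr <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Brute-force maximal-IR enumerator: every (position, arm, spacer) triple is
# tested by direct character comparison; maximality by re-testing the two
# one-pair extensions.
oracleIRs <- function(seq, armRange, spacerRange, maxMismatch) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  mmOf <- function(i, a, s) {
    left <- x[i:(i + a - 1)]
    right <- x[(i + a + s):(i + 2 * a + s - 1)]
    sum(left != COMP[rev(right)])
  }
  rows <- list()
  for (a in armRange[1]:armRange[2]) {
    for (s in spacerRange[1]:spacerRange[2]) {
      maxI <- L - 2 * a - s + 1
      if (maxI < 1) next
      for (i in seq_len(maxI)) {
        mm <- mmOf(i, a, s)
        if (mm > maxMismatch) next
        ext <- FALSE
        if (i - 1 >= 1 && a + 1 <= armRange[2] &&
            (i - 1) + 2 * (a + 1) + s - 1 <= L &&
            mmOf(i - 1, a + 1, s) <= maxMismatch) ext <- TRUE
        if (!ext && s - 2 >= spacerRange[1] && a + 1 <= armRange[2] &&
            mmOf(i, a + 1, s - 2) <= maxMismatch) ext <- TRUE
        if (!ext) rows[[length(rows) + 1]] <- c(i, a, s, mm)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_length = integer(), spacer = integer(),
                      mismatches = integer()))
  }
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("left_start", "arm_length", "spacer", "mismatches")
  d$left_end <- d$left_start + d$arm_length - 1
  d$right_start <- d$left_end + d$spacer + 1
  d$right_end <- d$right_start + d$arm_length - 1
  d <- d[order(-d$arm_length, d$mismatches, d$left_start, d$spacer), ]
  rownames(d) <- NULL
  d[, c("left_start", "left_end", "right_start", "right_end", "arm_length",
        "spacer", "mismatches")]
}

# Run-construction operon oracle: group id per feature row.
oracleOperonGroups <- function(df, maxGap) {
  n <- nrow(df)
  g <- integer(n)
  cur <- 1L
  g[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- df$start[i] - df$end[i - 1] - 1
    if (df$strand[i] == df$strand[i - 1] && gap <= maxGap) {
      g[i] <- cur
    } else {
      cur <- cur + 1L
      g[i] <- cur
    }
  }
  g
}

# Random sorted single-contig CDS layout (overlaps allowed, order preserved).
randomLayout <- function(n) {
  lens <- sample(90:600, n, replace = TRUE)
  gaps <- sample(-30:120, n, replace = TRUE)
  starts <- integer(n)
  ends <- integer(n)
  pos <- 100L
  for (i in seq_len(n)) {
    starts[i] <- pos + gaps[i]
    ends[i] <- starts[i] + lens[i] - 1L
    pos <- ends[i]
  }
  shift <- max(1L - min(starts), 0L)
  data.frame(start = starts + shift, end = ends + shift,
             strand = sample(c("+", "-"), n, replace = TRUE),
             cds_id = sprintf("f%03d", seq_len(n)), stringsAsFactors = FALSE)
}

# Exhaustive global-alignment enumeration (match +1, mismatch 0, gap -1):
# returns the set of spec-convention identities among optimal alignments.
oracleOptimalIdentities <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  res <- list()
  rec <- function(i, j, ca, cb) {
    if (i > length(A) && j > length(B)) {
      both <- ca != "-" & cb != "-"
      gaps <- sum(ca == "-") + sum(cb == "-")
      if (!any(both)) {
        res[[length(res) + 1]] <<- c(score = -gaps, identity = 0)
        return()
      }
      span <- range(which(both))
      cols <- span[1]:span[2]
      matches <- sum(ca[cols] == cb[cols] & both[cols])
      res[[length(res) + 1]] <<- c(score = matches - gaps,
                                   identity = matches / length(cols))
      return()
    }
    if (i <= length(A) && j <= length(B)) rec(i + 1, j + 1, c(ca, A[i]), c(cb, B[j]))
    if (i <= length(A)) rec(i + 1, j, c(ca, A[i]), c(cb, "-"))
    if (j <= length(B)) rec(i, j + 1, c(ca, "-"), c(cb, B[j]))
  }
  rec(1, 1, character(0), character(0))
  m <- do.call(rbind, res)
  best <- max(m[, "score"])
  sort(unique(m[m[, "score"] == best, "identity"]))
}

# Independent greedy-clustering oracle following the documented rule.
oracleGreedy <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  memb <- setNames(character(length(ids)), ids)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (pairwiseIdentity(seqs[[r]], seqs[[id]])["identity"] >= threshold) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      memb[id] <- id
    } else {
      memb[id] <- hit
    }
  }
  list(representatives = reps, membership = memb)
}

# A standard mutation-free synthetic community used by several tests.
makeCommunity <- function(seed, ...) {
  generateGenomes(syntheticConfig(seed = seed, ...))
}

# Truth association labels (aca cds id -> expected label) from a manifest.
truthLabels <- function(manifest) {
  lab <- setNames(rep("solo", nrow(manifest$solo_aca)),
                  manifest$solo_aca$cds_id)
  c(lab, setNames(rep("acr_associated", nrow(manifest$planted_operons)),
                  manifest$planted_operons$aca_id))
}

# Planted-IR recovery: does any reported IR contain both planted arms?
irRecovered <- function(irs, pp, k) {
  any(irs$left_start <= pp$ir1_left_start[k] &
        irs$left_end >= pp$ir1_left_end[k] &
        irs$right_start <= pp$ir1_right_start[k] &
        irs$right_end >= pp$ir1_right_end[k])
}

# Build a minimal Motif object from a count matrix (uniform background).
mkMotif <- function(cnt) {
  rownames(cnt) <- BASES
  n <- sum(cnt[, 1])
  freq <- (cnt + 0.25) / (n + 1)
  lo <- log2(freq / 0.25)
  p <- cnt / max(n, 1)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  methods::new("Motif", counts = cnt, logOdds = lo,
               background = rep(0.25, 4),
               sites = data.frame(promoter_id = character(),
                                  offset = integer(), strand = character(),
                                  stringsAsFactors = FALSE),
               ic = sum(2 + colSums(plogp)))
}

# Promoters with one planted, lightly mutated motif instance each.
plantedMotifCase <- function(seed, nProm = 20, promLen = 150, width = 18,
                             subsPerSite = 2) {
  set.seed(seed)
  motif <- randDna(width)
  proms <- vapply(seq_len(nProm), function(i) {
    bg <- randDna(promLen)
    site <- mutateSequence(motif, subsPerSite)
    pos <- sample.int(promLen - width + 1, 1)
    paste0(substr(bg, 1, pos - 1), site, substr(bg, pos + width, promLen))
  }, character(1))
  list(motif = motif, promoters = setNames(proms, sprintf("p%02d", seq_len(nProm))))
}
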