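# Promoter extraction, core-promoter scanning, IR detection, motif
# discovery/scanning/comparison.

promGenome <- function(seq, features) {
  annotatedGenome(setNames(seq, "c1"), features)
}

leaderAt <- function(start, end, strand) {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cds_id = "lead", translation = strrep("M", 10), product = "x")
  gr
}

test_that("promoter extraction is strand-aware with -1 next to the start codon", {
  set.seed(2)
  s <- randDna(1000)
  g <- promGenome(s, leaderAt(401, 700, "+"))
  ops <- callOperons(genomeFeatures(g))
  pr <- extractPromoters(g, ops)
  expect_identical(pr$sequence, substr(s, 1, 400))
  expect_equal(c(pr$start, pr$end), c(1L, 400L))
  expect_false(pr$clipped)
  # position -1 is genomic base 400
  expect_identical(substr(pr$sequence, 400, 400), substr(s, 400, 400))

  gm <- promGenome(s, leaderAt(301, 600, "-"))
  prm <- extractPromoters(gm, callOperons(genomeFeatures(gm)))
  expect_identical(prm$sequence, rcStr(substr(s, 601, 1000)))
  expect_equal(c(prm$start, prm$end), c(601L, 1000L))

  gc <- promGenome(s, leaderAt(100, 399, "+"))
  prc <- extractPromoters(gc, callOperons(genomeFeatures(gc)))
  expect_equal(nchar(prc$sequence), 99)
  expect_true(prc$clipped)
})

test_that("an exact planted core element pair is recovered at maximal score", {
  set.seed(6)
  bg <- randDna(400)
  m35pos <- 320L
  m10pos <- m35pos + 6L + 17L
  seq <- paste0(substr(bg, 1, m35pos - 1), "TTGACA",
                substr(bg, m35pos + 6, m10pos - 1), "TATAAT",
                substr(bg, m10pos + 6, 400))
  core <- scanCorePromoter(seq)
  expect_equal(core$m35_start, m35pos)
  expect_equal(core$m10_start, m10pos)
  expect_equal(core$spacer, 17)
  expect_identical(core$m35_seq, "TTGACA")
  expect_identical(core$m10_seq, "TATAAT")
  # exact consensus with optimal spacer is the maximal achievable score
  expect_equal(core$total_score, 12 * log2(0.7 / 0.25), tolerance = 1e-9)
})

test_that("ties between identical element pairs go to the 3'-most -10", {
  bg <- strrep("C", 400)
  insert <- function(s, what, at)
    paste0(substr(s, 1, at - 1), what, substr(s, at + nchar(what), nchar(s)))
  seq <- bg
  for (p in c(270L, 340L)) {
    seq <- insert(seq, "TTGACA", p)
    seq <- insert(seq, "TATAAT", p + 23L)
  }
  core <- scanCorePromoter(seq)
  expect_equal(core$m10_start, 340L + 23L)
})

test_that("background promoters rarely clear a calibrated significance bar", {
  thr <- calibrateCoreThreshold(n = 1000, probs = 0.99, seed = 501)
  set.seed(502)
  sig <- vapply(1:400, function(i) {
    scanCorePromoter(randDna(150), threshold = thr)$significant
  }, logical(1))
  expect_lte(mean(sig), 0.025)
})

test_that("a constructed palindrome is reported; homopolymers are not", {
  irs <- findInvertedRepeats("TTGACACCCCCTGTCAA", maxMismatch = 0)
  expect_gte(nrow(irs), 1)
  expect_equal(unlist(irs[1, c("left_start", "left_end", "right_start",
                               "right_end", "arm_length", "spacer",
                               "mismatches")], use.names = FALSE),
               c(1, 6, 12, 17, 6, 5, 0))
  expect_equal(nrow(findInvertedRepeats(strrep("A", 60))), 0)
})

test_that("IR detection equals the brute-force enumerator on random input", {
  set.seed(81)
  for (i in 1:30) {
    s <- randDna(sample(60:120, 1))
    got <- findInvertedRepeats(s, armRange = c(4, 8), spacerRange = c(0, 8),
                               maxMismatch = 1)
    exp <- oracleIRs(s, c(4, 8), c(0, 8), 1)
    expect_equal(got, exp)
  }
})

test_that("IR sets mirror under reverse complementation", {
  set.seed(82)
  for (i in 1:15) {
    s <- randDna(100)
    fwd <- findInvertedRepeats(s)
    rev <- findInvertedRepeats(rcStr(s))
    L <- nchar(s)
    mirrored <- data.frame(
      left_start = L - rev$right_end + 1L, left_end = L - rev$right_start + 1L,
      right_start = L - rev$left_end + 1L, right_end = L - rev$left_start + 1L,
      arm_length = rev$arm_length, spacer = rev$spacer,
      mismatches = rev$mismatches)
    key <- function(d) sort(do.call(paste, c(d[, 1:7], sep = ":")))
    expect_identical(key(fwd), key(mirrored))
  }
})

test_that("IRs classify as IR1 on core overlap, IR2 when disjoint", {
  core <- data.frame(m35_start = 100, m35_end = 105, m10_start = 123,
                     m10_end = 128)
  irs <- data.frame(left_start = c(103, 20, 130),
                    left_end = c(108, 25, 135),
                    right_start = c(112, 30, 140),
                    right_end = c(117, 35, 145),
                    arm_length = 6, spacer = c(3, 4, 4), mismatches = 0)
  out <- classifyInvertedRepeats(irs, core)
  expect_identical(out$classification, c("IR1", "IR2", "IR2"))
  out2 <- classifyInvertedRepeats(irs, NULL)
  expect_true(all(out2$classification == "unclassified"))
})

test_that("a noiseless planted word is recovered with every site located", {
  set.seed(91)
  word <- randDna(18)
  pos <- sample(1:(150 - 18 + 1), 20, replace = TRUE)
  proms <- setNames(vapply(1:20, function(i) {
    bg <- randDna(150)
    paste0(substr(bg, 1, pos[i] - 1), word, substr(bg, pos[i] + 18, 150))
  }, character(1)), sprintf("p%02d", 1:20))
  m <- discoverMotif(proms, width = 18, mode = "oops", seed = 7)
  sites <- motifSites(m)
  cons <- motifConsensus(m)
  if (all(sites$strand == "+")) {
    expect_identical(cons, word)
    expect_equal(sites$offset, unname(pos))
  } else {
    expect_true(all(sites$strand == "-"))
    expect_identical(cons, rcStr(word))
    expect_equal(sites$offset, unname(pos))
  }
  expect_error(discoverMotif(proms, width = 200), "width")
})

test_that("motif discovery is deterministic for a fixed seed", {
  cs <- plantedMotifCase(5)
  m1 <- discoverMotif(cs$promoters, seed = 77)
  m2 <- discoverMotif(cs$promoters, seed = 77)
  expect_identical(m1@counts, m2@counts)
  expect_identical(motifSites(m1), motifSites(m2))
})

test_that("motif scanning equals exhaustive window scoring", {
  cs <- plantedMotifCase(9)
  m <- discoverMotif(cs$promoters, mode = "oops", seed = 3)
  set.seed(19)
  s <- randDna(120)
  got <- scanMotif(m, s, threshold = -1e6)
  # naive per-window rescore on both strands
  w <- motifWidth(m)
  naive <- list()
  for (o in 1:(nchar(s) - w + 1)) {
    win <- substr(s, o, o + w - 1)
    for (st in c("+", "-")) {
      ww <- if (st == "+") win else rcStr(win)
      sc <- sum(vapply(seq_len(w), function(k)
        m@logOdds[substr(ww, k, k), k], numeric(1)))
      naive[[length(naive) + 1]] <- data.frame(offset = o, strand = st,
                                               score = sc)
    }
  }
  naive <- do.call(rbind, naive)
  naive <- naive[order(naive$offset, naive$strand), ]
  expect_equal(got$score, naive$score, tolerance = 1e-9)
  # embedded consensus gives the top hit at its offset
  embedded <- paste0(substr(s, 1, 39), motifConsensus(m),
                     substr(s, 40 + w, nchar(s)))
  hits <- scanMotif(m, embedded, threshold = -1e6)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$offset, 40)
  # a threshold above the maximum yields nothing
  expect_equal(nrow(scanMotif(m, s, threshold = 1e6)), 0)
})

test_that("motif comparison finds self and reverse-complement alignments", {
  set.seed(23)
  cnt <- matrix(0, 4, 10)
  for (j in 1:10) cnt[sample.int(4, 1), j] <- 20
  a <- mkMotif(cnt)
  expect_equal(compareMotifs(a, a),
               list(offset = 0L, orientation = "forward", correlation = 1),
               tolerance = 1e-12)
  rcCnt <- cnt[4:1, 10:1]
  b <- mkMotif(rcCnt)
  cmp <- compareMotifs(a, b)
  expect_identical(cmp$orientation, "reverse")
  expect_equal(cmp$correlation, 1, tolerance = 1e-12)
})

test_that("motif comparison equals an independent enumeration oracle", {
  set.seed(29)
  for (rep in 1:10) {
    ca <- matrix(rmultinom(8, 20, rep(0.25, 4)), nrow = 4)
    cb <- matrix(rmultinom(6, 20, rep(0.25, 4)), nrow = 4)
    a <- mkMotif(ca)
    b <- mkMotif(cb)
    got <- compareMotifs(a, b, minOverlap = 4)
    fa <- (ca + 0.25) / (20 + 1)
    fb <- (cb + 0.25) / (20 + 1)
    bestCor <- -Inf
    for (orient in 1:2) {
      fo <- if (orient == 1) fb else fb[4:1, ncol(fb):1]
      for (delta in -(ncol(fb) - 4):(ncol(fa) - 4)) {
        ja <- max(1, 1 + delta):min(ncol(fa), ncol(fb) + delta)
        if (length(ja) < 4) next
        cc <- mean(vapply(ja, function(j) {
          u <- fa[, j]; v <- fo[, j - delta]
          if (sd(u) > 0 && sd(v) > 0) cor(u, v)
          else if (max(abs(u - v)) < 1e-12) 1 else 0
        }, numeric(1)))
        bestCor <- max(bestCor, cc)
      }
    }
    expect_equal(got$correlation, bestCor, tolerance = 1e-9)
  }
})

test_that("MEME-minimal motif files round-trip", {
  cs <- plantedMotifCase(31)
  m <- discoverMotif(cs$promoters, mode = "oops", seed = 4)
  path <- file.path(tempdir(), "motif.meme")
  writeMemeMotif(m, path)
  m2 <- readMemeMotif(path)
  expect_equal(motifWidth(m2), motifWidth(m))
  expect_identical(motifConsensus(m2), motifConsensus(m))
  nsites <- nrow(motifSites(m))
  expect_equal(unname(m2@counts / nsites), unname(acaScan:::motifFreq(m)),
               tolerance = 1e-4)
})
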