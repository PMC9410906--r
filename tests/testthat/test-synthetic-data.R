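# Synthetic genome generator: determinism, planted-element bookkeeping,
# sequence composition and round-trip I/O.

test_that("same config and seed give byte-identical FASTA/GFF3 output", {
  cfg <- syntheticConfig(n_contigs = 2, contig_length = 8000,
                         n_acr_aca_operons = 1, n_solo_aca = 1,
                         n_background_cds = 4, seed = 11)
  g1 <- generateGenomes(cfg)
  g2 <- generateGenomes(cfg)
  p1 <- file.path(tempdir(), "det1")
  p2 <- file.path(tempdir(), "det2")
  f1 <- writeGenomeSet(g1$genome, p1)
  f2 <- writeGenomeSet(g2$genome, p2)
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})

test_that("nothing planted yields pure background and an empty manifest", {
  cfg <- syntheticConfig(n_contigs = 2, contig_length = 3000,
                         n_acr_aca_operons = 0, n_solo_aca = 0,
                         n_background_cds = 0, seed = 3)
  g <- generateGenomes(cfg)
  expect_length(genomeFeatures(g$genome), 0)
  expect_equal(nrow(g$manifest$planted_operons), 0)
  expect_equal(nrow(g$manifest$planted_promoters), 0)
  expect_equal(nrow(g$manifest$solo_aca), 0)
  expect_equal(sum(Biostrings::width(genomeSequences(g$genome))), 6000)
})

test_that("a too-small contig raises a capacity error", {
  cfg <- syntheticConfig(n_contigs = 1, contig_length = 900,
                         n_acr_aca_operons = 1, n_solo_aca = 0,
                         n_background_cds = 0, seed = 1)
  expect_error(generateGenomes(cfg), "capacity")
})

test_that("mutateSequence changes exactly n positions, reproducibly", {
  expect_identical(mutateSequence("ACGTACGT", 0, seed = 1), "ACGTACGT")
  noA <- mutateSequence("AAAA", 4, seed = 2)
  expect_false(grepl("A", noA))
  expect_identical(mutateSequence("ACGTACGTACGT", 5, seed = 9),
                   mutateSequence("ACGTACGTACGT", 5, seed = 9))
  set.seed(31)
  for (i in 1:25) {
    s <- randDna(sample(10:60, 1))
    k <- sample.int(nchar(s), 1)
    m <- mutateSequence(s, k, seed = i)
    expect_equal(hammingStr(s, m), k)
  }
})

test_that("plantPromoter records exact elements; arms are reverse complements", {
  sp <- promoterSpec(ir_mismatches = 0)
  p <- plantPromoter(sp, 400, seed = 5)
  el <- p$elements
  pick <- function(nm) el[el$element == nm, ]
  sub <- function(r) substr(p$sequence, r$start, r$end)
  expect_identical(sub(pick("minus35")), "TTGACA")
  expect_identical(sub(pick("minus10")), "TATAAT")
  expect_identical(sub(pick("ir1_left")), rcStr(sub(pick("ir1_right"))))
  expect_equal(pick("minus10")$start - pick("minus35")$end - 1, sp$spacer)
  # determinism
  expect_identical(plantPromoter(sp, 400, seed = 5)$sequence, p$sequence)
})

test_that("a second IR shares the first IR's arm consensus", {
  sp <- promoterSpec(ir_count = 2, ir_mismatches = 0)
  p <- plantPromoter(sp, 400, seed = 8)
  el <- p$elements
  sub <- function(nm) {
    r <- el[el$element == nm, ]
    substr(p$sequence, r$start, r$end)
  }
  expect_identical(sub("ir1_left"), sub("ir2_left"))
  expect_identical(sub("ir2_left"), rcStr(sub("ir2_right")))
})

test_that("planted IR arms differ by at most the configured mismatches", {
  sp <- promoterSpec(ir_mismatches = 1)
  p <- plantPromoter(sp, 400, seed = 13)
  el <- p$elements
  sub <- function(nm) {
    r <- el[el$element == nm, ]
    substr(p$sequence, r$start, r$end)
  }
  expect_equal(hammingStr(sub("ir1_left"), rcStr(sub("ir1_right"))), 1)
})

test_that("plantPromoter rejects regions too short for the footprint", {
  expect_error(plantPromoter(promoterSpec(), 30, seed = 1), "overflow")
  expect_error(plantPromoter(promoterSpec(ir_arm = 12), 400, seed = 1),
               "overflow|fit")
})

test_that("background base composition tracks the configured GC", {
  for (gc in c(0.38, 0.62)) {
    cfg <- syntheticConfig(n_contigs = 1, contig_length = 50000,
                           n_acr_aca_operons = 0, n_solo_aca = 0,
                           n_background_cds = 0, gc_content = gc, seed = 9)
    s <- as.character(genomeSequences(generateGenomes(cfg)$genome)[[1]])
    obs <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_lt(abs(obs - gc), 0.02)
  }
})

test_that("FASTA+GFF3 round-trip preserves coordinates and translations", {
  g <- makeCommunity(21, n_contigs = 3, contig_length = 12000,
                     n_acr_aca_operons = 2, n_solo_aca = 1,
                     n_background_cds = 6)
  prefix <- file.path(tempdir(), "roundtrip")
  paths <- writeGenomeSet(g$genome, prefix)
  g2 <- readGenomeSet(paths[["fna"]], paths[["gff3"]])
  f1 <- genomeFeatures(g$genome)
  f2 <- genomeFeatures(g2)
  expect_equal(length(f1), length(f2))
  o1 <- order(S4Vectors::mcols(f1)$cds_id)
  o2 <- order(S4Vectors::mcols(f2)$cds_id)
  expect_equal(GenomicRanges::start(f1)[o1], GenomicRanges::start(f2)[o2])
  expect_equal(GenomicRanges::end(f1)[o1], GenomicRanges::end(f2)[o2])
  expect_identical(as.character(GenomicRanges::strand(f1))[o1],
                   as.character(GenomicRanges::strand(f2))[o2])
  expect_identical(S4Vectors::mcols(f1)$translation[o1],
                   S4Vectors::mcols(f2)$translation[o2])
  # translations consistent with the nucleotide sequence on both strands
  for (i in seq_along(f2)) {
    nt <- acaScan:::featureSequence(g2, f2[i])
    expect_identical(acaScan:::translateCds(nt),
                     S4Vectors::mcols(f2)$translation[i])
  }
})

test_that("planted operon gaps respect the configured range", {
  g <- makeCommunity(5, operon_gap_range = c(10L, 30L))
  gaps <- as.integer(unlist(strsplit(g$manifest$planted_operons$gaps, ",")))
  expect_true(all(gaps >= 10 & gaps <= 30))
  # and the genomic gap between planted acr and aca equals the recorded gap
  f <- genomeFeatures(g$genome)
  mc <- S4Vectors::mcols(f)
  po <- g$manifest$planted_operons
  for (k in seq_len(nrow(po))) {
    ids <- strsplit(po$member_ids[k], ",")[[1]]
    rows <- f[match(ids, mc$cds_id)]
    ord <- order(GenomicRanges::start(rows))
    gapsGenomic <- GenomicRanges::start(rows)[ord][-1] -
      utils::head(GenomicRanges::end(rows)[ord], -1) - 1L
    expect_setequal(gapsGenomic,
                    as.integer(strsplit(po$gaps[k], ",")[[1]]))
  }
})

test_that("manifest round-trips through JSON", {
  g <- makeCommunity(33, n_contigs = 2, contig_length = 10000,
                     n_acr_aca_operons = 1, n_solo_aca = 1,
                     n_background_cds = 2)
  path <- file.path(tempdir(), "manifest.json")
  writeTruthManifest(g$manifest, path)
  m2 <- readTruthManifest(path)
  expect_equal(m2$planted_operons$aca_id, g$manifest$planted_operons$aca_id)
  expect_equal(m2$planted_promoters$start, g$manifest$planted_promoters$start)
  expect_equal(unlist(m2$family_references),
               unlist(g$manifest$family_references))
})
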