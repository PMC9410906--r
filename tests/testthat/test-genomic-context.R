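# Operon calling, neighborhoods, association classification and networks.

mkFeatures <- function(df, contig = "c1") {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cds_id = df$cds_id, translation = strrep("M", 10), product = "x")
  gr
}

mkGenome <- function(df, contigLength = max(df$end) + 6000,
                     contig = "c1") {
  set.seed(1)
  annotatedGenome(setNames(randDna(contigLength), contig),
                  mkFeatures(df, contig))
}

test_that("the intergenic-gap rule merges at the threshold and splits above", {
  base <- data.frame(start = c(1000, NA), end = c(1299, NA),
                     strand = "+", cds_id = c("a", "b"),
                     stringsAsFactors = FALSE)
  for (gap in c(55L, 56L)) {
    d <- base
    d$start[2] <- d$end[1] + gap + 1L
    d$end[2] <- d$start[2] + 299L
    ops <- callOperons(mkFeatures(d), maxGap = 55)
    expect_equal(length(unique(ops$operon_id)), if (gap == 55L) 1L else 2L)
  }
})

test_that("an intervening opposite-strand CDS breaks the run", {
  d <- data.frame(start = c(100, 401, 702), end = c(400, 701, 1002),
                  strand = c("+", "-", "+"),
                  cds_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  ops <- callOperons(mkFeatures(d), maxGap = 55)
  expect_equal(length(unique(ops$operon_id)), 3L)
})

test_that("operon leaders follow the coding strand", {
  d <- data.frame(start = c(100, 420), end = c(400, 720),
                  strand = "-", cds_id = c("x", "y"),
                  stringsAsFactors = FALSE)
  ops <- callOperons(mkFeatures(d), maxGap = 55)
  expect_identical(ops$cds_id[ops$is_leader], "y")
  d$strand <- "+"
  ops <- callOperons(mkFeatures(d), maxGap = 55)
  expect_identical(ops$cds_id[ops$is_leader], "x")
})

test_that("unsorted features are rejected", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(500, 100), width = 100),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cds_id = c("a", "b"), translation = "M", product = "x")
  expect_error(callOperons(gr), "sorted")
})

test_that("operon partition matches the run-construction oracle", {
  set.seed(42)
  for (rep in 1:200) {
    d <- randomLayout(sample(3:20, 1))
    ops <- callOperons(mkFeatures(d), maxGap = 55)
    g <- oracleOperonGroups(d, 55)
    # same partition (every CDS in exactly one operon, same groupings)
    expect_setequal(ops$cds_id, d$cds_id)
    expect_equal(anyDuplicated(ops$cds_id), 0L)
    opOf <- setNames(ops$operon_id, ops$cds_id)[d$cds_id]
    expect_equal(length(unique(opOf)), length(unique(g)))
    expect_true(all(tapply(g, opOf, function(v) length(unique(v))) == 1))
  }
})

test_that("neighborhood windows clip at contig edges and honor the flank", {
  d <- data.frame(start = c(50, 4000, 9500), end = c(350, 4300, 9800),
                  strand = "+", cds_id = c("edge", "mid", "far"),
                  stringsAsFactors = FALSE)
  genome <- mkGenome(d, contigLength = 12000)
  nb <- extractNeighborhood(genome, "edge", flank = 5000)
  expect_equal(nb$window[1], 1L)
  nb0 <- extractNeighborhood(genome, "mid", flank = 0)
  expect_identical(as.character(S4Vectors::mcols(nb0$features)$cds_id), "mid")
  expect_error(extractNeighborhood(genome, "nope"), "unknown")
})

test_that("a neighbor 4999 bases away is inside the window; 5001 is not", {
  for (dist in c(4999L, 5001L)) {
    acaStart <- 10000L
    acrEnd <- acaStart - dist - 1L
    d <- data.frame(start = c(acrEnd - 299L, acaStart),
                    end = c(acrEnd, acaStart + 299L), strand = "+",
                    cds_id = c("acr", "aca"), stringsAsFactors = FALSE)
    genome <- mkGenome(d, contigLength = 20000)
    nb <- extractNeighborhood(genome, "aca", flank = 5000)
    inside <- "acr" %in% as.character(S4Vectors::mcols(nb$features)$cds_id)
    expect_identical(inside, dist < 5000L)
  }
})

test_that("association labels follow operon > neighborhood > solo priority", {
  # acr(known) and aca in one operon, gap 10
  d <- data.frame(start = c(1000, 1311), end = c(1300, 1700), strand = "+",
                  cds_id = c("acr1", "aca1"), stringsAsFactors = FALSE)
  genome <- mkGenome(d)
  ops <- callOperons(genomeFeatures(genome))
  nb <- extractNeighborhood(genome, "aca1")
  rec <- classifyAssociation(nb, ops, c(acr1 = "known"))
  expect_identical(rec$label, "acr_associated")
  expect_identical(rec$acr_class, "known")
  expect_identical(rec$linked_acr_ids, "acr1")

  # acr 3 kb away on the opposite strand -> proximal
  d2 <- data.frame(start = c(1000, 4301), end = c(1300, 4700),
                   strand = c("-", "+"), cds_id = c("acr1", "aca1"),
                   stringsAsFactors = FALSE)
  genome2 <- mkGenome(d2)
  rec2 <- classifyAssociation(extractNeighborhood(genome2, "aca1"),
                              callOperons(genomeFeatures(genome2)),
                              c(acr1 = "candidate"))
  expect_identical(rec2$label, "proximal")
  expect_identical(rec2$acr_class, "candidate")

  # background only -> solo
  rec3 <- classifyAssociation(extractNeighborhood(genome2, "aca1"),
                              callOperons(genomeFeatures(genome2)),
                              c(other = "known"))
  expect_identical(rec3$label, "solo")
  expect_identical(rec3$linked_acr_ids, "")
  expect_identical(rec3$acr_class, "none")
})

test_that("network edges count records and distinct acr families", {
  recs <- data.frame(
    aca_cds_id = c("a1", "a2", "a3", "a4", "s1"),
    label = c(rep("acr_associated", 4), "solo"),
    acr_class = c(rep("known", 4), "none"),
    linked_acr_ids = c("r1", "r2", "r3", "r4,r5", ""),
    n_linked = c(1, 1, 1, 2, 0),
    operon_id = sprintf("op%d", 1:5), stringsAsFactors = FALSE)
  fam <- c(a1 = "Aca5", a2 = "Aca5", a3 = "Aca5", a4 = "Aca2", s1 = "Aca2",
           r1 = "AcrIF17", r2 = "AcrIF17", r3 = "AcrIF17",
           r4 = "F8", r5 = "F9")
  net <- buildNetwork(recs, fam)
  e <- net$edges
  expect_equal(e$weight[e$from == "Aca5" & e$to == "AcrIF17"], 3L)
  expect_equal(e$weight[e$from == "Aca2" & e$to == "F8"], 1L)
  expect_equal(e$weight[e$from == "Aca2" & e$to == "F9"], 1L)
  # conservation: total weight = sum over records of distinct linked families
  expect_equal(sum(e$weight), 5L)
  # solo-only records give nodes but no edges
  net0 <- buildNetwork(recs[recs$label == "solo", , drop = FALSE], fam)
  expect_equal(nrow(net0$edges), 0L)
  expect_true("Aca2" %in% net0$nodes)
  # unresolvable family errors
  expect_error(buildNetwork(recs, fam[setdiff(names(fam), "r2")]),
               "unresolvable|family")
})

test_that("strand mirroring leaves operons and association labels invariant", {
  g <- makeCommunity(55, n_contigs = 3, contig_length = 15000,
                     n_acr_aca_operons = 2, n_solo_aca = 2,
                     n_background_cds = 8)
  m <- g$manifest
  rcg <- reverseComplementGenome(g$genome)
  acrIds <- m$planted_members$cds_id[m$planted_members$role == "operon_acr"]
  acrLabels <- setNames(rep("known", length(acrIds)), acrIds)
  acaIds <- c(m$planted_operons$aca_id, m$solo_aca$cds_id)
  for (genome in list(g$genome, rcg)) {
    ops <- callOperons(genome)
    labs <- vapply(acaIds, function(id)
      classifyAssociation(extractNeighborhood(genome, id), ops,
                          acrLabels)$label, character(1))
    memberSets <- lapply(split(ops$cds_id, ops$operon_id), sort)
    if (genome@sequences[[1]] == g$genome@sequences[[1]]) {
      fwdLabs <- labs
      fwdSets <- memberSets
    } else {
      expect_identical(labs, fwdLabs)
      expect_setequal(
        unname(vapply(memberSets, paste, character(1), collapse = ",")),
        unname(vapply(fwdSets, paste, character(1), collapse = ",")))
    }
  }
})
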