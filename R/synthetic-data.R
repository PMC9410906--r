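# Synthetic annotated genomes with planted acr-aca operons, promoters, core
# elements and inverted repeats, plus a ground-truth manifest. The generator
# is the package's test bed: every downstream stage can be scored against the
# manifest without any external data.

#' Specification of a planted promoter
#'
#' Describes the sigma70 core element and inverted-repeat (IR) layout planted
#' by [plantPromoter()]: a -35 and -10 hexamer separated by `spacer` bases,
#' one or two IRs whose left arm is anchored on the -35 element (so the first
#' IR always overlaps the core promoter, the configuration observed for Aca
#' operators), and an optional second IR with the same arm consensus placed
#' upstream of the core.
#'
#' @param minus35,minus10 Length-6 DNA consensus hexamers.
#' @param spacer Core spacer in bases, 15-19.
#' @param ir_arm IR arm length in bases (>= 4).
#' @param ir_spacer Bases between the two IR arms.
#' @param ir_count 1 or 2 planted IRs.
#' @param ir_mismatches Substitutions applied to each IR's right arm after
#'   planting (arms are exact reverse complements before mutation).
#' @return A list of class `PlantedPromoterSpec`.
#' @export
promoterSpec <- function(minus35 = "TTGACA", minus10 = "TATAAT", spacer = 17,
                         ir_arm = 6, ir_spacer = 5, ir_count = 1,
                         ir_mismatches = 0) {
  stopifnot(nchar(minus35) == 6L, nchar(minus10) == 6L,
            grepl("^[ACGT]+$", minus35), grepl("^[ACGT]+$", minus10),
            spacer >= 15, spacer <= 19, ir_arm >= 4, ir_spacer >= 0,
            ir_count %in% c(1L, 2L), ir_mismatches >= 0)
  structure(list(minus35 = minus35, minus10 = minus10,
                 spacer = as.integer(spacer), ir_arm = as.integer(ir_arm),
                 ir_spacer = as.integer(ir_spacer),
                 ir_count = as.integer(ir_count),
                 ir_mismatches = as.integer(ir_mismatches)),
            class = "PlantedPromoterSpec")
}

#' Configuration for the synthetic genome generator
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param gc_content Background GC fraction, in (0,1); background bases are
#'   drawn i.i.d. with `P(G) = P(C) = gc_content/2`.
#' @param n_acr_aca_operons Planted acr-aca operons (acr gene(s) upstream of
#'   the aca on the coding strand, each preceded by a planted promoter).
#' @param n_solo_aca Planted aca genes without any nearby acr.
#' @param n_background_cds Random open reading frames planted as negatives.
#' @param operon_gap_range Integer `(min, max)` intergenic gap, in strictly
#'   intervening bases, between consecutive operon members.
#' @param promoter_spec A [promoterSpec()].
#' @param promoter_length Planted promoter window length (bases).
#' @param mutation_rate Integer substitutions applied to each planted core
#'   hexamer (-35 and -10) after planting.
#' @param member_sub_rate Per-site amino-acid substitution rate applied to
#'   planted operonic family members relative to the family reference.
#' @param solo_sub_rate Same for solo aca members (defaults to
#'   `member_sub_rate`; set higher to emulate the more divergent solo group).
#' @param n_acr_per_operon acr genes per operon.
#' @param n_aca_families,n_acr_families Number of synthetic families.
#' @param aca_ref_length,acr_ref_length Reference protein lengths (aa).
#' @param min_spacing Minimum background distance between planted elements,
#'   in bases; must exceed the operon gap threshold so planted loci never
#'   fuse with neighbours.
#' @param seed Integer master seed; the single source of randomness.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_contigs = 10, contig_length = 25000,
                            gc_content = 0.5, n_acr_aca_operons = 5,
                            n_solo_aca = 5, n_background_cds = 50,
                            operon_gap_range = c(0L, 55L),
                            promoter_spec = promoterSpec(),
                            promoter_length = 400, mutation_rate = 0,
                            member_sub_rate = 0,
                            solo_sub_rate = member_sub_rate,
                            n_acr_per_operon = 1,
                            n_aca_families = 2, n_acr_families = 2,
                            aca_ref_length = 70, acr_ref_length = 110,
                            min_spacing = 200, seed = 1) {
  stopifnot(n_contigs >= 1, contig_length > 0,
            gc_content > 0, gc_content < 1,
            length(operon_gap_range) == 2L,
            operon_gap_range[1] >= 0, diff(operon_gap_range) >= 0,
            inherits(promoter_spec, "PlantedPromoterSpec"),
            promoter_length > 0, mutation_rate >= 0,
            member_sub_rate >= 0, member_sub_rate < 1,
            solo_sub_rate >= 0, solo_sub_rate < 1,
            n_acr_per_operon >= 1,
            n_aca_families >= 1, n_acr_families >= 1,
            aca_ref_length >= 20, acr_ref_length >= 20,
            min_spacing > 55)
  structure(as.list(environment()), class = "SyntheticConfig")
}

#' Substitute exactly `n_subs` positions of a sequence
#'
#' Positions are sampled without replacement and every substituted symbol is
#' forced to differ from the original, so the Hamming distance between input
#' and output is exactly `n_subs`.
#'
#' @param seq A character string (DNA by default).
#' @param n_subs Number of substitutions, `0 <= n_subs <= nchar(seq)`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (the generator's internal mode).
#' @param alphabet Symbols to substitute from.
#' @return The mutated string.
#' @export
#' @examples
#' mutateSequence("ACGTACGT", 2, seed = 7)
mutateSequence <- function(seq, n_subs, seed = NULL,
                           alphabet = c("A", "C", "G", "T")) {
  stopifnot(n_subs >= 0, n_subs <= nchar(seq))
  run <- function() {
    if (n_subs == 0) return(seq)
    x <- strsplit(seq, "")[[1]]
    pos <- sample.int(length(x), n_subs)
    for (p in pos) {
      x[p] <- sample(setdiff(alphabet, x[p]), 1L)
    }
    paste(x, collapse = "")
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

randomDna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA4, n, replace = TRUE, prob = p), collapse = "")
}

randomProtein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

mutateProtein <- function(prot, rate) {
  n <- round(rate * nchar(prot))
  mutateSequence(prot, n, seed = NULL, alphabet = AA20)
}

CODON_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Back-translate a protein into a CDS with random synonymous codons + stop.
backTranslate <- function(prot) {
  aa <- strsplit(prot, "")[[1]]
  codons <- vapply(aa, function(a) {
    cs <- CODON_OF[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         STOP_CODONS[sample.int(3L, 1L)])
}

#' Plant a sigma70 core promoter and inverted repeats into background DNA
#'
#' Lays out, 5' to 3': optional second IR (IR pair with the same arm consensus
#' as the first), background, -35 hexamer, spacer, -10 hexamer, and 11 bases
#' of background before the 3' end (the downstream start codon). The first
#' IR's left arm is anchored at the -35 start, so it always overlaps the core
#' promoter; its right arm is written as the exact reverse complement of the
#' left arm into the core spacer. `ir_mismatches` substitutions are then
#' applied to each IR's right arm.
#'
#' @param spec A [promoterSpec()].
#' @param length Total promoter length in bases.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param gc Background GC fraction.
#' @return A list with `sequence` (character) and `elements` (data.frame of
#'   `element`, `start`, `end`, 1-based within the promoter).
#' @export
plantPromoter <- function(spec, length, seed = NULL, gc = 0.5) {
  stopifnot(inherits(spec, "PlantedPromoterSpec"), length > 0)
  run <- function() {
    a <- spec$ir_arm; irsp <- spec$ir_spacer; sp <- spec$spacer
    if (2L * a + irsp > 6L + sp)
      stop("promoter footprint overflow: IR (2*arm + spacer = ",
           2L * a + irsp, ") does not fit between the -35 start and the -10 (",
           6L + sp, " bases)")
    m10_end <- length - 11L
    m10_start <- m10_end - 5L
    m35_end <- m10_start - sp - 1L
    m35_start <- m35_end - 5L
    ir2_len <- 2L * a + irsp
    min_start <- if (spec$ir_count == 2L) m35_start - 4L - ir2_len else
      m35_start
    if (min_start < 1L)
      stop("promoter footprint overflow: length ", length,
           " too short for the planted elements")
    x <- strsplit(randomDna(length, gc), "")[[1]]
    x[m35_start:m35_end] <- strsplit(spec$minus35, "")[[1]]
    x[m10_start:m10_end] <- strsplit(spec$minus10, "")[[1]]
    ir1_l <- c(m35_start, m35_start + a - 1L)
    ir1_r <- c(ir1_l[2] + irsp + 1L, ir1_l[2] + irsp + a)
    arm_seq <- paste(x[ir1_l[1]:ir1_l[2]], collapse = "")
    x[ir1_r[1]:ir1_r[2]] <- strsplit(revcomp(arm_seq), "")[[1]]
    el <- data.frame(
      element = c("minus35", "minus10", "ir1_left", "ir1_right"),
      start = c(m35_start, m10_start, ir1_l[1], ir1_r[1]),
      end = c(m35_end, m10_end, ir1_l[2], ir1_r[2]),
      stringsAsFactors = FALSE)
    if (spec$ir_count == 2L) {
      ir2_r_end <- m35_start - 5L
      ir2_l <- c(ir2_r_end - ir2_len + 1L, ir2_r_end - ir2_len + a)
      ir2_r <- c(ir2_r_end - a + 1L, ir2_r_end)
      x[ir2_l[1]:ir2_l[2]] <- strsplit(arm_seq, "")[[1]]
      x[ir2_r[1]:ir2_r[2]] <- strsplit(revcomp(arm_seq), "")[[1]]
      el <- rbind(el, data.frame(
        element = c("ir2_left", "ir2_right"),
        start = c(ir2_l[1], ir2_r[1]), end = c(ir2_l[2], ir2_r[2]),
        stringsAsFactors = FALSE))
    }
    if (spec$ir_mismatches > 0) {
      for (arm in grep("_right$", el$element)) {
        iv <- el$start[arm]:el$end[arm]
        x[iv] <- strsplit(mutateSequence(paste(x[iv], collapse = ""),
                                         spec$ir_mismatches), "")[[1]]
      }
    }
    list(sequence = paste(x, collapse = ""), elements = el)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

flipInterval <- function(start, end, L) c(L - end + 1L, L - start + 1L)

#' Generate synthetic annotated genomes with a ground-truth manifest
#'
#' Plants acr-aca operon cassettes (planted promoter, acr gene(s), configured
#' intergenic gap, aca gene, random strand), solo aca cassettes (promoter +
#' aca), and background ORFs into i.i.d. background DNA, keeping all planted
#' elements at least `min_spacing` bases apart. Operon and solo cassettes are
#' placed on disjoint contig sets so a solo aca never has an acr gene in its
#' flanking window (which is what "solo" asserts); at least two contigs are
#' required when both kinds are requested. Family members are derived from
#' per-family random reference proteins by per-site substitution.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [syntheticConfig()].
#' @return A list with `genome` (an [AnnotatedGenome-class]), `manifest`
#'   (ground truth: family references and classes, planted operons,
#'   promoters with element coordinates, planted members, solo ids) and the
#'   echoed `config`.
#' @export
generateGenomes <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, generateGenomesImpl(config))
}

generateGenomesImpl <- function(config) {
  gc <- config$gc_content
  acaFams <- paste0("AcaF", seq_len(config$n_aca_families))
  acrFams <- paste0("AcrF", seq_len(config$n_acr_families))
  refs <- c(
    setNames(lapply(acaFams, function(f) randomProtein(config$aca_ref_length)),
             acaFams),
    setNames(lapply(acrFams, function(f) randomProtein(config$acr_ref_length)),
             acrFams))
  acrClass <- setNames(rep_len(c("known", "candidate", "putative"),
                               length(acrFams)), acrFams)

  cdsCounter <- 0L
  nextId <- function() {
    cdsCounter <<- cdsCounter + 1L
    sprintf("cds%04d", cdsCounter)
  }

  # Build cassettes in a forward frame; each is a list with seq, features
  # (relative coords, coding strand +), promoter info, strand to place on.
  mkCds <- function(prot, offset, family, role, product) {
    nt <- backTranslate(prot)
    list(id = nextId(), start = offset + 1L, end = offset + nchar(nt),
         seq = nt, translation = prot, family = family, role = role,
         product = product)
  }

  elements <- list()
  for (i in seq_len(config$n_acr_aca_operons)) {
    acaFam <- acaFams[(i - 1L) %% length(acaFams) + 1L]
    pr <- plantPromoter(config$promoter_spec, config$promoter_length,
                        seed = NULL, gc = gc)
    seqs <- pr$sequence
    off <- config$promoter_length
    cds <- list()
    gaps <- integer(0)
    for (k in seq_len(config$n_acr_per_operon)) {
      acrFam <- acrFams[(i + k - 2L) %% length(acrFams) + 1L]
      prot <- mutateProtein(refs[[acrFam]], config$member_sub_rate)
      if (k > 1L) {
        g <- sample(config$operon_gap_range[1]:config$operon_gap_range[2], 1L)
        gaps <- c(gaps, g)
        seqs <- paste0(seqs, randomDna(g, gc))
        off <- off + g
      }
      cd <- mkCds(prot, off, acrFam, "operon_acr", "anti-CRISPR protein (synthetic)")
      seqs <- paste0(seqs, cd$seq)
      off <- cd$end
      cds <- c(cds, list(cd))
    }
    g <- sample(config$operon_gap_range[1]:config$operon_gap_range[2], 1L)
    gaps <- c(gaps, g)
    seqs <- paste0(seqs, randomDna(g, gc))
    off <- off + g
    prot <- mutateProtein(refs[[acaFam]], config$member_sub_rate)
    cd <- mkCds(prot, off, acaFam, "operon_aca",
                "anti-CRISPR-associated regulator (synthetic)")
    seqs <- paste0(seqs, cd$seq)
    cds <- c(cds, list(cd))
    elements <- c(elements, list(list(
      type = "operon", operon_label = sprintf("planted_op%02d", i),
      seq = seqs, cds = cds, gaps = gaps, promoter = pr,
      strand = sample(c("+", "-"), 1L))))
  }
  for (i in seq_len(config$n_solo_aca)) {
    acaFam <- acaFams[(i - 1L) %% length(acaFams) + 1L]
    pr <- plantPromoter(config$promoter_spec, config$promoter_length,
                        seed = NULL, gc = gc)
    prot <- mutateProtein(refs[[acaFam]], config$solo_sub_rate)
    cd <- mkCds(prot, config$promoter_length, acaFam, "solo_aca",
                "anti-CRISPR-associated regulator (synthetic)")
    elements <- c(elements, list(list(
      type = "solo", seq = paste0(pr$sequence, cd$seq), cds = list(cd),
      promoter = pr, strand = sample(c("+", "-"), 1L))))
  }
  for (i in seq_len(config$n_background_cds)) {
    prot <- randomProtein(sample(50:300, 1L))
    cd <- mkCds(prot, 0L, NA_character_, "background", "hypothetical protein")
    elements <- c(elements, list(list(
      type = "background", seq = cd$seq, cds = list(cd),
      strand = sample(c("+", "-"), 1L))))
  }

  # Apply core-hexamer mutations after IR planting (may also perturb IR arms).
  if (config$mutation_rate > 0) {
    for (j in seq_along(elements)) {
      if (!is.null(elements[[j]]$promoter)) {
        x <- strsplit(elements[[j]]$seq, "")[[1]]
        el <- elements[[j]]$promoter$elements
        for (nm in c("minus35", "minus10")) {
          r <- el[el$element == nm, ]
          iv <- r$start:r$end
          x[iv] <- strsplit(mutateSequence(paste(x[iv], collapse = ""),
                                           min(config$mutation_rate, 6L)),
                            "")[[1]]
        }
        elements[[j]]$seq <- paste(x, collapse = "")
      }
    }
  }

  # Solo aca genes must truly be solo: operon cassettes (which carry acr
  # genes) and solo cassettes are placed on disjoint contig sets so no acr
  # ever falls inside a solo locus's flanking window.
  if (length(elements)) {
    elements <- elements[sample.int(length(elements))]
    types <- vapply(elements, `[[`, character(1), "type")
    nop <- sum(types == "operon")
    nsolo <- sum(types == "solo")
    contigOf <- integer(length(elements))
    if (nop > 0 && nsolo > 0) {
      if (config$n_contigs < 2)
        stop("capacity error: at least 2 contigs are needed to isolate solo ",
             "aca genes from acr-containing operons")
      nOpC <- max(1L, min(config$n_contigs - 1L,
                          round(config$n_contigs * nop / (nop + nsolo))))
      opPool <- seq_len(nOpC)
      soloPool <- (nOpC + 1L):config$n_contigs
    } else {
      opPool <- soloPool <- seq_len(config$n_contigs)
    }
    contigOf[types == "operon"] <- rep_len(opPool, nop)
    contigOf[types == "solo"] <- rep_len(soloPool, nsolo)
    contigOf[types == "background"] <-
      rep_len(seq_len(config$n_contigs), sum(types == "background"))
  } else {
    contigOf <- integer(0)
  }

  contigNamesV <- sprintf("contig%02d", seq_len(config$n_contigs))
  featRows <- list()
  opRows <- list()
  promRows <- list()
  soloRows <- list()
  memberRows <- list()
  seqsOut <- character(config$n_contigs)

  for (ci in seq_len(config$n_contigs)) {
    idx <- which(contigOf == ci)
    lens <- vapply(idx, function(j) nchar(elements[[j]]$seq), integer(1))
    k <- length(idx)
    slack <- config$contig_length - sum(lens) - (k + 1L) * config$min_spacing
    if (slack < 0)
      stop("capacity error: contig_length ", config$contig_length,
           " cannot hold ", k, " planted elements (need at least ",
           sum(lens) + (k + 1L) * config$min_spacing, " bases)")
    if (k > 0) {
      w <- runif(k + 1L)
      parts <- floor(slack * w / sum(w))
      parts[1L] <- parts[1L] + slack - sum(parts)
      gaps <- config$min_spacing + parts
    } else {
      gaps <- config$contig_length
    }
    pieces <- character(0)
    pos <- 0L
    for (m in seq_len(k)) {
      pieces <- c(pieces, randomDna(gaps[m], gc))
      pos <- pos + gaps[m]
      e <- elements[[idx[m]]]
      L <- nchar(e$seq)
      placed <- if (e$strand == "-") revcomp(e$seq) else e$seq
      pieces <- c(pieces, placed)
      cass0 <- pos  # 0-based offset of cassette start on the contig
      absIv <- function(s, en) {
        if (e$strand == "+") c(cass0 + s, cass0 + en)
        else cass0 + flipInterval(s, en, L)
      }
      for (cd in e$cds) {
        iv <- absIv(cd$start, cd$end)
        featRows[[length(featRows) + 1L]] <- data.frame(
          contig = contigNamesV[ci], start = iv[1], end = iv[2],
          strand = e$strand, cds_id = cd$id, translation = cd$translation,
          product = cd$product, stringsAsFactors = FALSE)
        if (!is.na(cd$family))
          memberRows[[length(memberRows) + 1L]] <- data.frame(
            cds_id = cd$id, family = cd$family, role = cd$role,
            stringsAsFactors = FALSE)
      }
      if (e$type == "operon") {
        ids <- vapply(e$cds, `[[`, character(1), "id")
        roles <- vapply(e$cds, `[[`, character(1), "role")
        opRows[[length(opRows) + 1L]] <- data.frame(
          operon_label = e$operon_label, contig = contigNamesV[ci],
          strand = e$strand,
          member_ids = paste(ids, collapse = ","),
          acr_ids = paste(ids[roles == "operon_acr"], collapse = ","),
          aca_id = ids[roles == "operon_aca"],
          gaps = paste(e$gaps, collapse = ","), stringsAsFactors = FALSE)
      }
      if (e$type == "solo") {
        cd <- e$cds[[1]]
        soloRows[[length(soloRows) + 1L]] <- data.frame(
          cds_id = cd$id, contig = contigNamesV[ci], strand = e$strand,
          family = cd$family, stringsAsFactors = FALSE)
      }
      if (!is.null(e$promoter)) {
        P <- config$promoter_length
        piv <- absIv(1L, P)
        leader <- e$cds[[1]]$id
        owner <- if (e$type == "operon") e$operon_label else e$cds[[1]]$id
        el <- e$promoter$elements
        getRel <- function(nm) {
          r <- el[el$element == nm, ]
          if (nrow(r)) c(r$start, r$end) else c(NA_integer_, NA_integer_)
        }
        m35 <- getRel("minus35"); m10 <- getRel("minus10")
        i1l <- getRel("ir1_left"); i1r <- getRel("ir1_right")
        i2l <- getRel("ir2_left"); i2r <- getRel("ir2_right")
        promRows[[length(promRows) + 1L]] <- data.frame(
          owner = owner, leader_cds = leader, contig = contigNamesV[ci],
          strand = e$strand, start = piv[1], end = piv[2],
          m35_start = m35[1], m35_end = m35[2],
          m10_start = m10[1], m10_end = m10[2],
          ir1_left_start = i1l[1], ir1_left_end = i1l[2],
          ir1_right_start = i1r[1], ir1_right_end = i1r[2],
          ir2_left_start = i2l[1], ir2_left_end = i2l[2],
          ir2_right_start = i2r[1], ir2_right_end = i2r[2],
          stringsAsFactors = FALSE)
      }
      pos <- pos + L
    }
    pieces <- c(pieces, randomDna(config$contig_length - pos, gc))
    seqsOut[ci] <- paste(pieces, collapse = "")
  }

  feats <- if (length(featRows)) do.call(rbind, featRows) else NULL
  gr <- if (!is.null(feats)) {
    g <- GenomicRanges::GRanges(feats$contig,
      IRanges::IRanges(feats$start, feats$end), strand = feats$strand)
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      cds_id = feats$cds_id, translation = feats$translation,
      product = feats$product)
    g
  } else GenomicRanges::GRanges()
  genome <- annotatedGenome(setNames(seqsOut, contigNamesV), gr)

  emptyDf <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  manifest <- list(
    family_references = lapply(refs, identity),
    aca_families = acaFams, acr_families = acrFams,
    acr_class_by_family = as.list(acrClass),
    planted_operons = if (length(opRows)) do.call(rbind, opRows) else
      emptyDf(operon_label = character(), contig = character(),
              strand = character(), member_ids = character(),
              acr_ids = character(), aca_id = character(), gaps = character()),
    planted_promoters = if (length(promRows)) do.call(rbind, promRows) else
      emptyDf(owner = character(), leader_cds = character(),
              contig = character(), strand = character(),
              start = integer(), end = integer()),
    planted_members = if (length(memberRows)) do.call(rbind, memberRows) else
      emptyDf(cds_id = character(), family = character(), role = character()),
    solo_aca = if (length(soloRows)) do.call(rbind, soloRows) else
      emptyDf(cds_id = character(), contig = character(),
              strand = character(), family = character()))
  list(genome = genome, manifest = manifest, config = config)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest The `manifest` component of [generateGenomes()] output.
#' @param path Output path.
#' @return `writeTruthManifest()` the path invisibly; `readTruthManifest()`
#'   the manifest list with data.frame components restored.
#' @export
writeTruthManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("planted_operons", "planted_promoters", "planted_members",
               "solo_aca")) {
    m[[nm]] <- as.data.frame(m[[nm]], stringsAsFactors = FALSE)
  }
  m
}
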