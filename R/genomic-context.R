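# Genomic neighborhood extraction, intergenic-gap operon calling,
# acr-association classification of aca loci, and the acr-aca gene
# association network.

ACR_CLASS_LEVELS <- c("known", "candidate", "putative")

featureDf <- function(features) {
  data.frame(cds_id = as.character(S4Vectors::mcols(features)$cds_id),
             contig = as.character(GenomicRanges::seqnames(features)),
             start = GenomicRanges::start(features),
             end = GenomicRanges::end(features),
             strand = as.character(GenomicRanges::strand(features)),
             stringsAsFactors = FALSE)
}

#' Extract the genomic neighborhood around a hit CDS
#'
#' The window is the center CDS extended by `flank` bases on both sides,
#' clipped to the contig; member features are all CDS overlapping the window
#' by at least one base, in genomic order.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param cdsId The center CDS id (e.g. a [scanGenome()] hit).
#' @param flank Flank size in bases (default 5000).
#' @return A list of class `Neighborhood`: `center`, `contig`, `window`
#'   (length-2 integer), `features` (a `GRanges`).
#' @export
extractNeighborhood <- function(genome, cdsId, flank = 5000) {
  f <- genome@features
  i <- match(cdsId, as.character(S4Vectors::mcols(f)$cds_id))
  if (is.na(i)) stop("unknown CDS id: ", cdsId)
  contig <- as.character(GenomicRanges::seqnames(f[i]))
  L <- Biostrings::width(genome@sequences)[[match(contig, names(genome@sequences))]]
  ws <- max(1L, GenomicRanges::start(f[i]) - as.integer(flank))
  we <- min(L, GenomicRanges::end(f[i]) + as.integer(flank))
  onContig <- f[as.character(GenomicRanges::seqnames(f)) == contig]
  keep <- GenomicRanges::start(onContig) <= we & GenomicRanges::end(onContig) >= ws
  feats <- onContig[keep]
  feats <- feats[order(GenomicRanges::start(feats))]
  structure(list(center = cdsId, contig = contig, window = c(ws, we),
                 features = feats), class = "Neighborhood")
}

#' Call operons by intergenic gap on same-strand CDS runs
#'
#' Consecutive CDS (in genomic order) are merged into one operon when they
#' are on the same strand and separated by at most `maxGap` strictly
#' intervening bases (`next.start - prev.end - 1`; overlapping CDS give a
#' negative gap and always merge). Any intervening opposite-strand CDS
#' breaks the run. Every CDS belongs to exactly one operon. The operon
#' leader is the 5'-most member on the coding strand: the first member for
#' `+` operons, the last for `-`.
#'
#' @param features A `GRanges` of CDS (may span several contigs; must be
#'   sorted by start within each contig) or an [AnnotatedGenome-class].
#' @param maxGap Maximum intergenic gap in bases (default 55).
#' @return data.frame with one row per CDS: `operon_id`, `contig`, `strand`,
#'   `cds_id`, `start`, `end`, `is_leader`, `member_index` (genomic order
#'   within the operon).
#' @export
callOperons <- function(features, maxGap = 55) {
  if (is(features, "AnnotatedGenome")) features <- features@features
  df <- featureDf(features)
  out <- list()
  opCounter <- 0L
  for (contig in unique(df$contig)) {
    d <- df[df$contig == contig, , drop = FALSE]
    if (is.unsorted(d$start)) stop("features not sorted by start on ", contig)
    runId <- integer(nrow(d))
    cur <- 1L
    for (i in seq_len(nrow(d))) {
      if (i == 1L) {
        runId[i] <- cur
      } else {
        gap <- d$start[i] - d$end[i - 1L] - 1L
        if (d$strand[i] == d$strand[i - 1L] && gap <= maxGap) {
          runId[i] <- cur
        } else {
          cur <- cur + 1L
          runId[i] <- cur
        }
      }
    }
    for (r in unique(runId)) {
      opCounter <- opCounter + 1L
      m <- d[runId == r, , drop = FALSE]
      leaderIdx <- if (m$strand[1] == "+") 1L else nrow(m)
      out[[length(out) + 1L]] <- data.frame(
        operon_id = sprintf("op%04d", opCounter), contig = contig,
        strand = m$strand, cds_id = m$cds_id, start = m$start, end = m$end,
        is_leader = seq_len(nrow(m)) == leaderIdx,
        member_index = seq_len(nrow(m)), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(operon_id = character(), contig = character(),
               strand = character(), cds_id = character(), start = integer(),
               end = integer(), is_leader = logical(),
               member_index = integer(), stringsAsFactors = FALSE)
}

#' Classify an aca locus by its association with acr genes
#'
#' `acr_associated` if at least one labelled acr CDS shares the aca's
#' operon; otherwise `proximal` if a labelled acr lies elsewhere in the
#' neighborhood; otherwise `solo`. The reported acr class is the best label
#' present among linked acrs (`known` > `candidate` > `putative`).
#'
#' @param nbhd A `Neighborhood` from [extractNeighborhood()] centred on the
#'   aca CDS.
#' @param operons Operon table from [callOperons()] covering the aca's
#'   contig.
#' @param acrLabels Named character vector: acr cds_id -> class in
#'   `known`/`candidate`/`putative`.
#' @return One-row data.frame: `aca_cds_id`, `label`, `acr_class`,
#'   `linked_acr_ids` (comma-separated), `n_linked`, `operon_id`.
#' @export
classifyAssociation <- function(nbhd, operons, acrLabels) {
  acaId <- nbhd$center
  opRow <- operons[operons$cds_id == acaId, , drop = FALSE]
  if (nrow(opRow) != 1L) stop("aca CDS ", acaId,
                              " must appear in exactly one operon")
  opId <- opRow$operon_id
  members <- operons$cds_id[operons$operon_id == opId]
  inOperon <- intersect(setdiff(members, acaId), names(acrLabels))
  nbIds <- as.character(S4Vectors::mcols(nbhd$features)$cds_id)
  inNbhd <- intersect(setdiff(nbIds, c(acaId, inOperon)), names(acrLabels))
  if (length(inOperon)) {
    label <- "acr_associated"; linked <- sort(inOperon)
  } else if (length(inNbhd)) {
    label <- "proximal"; linked <- sort(inNbhd)
  } else {
    label <- "solo"; linked <- character(0)
  }
  acrClass <- if (length(linked)) {
    ACR_CLASS_LEVELS[min(match(acrLabels[linked], ACR_CLASS_LEVELS))]
  } else "none"
  data.frame(aca_cds_id = acaId, label = label, acr_class = acrClass,
             linked_acr_ids = paste(linked, collapse = ","),
             n_linked = length(linked), operon_id = opId,
             stringsAsFactors = FALSE)
}

#' Build the acr-aca family association network
#'
#' For every `acr_associated` record, the edge between the aca's family and
#' each distinct linked acr family is incremented by one. Solo and proximal
#' records contribute their aca family as an isolated node.
#'
#' @param records data.frame of association records (rows from
#'   [classifyAssociation()]).
#' @param familyOf Named character vector: cds_id -> family label (both aca
#'   and acr CDS must be resolvable).
#' @return A list of class `AssociationNetwork`: `nodes` (character) and
#'   `edges` (data.frame `from`, `to`, `weight`; `from` is the aca family).
#' @export
buildNetwork <- function(records, familyOf) {
  nodes <- character(0)
  ecount <- list()
  for (i in seq_len(nrow(records))) {
    acaFam <- unname(familyOf[records$aca_cds_id[i]])
    if (is.na(acaFam))
      stop("no family for aca CDS ", records$aca_cds_id[i])
    nodes <- union(nodes, acaFam)
    if (records$label[i] != "acr_associated") next
    linked <- strsplit(records$linked_acr_ids[i], ",")[[1]]
    fams <- unique(vapply(linked, function(id) {
      f <- familyOf[id]
      if (is.na(f)) stop("unresolvable acr family for CDS ", id)
      unname(f)
    }, character(1)))
    nodes <- union(nodes, fams)
    for (f in fams) {
      key <- paste(acaFam, f, sep = "\t")
      ecount[[key]] <- (if (is.null(ecount[[key]])) 0L else ecount[[key]]) + 1L
    }
  }
  edges <- if (length(ecount)) {
    parts <- do.call(rbind, strsplit(names(ecount), "\t"))
    data.frame(from = parts[, 1], to = parts[, 2],
               weight = unlist(ecount, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), weight = integer(),
               stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges),
            class = "AssociationNetwork")
}

#' Export an association network as GraphML (via igraph)
#'
#' @param network An `AssociationNetwork` from [buildNetwork()].
#' @param path Output GraphML path.
#' @return The path, invisibly.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
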