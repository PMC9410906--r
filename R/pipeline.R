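# End-to-end orchestration: scan -> threshold calibration -> operons ->
# association -> promoters -> core/IR/motifs -> network -> family stats,
# with one master seed, stage-derived sub-seeds and a JSON-serialisable
# report.

#' Pipeline configuration
#'
#' Declarative configuration for [runPipeline()]. Either pass the arguments
#' in R or point `yamlPath` at a YAML file whose keys override the defaults
#' (paths in the file are taken as given).
#'
#' @param genome An [AnnotatedGenome-class], or `NULL` with `genomeFasta` /
#'   `genomeGff3` paths.
#' @param seedAlignments Named list: family -> character vector of aligned
#'   (or single, ungapped) seed protein sequences.
#' @param acrClassByFamily Named character vector: acr family ->
#'   `known`/`candidate`/`putative`. Families not listed are treated as aca
#'   families.
#' @param genomeFasta,genomeGff3 Input paths used when `genome` is `NULL`.
#' @param flank Neighborhood flank in bases (default 5000).
#' @param operonMaxGap Operon intergenic-gap threshold (default 55).
#' @param promoterLength Promoter extraction length (default 400).
#' @param searchWindow Core-promoter / IR search window (default 150).
#' @param irArmRange,irSpacerRange,irMaxMismatch IR detector bounds.
#' @param motifWidth Gibbs motif width (default 18); `doMotifs` disables
#'   motif discovery when `FALSE`.
#' @param doMotifs Run motif discovery over the high-confidence promoters.
#' @param coverageFilter Strict coverage filter for family summaries
#'   (default 0.4).
#' @param clusterThresholdProtein,clusterThresholdNt Greedy clustering
#'   identities (defaults 0.8 and 0.9).
#' @param scoreThresholds Optional named per-family bit-score thresholds;
#'   when `NULL` they are calibrated on a background-only synthetic genome
#'   (`calibrationQuantile`, with `calibrationCds` background ORFs).
#' @param calibrationQuantile Null quantile for threshold calibration.
#' @param calibrationCds Background ORFs in the calibration genome.
#' @param seed Master seed.
#' @param yamlPath Optional YAML file of overrides.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genome = NULL, seedAlignments = list(),
                           acrClassByFamily = character(),
                           genomeFasta = NULL, genomeGff3 = NULL,
                           flank = 5000, operonMaxGap = 55,
                           promoterLength = 400, searchWindow = 150,
                           irArmRange = c(4, 10), irSpacerRange = c(0, 12),
                           irMaxMismatch = 1, motifWidth = 18,
                           doMotifs = FALSE, coverageFilter = 0.4,
                           clusterThresholdProtein = 0.8,
                           clusterThresholdNt = 0.9,
                           scoreThresholds = NULL,
                           calibrationQuantile = 0.999,
                           calibrationCds = 300, seed = 1,
                           yamlPath = NULL) {
  cfg <- as.list(environment())
  cfg$yamlPath <- NULL
  if (!is.null(yamlPath)) {
    y <- yaml::read_yaml(yamlPath)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  stopifnot(cfg$flank >= 0, cfg$operonMaxGap >= 0, cfg$promoterLength > 0,
            cfg$searchWindow > 0, cfg$coverageFilter >= 0,
            cfg$clusterThresholdProtein > 0, cfg$clusterThresholdProtein <= 1,
            cfg$clusterThresholdNt > 0, cfg$clusterThresholdNt <= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

logStage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full aca analysis pipeline
#'
#' Stages, in order: profile construction from the seed alignments;
#' per-family score-threshold calibration on a background-only synthetic
#' genome (unless thresholds are supplied); genome scanning; greedy protein
#' clustering of aca hits; genome-wide operon calling; per-aca neighborhood
#' extraction and acr-association classification; promoter extraction for
#' every aca-bearing operon; core-promoter and inverted-repeat calls with
#' IR1/IR2 classification; optional Gibbs motif discovery on the
#' acr-associated (high-confidence) promoter set; the family association
#' network; and per-family summaries. Deterministic for a fixed
#' `config$seed` (per-stage sub-seeds via [deriveSeed()]).
#'
#' @param config A [pipelineConfig()].
#' @param verbose Emit one structured log line per stage.
#' @return A `RunReport` list: `config_echo`, `seed`, `thresholds`, `hits`,
#'   `clusters`, `operons`, `associations`, `promoters`, `core_calls`,
#'   `ir_calls`, `motif` (consensus/ic/sites or NULL), `network`,
#'   `family_summaries`, `counts`, `versions`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  genome <- config$genome
  if (is.null(genome)) {
    stopifnot(!is.null(config$genomeFasta), !is.null(config$genomeGff3))
    genome <- readGenomeSet(config$genomeFasta, config$genomeGff3)
  }
  seed <- config$seed
  fams <- names(config$seedAlignments)
  if (!length(fams)) stop("stage profiles: no seed alignments supplied")
  acrFams <- intersect(fams, names(config$acrClassByFamily))
  acaFams <- setdiff(fams, acrFams)

  profiles <- lapply(fams, function(f)
    buildProfile(config$seedAlignments[[f]], familyName = f))
  names(profiles) <- fams
  logStage(verbose, "profiles", length(profiles), " family profiles built")

  thresholds <- config$scoreThresholds
  if (is.null(thresholds)) {
    calCfg <- syntheticConfig(
      n_contigs = 1, contig_length = max(200000, config$calibrationCds * 1200),
      n_acr_aca_operons = 0, n_solo_aca = 0,
      n_background_cds = config$calibrationCds,
      seed = deriveSeed(seed, "calibration"))
    calGenome <- generateGenomes(calCfg)$genome
    thresholds <- calibrateProfileThresholds(profiles, calGenome,
                                             probs = config$calibrationQuantile)
    logStage(verbose, "calibration", "thresholds from ",
             config$calibrationCds, " background ORFs")
  }
  for (f in fams) profiles[[f]]@scoreThreshold <- unname(thresholds[[f]])

  hits <- scanGenome(profiles, genome)
  logStage(verbose, "scan", nrow(hits), " hits over ",
           length(genome@features), " CDS")

  # family assignment: best-scoring family per CDS
  familyOf <- character(0)
  if (nrow(hits)) {
    bestRows <- hits[!duplicated(hits$cds_id), , drop = FALSE]  # sorted by score
    familyOf <- setNames(bestRows$family, bestRows$cds_id)
  }
  acaIds <- names(familyOf)[familyOf %in% acaFams]
  acrIds <- names(familyOf)[familyOf %in% acrFams]
  acrLabels <- setNames(
    unname(unlist(config$acrClassByFamily)[familyOf[acrIds]]), acrIds)

  clusters <- NULL
  if (length(acaIds) >= 2) {
    f <- genome@features
    prots <- setNames(as.character(S4Vectors::mcols(f)$translation),
                      as.character(S4Vectors::mcols(f)$cds_id))
    clusters <- greedyCluster(prots[acaIds],
                              threshold = config$clusterThresholdProtein)
    logStage(verbose, "cluster", length(clusters$representatives),
             " representatives from ", length(acaIds), " aca hits")
  }

  operons <- callOperons(genome, maxGap = config$operonMaxGap)

  records <- list()
  for (id in acaIds) {
    nb <- extractNeighborhood(genome, id, flank = config$flank)
    records[[length(records) + 1L]] <-
      classifyAssociation(nb, operons, acrLabels)
  }
  associations <- if (length(records)) do.call(rbind, records) else
    data.frame(aca_cds_id = character(), label = character(),
               acr_class = character(), linked_acr_ids = character(),
               n_linked = integer(), operon_id = character(),
               stringsAsFactors = FALSE)
  logStage(verbose, "association",
           sum(associations$label == "acr_associated"), " associated, ",
           sum(associations$label == "proximal"), " proximal, ",
           sum(associations$label == "solo"), " solo")

  acaOperons <- unique(associations$operon_id)
  promoters <- if (length(acaOperons))
    extractPromoters(genome, operons, length = config$promoterLength,
                     operonIds = acaOperons)
  else
    data.frame(operon_id = character(), leader_cds = character(),
               contig = character(), strand = character(), start = integer(),
               end = integer(), sequence = character(), clipped = logical(),
               stringsAsFactors = FALSE)

  coreCalls <- list(); irCalls <- list()
  for (i in seq_len(nrow(promoters))) {
    seqi <- promoters$sequence[i]
    if (!nchar(seqi)) next
    core <- scanCorePromoter(seqi, searchWindow = config$searchWindow)
    irs <- findPromoterIRs(seqi, searchWindow = config$searchWindow,
                           armRange = config$irArmRange,
                           spacerRange = config$irSpacerRange,
                           maxMismatch = config$irMaxMismatch)
    irs <- classifyInvertedRepeats(irs, core)
    if (!is.null(core)) {
      core$operon_id <- promoters$operon_id[i]
      coreCalls[[length(coreCalls) + 1L]] <- core
    }
    if (nrow(irs)) {
      irs$operon_id <- promoters$operon_id[i]
      irCalls[[length(irCalls) + 1L]] <- irs
    }
  }
  coreCalls <- if (length(coreCalls)) do.call(rbind, coreCalls) else NULL
  irCalls <- if (length(irCalls)) do.call(rbind, irCalls) else NULL
  logStage(verbose, "promoters", nrow(promoters), " promoters, ",
           if (is.null(coreCalls)) 0L else nrow(coreCalls), " core calls, ",
           if (is.null(irCalls)) 0L else nrow(irCalls), " IRs")

  motif <- NULL
  if (isTRUE(config$doMotifs)) {
    hc <- promoters[promoters$operon_id %in%
      associations$operon_id[associations$label == "acr_associated"], ,
      drop = FALSE]
    hc <- hc[nchar(hc$sequence) >= config$motifWidth, , drop = FALSE]
    if (nrow(hc) >= 2) {
      motif <- discoverMotif(hc, width = config$motifWidth,
                             seed = deriveSeed(seed, "motif"))
      logStage(verbose, "motif", motifConsensus(motif), " IC ",
               round(motifIC(motif), 2))
    }
  }

  network <- if (nrow(associations))
    buildNetwork(associations, familyOf) else
    structure(list(nodes = character(0),
                   edges = data.frame(from = character(), to = character(),
                                      weight = integer(),
                                      stringsAsFactors = FALSE)),
              class = "AssociationNetwork")

  summaries <- list()
  for (f in acaFams) {
    fh <- hits[hits$family == f & hits$cds_id %in% acaIds, , drop = FALSE]
    if (nrow(fh))
      summaries[[length(summaries) + 1L]] <-
        summarizeFamily(fh, associations, minCoverage = config$coverageFilter)
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL

  perFamilyHits <- table(factor(familyOf, levels = fams))
  counts <- list(
    n_cds = length(genome@features),
    n_hits = nrow(hits),
    n_aca_hits = length(acaIds),
    n_acr_hits = length(acrIds),
    per_family_hits = as.list(setNames(as.integer(perFamilyHits), fams)),
    n_operons = length(unique(operons$operon_id)),
    n_associated = sum(associations$label == "acr_associated"),
    n_proximal = sum(associations$label == "proximal"),
    n_solo = sum(associations$label == "solo"))

  cfgEcho <- config
  cfgEcho$genome <- NULL
  report <- list(
    seed = seed,
    config_echo = cfgEcho[!vapply(cfgEcho, is.null, logical(1))],
    versions = list(acaScan = as.character(utils::packageVersion("acaScan"))),
    thresholds = as.list(thresholds),
    counts = counts,
    hits = hits,
    clusters = if (is.null(clusters)) NULL else
      list(representatives = clusters$representatives,
           membership = as.list(clusters$membership)),
    operons = operons,
    associations = associations,
    promoters = promoters,
    core_calls = coreCalls,
    ir_calls = irCalls,
    motif = if (is.null(motif)) NULL else
      list(consensus = motifConsensus(motif), ic = motifIC(motif),
           width = motifWidth(motif), sites = motifSites(motif)),
    network = list(nodes = network$nodes, edges = network$edges),
    family_summaries = summaries)
  class(report) <- c("RunReport", "list")
  report
}

#' Write a run report as JSON
#'
#' Deterministic serialisation (no timestamps), so identical runs produce
#' byte-identical files.
#'
#' @param report A `RunReport` from [runPipeline()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeRunReport <- function(report, path) {
  r <- unclass(report)
  r$config_echo <- lapply(r$config_echo, function(v)
    if (inherits(v, "PlantedPromoterSpec")) unclass(v) else v)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
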