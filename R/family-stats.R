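# Family-level summaries: length/identity contrasts between Acr-associated
# and solo members (Welch tests, t-based 95% CIs), identity-derived distance
# matrices and neighbor-joining trees with Newick export.

#' Welch's unequal-variance two-sample t-test
#'
#' Implemented from the Welch statistic and Welch-Satterthwaite degrees of
#' freedom, with a two-sided p-value from the t distribution. Matches
#' `stats::t.test(x, y)` (the package's independent cross-check) to
#' numerical precision.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Named numeric vector `c(t=, df=, p=)`.
#' @export
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
welchTTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) stop("degenerate input: zero variance, equal means")
  }
  sx <- vx / length(x); sy <- vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

ciHalfWidth <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
}

#' Summarise a family: associated vs solo lengths and identities
#'
#' Hits are first filtered to coverage strictly greater than `minCoverage`
#' (the ">40% query coverage" convention), then split by association label
#' into the acr-associated and solo groups (proximal records are excluded
#' by default, making the contrast binary). Per group and metric (protein
#' length in aa; identity to the family reference) the mean and t-based 95%
#' confidence half-width are reported, with a Welch test when both groups
#' have at least two members.
#'
#' @param hits [scanGenome()] hits for one family (`family` column must be
#'   uniform).
#' @param records Association records ([classifyAssociation()] rows) for
#'   the same CDS set.
#' @param minCoverage Strict lower coverage bound (default 0.4).
#' @param includeProximal Count proximal records into the associated group.
#' @return One-row data.frame with group sizes, means, CI half-widths and
#'   Welch `t`/`df`/`p` for length and identity (test columns `NA` when a
#'   group has fewer than 2 members).
#' @export
summarizeFamily <- function(hits, records, minCoverage = 0.4,
                            includeProximal = FALSE) {
  if (!nrow(hits)) stop("empty family: no hits")
  family <- unique(hits$family)
  stopifnot(length(family) == 1L)
  hits <- hits[hits$coverage > minCoverage, , drop = FALSE]
  lab <- setNames(records$label, records$aca_cds_id)
  hits$label <- unname(lab[hits$cds_id])
  assocLabels <- if (includeProximal) c("acr_associated", "proximal") else
    "acr_associated"
  a <- hits[!is.na(hits$label) & hits$label %in% assocLabels, , drop = FALSE]
  s <- hits[!is.na(hits$label) & hits$label == "solo", , drop = FALSE]
  testOrNA <- function(x, y) {
    if (length(x) >= 2 && length(y) >= 2 &&
        (stats::var(x) > 0 || stats::var(y) > 0 || mean(x) != mean(y))) {
      welchTTest(x, y)
    } else c(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  tl <- testOrNA(a$aa_length, s$aa_length)
  ti <- testOrNA(a$identity, s$identity)
  data.frame(
    family = family, n_associated = nrow(a), n_solo = nrow(s),
    assoc_length_mean = mean(a$aa_length), assoc_length_ci = ciHalfWidth(a$aa_length),
    solo_length_mean = mean(s$aa_length), solo_length_ci = ciHalfWidth(s$aa_length),
    assoc_identity_mean = mean(a$identity), assoc_identity_ci = ciHalfWidth(a$identity),
    solo_identity_mean = mean(s$identity), solo_identity_ci = ciHalfWidth(s$identity),
    length_t = unname(tl["t"]), length_df = unname(tl["df"]),
    length_p = unname(tl["p"]),
    identity_t = unname(ti["t"]), identity_df = unname(ti["df"]),
    identity_p = unname(ti["p"]), stringsAsFactors = FALSE)
}

#' Pairwise distance matrix from global-alignment identity
#'
#' `d(i, j) = 1 - identity(i, j)` with identity from [pairwiseIdentity()];
#' symmetric with a zero diagonal by construction.
#'
#' @param seqs Named character vector of >= 2 protein sequences.
#' @return A symmetric numeric matrix with the sequence ids as dimnames.
#' @export
distancesFromIdentity <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        1 - unname(pairwiseIdentity(seqs[[i]], seqs[[j]])["identity"])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]), exact on additive
#' distance matrices. Negative branch-length estimates are clamped to zero
#' and flagged in the `clamped` attribute.
#'
#' @param d Symmetric non-negative distance matrix with labels (or a
#'   `dist`).
#' @return An [ape] `phylo` tree (unrooted for >= 3 taxa; the 2-taxon case
#'   is the single edge split at its midpoint).
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-12) stop("asymmetric distance matrix")
  n <- nrow(d)
  stopifnot(n >= 2, !is.null(rownames(d)))
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    attr(tr, "clamped") <- FALSE
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Write a tree as Newick / a distance matrix as PHYLIP square format
#'
#' @param tree An ape `phylo`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @param d Symmetric distance matrix.
#' @export
writePhylipDistances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
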