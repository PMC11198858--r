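#' Link clusters across samples/species by profile correlation
#'
#' Spearman rank correlation (midranks) between every query and every
#' reference effect-size profile over the shared, mapped gene list. Each
#' query cluster is assigned the reference cluster with the highest
#' positive correlation; with no positive correlation it stays
#' unassigned, and exact ties go to the lowest-index reference with a
#' tie flag. The correlation uses the entire shared gene list, not
#' marker subsets.
#'
#' @param query,reference lists of [EffectSizeProfile-class].
#' @param gene_map a [GeneMap-class] translating query symbols to
#'   reference symbols; the default intersects shared symbols.
#' @param min_shared_genes error below this intersection size (default
#'   50).
#' @return a [LinkageResult-class].
#' @export
linkProfiles <- function(query, reference, gene_map = GeneMap(),
                         min_shared_genes = 50) {
  stopifnot(length(query) >= 1, length(reference) >= 1)
  qgenes <- query[[1]]@genes
  rgenes <- reference[[1]]@genes
  if (gene_map@mode == "explicit_pairs" && nrow(gene_map@pairs) > 0) {
    idx <- match(qgenes, gene_map@pairs$a)
    mapped <- gene_map@pairs$b[idx]
  } else {
    mapped <- qgenes
  }
  keep <- !is.na(mapped) & mapped %in% rgenes
  if (sum(keep) < min_shared_genes)
    stop(sprintf("only %d shared genes after mapping (floor %d)",
                 sum(keep), min_shared_genes))
  qm <- esMatrix(query)[keep, , drop = FALSE]
  rm_ <- esMatrix(reference)[match(mapped[keep], rgenes), , drop = FALSE]
  corr <- stats::cor(qm, rm_, method = "spearman")
  corr[is.na(corr)] <- 0            # constant profile has no rank order
  assignment <- do.call(rbind, lapply(seq_len(nrow(corr)), function(i) {
    row <- corr[i, ]
    best <- max(row)
    hits <- which(abs(row - best) < 1e-12)
    if (best > 0) {
      data.frame(query = rownames(corr)[i],
                 reference = colnames(corr)[hits[1]],
                 correlation = best, tied = length(hits) > 1)
    } else {
      data.frame(query = rownames(corr)[i], reference = NA_character_,
                 correlation = best, tied = FALSE)
    }
  }))
  out <- new("LinkageResult", corr = corr, assignment = assignment,
             n_shared_genes = as.integer(sum(keep)))
  validObject(out)
  out
}

#' Weighted Dice-Sorensen index between two clusterings
#'
#' Builds the confusion matrix of the two labellings over the same cell
#' set, matches clusters one-to-one (by default an optimal assignment
#' maximising total intersection; `matching = "greedy"` pairs largest
#' intersections first), scores each matched pair with
#' `dice = 2|A∩B| / (|A| + |B|)` and averages dice over A's clusters
#' weighted by their fractional sizes. Unmatched clusters score 0.
#' The index is 1 exactly when the two labellings induce identical
#' partitions, and is invariant to renaming labels on either side.
#'
#' @param labels_a,labels_b per-cell cluster labels; either both named
#'   by cell id (cells matched by name) or both unnamed and aligned.
#' @param matching `"optimal"` (default) or `"greedy"`.
#' @return a [DsiResult-class].
#' @examples
#' weightedDice(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2))
#' @export
weightedDice <- function(labels_a, labels_b,
                         matching = c("optimal", "greedy")) {
  matching <- match.arg(matching)
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0) stop("labelings share no cells")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    stop("unnamed labelings must have equal length")
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  n <- length(a)
  conf <- table(a, b)
  match_ab <- matchClusters(conf, matching)
  sizes_a <- rowSums(conf)
  sizes_b <- colSums(conf)
  pairs <- do.call(rbind, lapply(rownames(conf), function(ca) {
    cb <- match_ab[[ca]]
    if (is.null(cb)) {
      data.frame(cluster_a = ca, cluster_b = NA_character_,
                 intersection = 0, size_a = sizes_a[[ca]], size_b = 0,
                 dice = 0)
    } else {
      inter <- conf[ca, cb]
      data.frame(cluster_a = ca, cluster_b = cb,
                 intersection = as.numeric(inter),
                 size_a = sizes_a[[ca]], size_b = sizes_b[[cb]],
                 dice = 2 * inter / (sizes_a[[ca]] + sizes_b[[cb]]))
    }
  }))
  rownames(pairs) <- NULL
  wdsi <- sum(pairs$size_a / n * pairs$dice)
  out <- new("DsiResult", pairs = pairs, weighted_dsi = wdsi)
  validObject(out)
  out
}

# one-to-one cluster matching on a confusion matrix; returns a named
# list cluster_a -> cluster_b
matchClusters <- function(conf, matching) {
  ra <- rownames(conf)
  cb <- colnames(conf)
  if (matching == "greedy") {
    res <- list()
    m <- as.matrix(conf)
    while (any(m > 0)) {
      ij <- which(m == max(m), arr.ind = TRUE)[1, ]
      res[[ra[ij[1]]]] <- cb[ij[2]]
      m[ij[1], ] <- -1
      m[, ij[2]] <- -1
    }
    return(res)
  }
  m <- as.matrix(conf)
  dimnames(m) <- list(paste0("A_", ra), paste0("B_", cb))
  g <- igraph::graph_from_biadjacency_matrix(m, weighted = TRUE)
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  res <- list()
  for (i in seq_along(ra)) {
    partner <- mm$matching[[paste0("A_", ra[i])]]
    if (!is.na(partner)) res[[ra[i]]] <- sub("^B_", "", partner)
  }
  res
}
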