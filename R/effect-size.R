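#' Glass rank biserial effect size
#'
#' Rank-based two-group effect measure in [-1, 1]. The two groups are
#' pooled, midranks assigned, and
#' `rg = 2 * (mean rank of a - mean rank of b) / (n_a + n_b)`.
#' Positive values mean group `a` is stochastically larger. Without ties
#' this equals `2 * U_a / (n_a * n_b) - 1` with `U_a` the Mann-Whitney
#' statistic of group `a`; `rg = +/-1` exactly at complete separation.
#' The statistic is invariant under any strictly monotone transform of
#' the pooled values.
#'
#' @param a,b numeric vectors, each non-empty and finite.
#' @return the effect size, a single number in [-1, 1].
#' @examples
#' glassRankBiserial(c(1, 2, 3), c(4, 5, 6))  # -1, complete separation
#' @export
glassRankBiserial <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both groups must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite")
  r <- rank(c(a, b))
  rg <- 2 * (mean(r[seq_len(n_a)]) - mean(r[n_a + seq_len(n_b)])) /
    (n_a + n_b)
  min(1, max(-1, rg))
}

#' Effect-size profiles of every cluster in a sample
#'
#' For each cluster, each gene's Glass rank biserial coefficient of the
#' gene's log-normalised values in the cluster's cells versus all other
#' cells of the sample (one-vs-rest contrast). Computed on logcounts,
#' not z-scaled values (rank statistics are invariant to per-gene
#' monotone scaling, so only centring-induced ties could differ).
#' Clusters with fewer than 3 cells are computed but flagged low
#' confidence.
#'
#' @param norm a [NormalizedMatrix-class] for one sample.
#' @param clusters a [ClusterTree-class] or a per-cell label vector named
#'   by barcode (unnamed vectors are taken in column order).
#' @param sample_id optional id; defaults to the sample annotation of
#'   `norm`.
#' @return named list of [EffectSizeProfile-class], one per cluster.
#' @export
clusterProfiles <- function(norm, clusters, sample_id = NULL) {
  stopifnot(is(norm, "NormalizedMatrix"))
  if (is(clusters, "ClusterTree")) clusters <- leafLabels(clusters)
  labels <- as.character(clusters)
  if (!is.null(names(clusters))) {
    if (!all(colnames(norm) %in% names(clusters)))
      stop("labels must cover every cell of the sample")
    labels <- as.character(clusters[colnames(norm)])
  } else if (length(labels) != ncol(norm)) {
    stop("labels must cover every cell of the sample")
  }
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("at least 2 clusters are required")
  if (is.null(sample_id))
    sample_id <- sampleMeta(norm)$sample_id %||% "sample"
  V <- as.matrix(logValues(norm))
  n <- ncol(V)
  R <- t(apply(V, 1, rank))           # per-gene midranks across cells
  ind <- vapply(ulab, function(l) as.numeric(labels == l), numeric(n))
  S_a <- R %*% ind                    # per-gene rank sum inside cluster
  n_k <- colSums(ind)
  tot <- n * (n + 1) / 2              # midranks preserve the rank sum
  genes <- geneSymbols(norm)
  if (is.null(genes) || anyDuplicated(genes)) genes <- rownames(norm)
  out <- lapply(seq_along(ulab), function(j) {
    meanA <- S_a[, j] / n_k[j]
    meanB <- (tot - S_a[, j]) / (n - n_k[j])
    es <- pmin(1, pmax(-1, 2 * (meanA - meanB) / n))
    new("EffectSizeProfile", sample_id = sample_id,
        cluster_id = ulab[j], genes = genes, es = as.numeric(es),
        contrast = "cluster_vs_rest",
        low_confidence = n_k[j] < 3)
  })
  names(out) <- ulab
  out
}

#' Treatment-to-control effect-size ratios
#'
#' Compares the effect-size profile of a linked cell type between the
#' stimulated and the control sample. Genes with |effect size| below
#' `negligible_threshold` in either sample are flagged negligible and
#' carry no ratio; for the rest `ratio = |es_treated| / |es_control|`
#' (with a separate sign-concordance flag), and genes with
#' `ratio > selection_threshold` are selected as candidate
#' stimulation-responsive biomarkers. Rows are sorted by decreasing
#' ratio, negligible genes last.
#'
#' @param profile_treated,profile_control [EffectSizeProfile-class]
#'   objects for the same (linked) cell type; gene lists are intersected.
#' @param cell_type label stored in the result; defaults to the treated
#'   profile's cluster id.
#' @param negligible_threshold default 0.1.
#' @param selection_threshold default 1.5.
#' @return a [RatioTable-class].
#' @export
effectSizeRatios <- function(profile_treated, profile_control,
                             cell_type = profile_treated@cluster_id,
                             negligible_threshold = 0.1,
                             selection_threshold = 1.5) {
  shared <- intersect(profile_treated@genes, profile_control@genes)
  if (length(shared) == 0) stop("profiles share no genes")
  et <- profile_treated@es[match(shared, profile_treated@genes)]
  ec <- profile_control@es[match(shared, profile_control@genes)]
  negligible <- abs(et) < negligible_threshold |
    abs(ec) < negligible_threshold
  ratio <- ifelse(negligible, NA_real_, abs(et) / abs(ec))
  tb <- data.frame(gene = shared, es_treated = et, es_control = ec,
                   ratio = ratio,
                   sign_concordant = sign(et) == sign(ec),
                   negligible = negligible,
                   selected = !negligible & !is.na(ratio) &
                     ratio > selection_threshold)
  tb <- tb[order(-tb$ratio, tb$gene, na.last = TRUE), ]
  rownames(tb) <- NULL
  out <- new("RatioTable", cell_type = cell_type, table = tb,
             negligible_threshold = negligible_threshold,
             selection_threshold = selection_threshold)
  validObject(out)
  out
}

#' Genes responding consistently in both species
#'
#' Maps genes across the two species' ratio tables for a linked cell
#' type and keeps those whose effect-size ratio exceeds `threshold` in
#' both species, sorted by the smaller of the two ratios (decreasing).
#'
#' @param table_a,table_b [RatioTable-class] for species A and B.
#' @param gene_map a [GeneMap-class]; in symbol-intersection mode shared
#'   symbols are matched directly.
#' @param threshold minimum ratio in each species, default 1.
#' @return data.frame with gene_a, gene_b, ratio_a, ratio_b; attribute
#'   `"unmapped"` counts species-A genes without a mapping.
#' @export
crossSpeciesConsensus <- function(table_a, table_b, gene_map = GeneMap(),
                                  threshold = 1.0) {
  ta <- ratioTable(table_a)
  tb <- ratioTable(table_b)
  if (gene_map@mode == "explicit_pairs") {
    if (nrow(gene_map@pairs) == 0) {
      warning("empty gene map; no genes can be compared")
      out <- data.frame(gene_a = character(), gene_b = character(),
                        ratio_a = numeric(), ratio_b = numeric())
      attr(out, "unmapped") <- nrow(ta)
      return(out)
    }
    idx <- match(ta$gene, gene_map@pairs$a)
    mapped_b <- gene_map@pairs$b[idx]
  } else {
    mapped_b <- ifelse(ta$gene %in% tb$gene, ta$gene, NA)
  }
  unmapped <- sum(is.na(mapped_b))
  keep <- !is.na(mapped_b) & mapped_b %in% tb$gene
  ra <- ta$ratio[keep]
  rb <- tb$ratio[match(mapped_b[keep], tb$gene)]
  sel <- !is.na(ra) & !is.na(rb) & ra > threshold & rb > threshold
  out <- data.frame(gene_a = ta$gene[keep][sel],
                    gene_b = mapped_b[keep][sel],
                    ratio_a = ra[sel], ratio_b = rb[sel])
  out <- out[order(-pmin(out$ratio_a, out$ratio_b)), ]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Hypergeometric over-representation of a gene selection
#'
#' One-sided hypergeometric tail `P(X >= overlap)` of each gene set's
#' overlap with the selected genes, against the supplied universe, with
#' Benjamini-Hochberg adjustment across sets. Gene sets are intersected
#' with the universe first.
#'
#' @param selected character vector, a subset of `universe`.
#' @param universe character vector of all considered genes.
#' @param gene_sets named list of character vectors.
#' @return data.frame with set_name, set_size, overlap, universe_size,
#'   hits, p_value, adjusted_p, sorted by p_value.
#' @export
hypergeomEnrichment <- function(selected, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe)
  n_hit <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(set, selected))
    p <- stats::phyper(ov - 1, length(set), N - length(set), n_hit,
                       lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(set), overlap = ov,
               universe_size = N, hits = n_hit, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
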