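#' @describeIn divik cluster a normalised sample: feature statistics are
#'   taken from the log-normalised values, distances from the scaled
#'   values.
#' @export
setMethod("divik", "NormalizedMatrix", function(x, params = divikParams()) {
  divikCore(stat_m = as.matrix(logValues(x)),
            clust_m = as.matrix(scaledValues(x)),
            cells = colnames(x), params = params)
})

#' @describeIn divik cluster a plain matrix (observations in rows,
#'   features in columns); the same matrix serves for feature statistics
#'   and distances.
#' @export
setMethod("divik", "matrix", function(x, params = divikParams()) {
  cells <- rownames(x)
  if (is.null(cells)) cells <- paste0("obs", seq_len(nrow(x)))
  m <- t(x)
  colnames(m) <- cells
  divikCore(stat_m = m, clust_m = m, cells = cells, params = params)
})

# Recursive DivIK: per node, amplitude (root-only by default) then
# variance feature filtration, gap-statistic choice of k, k-means split,
# recursion into children. Stops on chosen_k == 1, min cluster size or
# max depth. Deterministic given params$seed.
divikCore <- function(stat_m, clust_m, cells, params) {
  root_n <- length(cells)
  min_size <- max(params$min_cluster_cells,
                  ceiling(params$min_cluster_fraction * root_n))
  counter <- new.env()
  counter$i <- 0L
  nodeSeed <- function() {
    counter$i <- counter$i + 1L
    as.integer((as.numeric(params$seed) + 104729 * counter$i) %% 2147483647)
  }
  feat_ids <- rownames(stat_m)
  if (is.null(feat_ids)) feat_ids <- paste0("f", seq_len(nrow(stat_m)))

  recurse <- function(cell_idx, depth, path) {
    node <- list(node_id = path, cell_ids = cells[cell_idx],
                 selected_feature_ids = character(), gap = NULL,
                 children = list())
    n <- length(cell_idx)
    if (n < 2 * params$min_cluster_cells || depth >= params$max_depth)
      return(node)
    seed_here <- nodeSeed()
    mask <- rep(TRUE, nrow(stat_m))
    sub_stat <- stat_m[, cell_idx, drop = FALSE]
    if (path == "0" || !params$amplitude_filter_at_root_only) {
      amp <- selectFeatures(sub_stat, "amplitude", seed = seed_here)
      if (any(amp)) mask <- amp
    }
    vmask <- selectFeatures(sub_stat[mask, , drop = FALSE], "variance",
                            seed = seed_here + 1L)
    sel <- which(mask)[vmask]
    if (length(sel) == 0) sel <- which(mask)
    node$selected_feature_ids <- feat_ids[sel]
    X <- t(clust_m[sel, cell_idx, drop = FALSE])
    gap <- gapStatistic(X, params, seed = seed_here + 2L)
    node$gap <- gap
    k <- gap@chosen_k
    if (k < 2) return(node)
    km <- withSeed(seed_here + 3L, fitKmeans(X, k, params))
    if (is.null(km)) return(node)
    sizes <- tabulate(km$cluster, nbins = k)
    if (any(sizes < min_size)) return(node)
    node$children <- lapply(seq_len(k), function(j) {
      recurse(cell_idx[km$cluster == j], depth + 1L,
              paste(path, j, sep = "."))
    })
    node
  }

  root <- recurse(seq_along(cells), 0L, "0")
  leaves <- collectLeaves(root)
  labels <- character(root_n)
  names(labels) <- cells
  for (lf in leaves) labels[lf$cell_ids] <- lf$node_id
  out <- new("ClusterTree", nodes = root, leaf_labels = labels,
             params = unclass(params))
  validObject(out)
  out
}

#' Serialise a ClusterTree to JSON-ready structure
#'
#' @param tree a [ClusterTree-class].
#' @return nested list mirroring the tree (node ids, cell counts,
#'   selected features, gap diagnostics), suitable for
#'   `jsonlite::write_json()`.
#' @export
treeToList <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  strip <- function(node) {
    g <- node$gap
    list(node_id = node$node_id,
         n_cells = length(node$cell_ids),
         selected_features = node$selected_feature_ids,
         gap = if (is.null(g)) NULL else
           list(k = g@k, logW = g@logW, ElogW = g@ElogW, gap = g@gap,
                s_k = g@s_k, chosen_k = g@chosen_k),
         children = lapply(node$children, strip))
  }
  strip(tree@nodes)
}
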