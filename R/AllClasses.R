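#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData rowData<- colData colData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Raw count matrix for one single-cell sample
#'
#' `CountMatrix` extends \linkS4class{SingleCellExperiment}: genes are rows,
#' cells (barcodes) are columns, and the single assay `"counts"` holds
#' non-negative integer counts. Row metadata carries gene symbols and a
#' mitochondrial-gene mask; object metadata carries the sample annotation
#' (sample id, species, condition) that downstream stages rely on.
#'
#' @slot int_elementMetadata,int_colData,... inherited from
#'   SingleCellExperiment.
#'
#' @seealso [CountMatrix()] the constructor, [read10x()], [filterCells()]
#' @export
setClass("CountMatrix", contains = "SingleCellExperiment")

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    mn <- suppressWarnings(min(cts))
    if (is.finite(mn) && mn < 0) msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (ncol(object) > 0 &&
      (is.null(colnames(object)) || anyDuplicated(colnames(object))))
    msg <- c(msg, "barcodes (colnames) must be present and unique")
  if (!"symbol" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'symbol' is required")
  if (!"mito" %in% colnames(rowData(object)) ||
      !is.logical(rowData(object)$mito))
    msg <- c(msg, "rowData column 'mito' (logical mask) is required")
  sm <- metadata(object)$sample_meta
  if (is.null(sm) || !all(c("sample_id", "species", "condition") %in% names(sm)))
    msg <- c(msg, "metadata sample_meta with sample_id, species, condition is required")
  else if (!sm$condition %in% c("control", "stimulated"))
    msg <- c(msg, "sample_meta$condition must be 'control' or 'stimulated'")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts non-negative integer matrix (base or `Matrix` sparse),
#'   genes in rows and cells in columns.
#' @param gene_ids unique gene identifiers (length `nrow(counts)`).
#' @param gene_symbols gene symbols, may repeat; defaults to `gene_ids`.
#' @param barcodes unique cell barcodes (length `ncol(counts)`).
#' @param sample_id,species sample annotation strings.
#' @param condition `"control"` or `"stimulated"`.
#' @param mito_mask logical mitochondrial mask per gene; if `NULL` it is
#'   derived from `gene_symbols` and `mito_prefix`.
#' @param mito_prefix character vector of symbol prefixes flagged as
#'   mitochondrial (case-insensitive), default `"MT-"`.
#'
#' @return a validated [CountMatrix-class] object.
#' @examples
#' m <- CountMatrix(matrix(0:5, 3, 2), gene_ids = c("g1", "g2", "g3"),
#'                  barcodes = c("AA", "AC"), sample_id = "s1",
#'                  species = "human", condition = "control")
#' @export
CountMatrix <- function(counts, gene_ids, gene_symbols = gene_ids, barcodes,
                        sample_id, species, condition = "control",
                        mito_mask = NULL, mito_prefix = "MT-") {
  # route via generalMatrix: a direct coercion of a symmetric-looking
  # matrix yields a dsCMatrix, which cannot carry asymmetric dimnames
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(mito_mask))
    mito_mask <- isMitoSymbol(gene_symbols, mito_prefix)
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(symbol = gene_symbols, mito = mito_mask,
                        row.names = gene_ids)
  )
  metadata(sce)$sample_meta <- list(sample_id = sample_id, species = species,
                                    condition = condition)
  out <- new("CountMatrix", sce)
  validObject(out)
  out
}

isMitoSymbol <- function(symbols, prefixes = "MT-") {
  hit <- rep(FALSE, length(symbols))
  for (p in prefixes)
    hit <- hit | startsWith(toupper(symbols), toupper(p))
  hit
}

#' Log-normalised expression matrix
#'
#' `NormalizedMatrix` extends \linkS4class{SingleCellExperiment} with two
#' assays: `"logcounts"` (`ln(1 + scale_factor * count / cell_total)`) and
#' `"scaled"` (gene-wise z-scores of the logcounts; genes of zero variance
#' become all-zero rows). Metadata records the QC parameters and per-stage
#' cell/gene counts (provenance).
#'
#' @seealso [logNormalize()], [clusterProfiles()], [divik()]
#' @export
setClass("NormalizedMatrix", contains = "SingleCellExperiment")

setValidity("NormalizedMatrix", function(object) {
  msg <- character()
  if (!all(c("logcounts", "scaled") %in% assayNames(object)))
    msg <- c(msg, "assays 'logcounts' and 'scaled' are required")
  else if (ncol(object) > 0 && min(assay(object, "logcounts")) < 0)
    msg <- c(msg, "logcounts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Gap-statistic model selection result
#'
#' Per candidate k: the log within-cluster dispersion of the data, its
#' expectation under uniform reference draws over the feature-wise bounding
#' box, gap(k) = E*[log W_k] - log W_k, and the B-adjusted reference
#' standard error s_k. `chosen_k` follows the one-standard-error rule:
#' the smallest k with `gap(k) >= gap(k+1) - s_(k+1)`.
#'
#' @slot k integer vector of candidate cluster counts.
#' @slot logW,ElogW,gap,s_k numeric vectors aligned with `k`.
#' @slot chosen_k the selected number of clusters.
#' @export
setClass("GapResult", representation(
  k = "integer", logW = "numeric", ElogW = "numeric",
  gap = "numeric", s_k = "numeric", chosen_k = "integer"
))

setValidity("GapResult", function(object) {
  msg <- character()
  n <- length(object@k)
  if (any(c(length(object@logW), length(object@ElogW),
            length(object@gap), length(object@s_k)) != n))
    msg <- c(msg, "per-k vectors must share length with k")
  if (max(abs(object@gap - (object@ElogW - object@logW))) > 1e-12)
    msg <- c(msg, "gap must equal ElogW - logW")
  if (any(object@s_k < 0)) msg <- c(msg, "s_k must be non-negative")
  if (!(object@chosen_k %in% c(object@k, 1L)))
    msg <- c(msg, "chosen_k must be 1 or a candidate k")
  if (length(msg)) msg else TRUE
})

#' Divisive clustering tree
#'
#' Result of [divik()]: a recursive node list (each node holds its cell
#' barcodes, the feature subset it was split on, its [GapResult-class] and
#' child nodes) plus path-encoded per-cell leaf labels (root `"0"`, its
#' children `"0.1"`, `"0.2"`, ...). Leaf cell sets partition the input
#' cells.
#'
#' @slot nodes recursive `list` of nodes.
#' @slot leaf_labels named character vector, one label per cell.
#' @slot params the `DivikParams` list used.
#' @seealso [divik()], [leafLabels()]
#' @export
setClass("ClusterTree", representation(
  nodes = "list", leaf_labels = "character", params = "list"
))

setValidity("ClusterTree", function(object) {
  msg <- character()
  if (is.null(names(object@leaf_labels)))
    msg <- c(msg, "leaf_labels must be named by cell barcode")
  leaves <- collectLeaves(object@nodes)
  cells <- unlist(lapply(leaves, `[[`, "cell_ids"), use.names = FALSE)
  if (anyDuplicated(cells) || !setequal(cells, names(object@leaf_labels)))
    msg <- c(msg, "leaf cell sets must partition the clustered cells")
  if (length(msg)) msg else TRUE
})

collectLeaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  do.call(c, lapply(node$children, collectLeaves))
}

#' Effect-size profile of one cluster
#'
#' The vector of Glass rank biserial coefficients (one per gene, in
#' [-1, 1]) for one cluster of one sample, contrasting the cluster's cells
#' against all other cells of the same sample on log-normalised values.
#'
#' @slot sample_id,cluster_id identifiers.
#' @slot genes ordered unique gene symbols.
#' @slot es numeric effect sizes aligned with `genes`.
#' @slot contrast the contrast used (`"cluster_vs_rest"`).
#' @slot low_confidence `TRUE` when the cluster has fewer than 3 cells.
#' @seealso [clusterProfiles()], [linkProfiles()]
#' @export
setClass("EffectSizeProfile", representation(
  sample_id = "character", cluster_id = "character",
  genes = "character", es = "numeric", contrast = "character",
  low_confidence = "logical"
))

setValidity("EffectSizeProfile", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@es))
    msg <- c(msg, "genes and es must have equal length")
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (length(object@es) && max(abs(object@es)) > 1 + 1e-9)
    msg <- c(msg, "effect sizes must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-sample cluster linkage result
#'
#' Spearman correlations between query and reference effect-size profiles
#' over the shared (mapped) gene list, plus per-query assignments: the
#' reference with the highest positive correlation, `NA` (unassigned) when
#' no correlation is positive, and a tie flag when the maximum is not
#' unique.
#'
#' @slot corr query x reference correlation matrix.
#' @slot assignment data.frame with columns query, reference, correlation,
#'   tied.
#' @slot n_shared_genes number of genes the correlations were computed on.
#' @seealso [linkProfiles()]
#' @export
setClass("LinkageResult", representation(
  corr = "matrix", assignment = "data.frame", n_shared_genes = "integer"
))

setValidity("LinkageResult", function(object) {
  msg <- character()
  if (length(object@corr) && max(abs(object@corr), na.rm = TRUE) > 1 + 1e-9)
    msg <- c(msg, "correlations must lie in [-1, 1]")
  need <- c("query", "reference", "correlation", "tied")
  if (!all(need %in% colnames(object@assignment)))
    msg <- c(msg, "assignment must have columns query, reference, correlation, tied")
  if (length(msg)) msg else TRUE
})

#' Treatment/control effect-size ratio table
#'
#' Per-gene comparison of a cluster's effect size in the stimulated sample
#' versus its matched control: genes with |es| below the negligible
#' threshold in either sample are flagged and excluded from the ratio;
#' for the rest, `ratio = |es_treated| / |es_control|`, sorted decreasing,
#' with `selected = ratio > selection_threshold` marking candidate
#' stimulation-responsive genes.
#'
#' @slot cell_type linked cell-type name.
#' @slot table data.frame with columns gene, es_treated, es_control,
#'   ratio, sign_concordant, negligible, selected.
#' @slot negligible_threshold,selection_threshold the thresholds applied.
#' @seealso [effectSizeRatios()], [crossSpeciesConsensus()]
#' @export
setClass("RatioTable", representation(
  cell_type = "character", table = "data.frame",
  negligible_threshold = "numeric", selection_threshold = "numeric"
))

setValidity("RatioTable", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("gene", "es_treated", "es_control", "ratio", "sign_concordant",
            "negligible", "selected")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  thr <- object@negligible_threshold
  bad <- tb$negligible != (abs(tb$es_treated) < thr | abs(tb$es_control) < thr)
  if (any(bad)) msg <- c(msg, "negligible flag inconsistent with thresholds")
  if (any(!is.na(tb$ratio) & tb$negligible))
    msg <- c(msg, "ratio must be undefined for negligible genes")
  if (any(tb$selected & (tb$negligible | is.na(tb$ratio) |
                         tb$ratio <= object@selection_threshold)))
    msg <- c(msg, "selected genes must be non-negligible with ratio above threshold")
  if (length(msg)) msg else TRUE
})

#' Weighted Dice-Sorensen comparison of two clusterings
#'
#' Clusters of labelling A are matched one-to-one to clusters of
#' labelling B (maximising total intersection); each matched pair scores
#' `dice = 2|A∩B| / (|A| + |B|)` and the weighted index is the
#' cluster-size-weighted mean of the dice scores over A's clusters
#' (unmatched clusters score 0). Equals 1 exactly when the two labellings
#' induce the same partition.
#'
#' @slot pairs data.frame with cluster_a, cluster_b, intersection, size_a,
#'   size_b, dice.
#' @slot weighted_dsi the index in [0, 1].
#' @seealso [weightedDice()]
#' @export
setClass("DsiResult", representation(
  pairs = "data.frame", weighted_dsi = "numeric"
))

setValidity("DsiResult", function(object) {
  msg <- character()
  p <- object@pairs
  if (nrow(p)) {
    d <- 2 * p$intersection / (p$size_a + p$size_b)
    d[p$size_a + p$size_b == 0] <- 0
    if (max(abs(d - p$dice)) > 1e-12)
      msg <- c(msg, "dice must equal 2*intersection/(size_a+size_b)")
  }
  if (object@weighted_dsi < -1e-12 || object@weighted_dsi > 1 + 1e-12)
    msg <- c(msg, "weighted_dsi must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-species gene symbol map
#'
#' Either an explicit one-to-one list of (species A symbol, species B
#' symbol) pairs, or the declaration that shared symbols should be
#' intersected directly.
#'
#' @slot pairs data.frame with columns a, b (empty in intersection mode).
#' @slot mode `"explicit_pairs"` or `"symbol_intersection"`.
#' @seealso [readGeneMap()], [linkProfiles()]
#' @export
setClass("GeneMap", representation(pairs = "data.frame", mode = "character"))

setValidity("GeneMap", function(object) {
  msg <- character()
  if (!object@mode %in% c("explicit_pairs", "symbol_intersection"))
    msg <- c(msg, "mode must be explicit_pairs or symbol_intersection")
  if (object@mode == "explicit_pairs" && nrow(object@pairs)) {
    if (anyDuplicated(object@pairs$a) || anyDuplicated(object@pairs$b))
      msg <- c(msg, "explicit pairs must be one-to-one")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneMap-class construct a gene map; with no pairs the map
#'   falls back to symbol intersection.
#' @param pairs two-column data.frame (species A symbol, species B symbol)
#'   or `NULL`.
#' @export
GeneMap <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(new("GeneMap", pairs = data.frame(a = character(), b = character()),
               mode = "symbol_intersection"))
  }
  pairs <- unique(data.frame(a = as.character(pairs[[1]]),
                             b = as.character(pairs[[2]])))
  obj <- new("GeneMap", pairs = pairs, mode = "explicit_pairs")
  validObject(obj)
  obj
}
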