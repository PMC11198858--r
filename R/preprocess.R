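#' Quality-control parameters
#'
#' Thresholds applied per sample before normalisation. Cells are retained
#' when their detected-feature count is strictly greater than
#' `min_features` and their mitochondrial-count percentage strictly below
#' `max_mito_percent`; boundary cells (exactly 200 features, exactly 10%
#' mito) are removed, reading the thresholds as strict inequalities.
#'
#' @param min_features minimum detected features per cell (exclusive),
#'   default 200.
#' @param max_mito_percent maximum mitochondrial percentage (exclusive),
#'   default 10.
#' @param scale_factor library-size scale factor for log-normalisation,
#'   default 10000.
#' @return a list of class `QCParams`.
#' @export
qcParams <- function(min_features = 200, max_mito_percent = 10,
                     scale_factor = 10000) {
  stopifnot(min_features >= 0, max_mito_percent >= 0,
            max_mito_percent <= 100, scale_factor > 0)
  structure(list(min_features = min_features,
                 max_mito_percent = max_mito_percent,
                 scale_factor = scale_factor),
            class = "QCParams")
}

#' Discard genes with no detected counts
#'
#' Retains exactly the genes with at least one nonzero count, preserving
#' order. Provenance records genes before/after.
#'
#' @param x a [CountMatrix-class].
#' @return the filtered [CountMatrix-class].
#' @export
filterGenes <- function(x) {
  stopifnot(is(x, "CountMatrix"))
  keep <- Matrix::rowSums(assay(x, "counts") > 0) > 0
  out <- x[keep, ]
  pv <- metadata(out)$provenance
  pv$gene_filter <- list(genes_in = nrow(x), genes_out = sum(keep),
                         genes_removed = sum(!keep))
  metadata(out)$provenance <- pv
  out
}

#' Filter cells on detected features and mitochondrial percentage
#'
#' A cell is kept when its number of detected (nonzero) genes exceeds
#' `params$min_features` and `100 * mito_counts / total_counts` is below
#' `params$max_mito_percent`. An empty cell (zero total) has its mito
#' percentage defined as 0 and is removed by the feature criterion.
#' Per-criterion removal counts are recorded in provenance.
#'
#' @param x a [CountMatrix-class] with the mitochondrial mask set.
#' @param params [qcParams()].
#' @return the filtered [CountMatrix-class].
#' @export
filterCells <- function(x, params = qcParams()) {
  stopifnot(is(x, "CountMatrix"))
  cts <- assay(x, "counts")
  nfeat <- Matrix::colSums(cts > 0)
  total <- Matrix::colSums(cts)
  mito <- if (any(mitoGenes(x))) {
    Matrix::colSums(cts[mitoGenes(x), , drop = FALSE])
  } else rep(0, ncol(x))
  mito_pct <- ifelse(total > 0, 100 * mito / total, 0)
  pass_feat <- nfeat > params$min_features
  pass_mito <- mito_pct < params$max_mito_percent
  keep <- pass_feat & pass_mito
  out <- x[, keep]
  pv <- metadata(out)$provenance
  pv$cell_filter <- list(
    cells_in = ncol(x), cells_out = sum(keep),
    removed_low_features = sum(!pass_feat),
    removed_high_mito = sum(!pass_mito),
    removed_total = sum(!keep),
    qc_params = unclass(params))
  metadata(out)$provenance <- pv
  out
}

#' Log-normalise and scale a filtered count matrix
#'
#' Per cell, counts are divided by the cell total, multiplied by the scale
#' factor and transformed as `ln(1 + .)` (assay `"logcounts"`); the
#' logcounts are then gene-wise centred and standardised (assay
#' `"scaled"`; zero-variance genes become all-zero rows, and z-scores are
#' not clipped).
#'
#' @param x a [CountMatrix-class]; every cell must have a positive total
#'   count (run [filterCells()] first).
#' @param params [qcParams()] (only `scale_factor` is used).
#' @return a [NormalizedMatrix-class] carrying the sample annotation and
#'   accumulated provenance of `x`.
#' @export
logNormalize <- function(x, params = qcParams()) {
  stopifnot(is(x, "CountMatrix"))
  cts <- as.matrix(assay(x, "counts"))
  total <- colSums(cts)
  if (any(total == 0))
    stop("cells with zero total counts present; run filterCells() first")
  vals <- log1p(sweep(cts, 2, params$scale_factor / total, `*`))
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  scaled <- (vals - mu) / ifelse(sdv > 0, sdv, 1)
  scaled[sdv == 0, ] <- 0
  sce <- SingleCellExperiment(
    assays = list(logcounts = vals, scaled = scaled),
    rowData = rowData(x))
  out <- new("NormalizedMatrix", sce)
  pv <- metadata(x)$provenance
  pv$qc_params <- unclass(params)
  metadata(out)$provenance <- pv
  metadata(out)$sample_meta <- sampleMeta(x)
  validObject(out)
  out
}

#' Per-sample QC report
#'
#' Collects the provenance of one or more filtered/normalised samples into
#' a data.frame (one row per sample: genes and cells before/after each
#' stage and per-criterion removals).
#'
#' @param samples named list of objects carrying provenance.
#' @return data.frame, one row per sample.
#' @export
qcReport <- function(samples) {
  rows <- lapply(names(samples), function(nm) {
    pv <- provenance(samples[[nm]])
    sm <- sampleMeta(samples[[nm]])
    data.frame(
      sample_id = if (!is.null(sm)) sm$sample_id else nm,
      genes_in = pv$gene_filter$genes_in %||% NA,
      genes_kept = pv$gene_filter$genes_out %||% NA,
      cells_in = pv$cell_filter$cells_in %||% NA,
      cells_kept = pv$cell_filter$cells_out %||% NA,
      removed_low_features = pv$cell_filter$removed_low_features %||% NA,
      removed_high_mito = pv$cell_filter$removed_high_mito %||% NA)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
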