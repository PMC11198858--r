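#' Accessors for esProfiler classes
#'
#' Small accessor layer so downstream code never touches slots directly:
#' `sampleMeta()` returns the sample annotation list (sample_id, species,
#' condition); `geneSymbols()` / `mitoGenes()` the per-gene metadata;
#' `logValues()` / `scaledValues()` the two assays of a
#' [NormalizedMatrix-class]; `provenance()` the QC bookkeeping;
#' `esMatrix()` stacks a list of [EffectSizeProfile-class] objects into a
#' genes x clusters matrix; `assignments()` and `ratioTable()` expose the
#' result tables of [linkProfiles()] and [effectSizeRatios()].
#'
#' @param x an esProfiler object.
#' @param ... for `esMatrix`, unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleMeta", "SingleCellExperiment",
          function(x) metadata(x)$sample_meta)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "SingleCellExperiment",
          function(x) rowData(x)$symbol)

#' @rdname accessors
#' @export
setMethod("mitoGenes", "SingleCellExperiment",
          function(x) rowData(x)$mito)

#' @rdname accessors
#' @export
setMethod("provenance", "SingleCellExperiment",
          function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setMethod("logValues", "NormalizedMatrix",
          function(x) assay(x, "logcounts"))

#' @rdname accessors
#' @export
setMethod("scaledValues", "NormalizedMatrix",
          function(x) assay(x, "scaled"))

#' Per-cell leaf labels of a clustering tree
#'
#' @param x a [ClusterTree-class].
#' @return named character vector (names are cell barcodes), labels
#'   path-encoded as in `"0.2.1"`.
#' @rdname leafLabels
#' @export
setMethod("leafLabels", "ClusterTree", function(x) x@leaf_labels)

#' @rdname accessors
#' @export
setMethod("assignments", "LinkageResult", function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("ratioTable", "RatioTable", function(x) x@table)

#' Stack effect-size profiles into a genes x clusters matrix
#'
#' @param profiles list of [EffectSizeProfile-class] sharing a gene list.
#' @return numeric matrix, genes in rows, one column per cluster.
#' @export
esMatrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  genes <- profiles[[1]]@genes
  for (p in profiles)
    if (!identical(p@genes, genes))
      stop("profiles must share an identical gene list")
  m <- vapply(profiles, function(p) p@es, numeric(length(genes)))
  rownames(m) <- genes
  colnames(m) <- vapply(profiles, function(p) p@cluster_id, character(1))
  m
}

setMethod("show", "CountMatrix", function(object) {
  sm <- sampleMeta(object)
  cat("CountMatrix:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  sample:", sm$sample_id, "|", sm$species, "|", sm$condition, "\n")
  cat("  mitochondrial genes:", sum(mitoGenes(object)), "\n")
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix:", nrow(object), "genes x", ncol(object), "cells",
      "(assays: logcounts, scaled)\n")
  pv <- provenance(object)
  if (!is.null(pv$qc_params))
    cat("  scale factor:", pv$qc_params$scale_factor, "\n")
})

setMethod("show", "ClusterTree", function(object) {
  lv <- unique(object@leaf_labels)
  cat("ClusterTree:", length(object@leaf_labels), "cells in", length(lv),
      "leaves\n")
  tab <- table(object@leaf_labels)
  for (l in names(tab)) cat("  ", l, ": ", tab[[l]], " cells\n", sep = "")
})

setMethod("show", "GapResult", function(object) {
  cat("GapResult: chosen k =", object@chosen_k, "\n")
  print(data.frame(k = object@k, logW = object@logW, ElogW = object@ElogW,
                   gap = object@gap, s_k = object@s_k))
})

setMethod("show", "EffectSizeProfile", function(object) {
  cat("EffectSizeProfile:", object@sample_id, "/", object@cluster_id,
      "-", length(object@genes), "genes",
      if (object@low_confidence) "(low confidence)" else "", "\n")
})

setMethod("show", "LinkageResult", function(object) {
  cat("LinkageResult:", nrow(object@corr), "query x", ncol(object@corr),
      "reference clusters over", object@n_shared_genes, "shared genes\n")
  print(object@assignment)
})

setMethod("show", "RatioTable", function(object) {
  tb <- object@table
  cat("RatioTable for", object@cell_type, "-", nrow(tb), "genes,",
      sum(tb$negligible), "negligible,", sum(tb$selected), "selected",
      sprintf("(ratio > %g)\n", object@selection_threshold))
})

setMethod("show", "DsiResult", function(object) {
  cat("DsiResult: weighted DSI =", round(object@weighted_dsi, 4), "over",
      nrow(object@pairs), "matched cluster pairs\n")
})

setMethod("show", "GeneMap", function(object) {
  cat("GeneMap (", object@mode, "): ", nrow(object@pairs), " pairs\n",
      sep = "")
})
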