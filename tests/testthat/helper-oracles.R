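# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths they verify.

assay <- SummarizedExperiment::assay

# Mann-Whitney U of group a by exhaustive pair counting (ties get 1/2)
bruteU <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp)
}

# Pearson correlation of midranks, written out from the definition
pearsonOfMidranks <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exhaustive hypergeometric tail: enumerate every draw of size n_draw
# from the universe and count overlaps >= observed
enumHyperTail <- function(universe, set, n_draw, observed) {
  draws <- utils::combn(length(universe), n_draw)
  set_idx <- which(universe %in% set)
  ov <- apply(draws, 2, function(d) sum(d %in% set_idx))
  mean(ov >= observed)
}

# tiny CountMatrix builder for IO/QC tests
tinyCountMatrix <- function(counts, symbols = NULL, sample_id = "s1",
                            species = "human", condition = "control") {
  ng <- nrow(counts)
  nc <- ncol(counts)
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(ng))
  CountMatrix(counts, gene_ids = sprintf("ENS%03d", seq_len(ng)),
              gene_symbols = symbols,
              barcodes = sprintf("BC%03d", seq_len(nc)),
              sample_id = sample_id, species = species,
              condition = condition)
}

# NormalizedMatrix straight from a dense value matrix (bypasses QC), for
# profile tests that need exact control over the values
normFromValues <- function(vals, sample_id = "s1") {
  rownames(vals) <- rownames(vals) %||% sprintf("G%03d", seq_len(nrow(vals)))
  colnames(vals) <- colnames(vals) %||% sprintf("BC%03d", seq_len(ncol(vals)))
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  scaled <- (vals - mu) / ifelse(sdv > 0, sdv, 1)
  scaled[sdv == 0, ] <- 0
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = vals, scaled = scaled),
    rowData = S4Vectors::DataFrame(symbol = rownames(vals),
                                   mito = rep(FALSE, nrow(vals)),
                                   row.names = rownames(vals)))
  out <- new("NormalizedMatrix", sce)
  S4Vectors::metadata(out)$sample_meta <-
    list(sample_id = sample_id, species = "human", condition = "control")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effect-size profiles of a sample using ground-truth labels
truthProfiles <- function(sim, sid, qc = qcParams()) {
  cm <- filterCells(filterGenes(sim$samples[[sid]]), qc)
  nm <- logNormalize(cm, qc)
  clusterProfiles(nm, sim$truth$cell_types[[sid]][colnames(nm)])
}
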