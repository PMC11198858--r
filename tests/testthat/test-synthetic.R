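# trimmed generator settings for unit tests; the acceptance suite runs
# the full defaults
smallSim <- function(seed, ...) {
  simulateTwoSpecies(simParams(n_genes = 500, n_cells = 250,
                               n_marker_genes = 20, n_response_genes = 20,
                               seed = seed, ...))
}

test_that("the generator is bitwise deterministic given the seed", {
  s1 <- smallSim(9)
  s2 <- smallSim(9)
  for (sid in names(s1$samples)) {
    expect_identical(as.matrix(assay(s1$samples[[sid]], "counts")),
                     as.matrix(assay(s2$samples[[sid]], "counts")))
  }
  expect_identical(s1$truth$response_genes, s2$truth$response_genes)
  s3 <- smallSim(10)
  expect_false(identical(as.matrix(assay(s1$samples[[1]], "counts")),
                         as.matrix(assay(s3$samples[[1]], "counts"))))
})

test_that("ground truth is consistent with the emitted matrices", {
  sim <- smallSim(11)
  expect_length(sim$samples, 4)
  for (sid in names(sim$samples)) {
    cm <- sim$samples[[sid]]
    tt <- sim$truth$cell_types[[sid]]
    expect_setequal(names(tt), colnames(cm))
    expect_true(all(table(tt) >= 1))            # every cell type present
    sm <- sampleMeta(cm)
    expect_identical(sid, paste(sm$species, sm$condition, sep = "_"))
  }
  # response genes are shared symbols present in both species
  for (sid in names(sim$samples))
    expect_true(all(sim$truth$response_genes %in% rownames(sim$samples[[sid]])))
  expect_true(all(sim$truth$response_genes %in% sim$gene_map@pairs$a))
  # markers and response genes are disjoint
  mk <- names(sim$truth$marker_of)[!is.na(sim$truth$marker_of)]
  expect_length(intersect(mk, sim$truth$response_genes), 0)
})

test_that("empirical gene means track the negative-binomial model", {
  sim <- simulateTwoSpecies(simParams(seed = 12))
  cm <- sim$samples$speciesA_control
  emp <- Matrix::rowMeans(assay(cm, "counts"))
  exp_mean <- sim$truth$expected_means$speciesA_control
  g <- names(exp_mean)[exp_mean >= 1]
  rel <- abs(emp[g] - exp_mean[g]) / exp_mean[g]
  # per-gene sampling error at n = 1500 puts a small tail beyond 10%;
  # the bulk must sit well inside it
  expect_gte(mean(rel <= 0.10), 0.95)
  expect_lt(stats::median(rel), 0.05)
  expect_lt(max(rel), 0.25)
})

test_that("invalid generator parameters are rejected", {
  expect_error(simParams(cell_types = data.frame(
    name = c("a", "b"), fraction = c(0.6, 0.6))), "sum to 1")
  expect_error(simParams(responsive_cell_type = "Missing"),
               "responsive_cell_type")
  expect_error(simulateGaussianClusters(100, 2, -1), "positive")
})

test_that("gaussian cluster fixture: determinism and separability", {
  g1 <- simulateGaussianClusters(300, 3, 8, seed = 13)
  g2 <- simulateGaussianClusters(300, 3, 8, seed = 13)
  expect_identical(g1$matrix, g2$matrix)
  expect_identical(g1$labels, g2$labels)
  # single cluster -> constant labels
  expect_length(unique(simulateGaussianClusters(50, 1, 8, seed = 1)$labels), 1)
  # nearest-centroid on informative features classifies near-perfectly
  inf <- g1$matrix[, startsWith(colnames(g1$matrix), "inf")]
  cents <- rowsum(inf, g1$labels) / as.vector(table(g1$labels))
  d2 <- as.matrix(dist(rbind(cents, inf)))[-(1:3), 1:3]
  pred <- max.col(-d2)
  expect_gte(mean(pred == g1$labels), 0.99)
})

test_that("planted QC violators are below / above the thresholds", {
  sim <- smallSim(14)
  for (sid in names(sim$samples)[1:2]) {
    cm <- sim$samples[[sid]]
    cts <- assay(cm, "counts")
    qv <- sim$truth$qc_violators[[sid]]
    nf <- Matrix::colSums(cts[, qv$low_features, drop = FALSE] > 0)
    expect_true(all(nf <= 200))
    mito <- Matrix::colSums(cts[mitoGenes(cm), qv$high_mito, drop = FALSE])
    tot <- Matrix::colSums(cts[, qv$high_mito, drop = FALSE])
    expect_true(all(100 * mito / tot > 10))
  }
})
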