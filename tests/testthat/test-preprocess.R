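test_that("gene filter retains exactly the detected genes, in order", {
  cts <- matrix(c(1, 0, 2,
                  0, 0, 0,
                  0, 3, 0,
                  1, 1, 1,
                  0, 0, 5), 5, 3, byrow = TRUE)
  m <- tinyCountMatrix(cts)
  f <- filterGenes(m)
  expect_identical(rownames(f), rownames(m)[c(1, 3, 4, 5)])
  expect_equal(provenance(f)$gene_filter$genes_removed, 1)
  # no zero rows -> identity; all-zero -> empty but valid
  expect_identical(rownames(filterGenes(f)), rownames(f))
  all0 <- filterGenes(tinyCountMatrix(matrix(0, 3, 2)))
  expect_equal(nrow(all0), 0)
  expect_true(validObject(all0))
})

test_that("cell filter applies strict feature and mito thresholds", {
  # 300 genes so feature counts can straddle the 200 threshold; gene 1
  # is mitochondrial
  ng <- 301
  mkcell <- function(nfeat, mito_frac) {
    v <- numeric(ng)
    v[1 + seq_len(nfeat - 1)] <- 1          # nfeat-1 nuclear features
    tot_nuc <- nfeat - 1
    v[1] <- round(mito_frac / (1 - mito_frac) * tot_nuc)
    v
  }
  cts <- cbind(
    mkcell(150, 0.01),   # too few features -> removed
    mkcell(300, 0.12),   # 12% mito -> removed
    mkcell(202, 0.05),   # retained
    mkcell(201, 0.0),    # 200 nuclear features + 0 mito = 200 -> removed
    rep(0, ng))          # empty cell -> removed, no div-by-zero
  m <- tinyCountMatrix(cts, symbols = c("MT-1", sprintf("G%03d", 2:ng)))
  f <- filterCells(m, qcParams(min_features = 200, max_mito_percent = 10))
  expect_identical(colnames(f), colnames(m)[3])
  pv <- provenance(f)$cell_filter
  expect_equal(pv$cells_in - pv$cells_out, pv$removed_total)
  expect_equal(pv$removed_low_features, 3)
  expect_equal(pv$removed_high_mito, 1)
})

test_that("boundary cells at exactly 10% mito are removed (strict <)", {
  # 250 detected nuclear genes, mito counts tuned to exactly 10%
  v <- c(30, rep(1, 270))                   # total 300, mito 30 = 10.0%
  m <- tinyCountMatrix(cbind(v, v + c(0, rep(0, 269), 0)),
                       symbols = c("MT-1", sprintf("G%03d", 2:271)))
  f <- filterCells(m, qcParams(min_features = 200, max_mito_percent = 10))
  expect_equal(ncol(f), 0)
})

test_that("cell filtering is idempotent", {
  set.seed(1)
  cts <- matrix(rpois(400 * 30, 1.5), 400, 30)
  m <- tinyCountMatrix(cts, symbols = c(sprintf("MT-%d", 1:5),
                                        sprintf("G%03d", 6:400)))
  p <- qcParams(min_features = 100, max_mito_percent = 10)
  f1 <- filterCells(m, p)
  f2 <- filterCells(f1, p)
  expect_identical(colnames(f2), colnames(f1))
})

test_that("log-normalisation follows ln(1 + sf * count / total)", {
  cts <- matrix(c(1, 1,
                  3, 0), 2, 2, byrow = TRUE)  # cell totals 4, 1
  m <- tinyCountMatrix(cts)
  nm <- logNormalize(m, qcParams(scale_factor = 10000))
  expect_equal(logValues(nm)[1, 1], log(1 + 2500), tolerance = 1e-12)
  expect_equal(log(1 + 2500), 7.8245, tolerance = 1e-4)
  expect_equal(logValues(nm)[2, 2], 0)  # zero count -> ln(1) = 0
})

test_that("scaled assay is gene-wise centred and standardised", {
  set.seed(3)
  m <- tinyCountMatrix(matrix(rpois(50 * 20, 2) + 1, 50, 20))
  nm <- logNormalize(m)
  sc <- scaledValues(nm)
  expect_true(all(abs(rowMeans(sc)) < 1e-8))
  sds <- apply(sc, 1, sd)
  vr <- apply(logValues(nm), 1, sd) > 0
  expect_true(all(abs(sds[vr] - 1) < 1e-6))
  # constant gene -> all-zero scaled row
  cts <- matrix(c(2, 2, 2, 1, 5, 9), 2, 3, byrow = TRUE)
  cts2 <- rbind(cts, colSums(cts) * 2)  # gene proportional to totals
  m2 <- tinyCountMatrix(matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE))
  nm2 <- logNormalize(m2)
  expect_false(any(abs(scaledValues(nm2)) > 10))  # no clipping artefacts
})

test_that("normalisation is invariant to duplicating a cell's counts", {
  set.seed(5)
  cts <- matrix(rpois(30 * 8, 3) + 1, 30, 8)
  cts2 <- cbind(cts, 2 * cts[, 3])
  m <- tinyCountMatrix(cts2)
  nm <- logNormalize(m)
  expect_equal(logValues(nm)[, 9], logValues(nm)[, 3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-total cells make logNormalize fail with guidance", {
  m <- tinyCountMatrix(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(logNormalize(m), "filterCells")
})
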