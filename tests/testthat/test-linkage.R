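mkProfile <- function(id, es, genes = sprintf("g%03d", seq_along(es))) {
  new("EffectSizeProfile", sample_id = "s", cluster_id = id,
      genes = genes, es = es, contrast = "cluster_vs_rest",
      low_confidence = FALSE)
}

test_that("identical profiles link as the identity with correlation 1", {
  set.seed(201)
  ref <- lapply(c("T", "B", "Mono"), function(id)
    mkProfile(id, runif(80, -0.5, 0.5)))
  lr <- linkProfiles(ref, ref, min_shared_genes = 50)
  a <- assignments(lr)
  expect_identical(a$reference, a$query)
  expect_equal(diag(lr@corr), rep(1, 3), ignore_attr = TRUE)
})

test_that("rank-reversed queries stay unassigned", {
  set.seed(202)
  es <- sort(runif(60, -0.8, 0.8))
  ref <- list(mkProfile("r1", es), mkProfile("r2", es * 0.5))
  qry <- list(mkProfile("q1", rev(es)))
  lr <- linkProfiles(qry, ref, min_shared_genes = 50)
  a <- assignments(lr)
  expect_true(is.na(a$reference))
  expect_true(all(lr@corr < 0))
})

test_that("correlations equal brute-force Pearson of midranks", {
  set.seed(203)
  for (i in 1:100) {
    x <- sample(round(runif(60, -1, 1), 2))  # ties via rounding
    y <- round(runif(60, -1, 1), 2)
    lr <- linkProfiles(list(mkProfile("q", x)), list(mkProfile("r", y)),
                       min_shared_genes = 50)
    expect_lt(abs(lr@corr[1, 1] - pearsonOfMidranks(x, y)), 1e-12)
  }
})

test_that("linkage is invariant under common gene reordering", {
  set.seed(204)
  es_q <- runif(70, -0.6, 0.6)
  es_r <- es_q + rnorm(70, 0, 0.1)
  perm <- sample(70)
  lr1 <- linkProfiles(list(mkProfile("q", es_q)),
                      list(mkProfile("r", es_r)), min_shared_genes = 50)
  lr2 <- linkProfiles(list(mkProfile("q", es_q[perm],
                                     genes = sprintf("g%03d", perm))),
                      list(mkProfile("r", es_r[perm],
                                     genes = sprintf("g%03d", perm))),
                      min_shared_genes = 50)
  expect_equal(lr1@corr[1, 1], lr2@corr[1, 1], tolerance = 1e-12)
})

test_that("gene maps translate query symbols before correlating", {
  set.seed(205)
  es <- runif(60, -0.5, 0.5)
  qry <- list(mkProfile("q", es, genes = sprintf("hsa%02d", 1:60)))
  ref <- list(mkProfile("r", es, genes = sprintf("bta%02d", 1:60)))
  gm <- GeneMap(data.frame(a = sprintf("hsa%02d", 1:60),
                           b = sprintf("bta%02d", 1:60)))
  lr <- linkProfiles(qry, ref, gm, min_shared_genes = 50)
  expect_equal(lr@corr[1, 1], 1)
  expect_equal(lr@n_shared_genes, 60L)
  # no mapping -> intersection empty -> floor error reports size
  expect_error(linkProfiles(qry, ref, min_shared_genes = 50), "0 shared")
})

test_that("exact ties pick the lowest-index reference and set the flag", {
  es <- c(seq(-0.5, 0.5, length.out = 60))
  lr <- linkProfiles(list(mkProfile("q", es)),
                     list(mkProfile("rA", es), mkProfile("rB", es)),
                     min_shared_genes = 50)
  a <- assignments(lr)
  expect_identical(a$reference, "rA")
  expect_true(a$tied)
})

test_that("weighted DSI worked example matches hand enumeration", {
  res <- weightedDice(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2))
  expect_equal(res@weighted_dsi, 0.5 * 0.8 + 0.5 * (6 / 7),
               tolerance = 1e-12)
  p <- res@pairs
  expect_equal(p$dice[p$cluster_a == "1"], 0.8)
  expect_equal(p$dice[p$cluster_a == "2"], 6 / 7, tolerance = 1e-12)
})

test_that("weighted DSI is 1 exactly on identical partitions", {
  set.seed(206)
  for (i in 1:20) {
    labs <- sample(letters[1:5], 200, replace = TRUE)
    expect_equal(weightedDice(labs, labs)@weighted_dsi, 1)
    # renaming labels on either side changes nothing
    ren <- setNames(LETTERS[1:5], letters[1:5])
    expect_equal(weightedDice(labs, ren[labs])@weighted_dsi, 1)
  }
})

test_that("optimal matching beats greedy on an adversarial confusion", {
  # confusion [[5,4],[4,0]]: greedy grabs A1-B1 (5) and strands A2;
  # the optimal pairing A1-B2 / A2-B1 totals 8
  a <- rep(c("A1", "A2"), c(9, 4))
  b <- c(rep("B1", 5), rep("B2", 4), rep("B1", 4))
  opt <- weightedDice(a, b)@weighted_dsi
  gr <- weightedDice(a, b, matching = "greedy")@weighted_dsi
  expect_gt(opt, gr)
})

test_that("named labelings are matched by cell id", {
  la <- setNames(c(1, 1, 2, 2), paste0("c", 1:4))
  lb <- setNames(c(2, 2, 1, 1), paste0("c", 4:1))  # same partition, shuffled
  expect_equal(weightedDice(la, lb)@weighted_dsi, 1)
  expect_error(weightedDice(la, setNames(1:2, c("x", "y"))), "share")
})

test_that("perturbing 5% of labels keeps the weighted DSI high", {
  set.seed(207)
  for (i in 1:5) {
    labs <- sample(paste0("k", 1:6), 1000, replace = TRUE)
    pert <- labs
    idx <- sample(1000, 50)
    pert[idx] <- sample(paste0("k", 1:6), 50, replace = TRUE)
    expect_gte(weightedDice(labs, pert)@weighted_dsi, 0.9)
  }
})
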