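test_that("rank biserial worked examples", {
  expect_equal(glassRankBiserial(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(glassRankBiserial(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(glassRankBiserial(c(2, 7, 9), c(2, 7, 9)), 0)
  # midranks of (1,1,1,2) are (2,2,2,4): rg = 2*(2-3)/4
  expect_equal(glassRankBiserial(c(1, 1), c(1, 2)), -0.5)
  expect_error(glassRankBiserial(numeric(), 1:3), "non-empty")
})

test_that("rank biserial equals the Mann-Whitney closed form without ties", {
  set.seed(101)
  for (i in 1:1000) {
    n_a <- sample(2:30, 1)
    n_b <- sample(2:30, 1)
    a <- rnorm(n_a)
    b <- rnorm(n_b)
    rg <- glassRankBiserial(a, b)
    expect_lt(abs(rg - (2 * bruteU(a, b) / (n_a * n_b) - 1)), 1e-12)
  }
})

test_that("antisymmetry, bounds and tie handling hold on random data", {
  set.seed(102)
  for (i in 1:1000) {
    a <- sample(0:5, sample(2:20, 1), replace = TRUE)  # heavy ties
    b <- sample(0:5, sample(2:20, 1), replace = TRUE)
    rg <- glassRankBiserial(a, b)
    expect_lte(abs(rg), 1)
    expect_equal(rg, -glassRankBiserial(b, a), tolerance = 1e-12)
  }
})

test_that("rank biserial is invariant under strictly monotone transforms", {
  set.seed(103)
  a <- rgamma(15, 2)
  b <- rgamma(20, 3)
  rg <- glassRankBiserial(a, b)
  expect_equal(glassRankBiserial(log(a), log(b)), rg)
  expect_equal(glassRankBiserial(a^3, b^3), rg)
  expect_equal(glassRankBiserial(rank(c(a, b))[1:15],
                                 rank(c(a, b))[16:35]), rg)
})

test_that("complete separation is the only way to reach +/-1", {
  set.seed(104)
  for (i in 1:50) {
    a <- rnorm(10)
    b <- rnorm(10)
    rg <- glassRankBiserial(a, b)
    sep <- max(a) < min(b) || max(b) < min(a)
    expect_equal(abs(rg) == 1, sep)
  }
})

test_that("cluster profiles: cluster-specific gene peaks in its cluster", {
  set.seed(110)
  labels <- rep(c("A", "B", "C"), c(30, 40, 30))
  vals <- matrix(rexp(60 * 100), 60, 100)
  vals[1, labels == "B"] <- vals[1, labels == "B"] + 5  # B-specific gene
  vals[2, ] <- 3                                        # constant gene
  nm <- normFromValues(vals)
  pr <- clusterProfiles(nm, setNames(labels, colnames(nm)))
  es <- esMatrix(pr)
  expect_gt(es[1, "B"], 0)
  expect_equal(unname(colnames(es)[which.max(es[1, ])]), "B")
  expect_equal(unname(es[2, ]), c(0, 0, 0))
  # exhaustive agreement with the scalar implementation
  for (cl in c("A", "B", "C")) {
    g <- sample(60, 5)
    for (gi in g) {
      expect_equal(es[gi, cl],
                   glassRankBiserial(vals[gi, labels == cl],
                                     vals[gi, labels != cl]),
                   tolerance = 1e-12)
    }
  }
})

test_that("two-cluster profiles are antisymmetric", {
  set.seed(111)
  labels <- rep(c("X", "Y"), c(25, 35))
  nm <- normFromValues(matrix(rpois(40 * 60, 3), 40, 60))
  es <- esMatrix(clusterProfiles(nm, setNames(labels, colnames(nm))))
  expect_equal(es[, "X"], -es[, "Y"], tolerance = 1e-12)
})

test_that("tiny clusters are flagged low confidence", {
  set.seed(112)
  labels <- rep(c("big", "tiny"), c(58, 2))
  nm <- normFromValues(matrix(rexp(20 * 60), 20, 60))
  pr <- clusterProfiles(nm, setNames(labels, colnames(nm)))
  expect_false(pr$big@low_confidence)
  expect_true(pr$tiny@low_confidence)
})

test_that("effect-size ratios apply negligible and selection rules", {
  mk <- function(genes, es) new("EffectSizeProfile", sample_id = "s",
                                cluster_id = "c", genes = genes, es = es,
                                contrast = "cluster_vs_rest",
                                low_confidence = FALSE)
  trt <- mk(c("g1", "g2", "g3", "g4"), c(0.6, 0.05, 0.5, -0.45))
  ctl <- mk(c("g1", "g2", "g3", "g4"), c(0.3, 0.8, 0.5, 0.15))
  rt <- effectSizeRatios(trt, ctl)
  tb <- ratioTable(rt)
  g1 <- tb[tb$gene == "g1", ]
  expect_equal(g1$ratio, 2.0)
  expect_true(g1$selected)                     # 2.0 > 1.5
  expect_true(tb$negligible[tb$gene == "g2"])  # |0.05| < 0.1
  expect_true(is.na(tb$ratio[tb$gene == "g2"]))
  g3 <- tb[tb$gene == "g3", ]
  expect_equal(g3$ratio, 1.0)
  expect_false(g3$selected)                    # ratio 1 not selected
  g4 <- tb[tb$gene == "g4", ]
  expect_equal(g4$ratio, 3.0)                  # |es| ratio
  expect_false(g4$sign_concordant)
  expect_equal(tb$gene[1], "g4")               # sorted by ratio, desc
  expect_error(effectSizeRatios(mk("a", 0.5), mk("b", 0.5)), "share")
})

test_that("cross-species consensus keeps genes above threshold in both", {
  mkrt <- function(genes, ratios) {
    tb <- data.frame(gene = genes, es_treated = 0.6, es_control = 0.3,
                     ratio = ratios, sign_concordant = TRUE,
                     negligible = FALSE, selected = ratios > 1.5)
    new("RatioTable", cell_type = "Monocytes", table = tb,
        negligible_threshold = 0.1, selection_threshold = 1.5)
  }
  ta <- mkrt(c("TNF", "IL6", "ACTB"), c(2.0, 2.0, 1.2))
  tb <- mkrt(c("TNF", "IL6", "ACTB"), c(1.5, 0.9, 0.8))
  cc <- crossSpeciesConsensus(ta, tb, GeneMap(), threshold = 1.0)
  expect_identical(cc$gene_a, "TNF")           # (2.0, 1.5) in; (2.0, 0.9) out
  gm <- GeneMap(data.frame(a = c("TNF", "IL6"), b = c("TNFb", "IL6b")))
  tb2 <- mkrt(c("TNFb", "IL6b"), c(1.5, 1.4))
  cc2 <- crossSpeciesConsensus(ta, tb2, gm, threshold = 1.0)
  expect_setequal(cc2$gene_a, c("TNF", "IL6"))
  expect_equal(attr(cc2, "unmapped"), 1)       # ACTB unmapped
  expect_warning(
    cc3 <- crossSpeciesConsensus(ta, tb2,
                                 new("GeneMap",
                                     pairs = data.frame(a = character(),
                                                        b = character()),
                                     mode = "explicit_pairs")),
    "empty")
  expect_equal(nrow(cc3), 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  selected <- c("g1", "g2", "g3", "g4", "g10")
  en <- hypergeomEnrichment(selected, universe, list(S = set5))
  expect_equal(en$p_value, enumHyperTail(universe, set5, 5, 4),
               tolerance = 1e-12)
  # disjoint set -> p = 1; set == universe -> p = 1
  en2 <- hypergeomEnrichment(selected, universe,
                             list(D = paste0("g", 15:18), U = universe))
  expect_equal(en2$p_value[en2$set_name == "D"], 1)  # P(X >= 0)
  expect_equal(en2$p_value[en2$set_name == "U"], 1)
  expect_true(all(en2$adjusted_p >= en2$p_value - 1e-15))
  expect_error(hypergeomEnrichment("a", character(), list()), "universe")
})
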