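test_that("negative sampling is balanced, disjoint from positives, and seeded", {
  genes <- sprintf("g%02d", 1:50)
  diseases <- sprintf("d%02d", 1:20)
  set.seed(1)
  pos <- unique(data.frame(gene = sample(genes, 100, replace = TRUE),
                           disease = sample(diseases, 100, replace = TRUE)))
  neg <- sampleNegatives(pos, genes, diseases, seed = 4)
  expect_equal(nrow(neg), nrow(pos))
  expect_equal(length(intersect(paste(neg$gene, neg$disease),
                                paste(pos$gene, pos$disease))), 0L)
  expect_equal(anyDuplicated(paste(neg$gene, neg$disease)), 0L)
  expect_true(all(neg$label == 0))
  neg2 <- sampleNegatives(pos, genes, diseases, seed = 4)
  expect_identical(neg, neg2)
  neg3 <- sampleNegatives(pos, genes, diseases, seed = 5)
  expect_false(identical(neg, neg3))
  expect_error(sampleNegatives(pos, genes[1:2], diseases[1:2], n = 100),
               "insufficient")
})

test_that("confusion metrics match hand-evaluated counts", {
  # perfect classifier
  cm <- confusionMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$precision, 1)
  expect_equal(cm$recall, 1)
  expect_equal(cm$f1, 1)

  # TP=3, FP=1, FN=2, TN=4
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  cm2 <- confusionMetrics(scores, labels, 0.5)
  expect_equal(unname(cm2$counts), c(3, 1, 4, 2))
  expect_equal(cm2$accuracy, 0.7)
  expect_equal(cm2$precision, 0.75)
  expect_equal(cm2$recall, 0.6)
  expect_equal(cm2$f1, 2 / 3)
  expect_equal(cm2$fpr, 1 / 5)
  # F1 equals 2TP/(2TP+FP+FN) algebraically
  expect_equal(cm2$f1, 2 * 3 / (2 * 3 + 1 + 2))

  # degenerate: all predicted negative -> precision missing, recall 0
  cm3 <- confusionMetrics(c(0.1, 0.2), c(1, 0), 0.5)
  expect_true(is.na(cm3$precision))
  expect_equal(cm3$recall, 0)
  # no positive labels -> recall missing
  cm4 <- confusionMetrics(c(0.9, 0.1), c(0, 0), 0.5)
  expect_true(is.na(cm4$recall))
})

test_that("AUC and AUPR match brute force and symmetry properties", {
  expect_equal(unname(curveAucs(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))["auc"]),
               0.75)
  # perfectly separated
  expect_equal(unname(curveAucs(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))["auc"]),
               1)
  # label inversion: AUC' = 1 - AUC
  set.seed(6)
  sc <- runif(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  a <- unname(curveAucs(sc, y)["auc"])
  b <- unname(curveAucs(sc, 1 - y)["auc"])
  expect_equal(a + b, 1)
  expect_error(curveAucs(sc, rep(1, 30)), "both classes")

  # rank AUC equals brute-force concordant-pair counting on random fixtures
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)   # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- sc[y == 1]; neg <- sc[y == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(unname(curveAucs(sc, y)["auc"]), brute, tolerance = 1e-12)
  }
})

test_that("AUC and AUPR agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- runif(200)
  y <- rbinom(200, 1, 0.4)
  ours <- curveAucs(sc, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<",
                                        levels = c(0, 1))))
  expect_equal(unname(ours["auc"]), ref, tolerance = 1e-10)
})

test_that("curve points trace monotone recall and match the integrals", {
  set.seed(10)
  sc <- runif(100); y <- rbinom(100, 1, 0.5)
  cp <- curvePoints(sc, y)
  expect_true(all(diff(cp$roc$fpr) >= 0))
  expect_true(all(diff(cp$roc$tpr) >= 0))
  # trapezoidal ROC integration equals the rank AUC
  trap <- sum(diff(cp$roc$fpr) * (head(cp$roc$tpr, -1) + tail(cp$roc$tpr, -1)) / 2)
  expect_equal(trap, unname(curveAucs(sc, y)["auc"]), tolerance = 1e-12)
})

test_that("cross-validation folds partition pairs with near-equal sizes", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 8), n)
  y <- rep(c(1, 0), 50)
  # a fast deterministic scorer isolates the fold bookkeeping
  seen <- list()
  scorer <- function(trainIdx, testIdx, foldSeed) {
    seen[[length(seen) + 1L]] <<- testIdx
    expect_equal(length(intersect(trainIdx, testIdx)), 0L)
    expect_equal(sort(c(trainIdx, testIdx)), 1:n)
    runif(length(testIdx))
  }
  rep <- crossValidate(X, labels = y, k = 5, combo = "GD", seed = 3,
                       scorer = scorer)
  sizes <- lengths(seen)
  expect_equal(sum(sizes), n)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(unlist(seen)), 1:n)
  expect_equal(sizes, rep.int(20L, 5L))  # 80/20 split on 100 pairs
  expect_s4_class(rep, "MetricReport")
  expect_equal(nrow(foldMetrics(rep)), 5L)
})

test_that("metric report means lie within per-fold ranges and F1 is consistent", {
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(n * 8), n)
  y <- rep(c(1, 0), 30)
  scorer <- function(trainIdx, testIdx, foldSeed) {
    withr::with_seed(foldSeed, runif(length(testIdx)))
  }
  rep <- crossValidate(X, labels = y, k = 3, repeats = 2, combo = "GD",
                       seed = 5, scorer = scorer)
  fm <- foldMetrics(rep)
  expect_equal(nrow(fm), 6L)
  sm <- metricSummary(rep)
  for (m in sm$metric) {
    expect_gte(sm$mean[sm$metric == m], min(fm[[m]], na.rm = TRUE))
    expect_lte(sm$mean[sm$metric == m], max(fm[[m]], na.rm = TRUE))
  }
})

test_that("ablation rejects unknown combinations and keys reports by combo", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n * 8), n)
  y <- rep(c(1, 0), 20)
  expect_error(ablationRun(X, X, X, y, combos = "GD+XX"), "unknown")
  scorer <- function(trainIdx, testIdx, foldSeed) runif(length(testIdx))
  reps <- ablationRun(X, X, X, y, combos = c("GD", "GD+GMD"), k = 2,
                      seed = 2, scorer = scorer)
  expect_named(reps, c("GD", "GD+GMD"))
  expect_s4_class(reps$GD, "MetricReport")
})

test_that("candidate ranking is a sorted permutation with deterministic ties", {
  net <- smallGmdNetwork()
  cfg <- embedConfig(e = 4, seed = 2)
  embG <- embedNetwork(net, cfg)
  embs <- list(gd = embG, gmd = embG, gld = embG)
  set.seed(16)
  X <- matrix(rnorm(10 * 16), 10)
  y <- rep(c(1, 0), 5)
  m <- trainModel(X, labels = y, combo = "GD",
                  config = trainConfig(epochs = 2, nHeads = 2, dF = 4,
                                       hidden = 4, seed = 1))
  cand <- c("g3", "g1", "g2")
  rk <- rankCandidateGenes(m, "d1", cand, embs)
  expect_setequal(rk$gene, cand)
  expect_true(all(diff(rk$score) <= 0))
  rk2 <- rankCandidateGenes(m, "d1", cand, embs, top = 2)
  expect_equal(nrow(rk2), 2L)
  expect_equal(rankCandidateGenes(m, "d1", character(0), embs)$gene,
               character(0))
})
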