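test_that("embed configuration validates its invariants", {
  expect_error(embedConfig(e = 7), "even")
  expect_error(embedConfig(e = 0), "even")
  expect_error(embedConfig(p = 0), "p and q")
  expect_error(embedConfig(q = -1), "p and q")
  expect_silent(embedConfig(e = 2))
})

test_that("second-order step distribution follows the p/q biases", {
  # path graph A-B-C, at B having arrived from A
  nbr <- c(1L, 3L)        # neighbors of B: A(1), C(3)
  w <- c(1, 1)
  prevNbr <- c(2L)        # neighbors of A: just B(2)
  pr <- hetfuse:::cpp_node2vec_step_probs(nbr, w, prevNbr, 1L, 1, 1)
  expect_equal(pr, c(0.5, 0.5))
  # p = 0.25, q = 4: unnormalized {A: 4, C: 0.25}
  pr2 <- hetfuse:::cpp_node2vec_step_probs(nbr, w, prevNbr, 1L, 0.25, 4)
  expect_equal(pr2, c(16 / 17, 1 / 17), tolerance = 1e-12)
})

test_that("walks stay on the graph, respect length, and isolated nodes self-walk", {
  net <- buildNetwork(
    data.frame(u = c("g1", "g2"), v = c("d1", "d1"), weight = 1,
               relation = "gene_disease"), "GD",
    isolated = data.frame(id = "g9", kind = "gene"))
  cfg <- embedConfig(e = 4, walksPerNode = 3, walkLength = 10, seed = 5)
  corpus <- generateWalks(net, cfg)
  expect_equal(length(corpus$walks), 4L * 3L)
  ids <- networkNodes(net)$id
  for (w in corpus$walks) {
    expect_true(all(w %in% ids))
    expect_lte(length(w), 10L)
  }
  isoWalks <- Filter(function(w) w[1] == "g9", corpus$walks)
  expect_equal(length(isoWalks), 3L)
  expect_true(all(vapply(isoWalks, identical, TRUE, "g9")))
})

test_that("with p = q = 1 and unit weights next-step frequencies are uniform", {
  # star-free 4-cycle: every node has exactly two neighbors
  ed <- data.frame(u = c("g1", "g2", "g3", "g4"),
                   v = c("g2", "g3", "g4", "g1"),
                   weight = 1, relation = "gene_gene")
  net <- buildNetwork(ed, "GD")
  cfg <- embedConfig(e = 4, walksPerNode = 40, walkLength = 100, seed = 2)
  corpus <- generateWalks(net, cfg)
  steps <- table(unlist(lapply(corpus$walks, function(w)
    paste(w[-length(w)], w[-1]))))
  # per (from, to) cell under uniformity: chi-square GOF over transitions
  # out of each node
  froms <- sub(" .*", "", names(steps))
  for (f in unique(froms)) {
    cnt <- as.numeric(steps[froms == f])
    expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
  }
})

test_that("skip-gram and LINE embeddings are reproducible and well-shaped", {
  net <- twoCliqueNetwork()
  cfg <- embedConfig(e = 8, seed = 11)
  corpus <- generateWalks(net, cfg)
  e1 <- trainSkipgram(corpus, cfg, net = net)
  e2 <- trainSkipgram(corpus, cfg, net = net)
  expect_identical(embeddingMatrix(e1), embeddingMatrix(e2))
  expect_equal(ncol(embeddingMatrix(e1)), 8L)
  expect_true(all(is.finite(embeddingMatrix(e1))))

  l1 <- trainLine(net, cfg)
  l2 <- trainLine(net, cfg)
  expect_identical(embeddingMatrix(l1), embeddingMatrix(l2))
  expect_equal(ncol(embeddingMatrix(l1)), 8L)

  cfgB <- embedConfig(e = 8, seed = 12)
  e3 <- trainSkipgram(generateWalks(net, cfgB), cfgB, net = net)
  expect_false(identical(embeddingMatrix(e1), embeddingMatrix(e3)))
})

test_that("community structure separates in embedding space", {
  net <- twoCliqueNetwork()
  cfg <- embedConfig(e = 8, seed = 3)
  for (emb in list(trainSkipgram(generateWalks(net, cfg), cfg, net = net),
                   trainLine(net, cfg))) {
    V <- embeddingMatrix(emb)
    Vn <- V / sqrt(rowSums(V^2))
    S <- Vn %*% t(Vn)
    grp <- rep(1:2, each = 6)
    same <- outer(grp, grp, "==") & upper.tri(S)
    diff <- !outer(grp, grp, "==") & upper.tri(S)
    expect_gt(mean(S[same]), mean(S[diff]))
  }
})

test_that("LINE training decreases its sampled objective on every fixture", {
  nets <- list(twoCliqueNetwork(), smallGmdNetwork())
  for (net in nets) {
    cfg <- embedConfig(e = 8, seed = 7)
    emb <- trainLine(net, cfg)
    hist <- lineLossHistory(emb)
    expect_lt(tail(hist$order1, 1), hist$order1[1])
    expect_lt(tail(hist$order2, 1), hist$order2[1])
    # the exact expected objective is finite and the positive (edge) term
    # improves over the seeded start
    expect_true(is.finite(lineFirstOrderLoss(emb, net)))
  }
})

test_that("LINE first-order gradient matches finite differences", {
  # 2-node, 1-edge graph; objective -log sigmoid(u . v) in u
  u <- c(0.3, -0.2)
  v <- c(0.1, 0.4)
  lossFn <- function(u) -log(1 / (1 + exp(-sum(u * v))))
  analytic <- -(1 - 1 / (1 + exp(-sum(u * v)))) * v
  eps <- 1e-6
  fd <- vapply(1:2, function(j) {
    up <- u; up[j] <- up[j] + eps
    um <- u; um[j] <- um[j] - eps
    (lossFn(up) - lossFn(um)) / (2 * eps)
  }, numeric(1))
  expect_equal(analytic, fd, tolerance = 1e-5)
})

test_that("LINE errors on an edgeless network", {
  net <- buildNetwork(NULL, "GD",
                      isolated = data.frame(id = "g1", kind = "gene"))
  expect_error(trainLine(net, embedConfig(e = 4)), "edges")
})

test_that("pair feature assembly concatenates in the documented order", {
  mkEmb <- function(alg, vals) {
    new("NodeEmbedding", algorithm = alg, layer = "GD",
        vectors = matrix(vals, 2, 2, byrow = TRUE,
                         dimnames = list(c("g", "d"), NULL)))
  }
  n2v <- mkEmb("node2vec", c(1, 2, 3, 4))
  line <- mkEmb("line", c(5, 6, 7, 8))
  pf <- assemblePairFeatures(data.frame(gene = "g", disease = "d"), n2v, line)
  expect_equal(as.numeric(featureMatrix(pf)), c(1, 2, 3, 4, 5, 6, 7, 8))
})

test_that("pair feature assembly imputes cold-start nodes or errors in strict mode", {
  net <- smallGmdNetwork()
  cfg <- embedConfig(e = 4, seed = 2)
  emb <- embedNetwork(net, cfg)
  pairs <- data.frame(gene = c("g1", "g2"), disease = c("d1", "d9"))
  expect_error(assemblePairFeatures(pairs, emb$node2vec, emb$line,
                                    strict = TRUE), "d9")
  pf <- assemblePairFeatures(pairs, emb$node2vec, emb$line)
  expect_equal(pf@imputed, "d9")
  expect_true(all(featureMatrix(pf)[2, c(5:8, 13:16)] == 0))
  expect_equal(dim(featureMatrix(pf)), c(2L, 16L))
})

test_that("pair feature assembly is permutation-equivariant", {
  net <- smallGmdNetwork()
  cfg <- embedConfig(e = 4, seed = 2)
  emb <- embedNetwork(net, cfg)
  pairs <- expand.grid(gene = c("g1", "g2", "g3"), disease = c("d1", "d2"),
                       stringsAsFactors = FALSE)
  pf <- assemblePairFeatures(pairs, emb$node2vec, emb$line)
  perm <- c(4, 2, 6, 1, 3, 5)
  pf2 <- assemblePairFeatures(pairs[perm, ], emb$node2vec, emb$line)
  expect_equal(featureMatrix(pf2), featureMatrix(pf)[perm, ])
})

test_that("embedding serialization round-trips", {
  net <- smallGmdNetwork()
  cfg <- embedConfig(e = 4, seed = 9)
  emb <- trainLine(net, cfg)
  f <- tempfile(fileext = ".tsv")
  writeEmbedding(emb, f)
  emb2 <- readEmbedding(f)
  expect_equal(emb2@algorithm, "line")
  expect_equal(emb2@layer, "GMD")
  expect_equal(embeddingMatrix(emb2), embeddingMatrix(emb),
               tolerance = 1e-12, ignore_attr = TRUE)
})
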