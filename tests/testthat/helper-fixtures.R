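# shared fixtures, all generated in code

writeTempEdges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# two 6-node cliques joined by a single bridge edge
twoCliqueNetwork <- function() {
  rows <- list()
  for (s in c(0L, 6L))
    for (i in 1:5) for (j in (i + 1):6)
      rows[[length(rows) + 1L]] <- data.frame(
        u = sprintf("g%02d", s + i), v = sprintf("g%02d", s + j),
        weight = 1, relation = "gene_gene")
  rows[[length(rows) + 1L]] <- data.frame(u = "g06", v = "g07", weight = 1,
                                          relation = "gene_gene")
  buildNetwork(do.call(rbind, rows), "GD")
}

# small GMD network: genes/diseases attached to module-specific miRNAs
smallGmdNetwork <- function() {
  ed <- rbind(
    data.frame(u = c("g1", "g2", "g3"), v = c("m1", "m1", "m2"), weight = 1,
               relation = "gene_mirna"),
    data.frame(u = c("d1", "d2"), v = c("m1", "m2"), weight = 1,
               relation = "disease_mirna"))
  buildNetwork(ed, "GMD")
}

randomPairFeatures <- function(n, e, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 4 * e), n, 4 * e)
}

tinySimConfig <- function(seed = 1) {
  syntheticConfig(nGenes = 60, nDiseases = 12, nLncRNAs = 20, nMiRNAs = 30,
                  nModules = 4, seed = seed)
}

# independently coded scalar softmax for oracles
oracleSoftmax <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))

# loop-based scaled dot-product attention oracle
oracleAttention <- function(Q, K, V) {
  n <- nrow(Q); dk <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    scores <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- oracleSoftmax(scores)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# loop-based multi-head oracle on initMultiHeadParams() structures
oracleMultiHead <- function(Q, K, V, params) {
  h <- length(params$Wq)
  heads <- vector("list", h)
  for (i in seq_len(h))
    heads[[i]] <- oracleAttention(Q %*% params$Wq[[i]], K %*% params$Wk[[i]],
                                  V %*% params$Wv[[i]])
  do.call(cbind, heads) %*% params$Wo
}
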