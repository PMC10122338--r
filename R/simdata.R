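#' Synthetic benchmark configuration
#'
#' Parameters of the planted-partition generator for tripartite
#' heterogeneous networks. Every node is assigned to one of
#' \code{nModules} latent disease modules; genes and diseases sharing a
#' module are preferentially connected both directly and through shared
#' miRNA / lncRNA neighbors, so the auxiliary networks carry association
#' signal beyond the gene--disease network itself.
#'
#' @param nGenes,nDiseases,nLncRNAs,nMiRNAs node counts per type.
#' @param nModules number of latent modules.
#' @param pIn within-module edge probability for cross-type relations.
#' @param pOut between-module edge probability (\code{pOut < pIn}).
#' @param simNoise standard deviation of the Gaussian jitter on
#'   similarity weights.
#' @param holdoutFrac fraction of positive gene--disease edges held out for
#'   testing, in (0, 1).
#' @param seed integer seed.
#' @return list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGenes = 300, nDiseases = 40, nLncRNAs = 80,
                            nMiRNAs = 120, nModules = 10, pIn = 0.1,
                            pOut = 0.01, simNoise = 0.05, holdoutFrac = 0.2,
                            seed = 1) {
  if (pIn <= pOut) stop("configuration error: pIn must exceed pOut")
  if (pOut < 0 || pIn > 1) stop("configuration error: 0 <= pOut < pIn <= 1")
  if (holdoutFrac <= 0 || holdoutFrac >= 1)
    stop("configuration error: holdoutFrac must be in (0, 1)")
  counts <- c(nGenes, nDiseases, nLncRNAs, nMiRNAs)
  if (any(counts < nModules))
    stop("configuration error: every node count must be >= nModules")
  structure(list(nGenes = nGenes, nDiseases = nDiseases,
                 nLncRNAs = nLncRNAs, nMiRNAs = nMiRNAs,
                 nModules = nModules, pIn = pIn, pOut = pOut,
                 simNoise = simNoise, holdoutFrac = holdoutFrac,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

crossTypeEdges <- function(idsA, idsB, modA, modB, pIn, pOut, relation) {
  grid <- expand.grid(a = seq_along(idsA), b = seq_along(idsB))
  pEdge <- ifelse(modA[grid$a] == modB[grid$b], pIn, pOut)
  keep <- runif(nrow(grid)) < pEdge
  data.frame(u = idsA[grid$a[keep]], v = idsB[grid$b[keep]], weight = 1,
             relation = relation, stringsAsFactors = FALSE)
}

similarityEdges <- function(ids, mod, nModules, noiseSd, relation) {
  n <- length(ids)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  w <- 1 - abs(mod[ij[, 1]] - mod[ij[, 2]]) / nModules +
    rnorm(nrow(ij), 0, noiseSd)
  w <- pmin(1, pmax(1e-6, w))   # clip into (0, 1]
  data.frame(u = ids[ij[, 1]], v = ids[ij[, 2]], weight = w,
             relation = relation, stringsAsFactors = FALSE)
}

#' Generate a synthetic tripartite heterogeneous network benchmark
#'
#' Assigns every node a latent module uniformly at random, then draws the
#' seven relation edge tables: cross-type association edges (gene--disease,
#' gene--miRNA, disease--miRNA, gene--lncRNA, disease--lncRNA) appear with
#' probability \code{pIn} within a module and \code{pOut} between modules
#' (binary weight 1); gene--gene and disease--disease similarity weights
#' equal \eqn{1 - |\Delta module|/nModules} plus Gaussian jitter, clipped
#' into (0, 1], mirroring the mix of continuous similarity matrices and
#' curated binary associations in real compilations. The planted positives
#' are the direct within-module gene--disease edges. Byte-identical output
#' for a fixed seed.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with elements \code{edges} (named list of the seven edge
#'   data.frames), \code{truth} (list: \code{modules} named integer vector,
#'   \code{positives} data.frame) and \code{cfg}.
#' @export
generateSyntheticHetnet <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withSeed(cfg$seed, {
    ids <- list(
      gene = sprintf("g%03d", seq_len(cfg$nGenes)),
      disease = sprintf("d%03d", seq_len(cfg$nDiseases)),
      lncRNA = sprintf("l%03d", seq_len(cfg$nLncRNAs)),
      miRNA = sprintf("m%03d", seq_len(cfg$nMiRNAs)))
    mods <- lapply(c(gene = cfg$nGenes, disease = cfg$nDiseases,
                     lncRNA = cfg$nLncRNAs, miRNA = cfg$nMiRNAs),
                   function(n) sample.int(cfg$nModules, n, replace = TRUE))
    edges <- list(
      gene_gene = similarityEdges(ids$gene, mods$gene, cfg$nModules,
                                  cfg$simNoise, "gene_gene"),
      disease_disease = similarityEdges(ids$disease, mods$disease,
                                        cfg$nModules, cfg$simNoise,
                                        "disease_disease"),
      gene_disease = crossTypeEdges(ids$gene, ids$disease, mods$gene,
                                    mods$disease, cfg$pIn, cfg$pOut,
                                    "gene_disease"),
      gene_mirna = crossTypeEdges(ids$gene, ids$miRNA, mods$gene,
                                  mods$miRNA, cfg$pIn, cfg$pOut,
                                  "gene_mirna"),
      disease_mirna = crossTypeEdges(ids$disease, ids$miRNA, mods$disease,
                                     mods$miRNA, cfg$pIn, cfg$pOut,
                                     "disease_mirna"),
      gene_lncrna = crossTypeEdges(ids$gene, ids$lncRNA, mods$gene,
                                   mods$lncRNA, cfg$pIn, cfg$pOut,
                                   "gene_lncrna"),
      disease_lncrna = crossTypeEdges(ids$disease, ids$lncRNA, mods$disease,
                                      mods$lncRNA, cfg$pIn, cfg$pOut,
                                      "disease_lncrna"))
    gd <- edges$gene_disease
    sameMod <- mods$gene[match(gd$u, ids$gene)] ==
      mods$disease[match(gd$v, ids$disease)]
    positives <- data.frame(gene = gd$u[sameMod], disease = gd$v[sameMod],
                            stringsAsFactors = FALSE)
    modules <- setNames(unlist(mods, use.names = FALSE),
                        unlist(ids, use.names = FALSE))
    list(edges = edges, truth = list(modules = modules,
                                     positives = positives, ids = ids),
         cfg = cfg)
  })
}

#' Split a synthetic benchmark into labelled train and test pair sets
#'
#' Removes a fraction of the planted positive gene--disease edges from the
#' GD edge table, so that the embeddings never see them, and places them in
#' the test set; the remaining positives train. Balanced negatives (one per
#' positive) are drawn disjointly for train and test with
#' [sampleNegatives()]. In leave-disease-out mode, all positives of the
#' named diseases are held out instead.
#'
#' @param sim result of [generateSyntheticHetnet()].
#' @param holdoutFrac fraction of positives held out (default from the
#'   generator config).
#' @param seed integer seed (default from the generator config).
#' @param leaveOutDiseases optional character vector of disease ids whose
#'   positives are all held out.
#' @return list with \code{edges} (the seven tables, GD reduced),
#'   \code{train} and \code{test} (data.frames gene/disease/label),
#'   \code{heldOut} (the held-out positive pairs).
#' @export
makeBenchmark <- function(sim, holdoutFrac = NULL, seed = NULL,
                          leaveOutDiseases = NULL) {
  cfg <- sim$cfg
  holdoutFrac <- holdoutFrac %||% cfg$holdoutFrac
  seed <- seed %||% cfg$seed
  pos <- sim$truth$positives
  if (nrow(pos) < 2) stop("not enough positives to hold any out")
  if (is.null(leaveOutDiseases)) {
    nHold <- max(1L, round(holdoutFrac * nrow(pos)))
    holdIdx <- withSeed(deriveSeed(seed, 71L), sample.int(nrow(pos), nHold))
  } else {
    holdIdx <- which(pos$disease %in% leaveOutDiseases)
    if (!length(holdIdx)) stop("named disease(s) have no positives")
  }
  if (length(holdIdx) >= nrow(pos))
    stop("holdout would empty the training positives")
  test <- pos[holdIdx, , drop = FALSE]
  train <- pos[-holdIdx, , drop = FALSE]

  gd <- sim$edges$gene_disease
  heldKey <- paste(test$gene, test$disease)
  edges <- sim$edges
  edges$gene_disease <- gd[!(paste(gd$u, gd$v) %in% heldKey), , drop = FALSE]

  negs <- sampleNegatives(pos, sim$truth$ids$gene, sim$truth$ids$disease,
                          n = nrow(train) + nrow(test),
                          seed = deriveSeed(seed, 73L))
  trainNeg <- negs[seq_len(nrow(train)), , drop = FALSE]
  testNeg <- negs[nrow(train) + seq_len(nrow(test)), , drop = FALSE]
  train$label <- 1; test$label <- 1
  out <- list(
    edges = edges,
    train = rbind(train, trainNeg[, c("gene", "disease", "label")]),
    test = rbind(test, testNeg[, c("gene", "disease", "label")]),
    heldOut = test[, c("gene", "disease")])
  rownames(out$train) <- rownames(out$test) <- NULL
  out
}

#' Build the three heterogeneous networks from a benchmark's edge tables
#'
#' Registers every node of the appropriate kinds as (possibly isolated)
#' nodes in each layer so that embeddings exist for all of them.
#'
#' @param edges named list of the seven relation edge data.frames.
#' @param ids named list of node id vectors per kind (gene, disease,
#'   lncRNA, miRNA).
#' @return named list of three [HeteroNetwork-class] objects (GD, GMD, GLD).
#' @export
benchmarkNetworks <- function(edges, ids) {
  iso <- function(kinds) do.call(rbind, lapply(kinds, function(k)
    data.frame(id = ids[[k]], kind = k, stringsAsFactors = FALSE)))
  list(
    GD = buildNetwork(edges[LAYER_RELATIONS$GD], "GD",
                      isolated = iso(c("gene", "disease"))),
    GMD = buildNetwork(edges[LAYER_RELATIONS$GMD], "GMD",
                       isolated = iso(c("gene", "miRNA", "disease"))),
    GLD = buildNetwork(edges[LAYER_RELATIONS$GLD], "GLD",
                       isolated = iso(c("gene", "lncRNA", "disease"))))
}
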