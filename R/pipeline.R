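#' Run the full scoring pipeline on a synthetic benchmark
#'
#' End-to-end: generate a planted-partition benchmark, hold out a fraction
#' of the positive gene--disease edges, build the three heterogeneous
#' networks, learn node2vec and LINE embeddings per network, assemble the
#' three pair feature matrices over one shared pair list, train the fusion +
#' self-attention + MLP scorer on the training pairs, and evaluate on the
#' held-out pairs. Every stage derives its seed from the single master
#' \code{seed}, so the whole run is reproducible end-to-end. Several network
#' combinations can be evaluated in one call; they share the benchmark and
#' the embeddings, so an ablation comparison is embedding-for-embedding.
#'
#' When \code{trainCfg} is \code{NULL}, benchmark-scaled training defaults
#' are used: full-batch attention (batch size = number of training pairs),
#' 800 epochs of full-batch Adam, and architecture widths scaled in
#' proportion to the benchmark's embedding dimension (\code{dF = 32},
#' \code{hidden = 96} at e = 16, preserving the width ratios of the
#' full-scale configuration). See the methods vignette for the rationale.
#'
#' @param simCfg a [syntheticConfig()].
#' @param embedCfg an [embedConfig()]; default uses e = 16, matched to the
#'   benchmark's scale.
#' @param trainCfg a [trainConfig()], or \code{NULL} for the
#'   benchmark-scaled defaults described above.
#' @param combos character vector of network combinations; the first one is
#'   reported in the top-level \code{metrics}.
#' @param seed master seed.
#' @return list with elements \code{metrics}, \code{model}, \code{scores}
#'   (for the first combination), \code{perCombo} (named list with
#'   \code{metrics}, \code{scores}, \code{model} per combination),
#'   \code{test}, \code{train}, \code{report} (plain-list summary suitable
#'   for JSON serialization), \code{features}, \code{networks}, \code{sim}.
#' @export
runPipeline <- function(simCfg = syntheticConfig(),
                        embedCfg = embedConfig(e = 16),
                        trainCfg = NULL,
                        combos = "GD+GMD+GLD", seed = 1) {
  simCfg$seed <- deriveSeed(seed, 301L)
  sim <- generateSyntheticHetnet(simCfg)
  bench <- makeBenchmark(sim, seed = deriveSeed(seed, 303L))
  nets <- benchmarkNetworks(bench$edges, sim$truth$ids)

  pairs <- rbind(bench$train[, c("gene", "disease")],
                 bench$test[, c("gene", "disease")])
  feats <- list()
  for (i in seq_along(nets)) {
    cfgL <- embedCfg
    cfgL$seed <- deriveSeed(seed, 310L + i)
    emb <- embedNetwork(nets[[i]], cfgL)
    feats[[names(nets)[i]]] <- assemblePairFeatures(pairs, emb$node2vec,
                                                    emb$line)
  }
  nTrain <- nrow(bench$train)
  trIdx <- seq_len(nTrain)
  teIdx <- nTrain + seq_len(nrow(bench$test))
  sub <- function(l, idx) featMat(l)[idx, , drop = FALSE]
  if (is.null(trainCfg)) {
    trainCfg <- trainConfig(epochs = 300, batchSize = nTrain,
                            dF = 2 * embedCfg$e, hidden = 6 * embedCfg$e)
  }
  trainCfg$seed <- deriveSeed(seed, 331L)

  perCombo <- list()
  yTe <- bench$test$label
  for (combo in combos) {
    br <- comboBranches(combo)
    model <- trainModel(sub(feats$GD, trIdx),
                        if ("m" %in% br) sub(feats$GMD, trIdx),
                        if ("l" %in% br) sub(feats$GLD, trIdx),
                        bench$train$label, config = trainCfg, combo = combo)
    scores <- predictScores(model, sub(feats$GD, teIdx),
                            if ("m" %in% br) sub(feats$GMD, teIdx),
                            if ("l" %in% br) sub(feats$GLD, teIdx))
    au <- curveAucs(scores, yTe)
    cm <- confusionMetrics(scores, yTe)
    perCombo[[combo]] <- list(
      metrics = list(auc = unname(au["auc"]), aupr = unname(au["aupr"]),
                     accuracy = cm$accuracy, precision = cm$precision,
                     recall = cm$recall, f1 = cm$f1),
      scores = scores, model = model)
  }
  first <- perCombo[[combos[1L]]]
  report <- c(list(seed = seed, nTrain = nTrain, nTest = length(yTe)),
              lapply(perCombo, `[[`, "metrics"))
  list(metrics = first$metrics, model = first$model, scores = first$scores,
       perCombo = perCombo, test = bench$test, train = bench$train,
       report = report, features = feats, networks = nets, sim = sim)
}
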