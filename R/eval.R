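#' Balanced negative sampling
#'
#' Draws unknown (gene, disease) pairs uniformly at random, disjoint from
#' the known positives and without duplicates, of size exactly equal to the
#' number of positives (class-balanced evaluation), labelled 0.
#'
#' @param positives data.frame with columns \code{gene}, \code{disease}.
#' @param genes,diseases candidate id sets.
#' @param n number of negatives (default \code{nrow(positives)}).
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{disease},
#'   \code{label} (all 0).
#' @export
sampleNegatives <- function(positives, genes, diseases,
                            n = nrow(positives), seed = 1) {
  genes <- sort(unique(genes)); diseases <- sort(unique(diseases))
  nG <- length(genes); nD <- length(diseases)
  posKey <- paste(positives$gene, positives$disease)
  gi <- match(positives$gene, genes)
  di <- match(positives$disease, diseases)
  posIdx <- (gi - 1L) * nD + di
  posIdx <- posIdx[!is.na(posIdx)]
  unknown <- setdiff(seq_len(nG * nD), posIdx)
  if (length(unknown) < n)
    stop("insufficient unknown pairs to sample ", n, " negatives")
  pick <- withSeed(seed, sample(unknown, n))
  data.frame(gene = genes[(pick - 1L) %/% nD + 1L],
             disease = diseases[(pick - 1L) %% nD + 1L],
             label = 0, stringsAsFactors = FALSE)
}

#' Threshold-based confusion counts and derived metrics
#'
#' A pair is predicted positive when its score exceeds the threshold.
#' Computes TP/FP/TN/FN and accuracy, precision, recall (TPR), FPR and F1.
#' Degenerate cases are reported as \code{NA}, not 0 (e.g. precision with no
#' predicted positives, recall with no positive labels).
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return list with \code{counts} (named TP/FP/TN/FN) and the metrics.
#' @export
confusionMetrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- scores > threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall)
  else if (!is.na(precision) && !is.na(recall)) NA_real_ else NA_real_
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall,
       fpr = safe(fp, fp + tn), f1 = f1)
}

#' Areas under the ROC and precision--recall curves
#'
#' AUC via the rank statistic (equivalent to trapezoidal integration of the
#' ROC curve, ties averaged); AUPR via step integration of the
#' precision--recall curve over distinct score thresholds.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return named numeric vector \code{c(auc = , aupr = )}.
#' @export
curveAucs <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cumTP <- cumsum(y == 1); cumFP <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)   # ends of tied-score groups
  tp <- cumTP[last]; fp <- cumFP[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  dR <- diff(c(0, recall))
  aupr <- sum(dR * precision)
  c(auc = auc, aupr = aupr)
}

#' ROC and precision--recall curve points
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @return list of two data.frames: \code{roc} (fpr, tpr) and \code{pr}
#'   (recall, precision), one row per distinct threshold.
#' @export
curvePoints <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last]; fp <- cumsum(y == 0)[last]
  list(roc = data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1)),
       pr = data.frame(recall = tp / n1, precision = tp / (tp + fp)))
}

#' Cross-validated evaluation of the association scorer
#'
#' Seeded shuffled k-fold cross-validation (default 5-fold: 80% of the
#' pairs train, 20% test per fold) on a balanced labelled pair set, repeated
#' \code{repeats} times with fresh fold assignments. A fresh model is
#' trained per fold; AUC, AUPR, accuracy, precision, recall and F1 are
#' collected per fold and summarized as mean and standard deviation.
#'
#' @param gd,gmd,gld aligned pair feature matrices.
#' @param labels 0/1 vector.
#' @param k folds.
#' @param repeats random-sampling repeats.
#' @param config a [trainConfig()].
#' @param combo network combination.
#' @param seed master seed; per-repeat fold seeds and per-fold training
#'   seeds are derived from it.
#' @param threshold decision threshold for the confusion metrics.
#' @param scorer optional replacement scoring function
#'   \code{function(trainIdx, testIdx, foldSeed)} returning scores for the
#'   test pairs; used for calibration checks instead of model training.
#' @return a [MetricReport-class].
#' @export
crossValidate <- function(gd, gmd = NULL, gld = NULL, labels, k = 5,
                          repeats = 1, config = trainConfig(),
                          combo = "GD+GMD+GLD", seed = 1, threshold = 0.5,
                          scorer = NULL) {
  Xgd <- featMat(gd)
  n <- nrow(Xgd)
  if (sum(labels == 1) < k) stop("fewer than k positive pairs")
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- withSeed(deriveSeed(seed, 100L + r),
                      sample(rep(seq_len(k), length.out = n)))
    for (f in seq_len(k)) {
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      foldSeed <- deriveSeed(seed, 1000L * r + f)
      if (is.null(scorer)) {
        cfgF <- config; cfgF$seed <- foldSeed
        sub <- function(x) if (!is.null(x)) x[trainIdx, , drop = FALSE]
        model <- trainModel(Xgd[trainIdx, , drop = FALSE],
                            sub(featMat(gmd)), sub(featMat(gld)),
                            labels[trainIdx], config = cfgF, combo = combo)
        te <- function(x) if (!is.null(x))
          featMat(x)[testIdx, , drop = FALSE]
        sc <- predictScores(model, Xgd[testIdx, , drop = FALSE],
                            te(gmd), te(gld))
      } else {
        sc <- scorer(trainIdx, testIdx, foldSeed)
      }
      yTe <- labels[testIdx]
      cm <- confusionMetrics(sc, yTe, threshold)
      au <- curveAucs(sc, yTe)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, auc = au[["auc"]], aupr = au[["aupr"]],
        accuracy = cm$accuracy, precision = cm$precision,
        recall = cm$recall, f1 = cm$f1)
    }
  }
  new("MetricReport", folds = do.call(rbind, rows), k = k, repeats = repeats)
}

#' Ablation over network combinations
#'
#' Runs [crossValidate()] for each requested combination of the three
#' heterogeneous networks. For combinations excluding an auxiliary network
#' the corresponding attention branch is removed from the architecture (the
#' GD-only model degenerates to an affine map of the GD pair features
#' feeding the predictor), rather than fed zeros.
#'
#' @param gd,gmd,gld aligned pair feature matrices.
#' @param labels 0/1 vector.
#' @param combos subset of \code{c("GD", "GD+GMD", "GD+GLD", "GD+GMD+GLD")}.
#' @param ... passed to [crossValidate()].
#' @return named list of [MetricReport-class], keyed by combination.
#' @export
ablationRun <- function(gd, gmd = NULL, gld = NULL, labels,
                        combos = c("GD", "GD+GMD", "GD+GLD", "GD+GMD+GLD"),
                        ...) {
  for (cb in combos) comboBranches(cb)   # reject unknown combo labels early
  out <- list()
  for (cb in combos)
    out[[cb]] <- crossValidate(gd,
                               if (grepl("GMD", cb)) gmd else NULL,
                               if (grepl("GLD", cb)) gld else NULL,
                               labels, combo = cb, ...)
  out
}

#' Rank candidate genes for a disease
#'
#' Scores every (candidate gene, disease) pair with a trained model and
#' returns the candidates sorted by descending score; ties are broken by
#' gene id (lexicographic) for determinism.
#'
#' @param model a [TrainedModel-class].
#' @param disease disease id.
#' @param candidates character vector of candidate gene ids.
#' @param embeddings list with elements \code{gd}, \code{gmd}, \code{gld},
#'   each a list with \code{node2vec} and \code{line}
#'   [NodeEmbedding-class] objects (as from [embedNetwork()]).
#' @param top optional truncation (e.g. 20 for a top-20 list).
#' @return data.frame with columns \code{gene}, \code{disease},
#'   \code{score}, sorted by descending score.
#' @export
rankCandidateGenes <- function(model, disease, candidates, embeddings,
                               top = NULL) {
  if (!length(candidates))
    return(data.frame(gene = character(0), disease = character(0),
                      score = numeric(0)))
  pairs <- data.frame(gene = candidates, disease = disease,
                      stringsAsFactors = FALSE)
  feat <- lapply(embeddings, function(e)
    assemblePairFeatures(pairs, e$node2vec, e$line))
  sc <- predictScores(model, feat$gd,
                      if ("m" %in% comboBranches(model@combo)) feat$gmd,
                      if ("l" %in% comboBranches(model@combo)) feat$gld)
  out <- data.frame(gene = candidates, disease = disease, score = sc,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Write a metric report as JSON
#'
#' Serializes the per-fold metric arrays and their mean/sd summary.
#'
#' @param report a [MetricReport-class].
#' @param path output path.
#' @export
writeMetricReport <- function(report, path) {
  obj <- list(k = report@k, repeats = report@repeats,
              folds = report@folds, summary = metricSummary(report))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
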