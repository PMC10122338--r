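#' Training configuration for the association scorer
#'
#' Defaults follow the grid-searched operating point of the method: dropout
#' 0.2 among the hidden layers, learning rate 0.01, fused width dF = 128,
#' hidden width 384, 8 attention heads, mini-batches of 30 pairs, 30 epochs.
#' Attention is computed within mini-batches (each gene--disease pair-row is
#' a token), so per-batch cost is O(batchSize^2); setting
#' \code{batchSize >= n} recovers full attention on small data.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize mini-batch (and attention block) size.
#' @param epochs training epochs.
#' @param dropout dropout rate after the hidden ReLU layer.
#' @param nHeads attention heads per fusion branch.
#' @param dF fused feature width (output of the fusion affine map).
#' @param hidden MLP hidden-layer width h'.
#' @param clipNorm global gradient-norm clip.
#' @param standardize z-score each feature column on the training set (the
#'   fitted centers/scales are stored in the model and applied at
#'   prediction time). Node2vec and LINE blocks come out of training on
#'   different scales; standardization puts them on equal footing before
#'   the attention stack.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.01, batchSize = 30, epochs = 30,
                        dropout = 0.2, nHeads = 8, dF = 128, hidden = 384,
                        clipNorm = 5, standardize = TRUE, seed = 1) {
  structure(list(learningRate = learningRate, batchSize = batchSize,
                 epochs = epochs, dropout = dropout, nHeads = nHeads,
                 dF = dF, hidden = hidden, clipNorm = clipNorm,
                 standardize = standardize, seed = as.integer(seed)),
            class = "TrainConfig")
}

# per-column z-scoring fitted on the training features
fitStandardizer <- function(X) {
  mu <- colMeans(X)
  sg <- pmax(apply(X, 2L, stats::sd), 1e-8)
  list(center = mu, scale = sg)
}

applyStandardizer <- function(X, st) {
  if (is.null(st) || is.null(X)) return(X)
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

#' Element-wise self-attention re-weighting
#'
#' Per fused row \eqn{x_i}, an attention score per feature is computed as
#' \eqn{\alpha_i = softmax(H^{att} \tanh(W^{att} x_i + b^{att}))} with the
#' softmax over the feature dimension, and the row is re-weighted
#' element-wise: \eqn{x_i' = \alpha_i \otimes x_i}. Output shape equals
#' input shape, and \eqn{|x'| \le |x|} element-wise since
#' \eqn{\alpha \in (0,1)}.
#'
#' @param x n x dF fused matrix.
#' @param params list with \code{H} (dF x dF), \code{W} (dF x dF), \code{b}
#'   (length-dF bias broadcast across rows).
#' @param returnWeights also return the attention-score matrix.
#' @return matrix like \code{x}, or a list \code{output}/\code{weights}.
#' @export
selfAttentionReweight <- function(x, params, returnWeights = FALSE) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (!all(dim(params$W) == d) || !all(dim(params$H) == d) ||
      length(params$b) != d)
    stop("self-attention parameter shapes do not match feature width")
  T1 <- tanh(sweep(x %*% t(params$W), 2L, params$b, "+"))
  A <- softmaxRows(T1 %*% t(params$H))
  out <- A * x
  if (returnWeights) list(output = out, weights = A) else out
}

#' Score rows with the sigmoid MLP
#'
#' \eqn{y = Sigmoid(Linear(Relu(Linear(x))))}; dropout (training mode only)
#' is applied after the hidden ReLU. Evaluation mode is deterministic.
#'
#' @param x n x dF input matrix.
#' @param params list with \code{W1} (dF x hidden), \code{b1}, \code{W2}
#'   (hidden x 1), \code{b2} (scalar).
#' @param training apply dropout.
#' @param dropout dropout rate used when \code{training}.
#' @return numeric score vector, entries in [0, 1].
#' @export
forwardScore <- function(x, params, training = FALSE, dropout = 0.2) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite input")
  H1 <- relu(sweep(x %*% params$W1, 2L, params$b1, "+"))
  if (training && dropout > 0) {
    mask <- matrix(runif(length(H1)) >= dropout, nrow(H1)) / (1 - dropout)
    H1 <- H1 * mask
  }
  as.numeric(sigmoid(H1 %*% params$W2 + params$b2))
}

#' Binary cross-entropy loss
#'
#' \eqn{L = -\frac{1}{n}\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with
#' scores clipped to \eqn{[\epsilon, 1-\epsilon]} before the logarithms.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @examples
#' bceLoss(c(0.8, 0.3), c(1, 0))   # -(log .8 + log .7)/2
#' @export
bceLoss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) != length(labels)) stop("length mismatch")
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

## flat parameter set -------------------------------------------------------

initModelParams <- function(dModel, cfg, combo) {
  if (dModel %% cfg$nHeads != 0)
    stop("configuration error: feature width 4e must be divisible by nHeads")
  dk <- dModel %/% cfg$nHeads
  br <- comboBranches(combo)
  par <- list()
  withSeed(deriveSeed(cfg$seed, 7L), {
    rmat <- function(nr, nc) {
      s <- 1 / sqrt(nr)
      matrix(runif(nr * nc, -s, s), nr, nc)
    }
    for (b in br) {
      for (i in seq_len(cfg$nHeads)) {
        par[[paste0(b, "_Wq", i)]] <- rmat(dModel, dk)
        par[[paste0(b, "_Wk", i)]] <- rmat(dModel, dk)
        par[[paste0(b, "_Wv", i)]] <- rmat(dModel, dk)
      }
      par[[paste0(b, "_Wo")]] <- rmat(dModel, dModel)
    }
    nIn <- (length(br) + 1L) * dModel
    par$fuse_W <- rmat(nIn, cfg$dF)
    par$fuse_b <- numeric(cfg$dF)
    par$att_H <- rmat(cfg$dF, cfg$dF)
    par$att_W <- rmat(cfg$dF, cfg$dF)
    par$att_b <- numeric(cfg$dF)
    par$mlp_W1 <- rmat(cfg$dF, cfg$hidden)
    par$mlp_b1 <- numeric(cfg$hidden)
    par$mlp_W2 <- rmat(cfg$hidden, 1L)
    par$mlp_b2 <- 0
    par
  })
}

mhaForwardFlat <- function(par, prefix, Q, K, nHeads) {
  dk <- ncol(par[[paste0(prefix, "_Wq", 1L)]])
  heads <- vector("list", nHeads)
  cache <- vector("list", nHeads)
  for (i in seq_len(nHeads)) {
    Qh <- Q %*% par[[paste0(prefix, "_Wq", i)]]
    Kh <- K %*% par[[paste0(prefix, "_Wk", i)]]
    Vh <- K %*% par[[paste0(prefix, "_Wv", i)]]
    P <- softmaxRows(Qh %*% t(Kh) / sqrt(dk))
    heads[[i]] <- P %*% Vh
    cache[[i]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, P = P)
  }
  Hcat <- do.call(cbind, heads)
  list(A = Hcat %*% par[[paste0(prefix, "_Wo")]], Hcat = Hcat, heads = cache)
}

mhaBackwardFlat <- function(par, prefix, dA, cache, Q, K, nHeads, grads) {
  dk <- ncol(par[[paste0(prefix, "_Wq", 1L)]])
  grads[[paste0(prefix, "_Wo")]] <- t(cache$Hcat) %*% dA
  dHcat <- dA %*% t(par[[paste0(prefix, "_Wo")]])
  for (i in seq_len(nHeads)) {
    cc <- cache$heads[[i]]
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    dH <- dHcat[, cols, drop = FALSE]
    dP <- dH %*% t(cc$Vh)
    dVh <- t(cc$P) %*% dH
    dS <- cc$P * (dP - rowSums(dP * cc$P))
    dQh <- dS %*% cc$Kh / sqrt(dk)
    dKh <- t(dS) %*% cc$Qh / sqrt(dk)
    grads[[paste0(prefix, "_Wq", i)]] <- t(Q) %*% dQh
    grads[[paste0(prefix, "_Wk", i)]] <- t(K) %*% dKh
    grads[[paste0(prefix, "_Wv", i)]] <- t(K) %*% dVh
  }
  grads
}

# full forward pass over one attention batch; returns every intermediate
# needed by the backward pass
modelForwardBatch <- function(par, combo, Xgd, Xm, Xl, cfg, dropMask = NULL) {
  br <- comboBranches(combo)
  mha <- list()
  blocks <- list()
  for (b in br) {
    Xq <- if (b == "m") Xm else Xl
    mha[[b]] <- mhaForwardFlat(par, b, Xq, Xgd, cfg$nHeads)
    blocks[[b]] <- mha[[b]]$A
  }
  C <- do.call(cbind, c(unname(blocks), list(Xgd)))
  F1 <- sweep(C %*% par$fuse_W, 2L, par$fuse_b, "+")
  S1 <- sweep(F1 %*% t(par$att_W), 2L, par$att_b, "+")
  T1 <- tanh(S1)
  U <- T1 %*% t(par$att_H)
  Alpha <- softmaxRows(U)
  R <- Alpha * F1
  A1 <- sweep(R %*% par$mlp_W1, 2L, par$mlp_b1, "+")
  H1 <- relu(A1)
  D <- if (is.null(dropMask)) H1 else H1 * dropMask
  z <- as.numeric(D %*% par$mlp_W2 + par$mlp_b2)
  list(mha = mha, C = C, F1 = F1, T1 = T1, Alpha = Alpha, R = R, A1 = A1,
       H1 = H1, D = D, z = z, p = sigmoid(z))
}

modelBackwardBatch <- function(par, combo, fw, y, Xgd, Xm, Xl, cfg,
                               dropMask = NULL) {
  n <- length(y)
  grads <- list()
  dz <- matrix((fw$p - y) / n, ncol = 1L)
  grads$mlp_W2 <- t(fw$D) %*% dz
  grads$mlp_b2 <- sum(dz)
  dD <- dz %*% t(par$mlp_W2)
  dH1 <- if (is.null(dropMask)) dD else dD * dropMask
  dA1 <- dH1 * (fw$A1 > 0)
  grads$mlp_W1 <- t(fw$R) %*% dA1
  grads$mlp_b1 <- colSums(dA1)
  dR <- dA1 %*% t(par$mlp_W1)
  dAlpha <- dR * fw$F1
  dF1 <- dR * fw$Alpha
  dU <- fw$Alpha * (dAlpha - rowSums(dAlpha * fw$Alpha))
  grads$att_H <- t(dU) %*% fw$T1
  dT1 <- dU %*% par$att_H
  dS1 <- dT1 * (1 - fw$T1^2)
  grads$att_W <- t(dS1) %*% fw$F1
  grads$att_b <- colSums(dS1)
  dF1 <- dF1 + dS1 %*% par$att_W
  grads$fuse_W <- t(fw$C) %*% dF1
  grads$fuse_b <- colSums(dF1)
  dC <- dF1 %*% t(par$fuse_W)
  br <- comboBranches(combo)
  dModel <- ncol(Xgd)
  for (i in seq_along(br)) {
    b <- br[i]
    cols <- ((i - 1L) * dModel + 1L):(i * dModel)
    Xq <- if (b == "m") Xm else Xl
    grads <- mhaBackwardFlat(par, b, dC[, cols, drop = FALSE], fw$mha[[b]],
                             Xq, Xgd, cfg$nHeads, grads)
  }
  grads
}

# evaluation-mode loss + analytic gradients over the full data in one
# attention block; used by the finite-difference gradient check
fullLossGrad <- function(par, combo, Xgd, Xm, Xl, y, cfg) {
  fw <- modelForwardBatch(par, combo, Xgd, Xm, Xl, cfg)
  loss <- mean(softplus(fw$z) - y * fw$z)
  grads <- modelBackwardBatch(par, combo, fw, y, Xgd, Xm, Xl, cfg)
  list(loss = loss, grads = grads)
}

featMat <- function(x) {
  if (is(x, "PairFeatureMatrix")) x@features else if (is.null(x)) NULL
  else as.matrix(x)
}

#' Train the fusion + self-attention + MLP scorer end-to-end
#'
#' Minimizes binary cross-entropy by Adam over every parameter group:
#' the per-branch multi-head attention projections, the fusion affine map,
#' the element-wise self-attention parameters, and the MLP. Mini-batches are
#' seeded-shuffled each epoch; attention is computed within each mini-batch.
#' Gradients are clipped at global norm \code{clipNorm}.
#'
#' @param gd,gmd,gld [PairFeatureMatrix-class] objects (or matrices) aligned
#'   to one shared pair list; \code{gmd}/\code{gld} may be \code{NULL} for
#'   combinations excluding them.
#' @param labels 0/1 vector, one per pair.
#' @param config a [trainConfig()].
#' @param combo network combination (see [initFusionParams()]); branches for
#'   excluded auxiliary networks are absent from the model, not zeroed.
#' @return a [TrainedModel-class].
#' @export
trainModel <- function(gd, gmd = NULL, gld = NULL, labels,
                       config = trainConfig(), combo = "GD+GMD+GLD") {
  Xgd <- featMat(gd); Xm <- featMat(gmd); Xl <- featMat(gld)
  br <- comboBranches(combo)
  if ("m" %in% br && is.null(Xm)) stop("combo requires GMD features")
  if ("l" %in% br && is.null(Xl)) stop("combo requires GLD features")
  for (X in list(Xm, Xl))
    if (!is.null(X) && !identical(dim(X), dim(Xgd)))
      stop("pair feature matrices must share shape")
  n <- nrow(Xgd)
  if (length(labels) != n) stop("labels must align with pairs")
  pre <- list()
  if (isTRUE(config$standardize)) {
    pre$gd <- fitStandardizer(Xgd)
    Xgd <- applyStandardizer(Xgd, pre$gd)
    if (!is.null(Xm)) {
      pre$gmd <- fitStandardizer(Xm)
      Xm <- applyStandardizer(Xm, pre$gmd)
    }
    if (!is.null(Xl)) {
      pre$gld <- fitStandardizer(Xl)
      Xl <- applyStandardizer(Xl, pre$gld)
    }
  }
  par <- initModelParams(ncol(Xgd), config, combo)
  mAdam <- lapply(par, function(p) p * 0)
  vAdam <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tAdam <- 0L
  lossHist <- numeric(config$epochs)
  withSeed(deriveSeed(config$seed, 13L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      epLoss <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(n, starts[bi] + config$batchSize - 1L)]
        bXgd <- Xgd[idx, , drop = FALSE]
        bXm <- if (!is.null(Xm)) Xm[idx, , drop = FALSE]
        bXl <- if (!is.null(Xl)) Xl[idx, , drop = FALSE]
        y <- labels[idx]
        mask <- if (config$dropout > 0)
          matrix(runif(length(idx) * config$hidden) >= config$dropout,
                 length(idx)) / (1 - config$dropout)
        fw <- modelForwardBatch(par, combo, bXgd, bXm, bXl, config, mask)
        loss <- mean(softplus(fw$z) - y * fw$z)
        if (!is.finite(loss))
          stop(sprintf("NaN loss at epoch %d, batch %d", ep, bi))
        epLoss <- epLoss + loss * length(idx)
        grads <- modelBackwardBatch(par, combo, fw, y, bXgd, bXm, bXl,
                                    config, mask)
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        scale <- if (gnorm > config$clipNorm) config$clipNorm / gnorm else 1
        tAdam <- tAdam + 1L
        corr <- sqrt(1 - b2^tAdam) / (1 - b1^tAdam)
        for (nm in names(grads)) {
          g <- grads[[nm]] * scale
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
          par[[nm]] <- par[[nm]] - config$learningRate * corr *
            mAdam[[nm]] / (sqrt(vAdam[[nm]]) + epsA)
        }
      }
      lossHist[ep] <- epLoss / n
    }
  })
  new("TrainedModel", params = par, config = unclass(config), combo = combo,
      preprocess = pre, lossHistory = lossHist)
}

#' Score gene--disease pairs with a trained model
#'
#' Deterministic evaluation-mode forward pass (dropout off). Pairs are
#' processed in sequential attention blocks of the training batch size, in
#' the order of the supplied pair list.
#'
#' @param model a [TrainedModel-class].
#' @param gd,gmd,gld aligned pair feature matrices.
#' @param batchSize attention block size (default: the training batch size).
#' @return numeric vector of association scores in [0, 1].
#' @export
predictScores <- function(model, gd, gmd = NULL, gld = NULL,
                          batchSize = NULL) {
  stopifnot(is(model, "TrainedModel"))
  Xgd <- featMat(gd); Xm <- featMat(gmd); Xl <- featMat(gld)
  br <- comboBranches(model@combo)
  if ("m" %in% br && is.null(Xm)) stop("model requires GMD features")
  if ("l" %in% br && is.null(Xl)) stop("model requires GLD features")
  cfg <- model@config
  if (nrow(model@params$fuse_W) != (length(br) + 1L) * ncol(Xgd))
    stop("feature width does not match the model")
  Xgd <- applyStandardizer(Xgd, model@preprocess$gd)
  Xm <- applyStandardizer(Xm, model@preprocess$gmd)
  Xl <- applyStandardizer(Xl, model@preprocess$gld)
  bs <- batchSize %||% cfg$batchSize
  n <- nrow(Xgd)
  scores <- numeric(n)
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(n, s + bs - 1L)
    fw <- modelForwardBatch(model@params, model@combo,
                            Xgd[idx, , drop = FALSE],
                            if (!is.null(Xm)) Xm[idx, , drop = FALSE],
                            if (!is.null(Xl)) Xl[idx, , drop = FALSE], cfg)
    scores[idx] <- fw$p
  }
  scores
}
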