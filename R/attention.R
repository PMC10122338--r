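#' Scaled dot-product attention
#'
#' Computes \eqn{Softmax(QK^\top/\sqrt{d_k})\,V} with the softmax applied
#' row-wise, so each row of the attention-weight matrix is a probability
#' vector over the m key rows.
#'
#' @param Q n x d_k query matrix.
#' @param K m x d_k key matrix.
#' @param V m x d_v value matrix.
#' @param returnWeights also return the attention-weight matrix.
#' @return n x d_v output matrix, or (with \code{returnWeights = TRUE}) a
#'   list with elements \code{output} and \code{weights}.
#' @examples
#' scaledDotAttention(matrix(c(1, 0), 1), diag(2), diag(2))
#' @export
scaledDotAttention <- function(Q, K, V, returnWeights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) == 0L) stop("d_k must be positive")
  if (nrow(K) == 0L) stop("attention needs at least one key")
  if (ncol(Q) != ncol(K)) stop("Q and K must share column count d_k")
  if (nrow(K) != nrow(V)) stop("K and V must share row count")
  W <- softmaxRows(Q %*% t(K) / sqrt(ncol(Q)))
  out <- W %*% V
  if (returnWeights) list(output = out, weights = W) else out
}

#' Initialize multi-head attention parameters
#'
#' Seeded uniform initialization scaled by \eqn{1/\sqrt{fan_{in}}}. Per-head
#' projection width is \eqn{d_k = d_v = d_{model}/h}.
#'
#' @param dModel input/output feature width.
#' @param nHeads number of heads h (must divide \code{dModel}).
#' @param seed integer seed.
#' @return list with elements \code{Wq}, \code{Wk}, \code{Wv} (each a list
#'   of h \code{dModel x dModel/h} matrices) and \code{Wo}
#'   (\code{dModel x dModel}).
#' @export
initMultiHeadParams <- function(dModel, nHeads = 8, seed = 1) {
  if (dModel %% nHeads != 0)
    stop("configuration error: dModel must be divisible by nHeads")
  dk <- dModel %/% nHeads
  withSeed(seed, {
    rmat <- function(nr, nc) {
      s <- 1 / sqrt(nr)
      matrix(runif(nr * nc, -s, s), nr, nc)
    }
    list(Wq = lapply(seq_len(nHeads), function(i) rmat(dModel, dk)),
         Wk = lapply(seq_len(nHeads), function(i) rmat(dModel, dk)),
         Wv = lapply(seq_len(nHeads), function(i) rmat(dModel, dk)),
         Wo = rmat(dModel, dModel))
  })
}

#' Multi-head attention
#'
#' \eqn{head_i = Attention(QW_i^Q, KW_i^K, VW_i^V)};
#' \eqn{MultiHead(Q,K,V) = Concat(head_1,\dots,head_h)\,W^O}. Output shape
#' equals Q's shape.
#'
#' @param Q,K,V matrices with \code{dModel} columns.
#' @param params as produced by [initMultiHeadParams()].
#' @return matrix of the same shape as \code{Q}.
#' @export
multiHeadAttention <- function(Q, K, V, params) {
  h <- length(params$Wq)
  heads <- lapply(seq_len(h), function(i)
    scaledDotAttention(Q %*% params$Wq[[i]], K %*% params$Wk[[i]],
                       V %*% params$Wv[[i]]))
  do.call(cbind, heads) %*% params$Wo
}

#' Initialize fusion parameters
#'
#' One multi-head attention branch per auxiliary network present in the
#' combination (miRNA branch for GMD, lncRNA branch for GLD) plus the final
#' affine map of the concatenated block onto \code{dF} features.
#'
#' @param dModel pair-feature width 4e.
#' @param dF fused feature width (default 128).
#' @param combo network combination: \code{"GD"}, \code{"GD+GMD"},
#'   \code{"GD+GLD"} or \code{"GD+GMD+GLD"}.
#' @param nHeads heads per branch.
#' @param seed integer seed.
#' @return list with elements \code{branches} (named sub-list of
#'   [initMultiHeadParams()] outputs, names among \code{"m"}, \code{"l"}),
#'   \code{W} and \code{b}.
#' @export
initFusionParams <- function(dModel, dF = 128, combo = "GD+GMD+GLD",
                             nHeads = 8, seed = 1) {
  br <- comboBranches(combo)
  branches <- list()
  for (i in seq_along(br))
    branches[[br[i]]] <- initMultiHeadParams(dModel, nHeads,
                                             deriveSeed(seed, 50L + i))
  nIn <- (length(br) + 1L) * dModel
  W <- withSeed(deriveSeed(seed, 60L), {
    s <- 1 / sqrt(nIn)
    matrix(runif(nIn * dF, -s, s), nIn, dF)
  })
  list(branches = branches, W = W, b = numeric(dF))
}

comboBranches <- function(combo) {
  switch(combo,
         "GD" = character(0),
         "GD+GMD" = "m",
         "GD+GLD" = "l",
         "GD+GMD+GLD" = c("m", "l"),
         stop("unknown network combination: ", combo))
}

#' Fuse pair features from the three networks
#'
#' Queries derived from the auxiliary features attend over the gene--disease
#' features of the pairs in the same mini-batch (each pair-row is a token):
#' \deqn{A_m = MultiHead(X_{gmd}, X_{gd}, X_{gd}), \quad
#'       A_l = MultiHead(X_{gld}, X_{gd}, X_{gd})}
#' and the fused matrix is the affine map of
#' \eqn{concat(A_m, A_l, X_{gd})}. With \code{batchSize >= n} the full
#' attention over all pairs is recovered.
#'
#' @param gd,gmd,gld [PairFeatureMatrix-class] objects (or plain matrices)
#'   sharing n and width 4e; \code{gmd}/\code{gld} may be \code{NULL} when
#'   the combination excludes them.
#' @param params as produced by [initFusionParams()].
#' @param batchSize attention batch size (default \code{Inf}: all pairs in
#'   one block).
#' @return n x dF fused matrix.
#' @export
fuseFeatures <- function(gd, gmd = NULL, gld = NULL, params,
                         batchSize = Inf) {
  Xgd <- if (is(gd, "PairFeatureMatrix")) gd@features else as.matrix(gd)
  aux <- list(
    m = if (!is.null(gmd)) {
      if (is(gmd, "PairFeatureMatrix")) gmd@features else as.matrix(gmd)
    },
    l = if (!is.null(gld)) {
      if (is(gld, "PairFeatureMatrix")) gld@features else as.matrix(gld)
    })
  for (b in names(params$branches)) {
    if (is.null(aux[[b]]))
      stop("combination requires the ", if (b == "m") "GMD" else "GLD",
           " feature matrix")
    if (!identical(dim(aux[[b]]), dim(Xgd)))
      stop("pair feature matrices must share shape")
  }
  n <- nrow(Xgd)
  out <- matrix(0, n, ncol(params$W))
  starts <- seq(1L, n, by = if (is.finite(batchSize)) batchSize else n)
  for (s in starts) {
    idx <- s:min(n, s + (if (is.finite(batchSize)) batchSize else n) - 1L)
    blocks <- list()
    for (b in names(params$branches))
      blocks[[b]] <- multiHeadAttention(aux[[b]][idx, , drop = FALSE],
                                        Xgd[idx, , drop = FALSE],
                                        Xgd[idx, , drop = FALSE],
                                        params$branches[[b]])
    C <- do.call(cbind, c(unname(blocks), list(Xgd[idx, , drop = FALSE])))
    out[idx, ] <- sweep(C %*% params$W, 2L, params$b, "+")
  }
  out
}
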