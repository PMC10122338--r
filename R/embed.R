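#' Embedding configuration
#'
#' Hyperparameters shared by the two graph-representation learners. The
#' embedding dimension \code{e} must be even: LINE spends \code{e/2}
#' dimensions on its first-order (direct edge) objective and \code{e/2} on
#' its second-order (shared neighborhood) objective. \code{p} and \code{q}
#' are the node2vec return and in-out parameters biasing the second-order
#' random walk.
#'
#' @param e embedding dimension (even, >= 2).
#' @param p return parameter (> 0): small p makes the walk likely to step
#'   back to the node it just came from.
#' @param q in-out parameter (> 0): small q pushes the walk outward
#'   (DFS-like), large q keeps it local (BFS-like).
#' @param walksPerNode walks started per node.
#' @param walkLength maximum walk length.
#' @param window skip-gram context window.
#' @param epochs training passes over the walk corpus (node2vec) and the
#'   multiplier for LINE's edge-sample budget.
#' @param negativeSamples negative samples per positive.
#' @param learningRate initial SGD learning rate (linearly decayed).
#' @param seed integer seed controlling all sampling and initialization.
#' @return list of class \code{EmbedConfig}.
#' @export
embedConfig <- function(e = 64, p = 1, q = 1, walksPerNode = 10,
                        walkLength = 80, window = 5, epochs = 5,
                        negativeSamples = 5, learningRate = 0.025,
                        seed = 1) {
  if (e < 2 || e %% 2 != 0) stop("configuration error: e must be even and >= 2")
  if (p <= 0 || q <= 0) stop("configuration error: p and q must be > 0")
  if (walkLength < 1 || walksPerNode < 1)
    stop("configuration error: walk settings must be positive")
  structure(list(e = e, p = p, q = q, walksPerNode = walksPerNode,
                 walkLength = walkLength, window = window, epochs = epochs,
                 negativeSamples = negativeSamples,
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "EmbedConfig")
}

# sorted 0-based-friendly adjacency from the undirected edge table
adjacencyList <- function(net) {
  ids <- net@nodes$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  ed <- net@edges
  if (nrow(ed)) {
    ui <- idx[ed$u]; vi <- idx[ed$v]
    both <- data.frame(a = c(ui, vi), b = c(vi, ui), w = c(ed$weight, ed$weight))
    both <- both[order(both$a, both$b), ]
    sp <- split(both[, c("b", "w")], both$a)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      adj[[i]] <- sp[[nm]]$b - 1L       # 0-based, sorted
      wts[[i]] <- sp[[nm]]$w
    }
  }
  list(ids = ids, adj = adj, wts = wts)
}

#' Generate second-order biased random walks
#'
#' Starts \code{walksPerNode} walks from every node. From current node v,
#' reached from t, the unnormalized probability of stepping to neighbor x is
#' the edge weight w(v, x) times 1/p if x = t, times 1 if x is also a
#' neighbor of t, and times 1/q otherwise. An isolated node yields walks of
#' length 1. Fully deterministic given \code{cfg$seed}.
#'
#' @param net a [HeteroNetwork-class].
#' @param cfg an [embedConfig()].
#' @return list of class \code{WalkCorpus} with elements \code{walks} (list
#'   of node-id character vectors) and \code{layer}.
#' @export
generateWalks <- function(net, cfg = embedConfig()) {
  stopifnot(is(net, "HeteroNetwork"), inherits(cfg, "EmbedConfig"))
  if (!nrow(net@nodes)) stop("network has no nodes")
  al <- adjacencyList(net)
  raw <- cpp_node2vec_walks(al$adj, al$wts, cfg$p, cfg$q, cfg$walksPerNode,
                            cfg$walkLength, deriveSeed(cfg$seed, 11L))
  walks <- lapply(raw, function(w) al$ids[w])
  structure(list(walks = walks, layer = net@layer, ids = al$ids),
            class = "WalkCorpus")
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (unigram^0.75 noise distribution,
#' linearly decayed learning rate), single-threaded and seeded so repeated
#' runs are bit-identical. A node present in \code{net} but absent from
#' every walk receives a seeded random vector with a warning.
#'
#' @param corpus result of [generateWalks()].
#' @param cfg an [embedConfig()].
#' @param net optional source network; when supplied, its full node set
#'   defines the vocabulary (covering corpus-absent nodes).
#' @return a [NodeEmbedding-class] with \code{algorithm = "node2vec"}.
#' @export
trainSkipgram <- function(corpus, cfg = embedConfig(), net = NULL) {
  stopifnot(inherits(corpus, "WalkCorpus"))
  if (!length(corpus$walks)) stop("empty walk corpus")
  ids <- if (!is.null(net)) net@nodes$id else corpus$ids
  idx <- setNames(seq_along(ids), ids)
  walksIdx <- lapply(corpus$walks, function(w) unname(idx[w]))
  emb <- cpp_train_sgns(walksIdx, length(ids), cfg$e, cfg$window,
                        cfg$negativeSamples, cfg$epochs, cfg$learningRate,
                        deriveSeed(cfg$seed, 23L))
  seen <- ids %in% unique(unlist(corpus$walks, use.names = FALSE))
  if (any(!seen)) {
    warning(sum(!seen), " node(s) absent from all walks; seeded random ",
            "vectors assigned")
    emb[!seen, ] <- withSeed(deriveSeed(cfg$seed, 29L),
                             matrix(runif(sum(!seen) * cfg$e, -0.5, 0.5) /
                                      cfg$e, ncol = cfg$e))
  }
  rownames(emb) <- ids
  new("NodeEmbedding", algorithm = "node2vec", layer = corpus$layer,
      vectors = emb)
}

#' Train LINE embeddings on a network
#'
#' Optimizes first-order proximity (the sigmoid of the dot product of
#' endpoint vectors, with weighted negative sampling) on \code{e/2}
#' dimensions and second-order proximity (separate context vectors) on the
#' other \code{e/2}, concatenating the two halves. Edges are sampled with
#' probability proportional to weight. Deterministic given \code{cfg$seed}.
#'
#' @param net a [HeteroNetwork-class] with at least one edge.
#' @param cfg an [embedConfig()].
#' @return a [NodeEmbedding-class] with \code{algorithm = "line"}.
#' @export
trainLine <- function(net, cfg = embedConfig()) {
  stopifnot(is(net, "HeteroNetwork"), inherits(cfg, "EmbedConfig"))
  ed <- net@edges
  if (!nrow(ed)) stop("LINE requires a network with edges")
  ids <- net@nodes$id
  idx <- setNames(seq_along(ids), ids)
  eu <- unname(idx[ed$u]) - 1L
  ev <- unname(idx[ed$v]) - 1L
  nSamples <- max(5000, cfg$epochs * nrow(ed) * 5)
  half <- cfg$e %/% 2L
  v1 <- cpp_train_line(eu, ev, ed$weight, length(ids), half, 1L, nSamples,
                       cfg$negativeSamples, cfg$learningRate,
                       deriveSeed(cfg$seed, 37L))
  v2 <- cpp_train_line(eu, ev, ed$weight, length(ids), half, 2L, nSamples,
                       cfg$negativeSamples, cfg$learningRate,
                       deriveSeed(cfg$seed, 41L))
  hist <- list(order1 = attr(v1, "lossHistory"),
               order2 = attr(v2, "lossHistory"))
  emb <- cbind(as.matrix(v1), as.matrix(v2))
  rownames(emb) <- ids
  attr(emb, "lossHistory") <- hist
  new("NodeEmbedding", algorithm = "line", layer = net@layer, vectors = emb)
}

#' Sampled training-loss history of a LINE embedding
#'
#' The per-sample negative-sampling objective averaged over ten equal bins
#' of the training run, per proximity order. Training is healthy when the
#' last bin is below the first.
#'
#' @param emb a LINE [NodeEmbedding-class] from [trainLine()].
#' @return list with numeric vectors \code{order1} and \code{order2}.
#' @export
lineLossHistory <- function(emb) {
  stopifnot(is(emb, "NodeEmbedding"), emb@algorithm == "line")
  attr(emb@vectors, "lossHistory")
}

#' LINE first-order objective on a full edge set
#'
#' The expected negative-sampling objective
#' \deqn{-\sum_e w_e [\log\sigma(u_i^\top u_j) + k\, E_{j' \sim P_n}
#'   \log\sigma(-u_i^\top u_{j'})]}
#' with the expectation over the noise distribution (weighted degree^0.75)
#' evaluated exactly. Used to verify that training decreases the loss.
#'
#' @param emb a [NodeEmbedding-class] (the first \code{e/2} columns hold the
#'   first-order half) or a plain matrix with node-id rownames.
#' @param net the network.
#' @param negativeSamples k in the objective.
#' @return scalar loss.
#' @export
lineFirstOrderLoss <- function(emb, net, negativeSamples = 5) {
  v <- if (is(emb, "NodeEmbedding")) {
    half <- ncol(emb@vectors) %/% 2L
    emb@vectors[, seq_len(half), drop = FALSE]
  } else emb
  ed <- net@edges
  ids <- rownames(v)
  deg <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(ed))) {
    deg[ed$u[i]] <- deg[ed$u[i]] + ed$weight[i]
    deg[ed$v[i]] <- deg[ed$v[i]] + ed$weight[i]
  }
  noise <- deg^0.75; noise <- noise / sum(noise)
  loss <- 0
  for (i in seq_len(nrow(ed))) {
    ui <- v[ed$u[i], ]; vj <- v[ed$v[i], ]
    pos <- log(sigmoid(sum(ui * vj)) + 1e-12)
    negdots <- as.numeric(v %*% ui)
    neg <- sum(noise * log(sigmoid(-negdots) + 1e-12))
    loss <- loss - ed$weight[i] * (pos + negativeSamples * neg)
  }
  loss
}

#' Assemble gene--disease pair features for one layer
#'
#' Row i of the result is the concatenation
#' \code{[n2v(gene_i), n2v(disease_i), line(gene_i), line(disease_i)]},
#' giving 4e columns. A pair endpoint missing from an embedding (a
#' cold-start node with no edges in this layer) is imputed with the zero
#' vector and recorded in the \code{imputed} slot, preserving row alignment
#' across the three layers; with \code{strict = TRUE} it is an error.
#'
#' @param pairs data.frame with columns \code{gene}, \code{disease}; no
#'   duplicate pairs.
#' @param embN2v,embLine [NodeEmbedding-class] objects from the same layer
#'   with equal dimension.
#' @param strict error on missing endpoints instead of zero-imputing.
#' @return a [PairFeatureMatrix-class].
#' @export
assemblePairFeatures <- function(pairs, embN2v, embLine, strict = FALSE) {
  stopifnot(is(embN2v, "NodeEmbedding"), is(embLine, "NodeEmbedding"))
  if (embN2v@layer != embLine@layer)
    stop("embeddings come from different layers")
  e <- ncol(embN2v@vectors)
  if (e != ncol(embLine@vectors))
    stop("embedding dimensions differ")
  if (anyDuplicated(paste(pairs$gene, pairs$disease)))
    stop("duplicate (gene, disease) pairs")
  lookup <- function(emb, id) {
    v <- emb@vectors
    out <- matrix(0, length(id), ncol(v))
    hit <- id %in% rownames(v)
    if (any(hit)) out[hit, ] <- v[id[hit], , drop = FALSE]
    list(mat = out, missing = unique(id[!hit]))
  }
  g1 <- lookup(embN2v, pairs$gene);  d1 <- lookup(embN2v, pairs$disease)
  g2 <- lookup(embLine, pairs$gene); d2 <- lookup(embLine, pairs$disease)
  missing <- unique(c(g1$missing, d1$missing, g2$missing, d2$missing))
  if (strict && length(missing))
    stop("pair endpoint(s) missing from embedding: ",
         paste(missing, collapse = ", "))
  mat <- cbind(g1$mat, d1$mat, g2$mat, d2$mat)
  rownames(mat) <- NULL
  new("PairFeatureMatrix", layer = embN2v@layer, features = mat,
      pairs = as.data.frame(pairs)[, c("gene", "disease")],
      imputed = as.character(missing))
}

#' Embed one network with both algorithms
#'
#' Convenience wrapper running [generateWalks()] + [trainSkipgram()] and
#' [trainLine()] on the same network with the same configuration.
#'
#' @param net a [HeteroNetwork-class].
#' @param cfg an [embedConfig()].
#' @return list with elements \code{node2vec} and \code{line}.
#' @export
embedNetwork <- function(net, cfg = embedConfig()) {
  corpus <- generateWalks(net, cfg)
  list(node2vec = trainSkipgram(corpus, cfg, net = net),
       line = trainLine(net, cfg))
}

## serialization ------------------------------------------------------------

#' Read / write node embeddings as tab-separated text
#'
#' Format: one header comment line
#' \code{#algorithm=<a> layer=<l> e=<e>}, then rows
#' \code{node_id<TAB>v1<TAB>...<TAB>ve}.
#'
#' @param emb a [NodeEmbedding-class].
#' @param path file path.
#' @return \code{writeEmbedding}: the path, invisibly; \code{readEmbedding}:
#'   a [NodeEmbedding-class].
#' @export
writeEmbedding <- function(emb, path) {
  stopifnot(is(emb, "NodeEmbedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#algorithm=%s layer=%s e=%d", emb@algorithm,
                     emb@layer, ncol(emb@vectors)), con)
  write.table(data.frame(id = rownames(emb@vectors),
                         format(emb@vectors, digits = 17, trim = TRUE,
                                scientific = TRUE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("#algorithm=(\\S+) layer=(\\S+) e=(\\d+)", hdr))[[1]]
  if (length(m) != 4L) stop("not an embedding file: ", path)
  tab <- read.delim(path, header = FALSE, skip = 1L,
                    stringsAsFactors = FALSE)
  vec <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(vec) <- list(tab[[1L]], NULL)
  new("NodeEmbedding", algorithm = m[2], layer = m[3], vectors = vec)
}
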