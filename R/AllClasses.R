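#' @include utils.R
NULL

## relation vocabulary ------------------------------------------------------

RELATIONS <- c("gene_gene", "disease_disease", "gene_disease",
               "gene_mirna", "disease_mirna",
               "gene_lncrna", "disease_lncrna")

# endpoint kinds by column position (source, target)
RELATION_KINDS <- list(
  gene_gene       = c("gene", "gene"),
  disease_disease = c("disease", "disease"),
  gene_disease    = c("gene", "disease"),
  gene_mirna      = c("gene", "miRNA"),
  disease_mirna   = c("disease", "miRNA"),
  gene_lncrna     = c("gene", "lncRNA"),
  disease_lncrna  = c("disease", "lncRNA")
)

LAYER_RELATIONS <- list(
  GD  = c("gene_gene", "disease_disease", "gene_disease"),
  GMD = c("gene_mirna", "disease_mirna"),
  GLD = c("gene_lncrna", "disease_lncrna")
)

LAYER_KINDS <- list(
  GD  = c("gene", "disease"),
  GMD = c("gene", "miRNA", "disease"),
  GLD = c("gene", "lncRNA", "disease")
)

NODE_KINDS <- c("gene", "disease", "lncRNA", "miRNA")

#' Heterogeneous biological network
#'
#' An undirected, weighted graph over typed biological nodes (gene, disease,
#' lncRNA, miRNA). A network carries a layer label: \code{"GD"}
#' (gene--disease, built from gene functional similarity, disease semantic
#' similarity and gene--disease associations), \code{"GMD"}
#' (gene--miRNA--disease) or \code{"GLD"} (gene--lncRNA--disease). Edges are
#' stored once per unordered endpoint pair with a strictly positive weight;
#' self-loops are never stored.
#'
#' @slot layer character, one of \code{"GD"}, \code{"GMD"}, \code{"GLD"}.
#' @slot nodes data.frame with columns \code{id}, \code{kind}.
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{weight},
#'   \code{relation}.
#'
#' @seealso [buildNetwork()], [summarizeNetwork()]
#' @export
setClass("HeteroNetwork",
  representation(layer = "character", nodes = "data.frame",
                 edges = "data.frame"))

setValidity("HeteroNetwork", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% names(LAYER_RELATIONS))
    msg <- c(msg, "layer must be one of GD, GMD, GLD")
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "kind") %in% names(nd)))
    msg <- c(msg, "nodes needs columns id, kind")
  if (!all(c("u", "v", "weight", "relation") %in% names(ed)))
    msg <- c(msg, "edges needs columns u, v, weight, relation")
  if (length(msg)) return(msg)
  if (anyDuplicated(nd$id))
    msg <- c(msg, "duplicate node ids")
  if (any(!nzchar(nd$id)))
    msg <- c(msg, "empty node id")
  allowed <- LAYER_KINDS[[object@layer]]
  if (length(allowed) && nrow(nd) && !all(nd$kind %in% allowed))
    msg <- c(msg, sprintf("layer %s admits only kinds: %s", object@layer,
                          paste(allowed, collapse = ", ")))
  if (nrow(ed)) {
    if (any(ed$weight <= 0)) msg <- c(msg, "edge weights must be > 0")
    if (any(ed$u == ed$v)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(ed$u, ed$v) %in% nd$id))
      msg <- c(msg, "edge endpoint missing from node set")
    if (!all(ed$relation %in% LAYER_RELATIONS[[object@layer]]))
      msg <- c(msg, sprintf("relation not allowed in layer %s", object@layer))
    key <- ifelse(ed$u < ed$v, paste(ed$u, ed$v), paste(ed$v, ed$u))
    if (anyDuplicated(paste(ed$relation, key)))
      msg <- c(msg, "duplicate undirected edges")
  }
  if (length(msg)) msg else TRUE
})

#' Node embedding learned from one heterogeneous network
#'
#' Maps every embedded node id to a real vector of fixed length, learned by
#' one of the two graph-representation algorithms (node2vec or LINE) on one
#' network layer.
#'
#' @slot algorithm \code{"node2vec"} or \code{"line"}.
#' @slot layer the source network layer.
#' @slot vectors numeric matrix, one row per node, rownames are node ids.
#' @export
setClass("NodeEmbedding",
  representation(algorithm = "character", layer = "character",
                 vectors = "matrix"))

setValidity("NodeEmbedding", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("node2vec", "line"))
    msg <- c(msg, "algorithm must be node2vec or line")
  if (!object@layer %in% names(LAYER_RELATIONS))
    msg <- c(msg, "unknown layer")
  v <- object@vectors
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "vectors must have node-id rownames")
  if (nrow(v) && !all(is.finite(v)))
    msg <- c(msg, "vectors must be finite")
  if (length(msg)) msg else TRUE
})

#' Gene--disease pair feature matrix for one network layer
#'
#' For a shared ordered list of (gene, disease) pairs, row i concatenates the
#' node2vec embeddings of gene and disease with their LINE embeddings, giving
#' a 4e-column feature row per pair (e = embedding dimension).
#'
#' @slot layer source network layer.
#' @slot features numeric n x 4e matrix, rows aligned with \code{pairs}.
#' @slot pairs data.frame with columns \code{gene}, \code{disease}.
#' @slot imputed character vector of node ids that were absent from an
#'   embedding and zero-imputed (cold-start nodes).
#' @export
setClass("PairFeatureMatrix",
  representation(layer = "character", features = "matrix",
                 pairs = "data.frame", imputed = "character"))

setValidity("PairFeatureMatrix", function(object) {
  msg <- character()
  if (!object@layer %in% names(LAYER_RELATIONS))
    msg <- c(msg, "unknown layer")
  if (nrow(object@features) != nrow(object@pairs))
    msg <- c(msg, "feature rows must match number of pairs")
  if (ncol(object@features) %% 4L != 0L)
    msg <- c(msg, "feature width must be 4e")
  if (length(object@features) && !all(is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (anyDuplicated(paste(object@pairs$gene, object@pairs$disease)))
    msg <- c(msg, "duplicate (gene, disease) pairs")
  if (length(msg)) msg else TRUE
})

#' Trained association-scoring model
#'
#' Holds every learned parameter array of the fusion + self-attention + MLP
#' scorer, the training configuration, the network combination it was trained
#' for, and the per-epoch training-loss history.
#'
#' @slot params named list of numeric parameter arrays.
#' @slot config training configuration (see [trainConfig()]).
#' @slot combo network combination, e.g. \code{"GD+GMD+GLD"}.
#' @slot preprocess per-layer feature standardizers fitted on the training
#'   set (empty when standardization is off).
#' @slot lossHistory numeric vector, one mean training loss per epoch.
#' @export
setClass("TrainedModel",
  representation(params = "list", config = "list", combo = "character",
                 preprocess = "list", lossHistory = "numeric"))

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (!all(vapply(object@params, function(p) all(is.finite(p)), logical(1))))
    msg <- c(msg, "non-finite model parameter")
  if (length(msg)) msg else TRUE
})

#' Cross-validated metric report
#'
#' Per-fold values of AUC, AUPR, accuracy, precision, recall and F1 over
#' folds x repeats, with mean and standard deviation summaries.
#'
#' @slot folds data.frame with columns \code{repeat_}, \code{fold} and one
#'   column per metric.
#' @slot k number of folds.
#' @slot repeats number of random-sampling repeats.
#' @export
setClass("MetricReport",
  representation(folds = "data.frame", k = "numeric", repeats = "numeric"))

## show methods -------------------------------------------------------------

setMethod("show", "HeteroNetwork", function(object) {
  s <- summarizeNetwork(object)
  cat(sprintf("HeteroNetwork [%s]: %d nodes, %d edges\n", object@layer,
              nrow(object@nodes), nrow(object@edges)))
  kinds <- s$nodes
  cat("  nodes:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "),
      "\n")
  rel <- s$relations
  if (length(rel))
    cat("  edges:", paste(sprintf("%s=%d", names(rel), rel), collapse = ", "),
        "\n")
})

setMethod("show", "NodeEmbedding", function(object) {
  cat(sprintf("NodeEmbedding [%s/%s]: %d nodes x %d dims\n", object@layer,
              object@algorithm, nrow(object@vectors), ncol(object@vectors)))
})

setMethod("show", "PairFeatureMatrix", function(object) {
  cat(sprintf("PairFeatureMatrix [%s]: %d pairs x %d features",
              object@layer, nrow(object@features), ncol(object@features)))
  if (length(object@imputed))
    cat(sprintf(" (%d cold-start nodes zero-imputed)", length(object@imputed)))
  cat("\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel [%s]: %d parameter arrays, %d epochs trained\n",
              object@combo, length(object@params),
              length(object@lossHistory)))
  if (length(object@lossHistory))
    cat(sprintf("  final training loss: %.4f\n",
                tail(object@lossHistory, 1L)))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d-fold CV x %d repeat(s)\n", object@k,
              object@repeats))
  print(metricSummary(object), row.names = FALSE)
})

## accessors ----------------------------------------------------------------

#' Accessors for hetfuse S4 containers
#'
#' @param x an object of the documented class.
#' @return \code{networkLayer}: the layer label; \code{networkNodes} /
#'   \code{networkEdges}: the node / edge table; \code{embeddingMatrix}:
#'   the node-by-dimension matrix; \code{featureMatrix}: the pair-feature
#'   matrix; \code{pairList}: the (gene, disease) pair data.frame;
#'   \code{lossHistory}: per-epoch training loss; \code{foldMetrics}:
#'   per-fold metric data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
networkLayer <- function(x) x@layer

#' @rdname accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname accessors
#' @export
embeddingMatrix <- function(x) x@vectors

#' @rdname accessors
#' @export
featureMatrix <- function(x) x@features

#' @rdname accessors
#' @export
pairList <- function(x) x@pairs

#' @rdname accessors
#' @export
lossHistory <- function(x) x@lossHistory

#' @rdname accessors
#' @export
foldMetrics <- function(x) x@folds

#' Summarize a metric report as mean and standard deviation per metric
#'
#' @param x a [MetricReport-class] object.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @export
metricSummary <- function(x) {
  stopifnot(is(x, "MetricReport"))
  metrics <- setdiff(names(x@folds), c("repeat_", "fold"))
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(x@folds[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(x@folds[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
}
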