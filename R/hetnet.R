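#' Read a typed weighted edge table
#'
#' Edge tables are tab-separated text with columns
#' \code{source<TAB>target<TAB>weight}; the weight column may be omitted
#' (default 1.0). Lines starting with \code{#} are ignored. Only edges with
#' strictly positive weight are kept: similarity matrices and association
#' lists contribute an edge exactly when the association weight exceeds 0.
#' Duplicate rows for the same unordered endpoint pair collapse to a single
#' edge carrying the maximum weight (first-seen column orientation is kept);
#' self-loops are dropped, since a node's similarity with itself carries no
#' pair information for link prediction.
#'
#' @param path path to the edge table.
#' @param relation one of the seven relation names:
#'   \code{gene_gene}, \code{disease_disease}, \code{gene_disease},
#'   \code{gene_mirna}, \code{disease_mirna}, \code{gene_lncrna},
#'   \code{disease_lncrna}.
#' @param minWeight optional minimum weight filter for similarity relations;
#'   edges with weight <= \code{minWeight} are dropped (default 0, i.e. the
#'   plain positivity rule).
#' @return data.frame with columns \code{u}, \code{v}, \code{weight},
#'   \code{relation}.
#' @examples
#' f <- tempfile()
#' writeLines(c("g1\td1\t0.8", "g2\td1\t0.0"), f)
#' loadEdgeTable(f, "gene_disease")   # the zero-weight row is dropped
#' @export
loadEdgeTable <- function(path, relation, minWeight = 0) {
  relation <- match.arg(relation, RELATIONS)
  if (!file.exists(path)) stop("edge table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    warning("empty edge table: ", path)
    return(emptyEdgeFrame(relation))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected 2 or 3 columns, got %d",
                 idx[bad[1L]], path, nf[bad[1L]]))
  u <- trimws(vapply(parts, `[[`, "", 1L))
  v <- trimws(vapply(parts, `[[`, "", 2L))
  w <- rep(1.0, length(parts))
  has3 <- nf == 3L
  if (any(has3)) {
    wtxt <- trimws(vapply(parts[has3], `[[`, "", 3L))
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum)) {
      bad <- idx[has3][which(is.na(wnum))[1L]]
      stop(sprintf("malformed row at line %d of %s: non-numeric weight", bad,
                   path))
    }
    w[has3] <- wnum
  }
  edges <- data.frame(u = u, v = v, weight = w, relation = relation,
                      stringsAsFactors = FALSE)
  collapseEdges(edges[edges$weight > minWeight & edges$weight > 0 &
                        edges$u != edges$v, , drop = FALSE])
}

emptyEdgeFrame <- function(relation = character(0)) {
  data.frame(u = character(0), v = character(0), weight = numeric(0),
             relation = character(0), stringsAsFactors = FALSE)
}

# collapse duplicate unordered endpoint pairs to max weight, keeping
# first-seen orientation (so kind-by-column inference stays valid)
collapseEdges <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$relation,
               ifelse(edges$u < edges$v, paste(edges$u, edges$v),
                      paste(edges$v, edges$u)))
  maxw <- tapply(edges$weight, key, max)
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$weight <- as.numeric(maxw[key[first]])
  rownames(out) <- NULL
  out
}

#' Write an edge table
#'
#' Inverse of [loadEdgeTable()]: writes \code{source<TAB>target<TAB>weight}.
#'
#' @param edges data.frame as returned by [loadEdgeTable()].
#' @param path output file path.
#' @export
writeEdgeTable <- function(edges, path) {
  write.table(edges[, c("u", "v", "weight")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a heterogeneous network from relation edge tables
#'
#' Builds one of the three undirected heterogeneous networks: \code{GD} from
#' gene--gene similarity, disease--disease similarity and gene--disease
#' association edges; \code{GMD} from gene--miRNA and disease--miRNA edges;
#' \code{GLD} from gene--lncRNA and disease--lncRNA edges. Node kinds are
#' inferred from the relation and column position of each endpoint; a node id
#' appearing with conflicting kinds is an error. The node set is the union of
#' edge endpoints plus any explicitly registered isolated nodes (so that
#' embeddings exist for nodes without edges in this layer).
#'
#' @param edges a data.frame with columns \code{u}, \code{v}, \code{weight},
#'   \code{relation} (rows from several relations may be concatenated), or a
#'   list of such data.frames.
#' @param layer \code{"GD"}, \code{"GMD"} or \code{"GLD"}.
#' @param isolated optional data.frame with columns \code{id}, \code{kind}
#'   registering isolated nodes.
#' @return a [HeteroNetwork-class] object.
#' @examples
#' ed <- rbind(
#'   data.frame(u = "g1", v = "m1", weight = 1, relation = "gene_mirna"),
#'   data.frame(u = "d1", v = "m1", weight = 1, relation = "disease_mirna"))
#' buildNetwork(ed, "GMD")
#' @export
buildNetwork <- function(edges, layer, isolated = NULL) {
  layer <- match.arg(layer, names(LAYER_RELATIONS))
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  if (is.null(edges) || !nrow(edges)) edges <- emptyEdgeFrame()
  allowed <- LAYER_RELATIONS[[layer]]
  badRel <- setdiff(unique(edges$relation), allowed)
  if (length(badRel))
    stop(sprintf("configuration error: relation(s) %s not allowed in layer %s",
                 paste(badRel, collapse = ", "), layer))
  edges <- collapseEdges(edges[edges$weight > 0 & edges$u != edges$v, ,
                               drop = FALSE])

  ids <- character(0); kinds <- character(0)
  if (nrow(edges)) {
    km <- RELATION_KINDS[edges$relation]
    ids <- c(edges$u, edges$v)
    kinds <- c(vapply(km, `[[`, "", 1L), vapply(km, `[[`, "", 2L))
  }
  if (!is.null(isolated) && nrow(isolated)) {
    ids <- c(ids, isolated$id)
    kinds <- c(kinds, isolated$kind)
  }
  nodes <- unique(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE))
  conflict <- nodes$id[duplicated(nodes$id)]
  if (length(conflict))
    stop("data error: node id(s) with conflicting kinds: ",
         paste(unique(conflict), collapse = ", "))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("HeteroNetwork", layer = layer, nodes = nodes, edges = edges)
}

#' Count nodes per kind and edges per relation
#'
#' @param net a [HeteroNetwork-class].
#' @return list with elements \code{nodes} (named integer vector per kind),
#'   \code{relations} (named integer vector per relation) and
#'   \code{edges} (total undirected edge count).
#' @export
summarizeNetwork <- function(net) {
  stopifnot(is(net, "HeteroNetwork"))
  kinds <- LAYER_KINDS[[net@layer]]
  nodeCounts <- vapply(kinds, function(k) sum(net@nodes$kind == k),
                       integer(1))
  rels <- LAYER_RELATIONS[[net@layer]]
  relCounts <- vapply(rels, function(r) sum(net@edges$relation == r),
                      integer(1))
  list(nodes = nodeCounts, relations = relCounts,
       edges = nrow(net@edges))
}

## serialization ------------------------------------------------------------

#' Read / write a heterogeneous network as plain text
#'
#' A network is serialized as two tab-separated files sharing a path prefix:
#' \code{<prefix>_nodes.tsv} (\code{id<TAB>kind}) and
#' \code{<prefix>_edges.tsv} (\code{u<TAB>v<TAB>weight<TAB>relation}), plus a
#' first comment line recording the layer.
#'
#' @param net a [HeteroNetwork-class].
#' @param prefix path prefix for the two files.
#' @return \code{writeNetwork}: the prefix, invisibly. \code{readNetwork}:
#'   the reconstructed [HeteroNetwork-class].
#' @export
writeNetwork <- function(net, prefix) {
  stopifnot(is(net, "HeteroNetwork"))
  nf <- paste0(prefix, "_nodes.tsv")
  ef <- paste0(prefix, "_edges.tsv")
  writeLines(sprintf("#layer=%s", net@layer), nf)
  write.table(net@nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  writeLines(sprintf("#layer=%s", net@layer), ef)
  write.table(net@edges, ef, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(prefix)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(prefix) {
  nf <- paste0(prefix, "_nodes.tsv")
  ef <- paste0(prefix, "_edges.tsv")
  layer <- sub("^#layer=", "", readLines(nf, n = 1L))
  nl <- readLines(nf)[-1L]
  nodes <- if (length(nl)) {
    p <- strsplit(nl, "\t", fixed = TRUE)
    data.frame(id = vapply(p, `[[`, "", 1L), kind = vapply(p, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  } else data.frame(id = character(0), kind = character(0))
  el <- readLines(ef)[-1L]
  edges <- if (length(el)) {
    p <- strsplit(el, "\t", fixed = TRUE)
    data.frame(u = vapply(p, `[[`, "", 1L), v = vapply(p, `[[`, "", 2L),
               weight = as.numeric(vapply(p, `[[`, "", 3L)),
               relation = vapply(p, `[[`, "", 4L), stringsAsFactors = FALSE)
  } else emptyEdgeFrame()
  new("HeteroNetwork", layer = layer, nodes = nodes, edges = edges)
}
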