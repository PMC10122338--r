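## plain-text serialization of pair features, labels and model checkpoints

#' Read / write a pair feature matrix as tab-separated text
#'
#' Format: header comment \code{#layer=<l> e=<e>}, then
#' \code{gene<TAB>disease<TAB>f1...f4e}.
#'
#' @param pfm a [PairFeatureMatrix-class].
#' @param path file path.
#' @return \code{writePairFeatures}: the path, invisibly;
#'   \code{readPairFeatures}: a [PairFeatureMatrix-class].
#' @export
writePairFeatures <- function(pfm, path) {
  stopifnot(is(pfm, "PairFeatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#layer=%s e=%d", pfm@layer, ncol(pfm@features) %/% 4L),
             con)
  write.table(cbind(pfm@pairs,
                    format(pfm@features, digits = 17, trim = TRUE,
                           scientific = TRUE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePairFeatures
#' @export
readPairFeatures <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("#layer=(\\S+) e=(\\d+)", hdr))[[1]]
  if (length(m) != 3L) stop("not a pair-feature file: ", path)
  tab <- read.delim(path, header = FALSE, skip = 1L, stringsAsFactors = FALSE)
  new("PairFeatureMatrix", layer = m[2],
      features = unname(as.matrix(tab[, -(1:2), drop = FALSE])),
      pairs = data.frame(gene = tab[[1]], disease = tab[[2]],
                         stringsAsFactors = FALSE),
      imputed = character(0))
}

#' Read / write labelled gene--disease pairs
#'
#' Tab-separated \code{gene<TAB>disease<TAB>label}.
#'
#' @param pairs data.frame with columns gene, disease, label.
#' @param path file path.
#' @export
writeLabels <- function(pairs, path) {
  write.table(pairs[, c("gene", "disease", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene = tab[[1]], disease = tab[[2]], label = as.numeric(tab[[3]]),
             stringsAsFactors = FALSE)
}

#' Read / write a trained model checkpoint
#'
#' A single JSON archive holding every parameter array (with its
#' dimensions), the training configuration, the network combination, the
#' loss history and a schema version.
#'
#' @param model a [TrainedModel-class].
#' @param path file path.
#' @return \code{writeModel}: the path, invisibly; \code{readModel}: a
#'   [TrainedModel-class].
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  par <- lapply(model@params, function(p)
    list(dim = dim(p), data = as.numeric(p)))
  obj <- list(schema = 1L, combo = model@combo, config = model@config,
              lossHistory = model@lossHistory, preprocess = model@preprocess,
              params = par)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$params, function(p) {
    if (length(p$dim)) array(p$data, dim = p$dim) else p$data
  })
  pre <- lapply(obj$preprocess, function(p)
    list(center = as.numeric(p$center), scale = as.numeric(p$scale)))
  new("TrainedModel", params = par, config = as.list(obj$config),
      combo = obj$combo, preprocess = pre,
      lossHistory = as.numeric(obj$lossHistory))
}
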