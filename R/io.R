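## Readers, writers and constructors for the interactome, the TF-TF
## regulatory layer, expression matrices and TF signatures.

.parseSign <- function(tokens, where = "interactome") {
  out <- rep(NA_integer_, length(tokens))
  tk <- tolower(trimws(as.character(tokens)))
  out[tk %in% c("+", "1", "+1", "activation", "activates", "stimulation")] <- 1L
  out[tk %in% c("-", "-1", "inhibition", "inhibits", "repression")] <- -1L
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown sign token '%s' at %s row %d",
                 tokens[bad], where, bad), call. = FALSE)
  }
  out
}

## Duplicate (from, to) pairs: identical signs collapse silently; a
## contradictory pair (database conflict) keeps the inhibitory sign, the
## conservative choice for downstream sign-consistency scoring.
.dedupeEdges <- function(ed) {
  key <- paste(ed$from, ed$to, sep = "\r")
  if (!anyDuplicated(key)) return(ed)
  sgn <- tapply(ed$sign, key, function(s) {
    if (length(unique(s)) > 1L) -1L else s[1L]
  })
  conflicts <- sum(tapply(ed$sign, key, function(s) length(unique(s)) > 1L))
  if (conflicts > 0L)
    warning(sprintf("%d contradictory duplicate edge(s): kept the inhibitory sign",
                    conflicts), call. = FALSE)
  first <- !duplicated(key)
  out <- ed[first, c("from", "to")]
  out$sign <- as.integer(sgn[key[first]])
  rownames(out) <- NULL
  out
}

#' Construct a signalling network from a signed edge table
#'
#' Validates edges, resolves duplicate pairs (a contradictory duplicate
#' keeps the inhibitory sign, with a warning) and assigns node layers.
#' When `layers` is not given, layers are inferred: declared `receptors`
#' (default: nodes with in-degree 0) become receptors, nodes listed in
#' `tfs` with at least one incoming edge become TFs, and the rest are
#' intermediates.
#'
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1 or
#'   sign tokens "+", "-", "activation", "inhibition", ...).
#' @param layers optional named character vector of layer labels.
#' @param receptors optional character vector of declared receptor nodes.
#' @param tfs optional character vector of known TFs (TF catalogue).
#' @return a [SignalingNetwork-class] object.
#' @examples
#' net <- SignalingNetwork(data.frame(
#'   from = c("L", "R", "K"), to = c("R", "K", "T"),
#'   sign = c(1, 1, -1)), tfs = "T")
#' nodeLayer(net)
#' @export
SignalingNetwork <- function(edges, layers = NULL, receptors = NULL,
                             tfs = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "sign") %in% names(edges)))
  ed <- data.frame(from = as.character(edges$from),
                   to = as.character(edges$to),
                   sign = if (is.numeric(edges$sign)) as.integer(edges$sign)
                          else .parseSign(edges$sign),
                   stringsAsFactors = FALSE)
  if (!all(ed$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1", call. = FALSE)
  ed <- .dedupeEdges(ed)
  nd <- sort(unique(c(ed$from, ed$to)))
  if (is.null(layers)) {
    indeg <- table(factor(ed$to, levels = nd))
    layers <- setNames(rep("intermediate", length(nd)), nd)
    rec <- if (is.null(receptors)) nd[indeg == 0L]
           else intersect(receptors, nd)
    layers[rec] <- "receptor"
    if (!is.null(tfs)) {
      cand <- intersect(tfs, nd)
      noIn <- cand[indeg[cand] == 0L]
      if (length(noIn))
        warning(sprintf("%d catalogued TF(s) have no incoming edge; kept as %s",
                        length(noIn),
                        paste(unique(layers[noIn]), collapse = "/")),
                call. = FALSE)
      layers[setdiff(cand, noIn)] <- "tf"
    }
  } else {
    layers <- setNames(as.character(layers), names(layers))[nd]
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = nd))
  new("SignalingNetwork", nodes = nd, edges = ed, layer = layers, graph = g)
}

#' Read a signed interactome from SIF or TSV
#'
#' `"sif"` expects headerless `source sign target` rows (tab or space
#' separated); `"tsv3col"` a tab-separated file with a header and columns
#' source, sign, target, plus an optional fourth layer column
#' (receptor/intermediate/tf). Sign tokens `+`, `1`, `activation` map to
#' +1 and `-`, `-1`, `inhibition` to -1; anything else is an error naming
#' the offending row.
#'
#' @param path file path.
#' @param dialect `"tsv3col"` (default) or `"sif"`.
#' @param tfCatalog optional path to a TF catalogue (one symbol per line)
#'   used for layer inference when no layer column is present.
#' @param receptors optional character vector of declared receptors.
#' @return a [SignalingNetwork-class].
#' @export
loadInteractome <- function(path, dialect = c("tsv3col", "sif"),
                            tfCatalog = NULL, receptors = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interactome file not found: ", path,
                               call. = FALSE)
  if (dialect == "sif") {
    raw <- read.table(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE,
                      col.names = c("source", "sign", "target"))
  } else {
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(raw) < 3L)
      stop("interactome TSV needs >= 3 columns (source, sign, target)",
           call. = FALSE)
  }
  ed <- data.frame(from = as.character(raw[[1L]]),
                   sign = .parseSign(raw[[2L]], basename(path)),
                   to = as.character(raw[[3L]]),
                   stringsAsFactors = FALSE)
  layers <- NULL
  if (dialect == "tsv3col" && ncol(raw) >= 4L) {
    ## fourth column labels the source node; pure targets (never a source)
    ## have no out-edges and sit in the terminal layer
    lay <- tolower(as.character(raw[[4L]]))
    src <- tapply(lay, ed$from, function(x) x[1L])
    layers <- setNames(as.character(src), names(src))
    onlyTarget <- setdiff(unique(c(ed$from, ed$to)), names(layers))
    if (length(onlyTarget)) layers[onlyTarget] <- "tf"
  }
  tfs <- if (!is.null(tfCatalog)) readLines(tfCatalog, warn = FALSE)
  SignalingNetwork(ed, layers = layers, receptors = receptors,
                   tfs = trimws(tfs))
}

#' Write an interactome as a 4-column TSV
#'
#' Emits `source`, `sign`, `target`, `source_layer`; `loadInteractome()`
#' on the result reproduces the edge set, signs and layers.
#'
#' @param network a [SignalingNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractome <- function(network, path) {
  ed <- edgeTable(network)
  out <- data.frame(source = ed$from,
                    sign = ifelse(ed$sign > 0, "+", "-"),
                    target = ed$to,
                    source_layer = nodeLayer(network)[ed$from],
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the TF-TF regulatory layer
#'
#' Same 3-column signed format as the interactome. When `network` is
#' given, every regulator must be a tf-layer node of the interactome
#' (targets may be TFs absent from it — that is the point of the layer).
#'
#' @param path file path (3-column TSV with header: regulator, sign,
#'   target).
#' @param network optional [SignalingNetwork-class] to validate against.
#' @return a [GeneRegulatoryNetwork-class].
#' @export
loadGRN <- function(path, network = NULL) {
  if (!file.exists(path)) stop("GRN file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ed <- data.frame(regulator = as.character(raw[[1L]]),
                   target = as.character(raw[[3L]]),
                   sign = .parseSign(raw[[2L]], basename(path)),
                   stringsAsFactors = FALSE)
  grn <- new("GeneRegulatoryNetwork", edges = ed)
  if (!is.null(network)) validateGRN(grn, network)
  grn
}

#' Check a regulatory layer against the interactome
#'
#' @param grn a [GeneRegulatoryNetwork-class].
#' @param network a [SignalingNetwork-class].
#' @return `grn` invisibly; errors if some regulator is not a tf-layer
#'   node of the network.
#' @export
validateGRN <- function(grn, network) {
  tfs <- names(nodeLayer(network))[nodeLayer(network) == "tf"]
  bad <- setdiff(unique(edgeTable(grn)$regulator), tfs)
  if (length(bad))
    stop("GRN regulators not tf-layer nodes of the interactome: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  invisible(grn)
}

#' Construct expression profiles
#'
#' @param values non-negative numeric matrix, genes in rows (rownames
#'   required). `NA` entries are replaced by 0 with a warning; duplicate
#'   gene rows are collapsed by summation.
#' @param condition condition label.
#' @return an [ExpressionProfiles-class].
#' @export
ExpressionProfiles <- function(values, condition = "") {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty expression matrix", call. = FALSE)
  if (anyNA(values)) {
    warning(sprintf("%d missing expression value(s) set to 0",
                    sum(is.na(values))), call. = FALSE)
    values[is.na(values)] <- 0
  }
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    message(sprintf("collapsing %d duplicate gene row(s) by summation",
                    sum(duplicated(rownames(values)))))
    values <- rowsum(values, rownames(values))
  }
  new("ExpressionProfiles", values = values,
      condition = as.character(condition))
}

#' Read an expression matrix
#'
#' `"tsv"` expects genes in rows, samples in columns, a header row and
#' gene identifiers in the first column. `"mtx"` expects a MatrixMarket
#' coordinate file plus CellRanger-style sidecars `<stem>.genes.tsv` and
#' `<stem>.barcodes.tsv` (or `genes.tsv`/`barcodes.tsv` in the same
#' directory), one name per line.
#'
#' @param path file path (.tsv or .mtx).
#' @param format `"tsv"` or `"mtx"`; default guesses from the extension.
#' @param condition condition label attached to the profiles.
#' @return an [ExpressionProfiles-class].
#' @export
loadExpression <- function(path, format = c("auto", "tsv", "mtx"),
                           condition = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  if (format == "tsv") {
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (nrow(raw) == 0L || ncol(raw) < 2L)
      stop("empty expression matrix: ", path, call. = FALSE)
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- as.character(raw[[1L]])
  } else {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gf <- if (file.exists(paste0(stem, ".genes.tsv")))
      paste0(stem, ".genes.tsv") else file.path(dirname(path), "genes.tsv")
    bf <- if (file.exists(paste0(stem, ".barcodes.tsv")))
      paste0(stem, ".barcodes.tsv") else file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("missing genes/barcodes sidecar files for ", path, call. = FALSE)
    vals <- as.matrix(m)
    rownames(vals) <- readLines(gf, warn = FALSE)
    colnames(vals) <- readLines(bf, warn = FALSE)
  }
  ExpressionProfiles(vals, condition = condition)
}

#' Construct a TF signature
#'
#' @param tf character vector of TF identifiers.
#' @param direction parallel vector of directions: `"up"`/`"down"`,
#'   +1/-1. Consistent duplicates collapse; conflicting duplicates are an
#'   error.
#' @return a [TFSignature-class].
#' @export
TFSignature <- function(tf, direction) {
  tf <- as.character(tf)
  if (is.character(direction)) {
    dk <- tolower(trimws(direction))
    dir <- ifelse(dk %in% c("up", "+1", "1", "+"), 1L,
                  ifelse(dk %in% c("down", "-1", "-"), -1L, NA_integer_))
    if (anyNA(dir))
      stop("unknown direction token '",
           direction[which(is.na(dir))[1L]], "'", call. = FALSE)
  } else dir <- as.integer(sign(direction))
  if (anyDuplicated(tf)) {
    nDir <- tapply(dir, tf, function(d) length(unique(d)))
    if (any(nDir > 1L))
      stop("conflicting directions for TF(s): ",
           paste(names(nDir)[nDir > 1L], collapse = ", "), call. = FALSE)
    keep <- !duplicated(tf)
    tf <- tf[keep]; dir <- dir[keep]
  }
  new("TFSignature", tf = tf, direction = dir)
}

#' Read a differential TF signature
#'
#' Two-column TSV (tf, direction), with or without a header row;
#' direction tokens: up/down/+1/-1.
#'
#' @param path file path.
#' @return a [TFSignature-class].
#' @export
loadTFSignature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE),
                  error = function(e) data.frame())
  if (nrow(raw) == 0L)
    stop("signature must contain >=1 TF: ", path, call. = FALSE)
  dirTok <- tolower(trimws(as.character(raw[[2L]])))
  known <- c("up", "down", "+1", "-1", "1", "+", "-")
  if (!dirTok[1L] %in% known) { # header row
    raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L)
      stop("signature must contain >=1 TF: ", path, call. = FALSE)
  }
  TFSignature(raw[[1L]], as.character(raw[[2L]]))
}
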