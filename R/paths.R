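## Shortest-path machinery: enumeration, sign propagation and the
## stationary-probability contribution weights (omega).

.edgeSignIndex <- function(network) {
  ed <- edgeTable(network)
  setNames(ed$sign, paste(ed$from, ed$to, sep = "\r"))
}

#' Enumerate all directed shortest paths between two nodes
#'
#' All minimum-hop directed paths from `from` to `to`, as node-id
#' vectors. Found by breadth-first distance labelling and enumeration
#' over the shortest-path DAG. Shortest-path counts can explode on dense
#' graphs, so the set is truncated at `maxPaths` with a warning.
#'
#' @param network a [SignalingNetwork-class].
#' @param from,to distinct node identifiers.
#' @param maxPaths truncation bound (default 10000).
#' @return list of character vectors (possibly empty when no path
#'   exists; that is not an error).
#' @export
enumerateShortestPaths <- function(network, from, to, maxPaths = 10000L) {
  nd <- nodes(network)
  if (!from %in% nd || !to %in% nd)
    stop("both endpoints must be network nodes", call. = FALSE)
  if (from == to) stop("source and target must differ", call. = FALSE)
  res <- suppressWarnings(
    igraph::all_shortest_paths(asIgraph(network), from = from, to = to,
                               mode = "out"))
  paths <- lapply(res$vpaths, function(p) names(p))
  if (length(paths) > maxPaths) {
    warning(sprintf("shortest-path set for %s -> %s truncated at %d of %d paths",
                    from, to, maxPaths, length(paths)), call. = FALSE)
    paths <- paths[seq_len(maxPaths)]
  }
  paths
}

#' Net regulatory sign of a path
#'
#' Product of the edge signs along the path: +1 means the source
#' activates the endpoint through this route, -1 that it inhibits it
#' (an even number of inhibitory edges is net-activating).
#'
#' @param path character vector of node ids (consecutive pairs must be
#'   network edges).
#' @param network a [SignalingNetwork-class].
#' @return +1 or -1.
#' @export
pathSign <- function(path, network) {
  idx <- .edgeSignIndex(network)
  key <- paste(path[-length(path)], path[-1L], sep = "\r")
  s <- idx[key]
  if (anyNA(s))
    stop("path contains a non-edge: ",
         gsub("\r", " -> ", key[which(is.na(s))[1L]]), call. = FALSE)
  prod(s)
}

#' Relative contribution (omega) of each shortest path
#'
#' The raw weight of a path is a summary of the stationary probabilities
#' of its interior nodes (exclusive of source and target): by default
#' their geometric mean, which does not penalise path length and is
#' stable under the overall scale of pi. Direct edges have no interior
#' and get raw weight 1. Omega is the raw weight normalised over the
#' pair's shortest-path set, so omegas sum to 1: each path's share of
#' the signal flow between the pair.
#'
#' @param paths list of node-id vectors for one (source, target) pair,
#'   all the same length.
#' @param pi a [StationaryDistribution-class] or named numeric vector.
#' @param variant interior summary: `"geometric"` (default),
#'   `"product"` or `"arithmetic"`.
#' @param includeTarget treat the path endpoint as an interior node.
#'   Used for regulatory-layer extended paths, where the listed endpoint
#'   is the interactome regulator and the true target (the external
#'   signature TF) lies outside the network, so the regulator is itself
#'   a path constituent.
#' @return numeric vector of omegas, summing to 1.
#' @export
pathOmega <- function(paths, pi, variant = c("geometric", "product",
                                             "arithmetic"),
                      includeTarget = FALSE) {
  variant <- match.arg(variant)
  if (!length(paths)) stop("need >= 1 path", call. = FALSE)
  p <- if (is(pi, "StationaryDistribution")) stationaryVector(pi) else pi
  raw <- vapply(paths, function(path) {
    last <- length(path) - if (includeTarget) 0L else 1L
    ii <- if (last < 2L) character() else path[seq(2L, last)]
    if (!length(ii)) return(1)
    v <- p[ii]
    if (anyNA(v)) stop("pi is undefined on path node(s): ",
                       paste(ii[is.na(v)], collapse = ", "), call. = FALSE)
    switch(variant,
           geometric  = if (any(v == 0)) 0 else exp(mean(log(v))),
           product    = prod(v),
           arithmetic = mean(v))
  }, numeric(1))
  tot <- sum(raw)
  if (tot == 0) {
    warning("all path weights are zero; using uniform contributions",
            call. = FALSE)
    return(rep(1 / length(raw), length(raw)))
  }
  raw / tot
}
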