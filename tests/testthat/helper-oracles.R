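`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent brute-force oracles and random-instance generators.
## These never call the package's path machinery; they recompute
## everything from the raw edge table.

## Exhaustive DFS over simple paths, keeping only minimum-length ones.
bruteShortestPaths <- function(edges, from, to) {
  adj <- split(edges$to, edges$from)
  best <- Inf
  out <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      if (length(path) < best) {
        best <<- length(path)
        out <<- list(path)
      } else if (length(path) == best) {
        out[[length(out) + 1L]] <<- path
      }
      return(invisible())
    }
    if (length(path) >= best) return(invisible())
    for (nxt in adj[[last]]) if (!nxt %in% path) rec(c(path, nxt))
  }
  rec(from)
  out
}

## Sign, omega and compatibility recomputed from scratch.
brutePathSign <- function(path, edges) {
  s <- 1
  for (k in seq_len(length(path) - 1L)) {
    hit <- edges$from == path[k] & edges$to == path[k + 1L]
    s <- s * edges$sign[hit][1L]
  }
  s
}

bruteOmega <- function(paths, piVec) {
  raw <- vapply(paths, function(p) {
    interior <- p[-c(1L, length(p))]
    if (!length(interior)) 1 else exp(mean(log(piVec[interior])))
  }, numeric(1))
  raw / sum(raw)
}

brutePairScore <- function(edges, piVec, node, tf, direction) {
  paths <- bruteShortestPaths(edges, node, tf)
  if (!length(paths)) return(NA_real_)
  omega <- bruteOmega(paths, piVec)
  signs <- vapply(paths, brutePathSign, numeric(1), edges = edges)
  sum(omega[signs == direction])
}

## Canonical form for comparing path sets irrespective of order.
pathSetKey <- function(paths) sort(vapply(paths, paste, "", collapse = ">"))

## Random signed digraph; a spanning cycle guarantees every node both an
## in- and an out-edge (so layers are all "intermediate" unless tfs given).
randomTestNetwork <- function(n, p = 0.25, seed = 1, tfs = NULL) {
  set.seed(seed)
  nd <- sprintf("N%02d", seq_len(n))
  grid <- expand.grid(from = nd, to = nd, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  ed <- grid[runif(nrow(grid)) < p, ]
  cyc <- data.frame(from = nd, to = c(nd[-1L], nd[1L]),
                    stringsAsFactors = FALSE)
  ed <- rbind(ed, cyc)
  ed <- ed[!duplicated(paste(ed$from, ed$to)), ]
  ed$sign <- sample(c(-1L, 1L), nrow(ed), replace = TRUE)
  SignalingNetwork(ed, tfs = tfs)
}

randomExpression <- function(network, seed = 1, min = 0.1, max = 10) {
  set.seed(seed)
  setNames(runif(length(nodes(network)), min, max), nodes(network))
}

## Tiny deterministic chain network used across unit tests:
##   L -> R -> K1 -> T1 (all +), K1 -| T2, and a parallel K2 branch.
chainNetwork <- function() {
  SignalingNetwork(data.frame(
    from = c("L", "R", "R", "K1", "K1", "K2"),
    to = c("R", "K1", "K2", "T1", "T2", "T1"),
    sign = c(1L, 1L, 1L, 1L, -1L, 1L)),
    tfs = c("T1", "T2"))
}
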