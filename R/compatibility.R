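## Compatibility of signalling nodes with the differential TF signature.

## Collect the shortest-path set from `node` to a signature TF, going
## through the regulatory layer when the TF is not an interactome node.
## Returns list(paths, signs, includeTarget) or NULL when unreachable.
.pairPaths <- function(node, tf, network, grn = NULL,
                       maxPaths = 10000L) {
  nd <- nodes(network)
  if (tf %in% nd) {
    if (identical(node, tf)) return(NULL)
    paths <- enumerateShortestPaths(network, node, tf, maxPaths)
    if (!length(paths)) return(NULL)
    return(list(paths = paths,
                signs = vapply(paths, pathSign, numeric(1),
                               network = network),
                viaGRN = FALSE))
  }
  if (is.null(grn)) return(NULL)
  ge <- edgeTable(grn)
  regs <- ge[ge$target == tf & ge$regulator %in% nd &
               ge$regulator != node, , drop = FALSE]
  if (!nrow(regs)) return(NULL)
  hits <- list()
  for (k in seq_len(nrow(regs))) {
    pp <- enumerateShortestPaths(network, node, regs$regulator[k],
                                 maxPaths)
    if (!length(pp)) next
    hits[[length(hits) + 1L]] <- list(
      paths = pp,
      signs = regs$sign[k] * vapply(pp, pathSign, numeric(1),
                                    network = network))
  }
  if (!length(hits)) return(NULL)
  ## the extended paths all gain one regulatory hop, so the shortest
  ## overall are those through the nearest regulator(s)
  lens <- vapply(hits, function(h) length(h$paths[[1L]]), numeric(1))
  keep <- hits[lens == min(lens)]
  list(paths = do.call(c, lapply(keep, `[[`, "paths")),
       signs = do.call(c, lapply(keep, `[[`, "signs")),
       viaGRN = TRUE)
}

#' Compatibility of one signalling node with one signature TF
#'
#' A shortest path is compatible with the TF when its propagated sign
#' matches the TF's differential direction: net-activating paths match
#' an up-regulated TF, net-inhibiting paths a down-regulated one. The
#' score is the omega-weighted fraction of compatible shortest paths —
#' both how many routes agree and how much stationary-probability flow
#' they carry — and reads as the probability that the node activates
#' (for `direction = "up"`) the observed TF change.
#'
#' A signature TF absent from the interactome is scored through the
#' interactome TFs that regulate it via exactly one regulatory-layer
#' edge, whose sign multiplies the path sign.
#'
#' @param node signalling node identifier.
#' @param tf signature TF identifier.
#' @param direction `"up"`/`"down"` (or +1/-1): the TF's differential
#'   direction in the condition being scored.
#' @param network a [SignalingNetwork-class].
#' @param pi condition-level [StationaryDistribution-class] (weights the
#'   path contributions).
#' @param grn optional [GeneRegulatoryNetwork-class].
#' @param omegaVariant passed to [pathOmega()].
#' @param maxPaths truncation bound per pair.
#' @return list with `score` (in [0,1], or NA when the pair has no
#'   path), `nPaths`, `nCompatible`, `viaGRN`.
#' @examples
#' net <- SignalingNetwork(data.frame(from = c("A", "B"), to = c("B", "T"),
#'                                    sign = c(1, -1)), tfs = "T")
#' tm <- buildTransitionMatrix(net, c(A = 1, B = 1, T = 1))
#' pi <- stationaryDistribution(tm, method = "linear")
#' pairCompatibility("A", "T", "down", net, pi)$score   # 1: net inhibition
#' @export
pairCompatibility <- function(node, tf, direction, network, pi,
                              grn = NULL,
                              omegaVariant = "geometric",
                              maxPaths = 10000L) {
  dir <- if (is.character(direction)) {
    if (tolower(direction) %in% c("up", "+1", "1", "+")) 1L else -1L
  } else as.integer(sign(direction))
  pp <- .pairPaths(node, tf, network, grn, maxPaths)
  if (is.null(pp))
    return(list(score = NA_real_, nPaths = 0L, nCompatible = 0L,
                viaGRN = NA))
  omega <- pathOmega(pp$paths, pi, variant = omegaVariant,
                     includeTarget = pp$viaGRN)
  compatible <- pp$signs == dir
  list(score = sum(omega[compatible]),
       nPaths = length(pp$paths),
       nCompatible = sum(compatible),
       viaGRN = pp$viaGRN)
}

#' Average compatibility of a node over the TF signature
#'
#' Unweighted mean of the node's pair scores over the signature TFs it
#' can reach. Unreachable TFs are excluded from the average rather than
#' scored 0 — no route is no evidence, not contradiction. The activity
#' call is `"active"` above `threshold`, `"inactive"` below, and
#' `"indeterminate"` at exactly the threshold.
#'
#' @param node signalling node identifier.
#' @param signature a [TFSignature-class] (directions for the condition
#'   being scored).
#' @param network a [SignalingNetwork-class].
#' @param pi condition-level [StationaryDistribution-class].
#' @param grn optional [GeneRegulatoryNetwork-class].
#' @param threshold activity threshold on the mean score (default 0.5).
#' @param omegaVariant,maxPaths passed to [pairCompatibility()].
#' @return list with `score` (mean over reachable TFs; NA when none is
#'   reachable), `call`, `nUsed` and the per-pair data.frame `pairs`.
#' @export
nodeCompatibility <- function(node, signature, network, pi, grn = NULL,
                              threshold = 0.5,
                              omegaVariant = "geometric",
                              maxPaths = 10000L) {
  tfs <- signature@tf
  rows <- lapply(seq_along(tfs), function(k) {
    pc <- pairCompatibility(node, tfs[k], signature@direction[k],
                            network, pi, grn = grn,
                            omegaVariant = omegaVariant,
                            maxPaths = maxPaths)
    data.frame(node = node, tf = tfs[k],
               direction = ifelse(signature@direction[k] > 0, "up", "down"),
               score = pc$score, n_paths = pc$nPaths,
               n_compatible = pc$nCompatible,
               via_grn = isTRUE(pc$viaGRN), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  used <- !is.na(pairs$score)
  if (!any(used))
    return(list(score = NA_real_, call = NA_character_, nUsed = 0L,
                pairs = pairs))
  m <- mean(pairs$score[used])
  call <- if (m > threshold) "active"
          else if (m < threshold) "inactive" else "indeterminate"
  list(score = m, call = call, nUsed = sum(used), pairs = pairs)
}

.scoreCondition <- function(nodesToScore, signature, network, pi, grn,
                            threshold, omegaVariant, maxPaths,
                            condition) {
  pairsList <- list(); sumList <- list()
  for (nd in nodesToScore) {
    nc <- nodeCompatibility(nd, signature, network, pi, grn = grn,
                            threshold = threshold,
                            omegaVariant = omegaVariant,
                            maxPaths = maxPaths)
    pairsList[[nd]] <- nc$pairs
    sumList[[nd]] <- data.frame(node = nd, mean_score = nc$score,
                                n_tfs_used = nc$nUsed, call = nc$call,
                                stringsAsFactors = FALSE)
  }
  emptyPairs <- data.frame(node = character(), tf = character(),
                           direction = character(), score = numeric(),
                           n_paths = integer(), n_compatible = integer(),
                           via_grn = logical(), stringsAsFactors = FALSE)
  emptySummary <- data.frame(node = character(), mean_score = numeric(),
                             n_tfs_used = integer(), call = character(),
                             stringsAsFactors = FALSE)
  pairs <- if (length(pairsList)) do.call(rbind, c(pairsList,
                                                   make.row.names = FALSE))
           else emptyPairs
  summ <- if (length(sumList)) do.call(rbind, c(sumList,
                                                make.row.names = FALSE))
          else emptySummary
  if (nrow(summ)) summ <- summ[order(-replace(summ$mean_score,
                                              is.na(summ$mean_score), -1),
                                     summ$node), ]
  rownames(summ) <- NULL
  new("CompatibilityTable", pairs = pairs, summary = summ,
      condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flip the directions of a TF signature
#'
#' The signature is stated for condition A relative to B; scoring
#' condition B uses the flipped directions.
#'
#' @param signature a [TFSignature-class].
#' @return a [TFSignature-class] with all directions negated.
#' @export
flipSignature <- function(signature)
  new("TFSignature", tf = signature@tf,
      direction = -signature@direction)

#' Run the full two-condition comparison
#'
#' For each condition: per-sample transition matrices, per-sample
#' stationary distributions, condition-level aggregation, hotspot
#' selection, and compatibility of every hotspot intermediate with the
#' TF signature (directions as given for condition A, flipped for
#' condition B). Each condition is weighted by its own stationary
#' distribution.
#'
#' @param network a [SignalingNetwork-class].
#' @param exprA,exprB [ExpressionProfiles-class] for the two conditions.
#' @param signature a [TFSignature-class], A-relative.
#' @param grn optional [GeneRegulatoryNetwork-class].
#' @param config a [hotspotConfig()] list of tuning parameters.
#' @return list with per-condition elements `tables` (two
#'   [CompatibilityTable-class]), `hotspots` (two hotspot data.frames),
#'   `pi` (two condition-level distributions), `samplePis` (per-sample
#'   distributions, for heterogeneity reporting) and `diff`, a joint
#'   data.frame of per-node score differences (score_A - score_B).
#' @export
compareConditions <- function(network, exprA, exprB, signature,
                              grn = NULL, config = hotspotConfig()) {
  if (!is.null(grn)) validateGRN(grn, network)
  runCondition <- function(expr, sig, label) {
    em <- matchExpression(network, expr, quiet = TRUE)
    unmatched <- sum(rowSums(em) == 0 &
                       !(nodes(network) %in% rownames(exprValues(expr))))
    pis <- lapply(seq_len(ncol(em)), function(s) {
      tm <- buildTransitionMatrix(network, em[, s],
                                  sample = colnames(em)[s],
                                  weight = config$weight)
      stationaryDistribution(tm, method = config$method,
                             beta = config$beta, tol = config$tol,
                             maxIter = config$maxIter,
                             steps = config$steps, seed = config$seed)
    })
    cpi <- conditionPi(pis, aggregate = config$aggregate, id = label)
    hs <- selectHotspots(cpi, network, percentile = config$percentile)
    cand <- hs$node[hs$hotspot]
    if (!length(cand))
      warning("no hotspot candidates in condition ", label, call. = FALSE)
    tab <- .scoreCondition(cand, sig, network, cpi, grn,
                           config$threshold, config$omegaVariant,
                           config$maxPaths, label)
    list(pi = cpi, samplePis = pis, hotspots = hs, table = tab,
         unmatched = unmatched)
  }
  labA <- conditionLabel(exprA); if (!nzchar(labA)) labA <- "A"
  labB <- conditionLabel(exprB); if (!nzchar(labB)) labB <- "B"
  A <- runCondition(exprA, signature, labA)
  B <- runCondition(exprB, flipSignature(signature), labB)
  sa <- nodeSummary(A$table); sb <- nodeSummary(B$table)
  diff <- merge(sa[, c("node", "mean_score", "call")],
                sb[, c("node", "mean_score", "call")],
                by = "node", all = TRUE, suffixes = c("_A", "_B"))
  diff$delta <- diff$mean_score_A - diff$mean_score_B
  diff <- diff[order(-replace(diff$delta, is.na(diff$delta), -Inf)), ]
  rownames(diff) <- NULL
  list(tables = list(A = A$table, B = B$table),
       hotspots = list(A = A$hotspots, B = B$hotspots),
       pi = list(A = A$pi, B = B$pi),
       samplePis = list(A = A$samplePis, B = B$samplePis),
       diff = diff,
       unmatched = c(A = A$unmatched, B = B$unmatched))
}
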