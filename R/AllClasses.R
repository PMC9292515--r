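#' @import methods
#' @importFrom stats quantile sd setNames rnorm rpois rbinom runif median
#' @importFrom utils read.delim write.table head
#' @useDynLib SignalingHotspots, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

LAYERS <- c("receptor", "intermediate", "tf")

#' Signed directed signalling network
#'
#' Holds a directed graph of signalling molecules. Each edge carries a sign
#' (+1 activation, -1 inhibition) and each node a layer label:
#' `"receptor"` (network inputs), `"intermediate"` (kinases, phosphatases,
#' adaptors, ...) or `"tf"` (transcription factors, the terminal layer).
#'
#' @slot nodes character vector of molecule identifiers (gene symbols).
#' @slot edges data.frame with columns `from`, `to`, `sign` (+1/-1).
#' @slot layer named character vector, one of `"receptor"`,
#'   `"intermediate"`, `"tf"` per node.
#' @slot graph cached igraph representation (directed).
#' @export
setClass("SignalingNetwork",
  representation(nodes = "character", edges = "data.frame",
                 layer = "character", graph = "ANY"))

setValidity("SignalingNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("from", "to", "sign") %in% names(ed)))
    msg <- c(msg, "edges must have columns from, to, sign")
  else {
    if (!all(c(ed$from, ed$to) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a network node")
    if (!all(ed$sign %in% c(-1L, 1L)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (anyDuplicated(paste(ed$from, ed$to)))
      msg <- c(msg, "duplicate (from, to) edges are not allowed")
  }
  if (is.null(names(object@layer)) ||
      !setequal(names(object@layer), object@nodes))
    msg <- c(msg, "layer must be named for exactly the node set")
  else {
    if (!all(object@layer %in% LAYERS))
      msg <- c(msg, "layers must be receptor/intermediate/tf")
    tfs <- names(object@layer)[object@layer == "tf"]
    if (length(tfs) && !all(tfs %in% ed$to))
      msg <- c(msg, "every tf-layer node needs at least one incoming edge")
  }
  if (length(msg)) msg else TRUE
})

#' TF-TF gene regulatory layer
#'
#' Signed regulator -> target edges used to reach signature TFs that have no
#' interactome connection: a signature TF absent from the network is scored
#' through the interactome TFs that regulate it via exactly one such edge.
#'
#' @slot edges data.frame with columns `regulator`, `target`, `sign`.
#' @export
setClass("GeneRegulatoryNetwork",
  representation(edges = "data.frame"))

setValidity("GeneRegulatoryNetwork", function(object) {
  ed <- object@edges
  if (!all(c("regulator", "target", "sign") %in% names(ed)))
    return("edges must have columns regulator, target, sign")
  if (!all(ed$sign %in% c(-1L, 1L)))
    return("edge signs must be +1 or -1")
  TRUE
})

#' Expression profiles for one condition
#'
#' A non-negative genes x samples matrix on any pre-normalised scale
#' (normalised counts, TPM, ...). For single-cell data the columns are
#' cells. Absolute scale is irrelevant downstream: transition probabilities
#' are scale-invariant.
#'
#' @slot values non-negative numeric matrix, genes in rows.
#' @slot condition condition label.
#' @export
setClass("ExpressionProfiles",
  representation(values = "matrix", condition = "character"))

setValidity("ExpressionProfiles", function(object) {
  v <- object@values
  if (!is.numeric(v) || length(v) == 0L)
    return("values must be a non-empty numeric matrix")
  if (anyNA(v)) return("values must not contain NA")
  if (any(v < 0)) return("values must be non-negative")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("gene identifiers (rownames) must be present and unique")
  TRUE
})

#' Differential TF signature
#'
#' The set of differentially expressed transcription factors between two
#' conditions, each with a direction (+1 up, -1 down) in condition A
#' relative to condition B. Only the direction is stored; effect magnitude
#' plays no role in compatibility scoring.
#'
#' @slot tf character vector of TF identifiers (unique).
#' @slot direction integer vector, +1 (up) or -1 (down), parallel to `tf`.
#' @export
setClass("TFSignature",
  representation(tf = "character", direction = "integer"))

setValidity("TFSignature", function(object) {
  if (length(object@tf) == 0L) return("signature must contain >=1 TF")
  if (anyDuplicated(object@tf)) return("each TF may appear at most once")
  if (length(object@direction) != length(object@tf))
    return("direction must be parallel to tf")
  if (!all(object@direction %in% c(-1L, 1L)))
    return("direction must be +1 (up) or -1 (down)")
  TRUE
})

#' Per-sample expression-weighted transition matrix
#'
#' Row-stochastic matrix P over the network nodes for one sample. Entry
#' (i, j) is the probability that a signal at node i moves to node j; it is nonzero
#' only along network edges (or the self-loop a zero-weight row collapses
#' to). Edge signs do not enter P.
#'
#' @slot nodes node order of the matrix.
#' @slot P sparse row-stochastic matrix (dgCMatrix).
#' @slot sample sample (or cell) identifier.
#' @export
setClass("TransitionMatrix",
  representation(nodes = "character", P = "ANY", sample = "character"))

setValidity("TransitionMatrix", function(object) {
  P <- object@P
  if (!is(P, "Matrix") && !is.matrix(P)) return("P must be a matrix")
  if (nrow(P) != ncol(P)) return("P must be square")
  if (nrow(P) != length(object@nodes))
    return("P dimension must match the node order")
  if (any(P < 0) || any(P > 1)) return("entries of P must lie in [0,1]")
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-10))
    return("every row of P must sum to 1 (tolerance 1e-10)")
  TRUE
})

#' Stationary distribution of the signalling walk
#'
#' Probability vector pi over network nodes: the long-run visit frequency
#' of the damped expression-weighted Markov chain, either for one sample or
#' aggregated to condition level. Carries convergence metadata and, for
#' aggregated distributions, the per-node dispersion across samples.
#'
#' @slot nodes node order.
#' @slot pi probability vector (sums to 1).
#' @slot id sample or condition identifier.
#' @slot method solver used ("power", "linear", "montecarlo", or
#'   an aggregation tag).
#' @slot beta teleportation (damping) probability used.
#' @slot iterations iterations / steps used by the solver.
#' @slot residual L1 fixed-point residual ||pi P' - pi||_1.
#' @slot dispersion per-node sd of pi across samples (aggregated
#'   distributions only; length 0 otherwise).
#' @export
setClass("StationaryDistribution",
  representation(nodes = "character", pi = "numeric", id = "character",
                 method = "character", beta = "numeric",
                 iterations = "integer", residual = "numeric",
                 dispersion = "numeric"))

setValidity("StationaryDistribution", function(object) {
  p <- object@pi
  if (length(p) != length(object@nodes))
    return("pi must match the node order")
  if (any(p < 0)) return("pi entries must be >= 0")
  if (abs(sum(p) - 1) > 1e-10) return("pi must sum to 1 (tolerance 1e-10)")
  if (length(object@dispersion) &&
      length(object@dispersion) != length(p))
    return("dispersion must be empty or parallel to pi")
  TRUE
})

#' Node-TF compatibility scores for one condition
#'
#' Per (signalling node, TF) compatibility scores in [0,1] — the
#' contribution-weighted fraction of shortest paths whose propagated sign
#' matches the TF's differential direction — plus per-node averages over
#' the signature and the resulting activity call.
#'
#' @slot pairs data.frame: `node`, `tf`, `direction`, `score`, `n_paths`,
#'   `n_compatible`, `via_grn`.
#' @slot summary data.frame: `node`, `mean_score`, `n_tfs_used`, `call`.
#' @slot condition condition label.
#' @export
setClass("CompatibilityTable",
  representation(pairs = "data.frame", summary = "data.frame",
                 condition = "character"))

setValidity("CompatibilityTable", function(object) {
  pr <- object@pairs
  if (nrow(pr)) {
    sc <- pr$score[!is.na(pr$score)]
    if (any(sc < 0 | sc > 1)) return("scores must lie in [0,1]")
  }
  sm <- object@summary
  if (nrow(sm)) {
    ms <- sm$mean_score[!is.na(sm$mean_score)]
    if (any(ms < 0 | ms > 1)) return("mean scores must lie in [0,1]")
    if (!all(sm$call %in% c("active", "inactive", "indeterminate", NA)))
      return("calls must be active/inactive/indeterminate/NA")
  }
  TRUE
})

#' Synthetic benchmark scenario
#'
#' A layered signed network with a planted activating driver cascade and a
#' sign-contradicting decoy cascade, matching two-condition expression,
#' the TF signature the construction implies, and the ground truth.
#'
#' @slot network SignalingNetwork.
#' @slot grn GeneRegulatoryNetwork connecting interactome TFs to external
#'   signature TFs.
#' @slot exprA,exprB ExpressionProfiles for the two conditions.
#' @slot signature TFSignature (condition A relative to B).
#' @slot truth list with planted `driver`, `decoy`, cascade members and
#'   intended activity calls.
#' @slot seed integer seed the scenario was generated from.
#' @slot params generation parameters.
#' @export
setClass("SyntheticScenario",
  representation(network = "SignalingNetwork",
                 grn = "GeneRegulatoryNetwork",
                 exprA = "ExpressionProfiles",
                 exprB = "ExpressionProfiles",
                 signature = "TFSignature",
                 truth = "list", seed = "integer", params = "list"))
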