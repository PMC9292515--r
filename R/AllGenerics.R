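#' Accessors
#'
#' Small accessor generics for the package classes; slot access is never
#' needed in user code.
#'
#' @param x an object of one of the package classes.
#' @return `nodes()` the node identifiers; `edgeTable()` the signed edge
#'   data.frame; `nodeLayer()` a named character vector of layer labels;
#'   `asIgraph()` the directed igraph; `exprValues()` the genes x samples
#'   matrix; `conditionLabel()` the condition label; `stationaryVector()`
#'   the named probability vector; `transitionMatrix()` the sparse
#'   row-stochastic matrix; `signatureTable()` / `pairScores()` /
#'   `nodeSummary()` data.frames.
#' @name accessors
#' @aliases nodes edgeTable nodeLayer asIgraph exprValues conditionLabel
#'   stationaryVector transitionMatrix signatureTable pairScores
#'   nodeSummary
NULL

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeLayer", function(x) standardGeneric("nodeLayer"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("stationaryVector", function(x) standardGeneric("stationaryVector"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))
#' @rdname accessors
#' @export
setGeneric("pairScores", function(x) standardGeneric("pairScores"))
#' @rdname accessors
#' @export
setGeneric("nodeSummary", function(x) standardGeneric("nodeSummary"))

#' @rdname accessors
setMethod("nodes", "SignalingNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("nodes", "TransitionMatrix", function(x) x@nodes)
#' @rdname accessors
setMethod("nodes", "StationaryDistribution", function(x) x@nodes)
#' @rdname accessors
setMethod("edgeTable", "SignalingNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("edgeTable", "GeneRegulatoryNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("nodeLayer", "SignalingNetwork", function(x) x@layer)
#' @rdname accessors
setMethod("asIgraph", "SignalingNetwork", function(x) x@graph)
#' @rdname accessors
setMethod("exprValues", "ExpressionProfiles", function(x) x@values)
#' @rdname accessors
setMethod("conditionLabel", "ExpressionProfiles", function(x) x@condition)
#' @rdname accessors
setMethod("stationaryVector", "StationaryDistribution",
          function(x) setNames(x@pi, x@nodes))
#' @rdname accessors
setMethod("transitionMatrix", "TransitionMatrix", function(x) x@P)
#' @rdname accessors
setMethod("signatureTable", "TFSignature", function(x)
  data.frame(tf = x@tf, direction = ifelse(x@direction > 0, "up", "down"),
             stringsAsFactors = FALSE))
#' @rdname accessors
setMethod("pairScores", "CompatibilityTable", function(x) x@pairs)
#' @rdname accessors
setMethod("nodeSummary", "CompatibilityTable", function(x) x@summary)

setMethod("show", "SignalingNetwork", function(object) {
  tab <- table(factor(object@layer, levels = LAYERS))
  cat(sprintf(paste0("SignalingNetwork: %d nodes (%d receptor, ",
                     "%d intermediate, %d tf), %d signed edges ",
                     "(%d activating, %d inhibiting)\n"),
              length(object@nodes), tab[["receptor"]],
              tab[["intermediate"]], tab[["tf"]], nrow(object@edges),
              sum(object@edges$sign > 0), sum(object@edges$sign < 0)))
})

setMethod("show", "GeneRegulatoryNetwork", function(object) {
  cat(sprintf("GeneRegulatoryNetwork: %d TF->TF edges, %d regulators, %d targets\n",
              nrow(object@edges), length(unique(object@edges$regulator)),
              length(unique(object@edges$target))))
})

setMethod("show", "ExpressionProfiles", function(object) {
  cat(sprintf("ExpressionProfiles '%s': %d genes x %d samples\n",
              object@condition, nrow(object@values), ncol(object@values)))
})

setMethod("show", "TFSignature", function(object) {
  cat(sprintf("TFSignature: %d TFs (%d up, %d down)\n",
              length(object@tf), sum(object@direction > 0),
              sum(object@direction < 0)))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix '%s': %d x %d, %d nonzero entries\n",
              object@sample, length(object@nodes), length(object@nodes),
              Matrix::nnzero(object@P)))
})

setMethod("show", "StationaryDistribution", function(object) {
  cat(sprintf("StationaryDistribution '%s' (%s, beta=%g): %d nodes, residual %.2e\n",
              object@id, object@method, object@beta, length(object@nodes),
              object@residual))
  top <- head(order(-object@pi), 5L)
  cat("  top nodes:", paste(sprintf("%s=%.3g", object@nodes[top],
                                    object@pi[top]), collapse = ", "), "\n")
})

setMethod("show", "CompatibilityTable", function(object) {
  cat(sprintf("CompatibilityTable '%s': %d node-TF pairs, %d nodes (%d active, %d inactive)\n",
              object@condition, nrow(object@pairs), nrow(object@summary),
              sum(object@summary$call == "active", na.rm = TRUE),
              sum(object@summary$call == "inactive", na.rm = TRUE)))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario (seed %d): driver %s, decoy %s\n",
              object@seed, object@truth$driver, object@truth$decoy))
  show(object@network)
  show(object@signature)
})
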