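## Run configuration, end-to-end pipeline and report assembly.

#' Pipeline configuration
#'
#' Validates every tuning parameter against its domain before any file
#' is read or any computation starts.
#'
#' @param weight transition-weight function, see
#'   [buildTransitionMatrix()].
#' @param beta teleportation (damping) probability in (0, 1].
#' @param method stationary solver: `"linear"` (exact direct solve, the
#'   default), `"power"` or `"montecarlo"`.
#' @param tol power-iteration L1 tolerance.
#' @param maxIter power-iteration cap.
#' @param steps Monte Carlo walk length.
#' @param percentile hotspot percentile in (0, 100).
#' @param aggregate per-condition aggregation of sample distributions.
#' @param omegaVariant path-contribution variant, see [pathOmega()].
#' @param threshold activity-call threshold on the mean score.
#' @param maxPaths shortest-path truncation bound per node-TF pair.
#' @param seed integer seed (Monte Carlo solver and any other
#'   randomness).
#' @return validated configuration list (class `"hotspotConfig"`).
#' @export
hotspotConfig <- function(weight = "product", beta = 0.01,
                          method = "linear", tol = 1e-10,
                          maxIter = 100000L, steps = 1e6,
                          percentile = 90, aggregate = "mean",
                          omegaVariant = "geometric", threshold = 0.5,
                          maxPaths = 10000L, seed = 0L) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what,
                                          call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  chk(weight %in% c("product", "target", "min"), "weight")
  chk(num1(beta) && beta > 0 && beta <= 1, "beta must be in (0, 1]")
  chk(method %in% c("linear", "power", "montecarlo"), "method")
  chk(num1(tol) && tol > 0, "tol must be > 0")
  chk(num1(maxIter) && maxIter >= 1, "maxIter must be >= 1")
  chk(num1(steps) && steps >= 1, "steps must be >= 1")
  chk(num1(percentile) && percentile > 0 && percentile < 100,
      "percentile must be in (0, 100)")
  chk(aggregate %in% c("mean", "median"), "aggregate")
  chk(omegaVariant %in% c("geometric", "product", "arithmetic"),
      "omegaVariant")
  chk(num1(threshold) && threshold >= 0 && threshold <= 1,
      "threshold must be in [0, 1]")
  chk(num1(maxPaths) && maxPaths >= 1, "maxPaths must be >= 1")
  chk(num1(seed), "seed")
  structure(list(weight = weight, beta = beta, method = method,
                 tol = tol, maxIter = as.integer(maxIter), steps = steps,
                 percentile = percentile, aggregate = aggregate,
                 omegaVariant = omegaVariant, threshold = threshold,
                 maxPaths = as.integer(maxPaths),
                 seed = as.integer(seed)),
            class = "hotspotConfig")
}

#' Single-cell heterogeneity report
#'
#' Dispersion of the signalling landscape across cells: per-node
#' standard deviation and interquartile range of the stationary
#' probability, and the fraction of cells in which the node is selected
#' as a hotspot. Optionally the per-cell dispersion of compatibility
#' scores for a set of nodes.
#'
#' @param samplePis list of per-cell [StationaryDistribution-class]
#'   (>= 2 cells).
#' @param network a [SignalingNetwork-class].
#' @param percentile hotspot percentile applied per cell.
#' @param signature optional [TFSignature-class]; when given together
#'   with `scoreNodes`, per-cell compatibility scores are computed for
#'   those nodes and their sd reported.
#' @param scoreNodes nodes to score per cell (default: none).
#' @param grn optional [GeneRegulatoryNetwork-class].
#' @return data.frame with `node`, `layer`, `pi_mean`, `pi_sd`,
#'   `pi_iqr`, `hotspot_frac` and (when scored) `score_mean`,
#'   `score_sd`.
#' @export
heterogeneityReport <- function(samplePis, network, percentile = 90,
                                signature = NULL, scoreNodes = NULL,
                                grn = NULL) {
  if (length(samplePis) < 2L)
    stop("heterogeneity report needs >= 2 cells", call. = FALSE)
  nd <- nodes(samplePis[[1L]])
  M <- do.call(rbind, lapply(samplePis, function(p) p@pi))
  hot <- matrix(FALSE, nrow(M), length(nd),
                dimnames = list(NULL, nd))
  for (i in seq_along(samplePis)) {
    hs <- selectHotspots(samplePis[[i]], network, percentile)
    hot[i, hs$node[hs$hotspot]] <- TRUE
  }
  out <- data.frame(node = nd, layer = unname(nodeLayer(network)[nd]),
                    pi_mean = colMeans(M), pi_sd = apply(M, 2L, sd),
                    pi_iqr = apply(M, 2L, stats::IQR),
                    hotspot_frac = colMeans(hot),
                    stringsAsFactors = FALSE)
  if (!is.null(signature) && length(scoreNodes)) {
    sc <- sapply(scoreNodes, function(n0)
      vapply(samplePis, function(p)
        nodeCompatibility(n0, signature, network, p, grn = grn)$score,
        numeric(1)))
    sc <- matrix(sc, ncol = length(scoreNodes),
                 dimnames = list(NULL, scoreNodes))
    out$score_mean <- NA_real_; out$score_sd <- NA_real_
    idx <- match(scoreNodes, out$node)
    out$score_mean[idx] <- colMeans(sc, na.rm = TRUE)
    out$score_sd[idx] <- apply(sc, 2L, sd, na.rm = TRUE)
  }
  rownames(out) <- NULL
  out[order(-out$hotspot_frac, -out$pi_mean, out$node), ]
}

#' Run the full pipeline from input files
#'
#' Loads the interactome, optional regulatory layer, the two expression
#' matrices and the TF signature, runs [compareConditions()], and
#' writes per-condition pair and summary tables, hotspot and
#' stationary-probability tables, a score-difference table, an optional
#' single-cell heterogeneity report, and a JSON run manifest (inputs
#' with checksums, full configuration, seed, RNG, package version,
#' convergence statistics, warning counts).
#'
#' @param interactome,exprA,exprB,signature input file paths (see
#'   [loadInteractome()], [loadExpression()], [loadTFSignature()]).
#' @param grn optional regulatory-layer path.
#' @param tfCatalog optional TF-catalogue path for layer inference.
#' @param receptors optional character vector of declared receptors.
#' @param outDir output directory.
#' @param config a [hotspotConfig()].
#' @param singleCell force the single-cell heterogeneity report on/off;
#'   default `NA` enables it for MatrixMarket input with >= 2 cells.
#' @return the [compareConditions()] result, invisibly, with elements
#'   `files` (written paths) and `manifest` added.
#' @export
runPipeline <- function(interactome, exprA, exprB, signature,
                        grn = NULL, tfCatalog = NULL, receptors = NULL,
                        outDir = ".", config = hotspotConfig(),
                        singleCell = NA) {
  stopifnot(inherits(config, "hotspotConfig"))
  t0 <- Sys.time()
  inputs <- c(interactome = interactome, exprA = exprA, exprB = exprB,
              signature = signature,
              if (!is.null(grn)) c(grn = grn),
              if (!is.null(tfCatalog)) c(tfCatalog = tfCatalog))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", names(missing), missing),
               collapse = ", "), call. = FALSE)
  warnings <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  net <- wh(loadInteractome(interactome, tfCatalog = tfCatalog,
                            receptors = receptors))
  g <- if (!is.null(grn)) wh(loadGRN(grn, net))
  eA <- wh(loadExpression(exprA, condition = "A"))
  eB <- wh(loadExpression(exprB, condition = "B"))
  sig <- wh(loadTFSignature(signature))
  res <- wh(compareConditions(net, eA, eB, sig, grn = g,
                              config = config))

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outDir, ...)
  files <- character()
  wTab <- function(df, name) {
    write.table(df, fp(name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[[name]] <<- fp(name)
  }
  for (cc in c("A", "B")) {
    wTab(pairScores(res$tables[[cc]]), sprintf("pairs_%s.tsv", cc))
    wTab(nodeSummary(res$tables[[cc]]), sprintf("summary_%s.tsv", cc))
    wTab(res$hotspots[[cc]], sprintf("hotspots_%s.tsv", cc))
    pi <- res$pi[[cc]]
    wTab(data.frame(node = nodes(pi), pi = pi@pi,
                    sd_across_samples =
                      if (length(pi@dispersion)) pi@dispersion else NA,
                    condition = cc),
         sprintf("pi_%s.tsv", cc))
  }
  wTab(res$diff, "score_diff.tsv")

  isSC <- if (is.na(singleCell))
    grepl("\\.mtx$", exprA, ignore.case = TRUE) &&
      length(res$samplePis$A) >= 2L
  else isTRUE(singleCell)
  if (isSC && length(res$samplePis$A) >= 2L) {
    for (cc in c("A", "B")) {
      sig2 <- if (cc == "A") sig else flipSignature(sig)
      hs <- res$hotspots[[cc]]
      het <- heterogeneityReport(res$samplePis[[cc]], net,
                                 percentile = config$percentile,
                                 signature = sig2,
                                 scoreNodes = hs$node[hs$hotspot],
                                 grn = g)
      wTab(het, sprintf("heterogeneity_%s.tsv", cc))
    }
  } else if (isTRUE(singleCell)) {
    warnings <- c(warnings,
                  "single-cell report requested but < 2 samples; skipped")
  }

  manifest <- list(
    package = "SignalingHotspots",
    version = as.character(utils::packageVersion("SignalingHotspots")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    checksums = as.list(tools::md5sum(inputs)),
    config = unclass(config),
    rng = RNGkind()[1L],
    single_cell_report = isSC,
    network = list(nodes = length(nodes(net)),
                   edges = nrow(edgeTable(net))),
    samples = list(A = length(res$samplePis$A),
                   B = length(res$samplePis$B)),
    convergence = lapply(res$pi, function(p)
      list(method = config$method, beta = p@beta,
           total_iterations = p@iterations)),
    unmatched_nodes = as.list(res$unmatched),
    n_warnings = length(warnings),
    warnings = warnings,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files[["manifest.json"]] <- fp("manifest.json")
  res$files <- unlist(files)
  res$manifest <- manifest
  invisible(res)
}
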