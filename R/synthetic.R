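## Synthetic benchmark scenarios: a layered signed network with one
## planted activating driver cascade, one sign-contradicting decoy
## cascade, and matching two-condition expression.

.lnFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)                     # E[factor] = 1, CV = cv
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate a synthetic benchmark scenario
#'
#' Builds a layered random signed network (receptors -> intermediate
#' layers -> TFs, edges only between consecutive layers) and plants two
#' cascades through dedicated nodes:
#'
#' * a *driver* cascade `receptor -> driver -> ... -> {TF1, TF2}` whose
#'   edges are all activating, so the driver's net effect on both TFs is
#'   positive and matches their up direction in the signature;
#' * a *decoy* cascade of equal expression whose terminal edges are
#'   inhibitory, so the decoy's net effect contradicts the signature.
#'
#' Both cascades are expressed at `foldChange` times baseline in
#' condition A and at baseline in condition B, making both driver and
#' decoy high-traffic (hotspot) nodes in A while only the driver is
#' sign-compatible with the TF changes. Two external TFs reachable only
#' through the regulatory layer (one up-regulated, activated by TF1; one
#' down-regulated, repressed by TF2) complete the signature.
#'
#' Expression is log-normal around the condition mean for bulk data; in
#' single-cell mode, counts are Poisson around the (log-normally
#' perturbed) mean and then thinned by Bernoulli dropout. Everything is
#' reproducible from `seed` (Mersenne-Twister).
#'
#' @param nNodes total network nodes (>= 6); roughly 10% receptors and
#'   20% TFs.
#' @param nLayers number of layers including receptor and TF layers
#'   (>= 3).
#' @param edgeDensity probability of each between-consecutive-layer
#'   background edge.
#' @param nCells samples (bulk) or cells (single-cell) per condition.
#' @param dropout per-entry Bernoulli dropout probability in [0, 1)
#'   (single-cell mode only).
#' @param noiseCv coefficient of variation of the log-normal expression
#'   noise.
#' @param foldChange planted cascade fold-change over baseline.
#' @param baseline baseline mean expression (counts scale).
#' @param mode `"single-cell"` (default) or `"bulk"`.
#' @param seed integer seed.
#' @return a [SyntheticScenario-class].
#' @export
generateScenario <- function(nNodes = 60L, nLayers = 4L,
                             edgeDensity = 0.15, nCells = 100L,
                             dropout = 0.3, noiseCv = 0.2,
                             foldChange = 10, baseline = 5,
                             mode = c("single-cell", "bulk"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (nNodes < 6L) stop("nNodes must be >= 6", call. = FALSE)
  if (nLayers < 3L) stop("nLayers must be >= 3", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  set.seed(as.integer(seed))

  nRec <- max(2L, round(0.1 * nNodes))
  nTF <- max(3L, round(0.2 * nNodes))
  nInt <- nNodes - nRec - nTF
  nIntLayers <- nLayers - 2L
  if (nInt < max(4L, 2L * nIntLayers))
    stop("too few intermediate nodes for the requested layering",
         call. = FALSE)
  receptors <- sprintf("RC%02d", seq_len(nRec))
  inters <- sprintf("SG%02d", seq_len(nInt))
  tfs <- sprintf("TF%02d", seq_len(nTF))
  intLayers <- split(inters, sort(rep_len(seq_len(nIntLayers), nInt)))
  layerSeq <- c(list(receptors), intLayers, list(tfs))

  ## dedicated cascade nodes: one driver-chain and one decoy-chain node
  ## per intermediate layer
  chainD <- unname(vapply(intLayers, `[`, "", 1L))
  chainX <- unname(vapply(intLayers, `[`, "", 2L))
  ## the planted driver/decoy are the cascade intermediates directly
  ## upstream of the TF layer, where the walk concentrates its mass
  driver <- chainD[length(chainD)]; decoy <- chainX[length(chainX)]
  cascadeD <- c(receptors[1L], chainD)        # ends at last-layer node
  cascadeX <- c(receptors[2L], chainX)
  tf1 <- tfs[1L]; tf2 <- tfs[2L]

  ## background edges between consecutive layers
  from <- character(); to <- character()
  for (k in seq_len(length(layerSeq) - 1L)) {
    u <- layerSeq[[k]]; v <- layerSeq[[k + 1L]]
    pick <- which(matrix(runif(length(u) * length(v)), length(u)) <
                    edgeDensity, arr.ind = TRUE)
    f <- u[pick[, 1L]]; t <- v[pick[, 2L]]
    ## connectivity fill: every non-receptor an in-edge, every
    ## non-terminal node an out-edge
    needIn <- setdiff(v, t)
    f <- c(f, sample(u, length(needIn), replace = TRUE)); t <- c(t, needIn)
    needOut <- setdiff(u, f)
    f <- c(f, needOut); t <- c(t, sample(v, length(needOut), replace = TRUE))
    from <- c(from, f); to <- c(to, t)
  }
  sign <- ifelse(runif(length(from)) < 0.7, 1L, -1L)
  ed <- data.frame(from = from, to = to, sign = sign,
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$from, ed$to)), ]

  ## planted edges (control their signs exactly: drop background copies
  ## and cross-talk between the two cascades first)
  ## the cascade endpoints are convergence hubs (like Akt integrating
  ## many upstream inputs): extra activating in-edges from the
  ## preceding layer make the planted nodes genuine high-traffic
  ## mediators rather than leaving their in-degree to background luck
  prevLayer <- layerSeq[[length(layerSeq) - 2L]]
  hubPool <- setdiff(prevLayer, c(cascadeD, cascadeX))
  nHub <- min(4L, length(hubPool))
  planted <- rbind(
    data.frame(from = cascadeD[-length(cascadeD)], to = cascadeD[-1L],
               sign = 1L),
    data.frame(from = cascadeX[-length(cascadeX)], to = cascadeX[-1L],
               sign = 1L),
    data.frame(from = cascadeD[length(cascadeD)], to = c(tf1, tf2),
               sign = 1L),
    data.frame(from = cascadeX[length(cascadeX)], to = c(tf1, tf2),
               sign = -1L),
    data.frame(from = sample(hubPool, nHub),
               to = cascadeD[length(cascadeD)], sign = 1L),
    data.frame(from = sample(hubPool, nHub),
               to = cascadeX[length(cascadeX)], sign = 1L))
  cross <- rbind(
    data.frame(from = cascadeD, to = c(cascadeX[-1L], NA)),
    data.frame(from = cascadeX, to = c(cascadeD[-1L], NA)),
    data.frame(from = cascadeX[length(cascadeX)], to = c(tf1, tf2)),
    data.frame(from = cascadeD[length(cascadeD)], to = c(tf1, tf2)))
  drop <- paste(ed$from, ed$to) %in%
    paste(cross$from, cross$to) |
    paste(ed$from, ed$to) %in% paste(planted$from, planted$to)
  ed <- rbind(ed[!drop, ], planted)

  layers <- setNames(c(rep("receptor", nRec), rep("intermediate", nInt),
                       rep("tf", nTF)), c(receptors, inters, tfs))
  network <- SignalingNetwork(ed, layers = layers)

  extUp <- "XT01"; extDown <- "XT02"
  grn <- new("GeneRegulatoryNetwork",
             edges = data.frame(regulator = c(tf1, tf2),
                                target = c(extUp, extDown),
                                sign = c(1L, -1L),
                                stringsAsFactors = FALSE))
  signature <- TFSignature(c(tf1, tf2, extUp, extDown),
                           c("up", "up", "up", "down"))

  genes <- c(receptors, inters, tfs, extUp, extDown)
  highA <- c(cascadeD, cascadeX, tf1, tf2, extUp)
  meanA <- setNames(rep(baseline, length(genes)), genes)
  meanB <- meanA
  meanA[highA] <- foldChange * baseline
  meanB[extDown] <- foldChange * baseline

  simulate <- function(means, prefix) {
    m <- matrix(rep(means, nCells), nrow = length(genes),
                dimnames = list(genes, sprintf("%s%04d", prefix,
                                               seq_len(nCells))))
    noisy <- m * matrix(.lnFactor(length(m), noiseCv), nrow = nrow(m))
    if (mode == "bulk") return(noisy)
    counts <- matrix(rpois(length(noisy), noisy), nrow = nrow(noisy),
                     dimnames = dimnames(noisy))
    if (dropout > 0)
      counts[matrix(runif(length(counts)) < dropout,
                    nrow = nrow(counts))] <- 0
    counts
  }
  exprA <- ExpressionProfiles(simulate(meanA, "A"), condition = "A")
  exprB <- ExpressionProfiles(simulate(meanB, "B"), condition = "B")

  truth <- list(driver = driver, decoy = decoy,
                driver_cascade = c(cascadeD, tf1, tf2),
                decoy_cascade = cascadeX,
                expected_calls = list(driver = "active",
                                      decoy = "inactive"),
                signature_tfs = signature@tf,
                external_tfs = c(extUp, extDown))
  new("SyntheticScenario", network = network, grn = grn,
      exprA = exprA, exprB = exprB, signature = signature,
      truth = truth, seed = as.integer(seed),
      params = list(nNodes = nNodes, nLayers = nLayers,
                    edgeDensity = edgeDensity, nCells = nCells,
                    dropout = dropout, noiseCv = noiseCv,
                    foldChange = foldChange, baseline = baseline,
                    mode = mode, rng = "Mersenne-Twister"))
}

#' Write a scenario to disk in the package's input formats
#'
#' Emits `interactome.tsv`, `grn.tsv`, `signature.tsv`,
#' `expression_A.tsv` / `expression_B.tsv` (plus MatrixMarket triplets
#' `expression_<c>.mtx` with `.genes.tsv`/`.barcodes.tsv` sidecars in
#' single-cell mode) and `truth.json` — everything the loaders read
#' back.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(interactome = file.path(dir, "interactome.tsv"),
             grn = file.path(dir, "grn.tsv"),
             signature = file.path(dir, "signature.tsv"),
             exprA = file.path(dir, "expression_A.tsv"),
             exprB = file.path(dir, "expression_B.tsv"),
             truth = file.path(dir, "truth.json"))
  writeInteractome(scenario@network, paths["interactome"])
  ge <- edgeTable(scenario@grn)
  write.table(data.frame(regulator = ge$regulator,
                         sign = ifelse(ge$sign > 0, "+", "-"),
                         target = ge$target),
              paths["grn"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(signatureTable(scenario@signature), paths["signature"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeExpr <- function(ep, path) {
    v <- exprValues(ep)
    write.table(data.frame(gene = rownames(v), v, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (scenario@params$mode == "single-cell") {
      stem <- sub("\\.tsv$", "", path)
      Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE),
                      paste0(stem, ".mtx"))
      writeLines(rownames(v), paste0(stem, ".genes.tsv"))
      writeLines(colnames(v), paste0(stem, ".barcodes.tsv"))
    }
  }
  writeExpr(scenario@exprA, paths["exprA"])
  writeExpr(scenario@exprB, paths["exprB"])
  jsonlite::write_json(c(scenario@truth,
                         list(seed = scenario@seed,
                              params = scenario@params)),
                       paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
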