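## Stationary distribution of the damped signalling walk, per-condition
## aggregation and hotspot selection.

## One damped step: y = x P' with P' = (1-beta) P + (beta/n) J.
## sum(x) = 1 is maintained, so the teleport term is a constant beta/n.
.dampedStep <- function(x, P, beta) {
  as.numeric((1 - beta) * (x %*% P)) + beta / length(x)
}

.residualL1 <- function(pi, P, beta) {
  sum(abs(.dampedStep(pi, P, beta) - pi))
}

#' Stationary distribution of a transition matrix
#'
#' Solves for the stationary vector pi of the damped chain
#' `P' = (1-beta) P + (beta/n) J`. The uniform teleportation makes the
#' chain ergodic, so pi is unique even on reducible or periodic graphs.
#' Three solvers are available:
#'
#' * `"power"`: iterate `x <- x P'` from the uniform vector until the L1
#'   change drops below `tol`;
#' * `"linear"`: solve the linear system `pi P' = pi`, `sum(pi) = 1`
#'   directly (exact up to floating point);
#' * `"montecarlo"`: long-run visit frequencies of one simulated walk of
#'   `steps` steps (after `burnin` discarded steps), seeded via `seed`.
#'
#' @param x a [TransitionMatrix-class].
#' @param method solver; see Details.
#' @param beta teleportation (damping) probability in (0, 1]; default
#'   0.01.
#' @param tol L1 convergence tolerance of the power iteration (> 0).
#' @param maxIter maximum power iterations.
#' @param steps,burnin Monte Carlo walk length and discarded prefix.
#' @param seed integer seed for the Monte Carlo walk.
#' @return a [StationaryDistribution-class]; its `residual` slot records
#'   the achieved fixed-point defect `||pi P' - pi||_1`.
#' @examples
#' net <- SignalingNetwork(data.frame(from = c("A", "B"), to = c("B", "A"),
#'                                    sign = c(1, 1)))
#' tm <- buildTransitionMatrix(net, c(A = 1, B = 1))
#' stationaryVector(stationaryDistribution(tm))   # 0.5, 0.5 by symmetry
#' @export
stationaryDistribution <- function(x, method = c("power", "linear",
                                                 "montecarlo"),
                                   beta = 0.01, tol = 1e-10,
                                   maxIter = 100000L, steps = 1e6,
                                   burnin = 1000L, seed = 0L) {
  method <- match.arg(method)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]", call. = FALSE)
  P <- transitionMatrix(x)
  n <- length(nodes(x))
  iters <- 0L

  if (method == "power") {
    v <- rep(1 / n, n)
    repeat {
      vNew <- .dampedStep(v, P, beta)
      delta <- sum(abs(vNew - v))
      v <- vNew
      iters <- iters + 1L
      if (delta < tol) break
      if (iters >= maxIter)
        stop(sprintf("power iteration did not converge in %d iterations (last residual %.3e)",
                     maxIter, delta), call. = FALSE)
    }
    pi <- v / sum(v)
  } else if (method == "linear") {
    Pd <- (1 - beta) * as.matrix(P) + beta / n
    A <- t(diag(n) - Pd)            # pi (P' - I) = 0
    A[n, ] <- 1                     # replace one redundant row by sum(pi)=1
    b <- c(rep(0, n - 1L), 1)
    pi <- solve(A, b)
    pi[pi < 0 & pi > -1e-12] <- 0   # clip round-off negatives
    pi <- pi / sum(pi)
    iters <- 1L
  } else {
    if (steps < 1) stop("steps must be >= 1", call. = FALSE)
    Pd <- (1 - beta) * as.matrix(P) + beta / n
    cum <- t(apply(Pd, 1L, cumsum))
    set.seed(as.integer(seed))
    visits <- mc_walk_visits(cum, as.double(steps), as.integer(burnin))
    pi <- visits / sum(visits)
    iters <- as.integer(steps)
  }
  new("StationaryDistribution", nodes = nodes(x), pi = as.numeric(pi),
      id = x@sample, method = method, beta = beta, iterations = iters,
      residual = .residualL1(pi, P, beta), dispersion = numeric())
}

#' Aggregate per-sample distributions to condition level
#'
#' Element-wise mean (default) or median over samples, renormalised to
#' sum 1. The per-node standard deviation across samples is retained for
#' the single-cell heterogeneity report.
#'
#' @param pis list of [StationaryDistribution-class] objects over an
#'   identical node order.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param id condition identifier for the result.
#' @return a condition-level [StationaryDistribution-class].
#' @export
conditionPi <- function(pis, aggregate = c("mean", "median"), id = "") {
  aggregate <- match.arg(aggregate)
  if (!length(pis)) stop("need >= 1 sample distribution", call. = FALSE)
  nd <- nodes(pis[[1L]])
  for (p in pis)
    if (!identical(nodes(p), nd))
      stop("sample distributions have mismatched node orders", call. = FALSE)
  M <- do.call(rbind, lapply(pis, function(p) p@pi))
  agg <- if (aggregate == "mean") colMeans(M)
         else apply(M, 2L, median)
  agg <- agg / sum(agg)
  disp <- if (nrow(M) > 1L) apply(M, 2L, sd) else rep(0, ncol(M))
  new("StationaryDistribution", nodes = nd, pi = as.numeric(agg),
      id = as.character(id), method = paste0("aggregate-", aggregate),
      beta = pis[[1L]]@beta,
      iterations = sum(vapply(pis, function(p) p@iterations, 1L)),
      residual = NA_real_, dispersion = as.numeric(disp))
}

#' Select signalling hotspots from a condition-level distribution
#'
#' Hotspots are intermediate-layer nodes whose stationary probability
#' reaches the given percentile of the pi distribution over intermediate
#' nodes; ties at the threshold are all included. Receptors and TFs are
#' never hotspot candidates but are ranked within their own layers in the
#' returned table, so the receptor-layer ranking (candidate niche inputs)
#' stays available.
#'
#' @param pi a [StationaryDistribution-class] (condition level).
#' @param network the [SignalingNetwork-class] providing layer labels.
#' @param percentile hotspot percentile in (0, 100); default 90.
#' @return data.frame with columns `node`, `layer`, `pi`, `rank` (within
#'   layer, by decreasing pi then node id) and `hotspot` (logical; TRUE
#'   only possible for intermediates). Attributes `threshold` and
#'   `percentile` record the cutoff.
#' @export
selectHotspots <- function(pi, network, percentile = 90) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)", call. = FALSE)
  lay <- nodeLayer(network)[nodes(pi)]
  df <- data.frame(node = nodes(pi), layer = unname(lay),
                   pi = pi@pi, stringsAsFactors = FALSE)
  df <- df[order(df$layer, -df$pi, df$node), ]
  df$rank <- stats::ave(-df$pi, df$layer,
                        FUN = function(x) rank(x, ties.method = "min"))
  inter <- df$layer == "intermediate"
  if (!any(inter))
    stop("network has no intermediate-layer nodes", call. = FALSE)
  thr <- as.numeric(quantile(df$pi[inter], percentile / 100))
  df$hotspot <- inter & df$pi >= thr
  df <- df[order(match(df$layer, c("intermediate", "receptor", "tf")),
                 -df$pi, df$node), ]
  rownames(df) <- NULL
  attr(df, "threshold") <- thr
  attr(df, "percentile") <- percentile
  df
}
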