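test_that("transition probabilities are the expression share of the out-neighbourhood", {
  net <- SignalingNetwork(data.frame(from = c("A", "A"),
                                     to = c("B", "C"), sign = c(1L, 1L)))
  P <- transitionMatrix(buildTransitionMatrix(net, c(A = 2, B = 3, C = 1)))
  expect_equal(P["A", "B"], 0.75)
  expect_equal(P["A", "C"], 0.25)
  ## the source expression cancels in the row normalisation
  P2 <- transitionMatrix(buildTransitionMatrix(net, c(A = 9, B = 3, C = 1)))
  expect_equal(as.matrix(P), as.matrix(P2))
})

test_that("zero-weight rows are redistributed uniformly (dangling treatment)", {
  net <- SignalingNetwork(data.frame(from = c("A", "A"),
                                     to = c("B", "C"), sign = c(1L, 1L)))
  P <- transitionMatrix(buildTransitionMatrix(net, c(A = 2, B = 0, C = 0)))
  expect_equal(unname(as.matrix(P)["A", ]), rep(1 / 3, 3))
  ## terminal nodes (no out-edges) likewise
  expect_equal(unname(as.matrix(P)["B", ]), rep(1 / 3, 3))
})

test_that("all-zero expression is rejected", {
  net <- chainNetwork()
  expect_error(buildTransitionMatrix(net, c(L = 0, R = 0)),
               "no expressed nodes")
})

test_that("rows are stochastic on random instances, for every weight function", {
  for (seed in 1:20) {
    net <- randomTestNetwork(sample(5:40, 1), p = 0.2, seed = seed)
    e <- randomExpression(net, seed = seed + 100)
    e[sample(length(e), length(e) %/% 4)] <- 0   # some unexpressed nodes
    for (w in c("product", "target", "min")) {
      P <- transitionMatrix(buildTransitionMatrix(net, e, weight = w))
      expect_equal(unname(Matrix::rowSums(P)),
                   rep(1, length(nodes(net))), tolerance = 1e-12)
      expect_true(all(P@x >= 0 & P@x <= 1))
    }
  }
})

test_that("P is invariant under global expression rescaling", {
  net <- randomTestNetwork(15, seed = 3)
  e <- randomExpression(net, seed = 4)
  P1 <- transitionMatrix(buildTransitionMatrix(net, e))
  for (c0 in c(1e-6, 0.37, 1e6)) {
    P2 <- transitionMatrix(buildTransitionMatrix(net, c0 * e))
    expect_equal(as.matrix(P1), as.matrix(P2), tolerance = 1e-12)
  }
})

test_that("raising one out-neighbour's expression strictly raises its probability", {
  net <- SignalingNetwork(data.frame(from = c("A", "A", "A"),
                                     to = c("B", "C", "D"),
                                     sign = c(1L, 1L, 1L)))
  e <- c(A = 1, B = 2, C = 3, D = 4)
  p1 <- transitionMatrix(buildTransitionMatrix(net, e))["A", "B"]
  e["B"] <- 5
  p2 <- transitionMatrix(buildTransitionMatrix(net, e))["A", "B"]
  expect_gt(p2, p1)
})

test_that("a symmetric 2-cycle has the uniform stationary distribution", {
  net <- SignalingNetwork(data.frame(from = c("A", "B"), to = c("B", "A"),
                                     sign = c(1L, 1L)))
  tm <- buildTransitionMatrix(net, c(A = 1, B = 1))
  pi <- stationaryDistribution(tm, method = "power", beta = 0.01)
  expect_equal(unname(stationaryVector(pi)), c(0.5, 0.5))
})

test_that("a single self-looping node carries all the mass", {
  net <- SignalingNetwork(data.frame(from = "A", to = "A", sign = 1L))
  tm <- buildTransitionMatrix(net, c(A = 2))
  expect_equal(stationaryDistribution(tm)@pi, 1)
})

test_that("power, linear and Monte Carlo solvers agree", {
  net <- randomTestNetwork(10, p = 0.3, seed = 11)
  tm <- buildTransitionMatrix(net, randomExpression(net, seed = 12))
  p1 <- stationaryDistribution(tm, "power", tol = 1e-12)
  p2 <- stationaryDistribution(tm, "linear")
  p3 <- stationaryDistribution(tm, "montecarlo", steps = 4e5, seed = 99)
  expect_lt(sum(abs(p1@pi - p2@pi)), 1e-8)
  expect_lt(sum(abs(p3@pi - p2@pi)), 0.02)
  ## the Monte Carlo walk is reproducible from its seed
  p4 <- stationaryDistribution(tm, "montecarlo", steps = 4e5, seed = 99)
  expect_identical(p3@pi, p4@pi)
})

test_that("solver contracts: bad tolerance and non-convergence raise errors", {
  net <- chainNetwork()
  tm <- buildTransitionMatrix(net,
                              setNames(rep(1, 6), nodes(net)))
  expect_error(stationaryDistribution(tm, tol = 0), "tol")
  expect_error(stationaryDistribution(tm, maxIter = 2L, tol = 1e-14),
               "did not converge")
  expect_error(stationaryDistribution(tm, beta = 0), "beta")
})

test_that("condition aggregation is idempotent, averages and renormalises", {
  net <- randomTestNetwork(8, seed = 21)
  tm <- buildTransitionMatrix(net, randomExpression(net, seed = 22))
  p <- stationaryDistribution(tm, "linear")
  agg <- conditionPi(list(p, p), id = "cond")
  expect_equal(agg@pi, p@pi, tolerance = 1e-12)
  expect_equal(agg@dispersion, rep(0, length(p@pi)))
  ## mean of orthogonal distributions
  mk <- function(v) new("StationaryDistribution", nodes = c("a", "b"),
                        pi = v, id = "s", method = "linear", beta = 0.01,
                        iterations = 1L, residual = 0,
                        dispersion = numeric())
  agg2 <- conditionPi(list(mk(c(1, 0)), mk(c(0, 1))))
  expect_equal(agg2@pi, c(0.5, 0.5))
  expect_equal(sum(agg2@pi), 1, tolerance = 1e-10)
  mk2 <- new("StationaryDistribution", nodes = c("b", "a"),
             pi = c(0.5, 0.5), id = "s", method = "linear", beta = 0.01,
             iterations = 1L, residual = 0, dispersion = numeric())
  expect_error(conditionPi(list(mk(c(1, 0)), mk2)), "mismatched")
})

test_that("hotspot selection keeps top-percentile intermediates, with ties", {
  nd <- sprintf("I%02d", 1:10)
  net <- SignalingNetwork(
    data.frame(from = c(rep("RCP", 10), nd), to = c(nd, rep("TFX", 10)),
               sign = 1L), tfs = "TFX")
  mkpi <- function(v) {
    full <- setNames(rep(0, length(nodes(net))), nodes(net))
    full[nd] <- v
    new("StationaryDistribution", nodes = nodes(net),
        pi = full / sum(full), id = "c", method = "linear", beta = 0.01,
        iterations = 1L, residual = 0, dispersion = numeric())
  }
  hs <- selectHotspots(mkpi(c(0.19, rep(0.01, 9))), net, percentile = 90)
  expect_equal(hs$node[hs$hotspot], "I01")
  ## all-equal pi: everyone ties at the threshold and all are kept
  hs2 <- selectHotspots(mkpi(rep(0.1, 10)), net, percentile = 90)
  expect_equal(sum(hs2$hotspot), 10L)
  ## receptors and TFs are reported but never hotspots
  expect_true(all(!hs$hotspot[hs$layer != "intermediate"]))
  expect_error(selectHotspots(mkpi(rep(0.1, 10)), net, percentile = 150),
               "percentile")
  expect_error(selectHotspots(mkpi(rep(0.1, 10)), net, percentile = 0),
               "percentile")
})
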