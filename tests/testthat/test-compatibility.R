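## A fixed stationary vector (uniform) for tests that only exercise the
## sign/combinatorics layer.
uniformPi <- function(net) {
  n <- length(nodes(net))
  new("StationaryDistribution", nodes = nodes(net), pi = rep(1 / n, n),
      id = "c", method = "linear", beta = 0.01, iterations = 1L,
      residual = 0, dispersion = numeric())
}

test_that("single-path pairs score 1 when compatible, 0 when not", {
  net <- chainNetwork()
  pi <- uniformPi(net)
  ## L -> R -> K1 -> T1, all activating
  expect_equal(pairCompatibility("L", "T1", "up", net, pi)$score, 1)
  expect_equal(pairCompatibility("L", "T1", "down", net, pi)$score, 0)
  ## K1 -| T2, net inhibition matches "down"
  expect_equal(pairCompatibility("K1", "T2", "down", net, pi)$score, 1)
})

test_that("opposite-sign equal-contribution paths split the score", {
  net <- SignalingNetwork(data.frame(
    from = c("A", "A", "B", "C"), to = c("B", "C", "T", "T"),
    sign = c(1L, 1L, 1L, -1L)), tfs = "T")
  pc <- pairCompatibility("A", "T", "up", net, uniformPi(net))
  expect_equal(pc$score, 0.5)
  expect_equal(pc$nPaths, 2L)
  expect_equal(pc$nCompatible, 1L)
})

test_that("up and down scores are complementary whenever a path exists", {
  for (seed in 1:25) {
    net <- randomTestNetwork(sample(6:14, 1), p = 0.3, seed = seed)
    e <- randomExpression(net, seed = seed + 500)
    pi <- stationaryDistribution(buildTransitionMatrix(net, e), "linear")
    nd <- nodes(net)
    for (k in 1:4) {
      st <- sample(nd, 2)
      up <- pairCompatibility(st[1], st[2], "up", net, pi)
      if (up$nPaths == 0L) next
      dn <- pairCompatibility(st[1], st[2], "down", net, pi)
      expect_equal(up$score + dn$score, 1, tolerance = 1e-12)
    }
  }
})

test_that("pair scores match the brute-force recomputation on random networks", {
  for (seed in 1:20) {
    net <- randomTestNetwork(sample(6:15, 1), p = 0.3, seed = seed)
    ed <- edgeTable(net)
    e <- randomExpression(net, seed = seed + 900)
    pi <- stationaryDistribution(buildTransitionMatrix(net, e), "linear")
    piVec <- stationaryVector(pi)
    nd <- nodes(net)
    for (k in 1:4) {
      st <- sample(nd, 2)
      got <- pairCompatibility(st[1], st[2], "up", net, pi)$score
      want <- brutePairScore(ed, piVec, st[1], st[2], 1)
      expect_equal(got, want, tolerance = 1e-12,
                   info = sprintf("seed %d %s->%s", seed, st[1], st[2]))
    }
  }
})

test_that("node averages, activity calls and unreachable-TF exclusion", {
  net <- chainNetwork()
  pi <- uniformPi(net)
  ## K1 activates T1 and inhibits T2: signature (T1 up, T2 down) -> 1.0
  sig <- TFSignature(c("T1", "T2"), c("up", "down"))
  nc <- nodeCompatibility("K1", sig, net, pi)
  expect_equal(nc$score, 1)
  expect_equal(nc$call, "active")
  ## (T1 up, T2 up): scores (1, 0) -> exactly at the threshold
  nc2 <- nodeCompatibility("K1", TFSignature(c("T1", "T2"), c("up", "up")),
                           net, pi)
  expect_equal(nc2$score, 0.5)
  expect_equal(nc2$call, "indeterminate")
  ## K2 cannot reach T2: that pair is dropped, not scored 0
  nc3 <- nodeCompatibility("K2", sig, net, pi)
  expect_equal(nc3$nUsed, 1L)
  expect_equal(nc3$score, 1)
  ## a node reaching no signature TF gets an NA score
  nc4 <- nodeCompatibility("K2", TFSignature("T2", "down"), net, pi)
  expect_true(is.na(nc4$score))
  expect_equal(nc4$nUsed, 0L)
})

test_that("signature TFs outside the interactome are scored via one regulatory edge", {
  net <- chainNetwork()
  pi <- uniformPi(net)
  grn <- new("GeneRegulatoryNetwork",
             edges = data.frame(regulator = c("T1", "T2"),
                                target = c("FOXO6", "FOXO6"),
                                sign = c(1L, -1L)))
  ## without the GRN the external TF is unreachable
  expect_true(is.na(pairCompatibility("L", "FOXO6", "up", net, pi)$score))
  ## path L->R->K1->T1 (+) times GRN +: compatible with "up";
  ## T1 and T2 are equidistant so both regulators pool, with
  ## L->R->K1->T2 (-) times GRN (-) also giving +
  pc <- pairCompatibility("L", "FOXO6", "up", net, pi, grn = grn)
  expect_equal(pc$score, 1)
  expect_true(pc$viaGRN)
  ## the regulatory edge sign multiplies the propagated sign
  pc2 <- pairCompatibility("K1", "FOXO6", "down", net, pi,
                           grn = new("GeneRegulatoryNetwork",
                                     edges = data.frame(regulator = "T1",
                                                        target = "FOXO6",
                                                        sign = -1L)))
  expect_equal(pc2$score, 1)   # K1 -> T1 (+) times (-) = net inhibition
})

test_that("two identical conditions give exactly complementary scores", {
  suppressWarnings(sc <- generateScenario(nNodes = 30, nCells = 4,
                                          dropout = 0, noiseCv = 0.1,
                                          mode = "bulk", seed = 42))
  res <- compareConditions(sc@network, sc@exprA, sc@exprA, sc@signature,
                           grn = sc@grn)
  ## same expression -> same pi, same hotspot set
  expect_equal(res$pi$A@pi, res$pi$B@pi, tolerance = 1e-12)
  expect_equal(res$hotspots$A$node, res$hotspots$B$node)
  sa <- nodeSummary(res$tables$A); sb <- nodeSummary(res$tables$B)
  full <- sa$node[sa$n_tfs_used == length(sc@signature@tf)]
  for (nd in full) {
    expect_equal(sb$mean_score[sb$node == nd],
                 1 - sa$mean_score[sa$node == nd], tolerance = 1e-12)
  }
  expect_gt(length(full), 0)
})

test_that("the planted scenario separates driver and decoy across conditions", {
  suppressWarnings(sc <- generateScenario(nCells = 30, seed = 7))
  res <- compareConditions(sc@network, sc@exprA, sc@exprB, sc@signature,
                           grn = sc@grn)
  sa <- nodeSummary(res$tables$A)
  expect_true(sc@truth$driver %in% sa$node)
  expect_equal(sa$call[sa$node == sc@truth$driver], "active")
  ## the decoy contradicts the signature wherever it is scored
  piA <- res$pi$A
  ncX <- nodeCompatibility(sc@truth$decoy, sc@signature, sc@network, piA,
                           grn = sc@grn)
  expect_equal(ncX$call, "inactive")
})
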