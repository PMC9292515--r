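test_that("a SIF interactome parses into the expected signed network", {
  f <- withr::local_tempfile(lines = c("L\t+\tR", "R\t+\tK", "K\t-\tT"),
                             fileext = ".sif")
  net <- loadInteractome(f, dialect = "sif")
  expect_setequal(nodes(net), c("L", "R", "K", "T"))
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 3L)
  expect_equal(ed$sign[ed$from == "K"], -1L)
  expect_equal(sum(ed$sign == 1L), 2L)
  ## layer inference: in-degree 0 -> receptor, rest intermediate
  expect_equal(unname(nodeLayer(net)[c("L", "R", "T")]),
               c("receptor", "intermediate", "intermediate"))
})

test_that("TF catalogue and explicit layer column drive layer assignment", {
  f <- withr::local_tempfile(lines = c("L\t+\tR", "R\t+\tK", "K\t-\tT"),
                             fileext = ".sif")
  cat_f <- withr::local_tempfile(lines = "T")
  net <- loadInteractome(f, dialect = "sif", tfCatalog = cat_f)
  expect_equal(unname(nodeLayer(net)["T"]), "tf")
  ## a catalogued TF with no incoming edge cannot sit in the tf layer
  cat2 <- withr::local_tempfile(lines = "L")
  expect_warning(net2 <- loadInteractome(f, dialect = "sif",
                                         tfCatalog = cat2),
                 "no incoming edge")
  expect_equal(unname(nodeLayer(net2)["L"]), "receptor")
})

test_that("unknown sign tokens fail loudly, naming the row", {
  f <- withr::local_tempfile(lines = c("A\t+\tB", "B\t0\tC"),
                             fileext = ".sif")
  expect_error(loadInteractome(f, dialect = "sif"),
               "unknown sign token '0'.*row 2")
})

test_that("contradictory duplicate edges collapse to inhibition with a warning", {
  f <- withr::local_tempfile(lines = c("A\t+\tB", "A\t-\tB"),
                             fileext = ".sif")
  expect_warning(net <- loadInteractome(f, dialect = "sif"),
                 "contradictory")
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$sign, -1L)
  ## consistent duplicates collapse silently
  f2 <- withr::local_tempfile(lines = c("A\t+\tB", "A\t+\tB"),
                              fileext = ".sif")
  expect_silent(net2 <- loadInteractome(f2, dialect = "sif"))
  expect_equal(edgeTable(net2)$sign, 1L)
})

test_that("write/load round-trips preserve edges, signs and layers", {
  net <- chainNetwork()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeInteractome(net, f)
  net2 <- loadInteractome(f)
  ed1 <- edgeTable(net)[order(edgeTable(net)$from, edgeTable(net)$to), ]
  ed2 <- edgeTable(net2)[order(edgeTable(net2)$from, edgeTable(net2)$to), ]
  expect_equal(ed1$sign, ed2$sign)
  expect_equal(ed1$from, ed2$from)
  expect_equal(ed1$to, ed2$to)
  expect_equal(nodeLayer(net2)[nodes(net)], nodeLayer(net))
})

test_that("expression loads identically from TSV and MatrixMarket", {
  vals <- matrix(c(5, 0, 1.5, 0, 2, 0), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  d <- withr::local_tempdir()
  tsv <- file.path(d, "expr.tsv")
  write.table(data.frame(gene = rownames(vals), vals), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE),
                  file.path(d, "expr.mtx"))
  writeLines(rownames(vals), file.path(d, "expr.genes.tsv"))
  writeLines(colnames(vals), file.path(d, "expr.barcodes.tsv"))
  e1 <- loadExpression(tsv)
  e2 <- loadExpression(file.path(d, "expr.mtx"))
  expect_equal(exprValues(e1), exprValues(e2))
  expect_equal(exprValues(e2)["G1", "S1"], 5)
  expect_equal(unname(exprValues(e2)["G2", ]), c(0, 2))
})

test_that("expression contracts: no negatives, no empties, NA -> 0, duplicates summed", {
  f <- withr::local_tempfile(lines = c("gene\tS1", "G1\t-2.3"))
  expect_error(loadExpression(f), "non-negative")
  f2 <- withr::local_tempfile(lines = "gene\tS1")
  expect_error(loadExpression(f2), "empty")
  expect_warning(e <- ExpressionProfiles(matrix(c(1, NA), 2,
                   dimnames = list(c("G1", "G2"), NULL))),
                 "missing")
  expect_equal(unname(exprValues(e)["G2", 1]), 0)
  expect_message(e2 <- ExpressionProfiles(matrix(c(1, 2), 2,
                   dimnames = list(c("G1", "G1"), NULL))),
                 "duplicate")
  expect_equal(unname(exprValues(e2)["G1", 1]), 3)
})

test_that("TF signatures parse, deduplicate and reject conflicts", {
  f <- withr::local_tempfile(lines = c("FOXO1\tup", "MYOD1\tdown"))
  sig <- loadTFSignature(f)
  expect_equal(signatureTable(sig),
               data.frame(tf = c("FOXO1", "MYOD1"),
                          direction = c("up", "down")))
  f2 <- withr::local_tempfile(lines = c("FOXO1\tup", "FOXO1\tdown"))
  expect_error(loadTFSignature(f2), "conflicting")
  f3 <- withr::local_tempfile(lines = character())
  expect_error(loadTFSignature(f3), "must contain >=1 TF")
  ## header rows are tolerated
  f4 <- withr::local_tempfile(lines = c("tf\tdirection", "FOXO1\t-1"))
  expect_equal(signatureTable(loadTFSignature(f4))$direction, "down")
})

test_that("GRN regulators must be tf-layer nodes of the interactome", {
  net <- chainNetwork()
  f <- withr::local_tempfile(lines = c("regulator\tsign\ttarget",
                                       "T1\t+\tFOXO6"))
  grn <- loadGRN(f, network = net)
  expect_equal(edgeTable(grn)$target, "FOXO6")
  f2 <- withr::local_tempfile(lines = c("regulator\tsign\ttarget",
                                        "K1\t+\tFOXO6"))
  expect_error(loadGRN(f2, network = net), "not tf-layer")
})
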