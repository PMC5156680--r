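test_that("predictor verdicts follow each method's published rule", {
  sc <- data.frame(mutation = c("m1", "m2"),
                   provean = c(-3.0, -1.0),
                   mutation_assessor = c(2.5, 1.0),
                   polyphen2 = c(0.9, 0.1),
                   ponp2 = c(0.8, 0.2),
                   snap2 = c(-1, 3),
                   mutpred = c(0.9, 0.2),
                   align_gvgd = c("C65", "C0"))
  out <- consensusClassify(sc)
  expect_equal(out$verdict_provean, c("deleterious", "neutral"))
  expect_equal(out$consensusCount, c(7L, 0L))
  expect_equal(out$completeConsensus, c(TRUE, FALSE))
  expect_equal(out$nMethods, c(7L, 7L))

  expect_error(consensusClassify(cbind(sc, sift = 0.1)), "sift")
})

test_that("missing scores shrink the consensus denominator, order is irrelevant", {
  sc <- data.frame(mutation = "m", provean = -5, snap2 = NA_real_,
                   mutpred = 0.9)
  out <- consensusClassify(sc)
  expect_equal(out$nMethods, 2L)
  expect_equal(out$consensusCount, 2L)
  expect_true(out$completeConsensus)

  sc2 <- sc[, c("mutation", "mutpred", "provean", "snap2")]
  out2 <- consensusClassify(sc2)
  expect_equal(out2$consensusCount, out$consensusCount)
  expect_equal(out2$completeConsensus, out$completeConsensus)
})

test_that("planted consensus classes are recovered exactly", {
  classes <- rep("mixed", 44L)
  classes[c(3, 7, 10, 15, 21, 28, 33, 39, 44)] <- "deleterious-consensus"
  classes[1:5][classes[1:5] == "mixed"] <- "neutral-consensus"
  tab <- makePredictorTable(sprintf("M%02d", 1:44), classes, seed = 12)
  out <- consensusClassify(tab)
  expect_equal(sum(out$completeConsensus), 9L)
  expect_equal(which(out$completeConsensus),
               c(3L, 7L, 10L, 15L, 21L, 28L, 33L, 39L, 44L))
  expect_equal(out$consensusCount[classes == "neutral-consensus"],
               rep(0L, sum(classes == "neutral-consensus")))
  mixed <- out$consensusCount[classes == "mixed"]
  expect_true(all(mixed >= 1L & mixed <= 6L))
})

test_that("docking filter keeps strictly favourable energies only", {
  e <- data.frame(complex = c("a", "b", "c", "d"),
                  energy = c(-33.5, -1.0, -2.39, -40))
  out <- filterDocking(e)
  expect_equal(out$complex, c("d", "a"))   # sorted ascending
  expect_false("c" %in% out$complex)       # boundary is strict
})

test_that("node value is the absolute difference of median log2 counts", {
  counts <- rbind(g1 = c(3, 3, 3, 1, 1, 1),
                  g2 = c(10, 12, 14, 10, 12, 14))
  pcm <- pairedCountMatrix(counts,
                           condition = rep(c("tumor", "normal"), each = 3),
                           patient = rep(paste0("p", 1:3), 2))
  expect_equal(nodeValue(pcm, "g1"), 1)          # |log2(4) - log2(2)|
  expect_equal(nodeValue(pcm, "g2"), 0)
  ## invariant to sample order within conditions
  perm <- pairedCountMatrix(counts[, c(2, 3, 1, 6, 4, 5)],
                            condition = rep(c("tumor", "normal"), each = 3),
                            patient = paste0("p", c(2, 3, 1, 3, 1, 2)))
  expect_equal(nodeValue(perm, "g1"), 1)
  expect_error(nodeValue(pcm, "g9"), "not found")
})

test_that("edge value correlates paired per-patient log2 changes", {
  ## gene B's changes exactly equal gene A's -> r = 1; gene C's changes
  ## are 4,3,2,1 against gene A's 0,1,2,3 -> r = -1 exactly
  tumor <- rbind(gA = c(1, 3, 7, 15), gB = c(1, 3, 7, 15),
                 gC = c(15, 7, 3, 1), gD = c(5, 5, 5, 5))
  normal <- matrix(1, 4, 4, dimnames = list(rownames(tumor), NULL))
  normal["gC", ] <- 0
  pcm <- pairedCountMatrix(cbind(tumor, normal),
                           condition = rep(c("tumor", "normal"), each = 4),
                           patient = rep(paste0("p", 1:4), 2))
  expect_equal(edgeValue(pcm, "gA", "gB"), 1)
  expect_equal(edgeValue(pcm, "gA", "gC"), -1)
  expect_equal(edgeValue(pcm, "gA", "gB"), edgeValue(pcm, "gB", "gA"))
  ## zero variance is NA with a warning, never silently 0
  expect_warning(r <- edgeValue(pcm, "gA", "gD"), "undefined")
  expect_true(is.na(r))
})

test_that("edge value matches a direct Pearson computation", {
  tumor <- rbind(gA = c(3, 9, 2, 30), gB = c(7, 2, 19, 4))
  normal <- rbind(gA = c(2, 2, 5, 6), gB = c(3, 8, 2, 9))
  pcm <- pairedCountMatrix(cbind(tumor, normal),
                           condition = rep(c("tumor", "normal"), each = 4),
                           patient = rep(paste0("p", 1:4), 2))
  da <- log2(tumor["gA", ] + 1) - log2(normal["gA", ] + 1)
  db <- log2(tumor["gB", ] + 1) - log2(normal["gB", ] + 1)
  want <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  expect_equal(edgeValue(pcm, "gA", "gB"), want, tolerance = 1e-12)
  expect_true(abs(want) <= 1)
  ## tumor-only mode uses tumor samples only
  la <- log2(tumor["gA", ] + 1); lb <- log2(tumor["gB", ] + 1)
  expect_equal(edgeValue(pcm, "gA", "gB", mode = "tumor_only"),
               cor(la, lb), tolerance = 1e-12)
})

test_that("paired mode demands enough properly paired patients", {
  counts <- rbind(gA = 1:4, gB = 4:1)
  pcm <- pairedCountMatrix(counts,
                           condition = c("tumor", "tumor", "normal",
                                         "normal"),
                           patient = c("p1", "p2", "p1", "p2"))
  expect_error(edgeValue(pcm, "gA", "gB"), "at least 3")
  expect_error(edgeValue(pcm, "gA", "gB", mode = "tumor_only"),
               "at least 3")
})

test_that("annotation networks carry attributes and survive a round trip", {
  nv <- c(MZF1 = 1.4, CDK4 = 0.2, SCAND1 = 0.9)
  edges <- data.frame(geneA = c("MZF1", "MZF1"),
                      geneB = c("CDK4", "SCAND1"))
  g <- buildAnnotationNetwork(edges, nv, c(0.8, -0.35))
  expect_equal(igraph::V(g)$name, names(nv))
  expect_equal(igraph::V(g)$abs_log2_median_diff, unname(nv))
  expect_equal(igraph::E(g)$pearson_r, c(0.8, -0.35))

  f <- withr::local_tempfile(fileext = ".graphml")
  writeAnnotationNetwork(g, f)
  back <- readAnnotationNetwork(f)
  idx <- match(igraph::V(g)$name, igraph::V(back)$name)
  expect_equal(igraph::V(back)$abs_log2_median_diff[idx],
               igraph::V(g)$abs_log2_median_diff)
  expect_equal(sort(igraph::E(back)$pearson_r),
               sort(igraph::E(g)$pearson_r))

  expect_error(buildAnnotationNetwork(
    data.frame(geneA = "MZF1", geneB = "ZNF24"), nv, 0.5), "ZNF24")
  empty <- buildAnnotationNetwork(edges[0, ], nv, numeric(0))
  expect_equal(igraph::gorder(empty), 3L)
  expect_equal(igraph::gsize(empty), 0L)
})
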