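test_that("frame contacts respect the cutoff boundary convention", {
  coms <- rbind(c(0, 0, 0), c(0.49, 0, 0))
  expect_equal(nrow(frameContacts(coms, 0.5)), 1L)
  expect_equal(nrow(frameContacts(rbind(c(0, 0, 0), c(0.6, 0, 0)), 0.5)),
               0L)
  atcut <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  expect_equal(nrow(frameContacts(atcut, 0.5)), 1L)   # inclusive default
  expect_equal(nrow(frameContacts(atcut, 0.5, boundaryInclusive = FALSE)),
               0L)
})

test_that("frame contacts match an all-pairs brute-force check", {
  for (s in 1:20) {
    coms <- withr::with_seed(s, matrix(runif(30, 0, 1.5), 10L, 3L))
    got <- frameContacts(coms, 0.6)
    want <- do.call(rbind, lapply(1:9, function(i)
      do.call(rbind, lapply((i + 1):10, function(j) {
        if (sqrt(sum((coms[i, ] - coms[j, ])^2)) <= 0.6)
          data.frame(i = i, j = j)
      }))))
    if (is.null(want)) want <- data.frame(i = integer(0), j = integer(0))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("edge occurrence is the contact frame fraction, filtered at pCrit", {
  ens <- makeDimerEnsemble(20, 4, rbind(
    contactSpec("A", 1, "B", 1, persistence = 0.5),
    contactSpec("A", 2, "B", 2, persistence = 0.15)), seed = 8)
  psn <- buildPsn(ens, pCrit = 0.20)
  e <- psnEdges(psn)
  expect_equal(nrow(e), 1L)           # the 15% contact is filtered out
  expect_equal(e$occurrence, 0.5)
  ## the 3-in-20-frames contact survives only if pCrit is lowered
  e2 <- psnEdges(buildPsn(ens, pCrit = 0.10))
  expect_equal(sort(e2$occurrence), c(0.15, 0.5))
})

test_that("planted contact persistence is recovered under coordinate noise", {
  ens <- makeDimerEnsemble(500, 4,
                           contactSpec("A", 1, "B", 2, persistence = 0.35),
                           noiseSd = 0.01, seed = 13)
  e <- psnEdges(buildPsn(ens))
  expect_equal(nrow(e), 1L)
  expect_lt(abs(e$occurrence - 0.35), 0.05)
})

test_that("raising pCrit never adds edges; raising the cutoff never removes contacts", {
  ens <- makeDimerEnsemble(50, 5, rbind(
    contactSpec("A", 1, "B", 1, 0.9), contactSpec("A", 2, "B", 2, 0.5),
    contactSpec("A", 3, "B", 3, 0.25)), noiseSd = 0.02, seed = 21)
  key <- function(e) paste(e$from, e$to)
  prev <- NULL
  for (pc in c(0.1, 0.3, 0.6, 0.95)) {
    e <- key(psnEdges(buildPsn(ens, pCrit = pc)))
    if (!is.null(prev)) expect_true(all(e %in% prev))
    prev <- e
  }
  coms <- withr::with_seed(4, matrix(runif(24, 0, 1), 8L, 3L))
  prevN <- -1L
  for (cut in c(0.2, 0.4, 0.6, 1.0)) {
    e <- frameContacts(coms, cut)
    expect_gte(nrow(e), prevN)
    prevN <- nrow(e)
  }
})

test_that("hub detection follows the degree threshold and its strict variant", {
  star <- graphAsPsn(5, data.frame(i = 1L, j = 2:5))
  hubs <- findHubs(star, 3)
  expect_equal(hubs$label, "R1_A")
  expect_equal(hubs$degree, 4L)
  path <- graphAsPsn(5, data.frame(i = 1:4, j = 2:5))
  expect_equal(nrow(findHubs(path, 3)), 0L)
  ## degree exactly 3: in by the at-least rule, out by the strict rule
  star3 <- graphAsPsn(4, data.frame(i = 1L, j = 2:4))
  expect_equal(findHubs(star3, 3)$label, "R1_A")
  expect_equal(nrow(findHubs(star3, 3, strictlyGreater = TRUE)), 0L)
})

test_that("a planted hub is recovered with its planted degree", {
  ens <- makeDimerEnsemble(30, 6, rbind(
    contactSpec("A", 1, "B", 2, 0.8), contactSpec("A", 1, "B", 3, 0.7),
    contactSpec("A", 1, "B", 4, 0.6), contactSpec("A", 1, "B", 5, 0.9)),
    noiseSd = 0.01, seed = 17)
  hubs <- findHubs(buildPsn(ens))
  expect_equal(hubs$label, "A1_A")
  expect_equal(hubs$degree, 4L)
})

test_that("connected components partition non-orphans; orphans have degree zero", {
  two <- graphAsPsn(7, data.frame(i = c(1, 2, 1, 4, 5, 4),
                                  j = c(2, 3, 3, 5, 6, 6)))
  cc <- connectedComponents(two)
  expect_equal(cc$sizes, c(3L, 3L))
  expect_equal(cc$orphans, "R7_A")
  expect_equal(sort(unlist(cc$components)),
               sort(setdiff(psnNodes(two)$label, cc$orphans)))

  empty <- graphAsPsn(4, data.frame(i = integer(0), j = integer(0)))
  cce <- connectedComponents(empty)
  expect_equal(length(cce$components), 0L)
  expect_equal(length(cce$orphans), 4L)
})

test_that("components match the union-find oracle on random graphs", {
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(3:12, 1L))
    edges <- withr::with_seed(s + 1000, randomGraph(n, 0.25))
    cc <- connectedComponents(graphAsPsn(n, edges))
    want <- oracleComponents(n, edges)
    want <- Filter(function(x) length(x) > 1L, want)  # singletons = orphans
    got <- lapply(cc$components, function(ns)
      sort(as.integer(sub("^R(\\d+)_A$", "\\1", ns))))
    expect_equal(sort(vapply(got, paste, character(1), collapse = ",")),
                 sort(vapply(lapply(want, sort), paste, character(1),
                             collapse = ",")))
  }
})

test_that("cutoff diagnostic flags collapse and handles edgeless cutoffs", {
  ens <- makeDimerEnsemble(5, 5, noiseSd = 0.01, seed = 2)
  d <- cutoffDiagnostic(ens, c(0.001, 0.5, 50))
  expect_equal(d$nEdges[1L], 0L)
  expect_equal(d$top5[1L], "")
  expect_false(d$collapsed[2L])
  expect_true(d$collapsed[3L])               # giant component at huge cutoff
  expect_equal(d$largestFraction[3L], 1)
  expect_true(!is.unsorted(d$nEdges))
})

test_that("shortest paths carry occurrence weights with consistent sums", {
  direct <- graphAsPsn(3, data.frame(i = c(1, 2), j = c(2, 3)),
                       occurrence = c(0.8, 0.6))
  sp <- shortestPaths(direct, "R1_A", "R2_A")
  expect_true(sp$connected)
  expect_equal(sp$length, 1L)
  expect_equal(sp$paths[[1L]]$sumWeight, 80)
  ## 7-node chain: 6 edges at 68.6% -> sum 411.6, average 68.6
  chain <- graphAsPsn(7, data.frame(i = 1:6, j = 2:7),
                      occurrence = rep(0.686, 6L))
  sp7 <- shortestPaths(chain, "R1_A", "R7_A")
  expect_equal(sp7$paths[[1L]]$sumWeight, 411.6, tolerance = 1e-9)
  expect_equal(sp7$paths[[1L]]$avgWeight, 68.6, tolerance = 1e-9)
  for (p in sp7$paths)
    expect_lt(abs(p$avgWeight - p$sumWeight / (length(p$nodes) - 1L)),
              0.05)
})

test_that("disconnected node pairs give a disconnected result, not an error", {
  g <- graphAsPsn(4, data.frame(i = 1L, j = 2L))
  sp <- shortestPaths(g, "R1_A", "R4_A")
  expect_false(sp$connected)
  expect_equal(length(sp$paths), 0L)
  expect_error(shortestPaths(g, "R1_A", "R1_A"), "must differ")
  expect_error(shortestPaths(g, "R1_A", "nope"), "not in network")
})

test_that("minimal path sets match the BFS enumeration oracle", {
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(4:12, 1L))
    edges <- withr::with_seed(s + 500, randomGraph(n, 0.3))
    st <- withr::with_seed(s + 900, sample(n, 2L))
    sp <- shortestPaths(graphAsPsn(n, edges),
                        paste0("R", st[1L], "_A"),
                        paste0("R", st[2L], "_A"))
    want <- oraclePaths(n, edges, st[1L], st[2L])
    if (!length(want)) {
      expect_false(sp$connected)
    } else {
      got <- lapply(sp$paths, function(p)
        as.integer(sub("^R(\\d+)_A$", "\\1", p$nodes)))
      expect_equal(sort(vapply(got, paste, character(1), collapse = ",")),
                   sort(vapply(want, paste, character(1), collapse = ",")))
    }
  }
})

test_that("jack-knife similarity is 1 for invariant ensembles and high when stationary", {
  still <- makeDimerEnsemble(20, 4, contactSpec("A", 1, "B", 1, 1.0),
                             seed = 5)
  jk <- jackknifePsn(still)
  expect_equal(nrow(jk$blocks), 10L)
  expect_true(all(jk$blocks$edgeJaccard == 1))
  expect_true(all(jk$blocks$hubOverlap == 1))

  jk0 <- jackknifePsn(still, dropFraction = 0)
  expect_equal(jk0$meanEdgeJaccard, 1)

  expect_error(jackknifePsn(makeDimerEnsemble(5, 3, seed = 1)),
               "at least 10 frames")

  stat <- makeDimerEnsemble(200, 5, rbind(
    contactSpec("A", 1, "B", 1, 0.9), contactSpec("A", 2, "B", 2, 0.6),
    contactSpec("A", 3, "B", 3, 0.4)), noiseSd = 0.01, seed = 31)
  expect_gte(jackknifePsn(stat)$meanEdgeJaccard, 0.9)
})

test_that("graph export writes edge lists and GraphML with node attributes", {
  psn <- graphAsPsn(5, data.frame(i = c(1, 1, 1, 4), j = c(2, 3, 5, 5)),
                    occurrence = c(0.9, 0.8, 0.7, 0.3))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePsnGraph(psn, f)
  e <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(e), 4L)
  nodes <- read.table(paste0(f, ".nodes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nodes$degree[nodes$label == "R1_A"], 3L)
  expect_true(nodes$hub[nodes$label == "R1_A"])
  g <- withr::local_tempfile(fileext = ".graphml")
  writePsnGraph(psn, g, format = "graphml")
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(sort(igraph::E(back)$occurrence), c(0.3, 0.7, 0.8, 0.9))
})
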