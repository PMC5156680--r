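## Independent brute-force oracles. These deliberately avoid igraph and the
## package's own graph code: components by union-find, shortest paths by
## exhaustive BFS-layered enumeration.

oracleComponents <- function(nNodes, edges) {
  parent <- seq_len(nNodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      a <- find(edges$i[k]); b <- find(edges$j[k])
      if (a != b) parent[a] <- b
    }
  roots <- vapply(seq_len(nNodes), find, integer(1))
  unname(split(seq_len(nNodes), roots))
}

## All minimal-hop paths between s and t by breadth-first layering plus
## recursive backtracking over the predecessor structure.
oraclePaths <- function(nNodes, edges, s, t) {
  adj <- vector("list", nNodes)
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      adj[[edges$i[k]]] <- c(adj[[edges$i[k]]], edges$j[k])
      adj[[edges$j[k]]] <- c(adj[[edges$j[k]]], edges$i[k])
    }
  dist <- rep(Inf, nNodes)
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]])
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
  }
  if (is.infinite(dist[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) {
      paths[[length(paths) + 1L]] <<- rev(c(acc, s))
      return(invisible())
    }
    for (w in adj[[v]])
      if (dist[w] == dist[v] - 1) walk(w, c(acc, v))
  }
  walk(t, integer(0))
  paths
}

randomGraph <- function(nNodes, pEdge = 0.3) {
  pairs <- which(upper.tri(matrix(TRUE, nNodes, nNodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < pEdge
  data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L])
}

## Wrap an abstract integer-labelled graph as a Psn (nodes R1_A..Rn_A).
graphAsPsn <- function(nNodes, edges, occurrence = NULL) {
  nodes <- data.frame(chain = "A", resnum = seq_len(nNodes),
                      resname = "ARG")
  lab <- paste0("R", seq_len(nNodes), "_A")
  occ <- if (is.null(occurrence)) rep(0.5, nrow(edges)) else occurrence
  psnFromEdges(nodes,
               data.frame(from = lab[edges$i], to = lab[edges$j],
                          occurrence = occ))
}

## Independent RMSIP oracle: own Kabsch superposition (mirroring the
## two-pass fit-to-mean scheme), PCA by SVD of the centred coordinate
## matrix, and an explicit double loop over inner products.
oracleRmsip <- function(ensA, ensB, nModes) {
  caMat <- function(ens) {
    at <- atomData(ens)
    idx <- which(at$atom == "CA")
    x <- ensCoords(ens)[idx, , , drop = FALSE]
    t(apply(x, 3L, function(fr) as.vector(t(fr))))
  }
  kabsch <- function(ref, xyz) {
    refM <- matrix(ref, ncol = 3L, byrow = TRUE)
    refC <- scale(refM, scale = FALSE)
    t(apply(xyz, 1L, function(row) {
      m <- matrix(row, ncol = 3L, byrow = TRUE)
      mc <- scale(m, scale = FALSE)
      s <- svd(t(mc) %*% refC)
      d <- sign(det(s$v %*% t(s$u)))
      rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      fitted <- mc %*% t(rot)
      as.vector(t(sweep(fitted, 2L, -colMeans(refM))))
    }))
  }
  modes <- function(ens) {
    xyz <- caMat(ens)
    fitted <- kabsch(xyz[1L, ], xyz)
    for (i in 1:2) fitted <- kabsch(colMeans(fitted), fitted)
    centred <- scale(fitted, scale = FALSE)
    sv <- svd(centred)
    sv$v[, seq_len(nModes), drop = FALSE]
  }
  va <- modes(ensA); vb <- modes(ensB)
  total <- 0
  for (i in seq_len(nModes))
    for (j in seq_len(nModes))
      total <- total + sum(va[, i] * vb[, j])^2
  sqrt(total / nModes)
}
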