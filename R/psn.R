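## Node label in the field's residue notation, e.g. "C69_A".
.nodeLabels <- function(rt)
  paste0(.AA3_TO_1[rt$resname], rt$resnum, "_", rt$chain)

#' Contacts within a single frame
#'
#' Edge set for one frame: every pair of residues whose side-chain centres
#' of mass are within the distance cutoff (boundary inclusive by default,
#' i.e. d <= cutoff counts as a contact).
#'
#' @param coms numeric matrix \code{nResidues x 3} of side-chain COMs (nm)
#' @param cutoff contact distance cutoff in nm
#' @param boundaryInclusive treat d == cutoff as a contact
#' @return data.frame with columns \code{i}, \code{j} (row indices into
#'   \code{coms}, i < j); zero rows when no pair is in contact
#' @export
frameContacts <- function(coms, cutoff, boundaryInclusive = TRUE) {
  d <- as.matrix(dist(coms))
  hit <- if (boundaryInclusive) d <= cutoff else d < cutoff
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  data.frame(i = unname(idx[ord, 1L]), j = unname(idx[ord, 2L]))
}

#' Build a persistence-filtered protein structure network
#'
#' Computes side-chain COM contacts in every frame, scores each residue
#' pair by its occurrence (fraction of frames in contact) and keeps edges
#' with occurrence at or above \code{pCrit}. Glycines carry no side chain
#' and are excluded from the network entirely.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble} with >= 1 frame
#' @param cutoff distance cutoff in nm (default 0.5)
#' @param pCrit persistence threshold in [0, 1]; an edge is kept when its
#'   contact is present in at least this fraction of frames (default 0.20)
#' @param includeHydrogens include hydrogens in side-chain COMs
#' @param boundaryInclusive treat d == cutoff as a contact
#' @return a \linkS4class{Psn}
#' @examples
#' ens <- makeDimerEnsemble(20, residuesPerChain = 4,
#'   contactSpecs = contactSpec("A", 1, "B", 2, persistence = 0.5), seed = 1)
#' buildPsn(ens)
#' @export
buildPsn <- function(ensemble, cutoff = 0.5, pCrit = 0.20,
                     includeHydrogens = FALSE, boundaryInclusive = TRUE) {
  stopifnot(cutoff > 0, pCrit >= 0, pCrit <= 1)
  nfr <- nFrames(ensemble)
  if (nfr < 1L) stop("ensemble has no frames")
  coms <- allSidechainCOMs(ensemble, includeHydrogens)
  rt <- attr(coms, "residues")
  if (nrow(rt) < 2L) stop("need at least two non-glycine residues")
  nres <- nrow(rt)
  counts <- matrix(0L, nres, nres)
  for (f in seq_len(nfr)) {
    e <- frameContacts(coms[, , f], cutoff, boundaryInclusive)
    if (nrow(e)) counts[cbind(e$i, e$j)] <- counts[cbind(e$i, e$j)] + 1L
  }
  idx <- which(counts > 0L, arr.ind = TRUE)
  occ <- counts[idx] / nfr
  keep <- occ >= pCrit & occ > 0
  labels <- .nodeLabels(rt)
  edges <- data.frame(from = labels[idx[keep, 1L]],
                      to = labels[idx[keep, 2L]],
                      occurrence = occ[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, labels),
                       match(edges$to, labels)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- cbind(rt, label = labels, stringsAsFactors = FALSE)
  new("Psn", nodes = nodes, edges = edges,
      param = list(cutoff = cutoff, pCrit = pCrit, nFrames = nfr,
                   boundaryInclusive = boundaryInclusive,
                   includeHydrogens = includeHydrogens))
}

#' Assemble a Psn directly from node and edge tables
#'
#' Constructor for networks whose edge occurrences are already known
#' (reanalysis of published networks, tests, toy graphs). Node labels
#' default to the \code{R66_A} convention.
#'
#' @param nodes data.frame with \code{chain}, \code{resnum}, \code{resname}
#'   (and optionally \code{label})
#' @param edges data.frame with \code{from}, \code{to} (labels) and
#'   \code{occurrence} in (0, 1]
#' @param pCrit persistence threshold the edges are understood to satisfy
#' @param cutoff nominal distance cutoff (nm), metadata only
#' @return a \linkS4class{Psn}
#' @export
psnFromEdges <- function(nodes, edges, pCrit = 0.20, cutoff = 0.5) {
  if (is.null(nodes$label)) nodes$label <- .nodeLabels(nodes)
  edges$occurrence <- as.numeric(edges$occurrence)
  new("Psn", nodes = nodes,
      edges = as.data.frame(edges, stringsAsFactors = FALSE),
      param = list(cutoff = cutoff, pCrit = pCrit, nFrames = NA_integer_,
                   boundaryInclusive = TRUE, includeHydrogens = FALSE))
}

psnToIgraph <- function(psn) {
  igraph::graph_from_data_frame(psn@edges, directed = FALSE,
                                vertices = psn@nodes$label)
}

#' Node degrees of a Psn
#' @param psn a \linkS4class{Psn}
#' @return named integer vector, one entry per node (zero for orphans)
#' @export
nodeDegrees <- function(psn) {
  deg <- setNames(integer(nrow(psn@nodes)), psn@nodes$label)
  if (nrow(psn@edges)) {
    tab <- table(c(psn@edges$from, psn@edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Hub residues of a protein structure network
#'
#' Hubs are highly connected nodes. The default rule follows the
#' at-least-three-edges convention (degree >= \code{minDegree}); set
#' \code{strictlyGreater = TRUE} for the stricter more-than-\code{minDegree}
#' reading.
#'
#' @param psn a \linkS4class{Psn}
#' @param minDegree hub degree threshold (default 3)
#' @param strictlyGreater require degree > \code{minDegree} instead of >=
#' @return data.frame of hubs (chain, resnum, resname, label, degree),
#'   sorted by descending degree then node order
#' @export
findHubs <- function(psn, minDegree = 3L, strictlyGreater = FALSE) {
  stopifnot(minDegree >= 1L)
  deg <- nodeDegrees(psn)
  keep <- if (strictlyGreater) deg > minDegree else deg >= minDegree
  out <- cbind(psn@nodes[keep, , drop = FALSE],
               degree = as.integer(deg[keep]))
  out <- out[order(-out$degree, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected components and orphans of a Psn
#'
#' Standard connected components of the undirected network; zero-degree
#' nodes are reported separately as orphans. Components are sorted by
#' descending size, ties broken by the smallest residue number they
#' contain.
#'
#' @param psn a \linkS4class{Psn}
#' @return list with \code{components} (list of node-label vectors),
#'   \code{sizes} (integer vector), \code{orphans} (label vector) and
#'   \code{membership} (named integer vector; NA for orphans)
#' @export
connectedComponents <- function(psn) {
  deg <- nodeDegrees(psn)
  orphans <- names(deg)[deg == 0L]
  membership <- setNames(rep(NA_integer_, nrow(psn@nodes)),
                         psn@nodes$label)
  comps <- list()
  if (nrow(psn@edges)) {
    g <- psnToIgraph(psn)
    cc <- igraph::components(g)
    mem <- cc$membership[setdiff(names(cc$membership), orphans)]
    comps <- split(names(mem), mem)
    minres <- vapply(comps, function(ns)
      min(psn@nodes$resnum[match(ns, psn@nodes$label)]), numeric(1))
    ord <- order(-lengths(comps), minres)
    comps <- unname(comps[ord])
    for (k in seq_along(comps))
      membership[comps[[k]]] <- k
  }
  list(components = comps, sizes = lengths(comps),
       orphans = orphans, membership = membership)
}

#' Cutoff sensitivity diagnostic
#'
#' Rebuilds the network at each candidate distance cutoff and reports the
#' sizes of the five most populated connected components and the
#' node-degree distribution, flagging cutoffs at which the network has
#' collapsed into one giant component (largest component holding more than
#' \code{collapseFraction} of the nodes) — the signature of a cutoff too
#' large for a meaningful network description.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param cutoffs numeric vector of distance cutoffs (nm), e.g.
#'   \code{c(0.5, 0.55)}
#' @param pCrit persistence threshold passed to [buildPsn()]
#' @param collapseFraction giant-component fraction above which a cutoff is
#'   flagged as collapsed (default 0.8)
#' @param ... further arguments to [buildPsn()]
#' @return data.frame with one row per cutoff: \code{cutoff}, \code{nEdges},
#'   \code{top5} (comma string of the five largest component sizes),
#'   \code{largestFraction}, \code{collapsed}, \code{nHubs}; the per-cutoff
#'   degree histograms are attached as attribute \code{"degreeHist"}
#' @export
cutoffDiagnostic <- function(ensemble, cutoffs, pCrit = 0.20,
                             collapseFraction = 0.8, ...) {
  stopifnot(length(cutoffs) >= 1L)
  hists <- vector("list", length(cutoffs))
  rows <- lapply(seq_along(cutoffs), function(k) {
    psn <- buildPsn(ensemble, cutoff = cutoffs[k], pCrit = pCrit, ...)
    cc <- connectedComponents(psn)
    top5 <- head(sort(cc$sizes, decreasing = TRUE), 5L)
    deg <- nodeDegrees(psn)
    hists[[k]] <<- table(degree = deg)
    frac <- if (length(top5)) top5[1L] / nrow(psn@nodes) else 0
    data.frame(cutoff = cutoffs[k], nEdges = nrow(psn@edges),
               top5 = paste(top5, collapse = ","),
               largestFraction = frac,
               collapsed = frac > collapseFraction,
               nHubs = nrow(findHubs(psn)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degreeHist") <- hists
  out
}

#' All shortest communication paths between two residues
#'
#' Minimal-hop paths in the unweighted network (directly connected
#' residues are at distance one). Every path of minimal length is
#' returned, in lexicographic order of its node sequence, annotated with
#' its edge occurrence weights on the percent scale together with their
#' sum and average — the standard report for residue communication paths.
#'
#' @param psn a \linkS4class{Psn}
#' @param source,target node labels (e.g. \code{"C69_A"}); must differ
#' @return list with \code{connected} (logical), \code{length} (hop count,
#'   NA when disconnected) and \code{paths}: a list of paths, each a list
#'   with \code{nodes}, \code{weights} (percent per edge), \code{sumWeight}
#'   and \code{avgWeight}
#' @export
shortestPaths <- function(psn, source, target) {
  labels <- psn@nodes$label
  for (v in c(source, target))
    if (!v %in% labels)
      stop("node not in network: ", v)
  if (source == target) stop("source and target must differ")
  g <- psnToIgraph(psn)
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = target))$res
  if (!length(res))
    return(list(connected = FALSE, length = NA_integer_, paths = list()))
  seqs <- lapply(res, function(p) igraph::as_ids(p))
  ord <- order(vapply(seqs, paste, character(1), collapse = "\r"))
  seqs <- seqs[ord]
  ekey <- .edgeKey(psn@edges$from, psn@edges$to)
  occ <- setNames(psn@edges$occurrence, ekey)
  paths <- lapply(seqs, function(ns) {
    w <- unname(occ[.edgeKey(ns[-length(ns)], ns[-1L])]) * 100
    list(nodes = ns, weights = w,
         sumWeight = sum(w), avgWeight = sum(w) / length(w))
  })
  list(connected = TRUE, length = length(seqs[[1L]]) - 1L, paths = paths)
}

.edgeKey <- function(a, b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Jack-knife convergence check of a PSN
#'
#' Rebuilds the network after discarding a fraction of the frames in
#' contiguous blocks at regular intervals and compares each reduced
#' network with the full one: Jaccard similarity of the edge sets, Jaccard
#' overlap of the hub sets, and the five largest component sizes. Stable
#' statistics across blocks indicate a converged network.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble} with >= 10 frames
#' @param cutoff,pCrit network parameters, as in [buildPsn()]
#' @param dropFraction fraction of frames discarded per block (default
#'   0.10); 0 gives the degenerate single self-comparison
#' @param minDegree hub threshold passed to [findHubs()]
#' @param ... further arguments to [buildPsn()]
#' @return list with \code{full} (the full-ensemble \linkS4class{Psn}),
#'   \code{blocks} (data.frame: block, droppedFrom, droppedTo,
#'   edgeJaccard, hubOverlap, top5) and \code{meanEdgeJaccard}
#' @export
jackknifePsn <- function(ensemble, cutoff = 0.5, pCrit = 0.20,
                         dropFraction = 0.10, minDegree = 3L, ...) {
  nfr <- nFrames(ensemble)
  if (nfr < 10L) stop("jack-knife needs at least 10 frames, got ", nfr)
  stopifnot(dropFraction >= 0, dropFraction < 1)
  full <- buildPsn(ensemble, cutoff = cutoff, pCrit = pCrit, ...)
  fullEdges <- .edgeKey(full@edges$from, full@edges$to)
  fullHubs <- findHubs(full, minDegree)$label
  if (dropFraction == 0) {
    blocks <- data.frame(block = 1L, droppedFrom = NA_integer_,
                         droppedTo = NA_integer_, edgeJaccard = 1,
                         hubOverlap = 1,
                         top5 = paste(head(sort(
                           connectedComponents(full)$sizes,
                           decreasing = TRUE), 5L), collapse = ","))
    return(list(full = full, blocks = blocks, meanEdgeJaccard = 1))
  }
  nblocks <- floor(1 / dropFraction)
  bounds <- floor(seq(0L, nfr, length.out = nblocks + 1L))
  rows <- lapply(seq_len(nblocks), function(b) {
    drop <- (bounds[b] + 1L):bounds[b + 1L]
    sub <- initialize(ensemble,
                      coords = ensemble@coords[, , -drop, drop = FALSE])
    psn <- buildPsn(sub, cutoff = cutoff, pCrit = pCrit, ...)
    e <- .edgeKey(psn@edges$from, psn@edges$to)
    h <- findHubs(psn, minDegree)$label
    cc <- connectedComponents(psn)
    data.frame(block = b, droppedFrom = drop[1L],
               droppedTo = drop[length(drop)],
               edgeJaccard = .jaccard(e, fullEdges),
               hubOverlap = .jaccard(h, fullHubs),
               top5 = paste(head(sort(cc$sizes, decreasing = TRUE), 5L),
                            collapse = ","))
  })
  blocks <- do.call(rbind, rows)
  list(full = full, blocks = blocks,
       meanEdgeJaccard = mean(blocks$edgeJaccard))
}

.jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Export a Psn as tables or a graph-exchange file
#'
#' Writes the network either as a tab-separated edge list (plus a node
#' table with degree, hub flag and component id) or as GraphML with the
#' same attributes.
#'
#' @param psn a \linkS4class{Psn}
#' @param path output file; for \code{format = "edgelist"} the node table
#'   is written next to it with suffix \code{".nodes.tsv"}
#' @param format \code{"edgelist"} or \code{"graphml"}
#' @param minDegree hub threshold for the hub flag
#' @return \code{path}, invisibly
#' @export
writePsnGraph <- function(psn, path, format = c("edgelist", "graphml"),
                          minDegree = 3L) {
  format <- match.arg(format)
  deg <- nodeDegrees(psn)
  cc <- connectedComponents(psn)
  nodes <- cbind(psn@nodes, degree = as.integer(deg),
                 hub = deg >= minDegree,
                 component = unname(cc$membership[psn@nodes$label]))
  if (format == "edgelist") {
    write.table(psn@edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    g <- psnToIgraph(psn)
    idx <- match(igraph::V(g)$name, nodes$label)
    igraph::V(g)$degree <- nodes$degree[idx]
    igraph::V(g)$hub <- nodes$hub[idx]
    igraph::V(g)$component <- nodes$component[idx]
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
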