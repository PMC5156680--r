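#' Published decision rules for seven variant-effect predictors
#'
#' Per-method cutoffs used to binarise raw predictor output into
#' deleterious/neutral verdicts: Provean < -2.5, Mutation Assessor > 2,
#' Polyphen2 > 0.5, PON-P2 > 0.5, SNAP2 < 0, MutPred > 0.75, and
#' Align-GVGD classes C45/C55/C65. The SNAP2 rule is kept exactly as
#' published here even though that tool's usual convention is the
#' opposite (positive score = effect); flip it with
#' \code{snap2Direction = "gt"} if scores follow the tool's native
#' convention.
#'
#' @param snap2Direction \code{"lt"} (published form, default) or
#'   \code{"gt"}
#' @return named list of rules; numeric rules have \code{direction}
#'   (\code{"lt"}/\code{"gt"}) and \code{cut}, the class rule has
#'   \code{classes}
#' @export
predictorThresholds <- function(snap2Direction = c("lt", "gt")) {
  snap2Direction <- match.arg(snap2Direction)
  list(
    provean = list(direction = "lt", cut = -2.5),
    mutation_assessor = list(direction = "gt", cut = 2),
    polyphen2 = list(direction = "gt", cut = 0.5),
    ponp2 = list(direction = "gt", cut = 0.5),
    snap2 = list(direction = snap2Direction, cut = 0),
    mutpred = list(direction = "gt", cut = 0.75),
    align_gvgd = list(classes = c("C45", "C55", "C65"))
  )
}

.applyRule <- function(x, rule) {
  if (!is.null(rule$classes)) {
    out <- ifelse(is.na(x), NA, as.character(x) %in% rule$classes)
  } else {
    x <- suppressWarnings(as.numeric(x))
    out <- switch(rule$direction, lt = x < rule$cut, gt = x > rule$cut)
  }
  out
}

#' Consensus classification over variant-effect predictor scores
#'
#' Applies each method's published rule to its score column, counts the
#' deleterious verdicts per mutation, and flags a complete consensus when
#' every method with a score available calls the mutation deleterious.
#' Missing scores are excluded from the denominator rather than counted as
#' neutral.
#'
#' @param scores data.frame with a \code{mutation} column plus one column
#'   per method named as in [predictorThresholds()]; unknown method
#'   columns are an error
#' @param thresholds rule list from [predictorThresholds()]
#' @return data.frame: \code{mutation}, one \code{verdict_*} column per
#'   method (\code{"deleterious"}/\code{"neutral"}/\code{NA}),
#'   \code{nMethods} (non-missing), \code{consensusCount},
#'   \code{completeConsensus}
#' @export
consensusClassify <- function(scores, thresholds = predictorThresholds()) {
  if (is.null(scores$mutation)) stop("scores need a 'mutation' column")
  methods <- setdiff(names(scores), "mutation")
  unknown <- setdiff(methods, names(thresholds))
  if (length(unknown))
    stop("unknown method column(s): ", paste(unknown, collapse = ", "))
  out <- data.frame(mutation = scores$mutation)
  verdicts <- sapply(methods, function(m)
    .applyRule(scores[[m]], thresholds[[m]]))
  verdicts <- matrix(verdicts, nrow = nrow(scores),
                     dimnames = list(NULL, methods))
  for (m in methods)
    out[[paste0("verdict_", m)]] <-
      ifelse(is.na(verdicts[, m]), NA_character_,
             ifelse(verdicts[, m], "deleterious", "neutral"))
  out$nMethods <- rowSums(!is.na(verdicts))
  out$consensusCount <- rowSums(verdicts, na.rm = TRUE)
  out$completeConsensus <- out$nMethods > 0L &
    out$consensusCount == out$nMethods
  out
}

#' Filter docked complexes by docking energy
#'
#' Retains complexes with a predicted docking energy strictly lower than
#' the cutoff (default -2.39 kcal/mol, the published significance
#' threshold for favourable interactions). A complex at exactly the
#' cutoff is dropped.
#'
#' @param energies data.frame with columns \code{complex} and
#'   \code{energy} (kcal/mol)
#' @param cutoff kcal/mol (default -2.39)
#' @return the retained rows, sorted by ascending energy
#' @export
filterDocking <- function(energies, cutoff = -2.39) {
  stopifnot(all(is.finite(energies$energy)))
  out <- energies[energies$energy < cutoff, , drop = FALSE]
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a PairedCountMatrix
#'
#' @param counts non-negative gene x sample matrix (rownames = genes)
#' @param condition per-sample \code{"tumor"}/\code{"normal"}
#' @param patient per-sample patient identifier
#' @return a \linkS4class{PairedCountMatrix}
#' @export
pairedCountMatrix <- function(counts, condition, patient) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts)),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   patient = as.character(patient)))
  as(se, "PairedCountMatrix")
}

.condSplit <- function(counts, gene) {
  a <- SummarizedExperiment::assay(counts, "counts")
  if (!gene %in% rownames(a)) stop("gene not found: ", gene)
  cond <- as.character(SummarizedExperiment::colData(counts)$condition)
  list(tumor = a[gene, cond == "tumor"],
       normal = a[gene, cond == "normal"])
}

#' Node value: absolute tumor-normal difference of median log2 counts
#'
#' \code{|median(log2(tumor + 1)) - median(log2(normal + 1))|} for one
#' gene — the node shade used when painting expression changes onto an
#' interaction network. The pseudo-count of 1 guards against zeros.
#'
#' @param counts a \linkS4class{PairedCountMatrix}
#' @param gene gene identifier (rowname)
#' @return non-negative numeric
#' @export
nodeValue <- function(counts, gene) {
  x <- .condSplit(counts, gene)
  if (!length(x$tumor) || !length(x$normal))
    stop("both tumor and normal samples are required for gene ", gene)
  abs(median(log2(x$tumor + 1)) - median(log2(x$normal + 1)))
}

.pairedChanges <- function(counts, gene) {
  a <- SummarizedExperiment::assay(counts, "counts")
  if (!gene %in% rownames(a)) stop("gene not found: ", gene)
  cd <- SummarizedExperiment::colData(counts)
  cond <- as.character(cd$condition)
  pat <- as.character(cd$patient)
  tt <- table(pat, cond)
  ok <- rownames(tt)[tt[, "tumor"] == 1L & tt[, "normal"] == 1L]
  if (!length(ok))
    stop("no patient has exactly one tumor and one normal sample")
  ti <- match(paste(ok, "tumor"), paste(pat, cond))
  ni <- match(paste(ok, "normal"), paste(pat, cond))
  setNames(log2(a[gene, ti] + 1) - log2(a[gene, ni] + 1), ok)
}

#' Edge value: correlation of expression (changes) between two genes
#'
#' Default \code{"paired_change"} mode: the Pearson correlation, across
#' patients, of the per-patient tumor-minus-normal log2 changes of the two
#' genes (matching the convention of correlating expression \emph{changes}
#' in paired cohorts). \code{"tumor_only"} mode instead correlates
#' log2 counts across tumor samples. A zero-variance series yields
#' \code{NA} with a warning — undefined, never silently 0.
#'
#' @param counts a \linkS4class{PairedCountMatrix}
#' @param geneA,geneB gene identifiers
#' @param mode \code{"paired_change"} or \code{"tumor_only"}
#' @return Pearson correlation in [-1, 1], or \code{NA} if undefined
#' @export
edgeValue <- function(counts, geneA, geneB,
                      mode = c("paired_change", "tumor_only")) {
  mode <- match.arg(mode)
  if (mode == "paired_change") {
    xa <- .pairedChanges(counts, geneA)
    xb <- .pairedChanges(counts, geneB)
    if (length(xa) < 3L)
      stop("paired mode needs at least 3 usable patients, got ",
           length(xa))
  } else {
    xa <- log2(.condSplit(counts, geneA)$tumor + 1)
    xb <- log2(.condSplit(counts, geneB)$tumor + 1)
    if (length(xa) < 3L)
      stop("tumor_only mode needs at least 3 tumor samples, got ",
           length(xa))
  }
  if (sd(xa) == 0 || sd(xb) == 0) {
    warning("zero variance for ",
            if (sd(xa) == 0) geneA else geneB,
            "; correlation undefined (NA)")
    return(NA_real_)
  }
  cor(xa, xb)
}

#' Annotated interaction network
#'
#' Combines an interaction edge list with per-gene node values and
#' per-edge correlation values into an igraph object carrying the node
#' attribute \code{abs_log2_median_diff} and the edge attribute
#' \code{pearson_r}. Nodes appear in the (deterministic) order of
#' \code{nodeValues}; every edge endpoint must have a node value.
#'
#' @param edges data.frame with columns \code{geneA}, \code{geneB}
#' @param nodeValues named numeric vector (names = genes)
#' @param edgeValues numeric vector, one per edge row
#' @return an \code{igraph} graph
#' @export
buildAnnotationNetwork <- function(edges, nodeValues, edgeValues) {
  genes <- names(nodeValues)
  if (nrow(edges)) {
    dangling <- setdiff(unique(c(edges$geneA, edges$geneB)), genes)
    if (length(dangling))
      stop("edge endpoint(s) without a node value: ",
           paste(dangling, collapse = ", "))
    if (length(edgeValues) != nrow(edges))
      stop("need one edge value per edge")
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = edges$geneA, to = edges$geneB)
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = genes))
  igraph::V(g)$abs_log2_median_diff <-
    unname(nodeValues[igraph::V(g)$name])
  if (nrow(edges)) igraph::E(g)$pearson_r <- edgeValues
  g
}

#' Write/read an annotated network as GraphML
#'
#' Round-trip-safe export of [buildAnnotationNetwork()] output in the
#' standard graph-exchange format.
#' @param graph igraph object
#' @param path output file
#' @return \code{path} (write) / the graph (read)
#' @export
writeAnnotationNetwork <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname writeAnnotationNetwork
#' @export
readAnnotationNetwork <- function(path)
  igraph::read_graph(path, format = "graphml")
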