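#' @import methods
#' @importFrom stats cov dist median rnorm rnbinom runif sd cor setNames
#' @importFrom utils head read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

.AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## Unified atomic masses (amu) for elements occurring in standard residues.
.DEFAULT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

## Backbone atom names excluded from side-chain centre-of-mass computation.
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                     "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3")

#' ConformationalEnsemble: ordered frames of atomic coordinates
#'
#' Container for a multi-frame structure (an NMR ensemble or frames sampled
#' from a trajectory). Coordinates are stored in nanometres in an
#' atoms x 3 x frames array; every frame shares the same atom and residue
#' composition. A mass table (element -> unified amu) with optional
#' per-atom-name overrides supports mass-weighted centre-of-mass
#' computations.
#'
#' @slot coords numeric array, dim \code{c(nAtoms, 3, nFrames)}, in nm.
#' @slot atoms data.frame with one row per atom: \code{chain},
#'   \code{resnum}, \code{resname}, \code{atom}, \code{element}.
#' @slot masses named numeric vector of element masses (amu), all > 0.
#' @slot massOverrides named numeric vector of per-atom-name mass overrides
#'   (may be empty).
#'
#' @seealso [readEnsemblePDB()], [makeDimerEnsemble()], [sidechainCOM()]
#' @export
setClass("ConformationalEnsemble",
         representation(coords = "array",
                        atoms = "data.frame",
                        masses = "numeric",
                        massOverrides = "numeric"))

setValidity("ConformationalEnsemble", function(object) {
  msg <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[3] < 1L) msg <- c(msg, "ensemble must contain at least one frame")
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "coords and atom table disagree on atom count")
  }
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must all be finite")
  need <- c("chain", "resnum", "resname", "atom", "element")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atom table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(!nzchar(object@atoms$chain)))
      msg <- c(msg, "chain labels must be non-empty")
    if (any(object@atoms$resnum < 1L))
      msg <- c(msg, "residue numbers must be >= 1")
  }
  if (any(object@masses <= 0) ||
      (length(object@massOverrides) && any(object@massOverrides <= 0)))
    msg <- c(msg, "all masses must be > 0")
  if (length(msg)) msg else TRUE
})

#' Psn: persistence-filtered protein structure network
#'
#' Weighted undirected residue graph. Nodes are the non-glycine residues of
#' the source ensemble; an edge records the fraction of frames (its
#' \emph{occurrence}) in which the two residues' side-chain centres of mass
#' were within the distance cutoff. Only edges with occurrence at or above
#' the persistence threshold \code{pCrit} are retained.
#'
#' @slot nodes data.frame: \code{chain}, \code{resnum}, \code{resname},
#'   \code{label} (e.g. \code{"C69_A"}).
#' @slot edges data.frame: \code{from}, \code{to} (node labels),
#'   \code{occurrence} in (0, 1].
#' @slot param list of build parameters (cutoff nm, pCrit, nFrames,
#'   boundaryInclusive, includeHydrogens).
#'
#' @seealso [buildPsn()], [findHubs()], [connectedComponents()],
#'   [shortestPaths()]
#' @export
setClass("Psn",
         representation(nodes = "data.frame",
                        edges = "data.frame",
                        param = "list"))

setValidity("Psn", function(object) {
  msg <- character(0)
  if (!all(c("chain", "resnum", "resname", "label") %in% names(object@nodes)))
    msg <- c(msg, "nodes must have chain, resnum, resname, label")
  if (!all(c("from", "to", "occurrence") %in% names(object@edges)))
    msg <- c(msg, "edges must have from, to, occurrence")
  else if (nrow(object@edges)) {
    if (any(object@edges$from == object@edges$to))
      msg <- c(msg, "self-edges are not allowed")
    occ <- object@edges$occurrence
    if (any(occ <= 0 | occ > 1))
      msg <- c(msg, "edge occurrence must lie in (0, 1]")
    bad <- !(object@edges$from %in% object@nodes$label) |
           !(object@edges$to %in% object@nodes$label)
    if (any(bad)) msg <- c(msg, "edges reference unknown nodes")
    pc <- object@param$pCrit
    if (!is.null(pc) && any(occ < pc))
      msg <- c(msg, "retained edges must have occurrence >= pCrit")
  }
  if (any(object@nodes$resname == "GLY"))
    msg <- c(msg, "glycine residues cannot be network nodes")
  if (length(msg)) msg else TRUE
})

#' ScanMatrix: aggregated saturation-mutagenesis scan
#'
#' Mean and dispersion of the free-energy change for every
#' (position, substitution) cell of a saturation scan, aggregated over all
#' conformer x run records. Rows are scan sites (optionally chain-qualified
#' for dimer scans); columns are the 20 amino acids, with the wild-type
#' column of each row set to NA (a residue is never "mutated" to itself,
#' so a complete scan has 19 cells per site).
#'
#' @slot sites data.frame: \code{chain} (may be \code{NA}), \code{position},
#'   \code{wt} (one-letter wild type).
#' @slot means numeric matrix, sites x 20 (colnames = one-letter codes).
#' @slot sds numeric matrix, same shape; sample standard deviations.
#' @slot counts integer matrix, same shape; records per cell.
#' @slot scope character, \code{"stability"} or \code{"binding"}.
#'
#' @seealso [aggregateScan()], [hotspotPositions()]
#' @export
setClass("ScanMatrix",
         representation(sites = "data.frame",
                        means = "matrix",
                        sds = "matrix",
                        counts = "matrix",
                        scope = "character"))

setValidity("ScanMatrix", function(object) {
  msg <- character(0)
  n <- nrow(object@sites)
  for (nm in c("means", "sds", "counts")) {
    m <- slot(object, nm)
    if (nrow(m) != n || ncol(m) != 20L)
      msg <- c(msg, sprintf("%s must be nSites x 20", nm))
  }
  if (!all(c("chain", "position", "wt") %in% names(object@sites)))
    msg <- c(msg, "sites must have chain, position, wt")
  else if (n) {
    wtcol <- match(object@sites$wt, colnames(object@means))
    if (anyNA(wtcol))
      msg <- c(msg, "wild-type codes must be one-letter amino acids")
    else if (!all(is.na(object@means[cbind(seq_len(n), wtcol)])))
      msg <- c(msg, "wild-type cells must be NA")
  }
  if (length(object@scope) != 1L ||
      !object@scope %in% c("stability", "binding"))
    msg <- c(msg, "scope must be 'stability' or 'binding'")
  if (length(msg)) msg else TRUE
})

#' PairedCountMatrix: gene x sample counts with tumor/normal pairing
#'
#' A \linkS4class{SummarizedExperiment} whose \code{colData} carries a
#' \code{condition} factor (\code{"tumor"}/\code{"normal"}) and a
#' \code{patient} identifier, supporting paired per-patient expression-change
#' analyses. Pairing completeness (exactly one tumor and one normal sample
#' per used patient) is enforced by the paired-mode operations, not by the
#' class, so partially paired cohorts can still be held and subset.
#'
#' @seealso [pairedCountMatrix()], [nodeValue()], [edgeValue()],
#'   [makePairedCounts()]
#' @export
setClass("PairedCountMatrix",
         contains = "SummarizedExperiment")

setValidity("PairedCountMatrix", function(object) {
  msg <- character(0)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "patient") %in% names(cd)))
    msg <- c(msg, "colData must have 'condition' and 'patient'")
  else if (!all(as.character(cd$condition) %in% c("tumor", "normal")))
    msg <- c(msg, "condition must be 'tumor' or 'normal'")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    a <- SummarizedExperiment::assay(object, "counts")
    if (any(a < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
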