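#' Number of frames in an ensemble
#' @param x a \linkS4class{ConformationalEnsemble}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms per frame
#' @param x a \linkS4class{ConformationalEnsemble}
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Coordinate array of an ensemble
#' @param x a \linkS4class{ConformationalEnsemble}
#' @return numeric array \code{nAtoms x 3 x nFrames}, nm
#' @export
setGeneric("ensCoords", function(x) standardGeneric("ensCoords"))

#' Per-atom metadata table
#' @param x a \linkS4class{ConformationalEnsemble}
#' @return data.frame with chain, resnum, resname, atom, element
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Residue table of an object
#'
#' One row per residue, in file order: chain, resnum, resname.
#' @param x a \linkS4class{ConformationalEnsemble}
#' @return data.frame
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' Nodes of a protein structure network
#' @param x a \linkS4class{Psn}
#' @return data.frame with chain, resnum, resname, label
#' @export
setGeneric("psnNodes", function(x) standardGeneric("psnNodes"))

#' Edges of a protein structure network
#' @param x a \linkS4class{Psn}
#' @return data.frame with from, to, occurrence
#' @export
setGeneric("psnEdges", function(x) standardGeneric("psnEdges"))

#' Build parameters of a protein structure network
#' @param x a \linkS4class{Psn}
#' @return list (cutoff, pCrit, nFrames, ...)
#' @export
setGeneric("psnParam", function(x) standardGeneric("psnParam"))

#' Scan sites of an aggregated mutational scan
#' @param x a \linkS4class{ScanMatrix}
#' @return data.frame with chain, position, wt
#' @export
setGeneric("scanSites", function(x) standardGeneric("scanSites"))

#' Mean free-energy changes of an aggregated scan
#' @param x a \linkS4class{ScanMatrix}
#' @return sites x 20 numeric matrix (kcal/mol), wild-type cells NA
#' @export
setGeneric("scanMeans", function(x) standardGeneric("scanMeans"))

#' Per-cell standard deviations of an aggregated scan
#' @param x a \linkS4class{ScanMatrix}
#' @return sites x 20 numeric matrix
#' @export
setGeneric("scanSds", function(x) standardGeneric("scanSds"))

#' Per-cell record counts of an aggregated scan
#' @param x a \linkS4class{ScanMatrix}
#' @return sites x 20 integer matrix
#' @export
setGeneric("scanCounts", function(x) standardGeneric("scanCounts"))

#' Scope of an aggregated scan
#' @param x a \linkS4class{ScanMatrix}
#' @return \code{"stability"} (monomer) or \code{"binding"} (dimer)
#' @export
setGeneric("scanScope", function(x) standardGeneric("scanScope"))
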