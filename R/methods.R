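#' @rdname nFrames
#' @export
setMethod("nFrames", "ConformationalEnsemble",
          function(x) dim(x@coords)[3L])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ConformationalEnsemble",
          function(x) dim(x@coords)[1L])

#' @rdname ensCoords
#' @export
setMethod("ensCoords", "ConformationalEnsemble", function(x) x@coords)

#' @rdname atomData
#' @export
setMethod("atomData", "ConformationalEnsemble", function(x) x@atoms)

#' @rdname residueTable
#' @export
setMethod("residueTable", "ConformationalEnsemble", function(x) {
  key <- paste(x@atoms$chain, x@atoms$resnum)
  keep <- !duplicated(key)
  out <- x@atoms[keep, c("chain", "resnum", "resname")]
  rownames(out) <- NULL
  out
})

setMethod("show", "ConformationalEnsemble", function(object) {
  rt <- residueTable(object)
  cat("ConformationalEnsemble:",
      nFrames(object), "frame(s),",
      nrow(rt), "residues in",
      length(unique(rt$chain)), "chain(s),",
      nAtoms(object), "atoms/frame\n")
  cat("  chains:", paste(unique(rt$chain), collapse = ", "), "\n")
  cat("  coordinates in nm; mass table:",
      paste(names(object@masses), collapse = " "),
      if (length(object@massOverrides))
        sprintf("(+%d atom-name overrides)", length(object@massOverrides))
      else "", "\n")
})

#' @rdname psnNodes
#' @export
setMethod("psnNodes", "Psn", function(x) x@nodes)

#' @rdname psnEdges
#' @export
setMethod("psnEdges", "Psn", function(x) x@edges)

#' @rdname psnParam
#' @export
setMethod("psnParam", "Psn", function(x) x@param)

setMethod("show", "Psn", function(object) {
  cat("Psn:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  p <- object@param
  if (length(p))
    cat(sprintf("  cutoff %.3g nm, pCrit %.3g, %s frames\n",
                p$cutoff, p$pCrit,
                if (is.null(p$nFrames)) "?" else p$nFrames))
  deg <- nodeDegrees(object)
  cat("  degree range:", paste(range(deg), collapse = "-"),
      "| orphans:", sum(deg == 0), "\n")
})

#' @rdname scanSites
#' @export
setMethod("scanSites", "ScanMatrix", function(x) x@sites)

#' @rdname scanMeans
#' @export
setMethod("scanMeans", "ScanMatrix", function(x) x@means)

#' @rdname scanSds
#' @export
setMethod("scanSds", "ScanMatrix", function(x) x@sds)

#' @rdname scanCounts
#' @export
setMethod("scanCounts", "ScanMatrix", function(x) x@counts)

#' @rdname scanScope
#' @export
setMethod("scanScope", "ScanMatrix", function(x) x@scope)

setMethod("show", "ScanMatrix", function(object) {
  n <- nrow(object@sites)
  filled <- sum(!is.na(object@means))
  cat(sprintf("ScanMatrix (%s): %d sites, %d/%d substitution cells filled\n",
              object@scope, n, filled, n * 19L))
  cts <- object@counts[!is.na(object@means)]
  if (length(cts))
    cat(sprintf("  records/cell: expected %d (modal), found %d-%d\n",
                as.integer(names(sort(table(cts), decreasing = TRUE))[1]),
                min(cts), max(cts)))
})
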