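.shiftKey <- function(chain, resnum, atom) paste(chain, resnum, atom)

.checkShiftTables <- function(predicted, experimental) {
  for (nm in c("chain", "resnum", "atom", "shift"))
    if (is.null(predicted[[nm]]) || is.null(experimental[[nm]]))
      stop("shift tables need columns chain, resnum, atom, shift")
  if (is.null(predicted$frame))
    stop("predicted shifts need a 'frame' column")
  if (any(experimental$shift == 0))
    stop("experimental shift of 0 ppm: chi-square denominator undefined")
  ek <- .shiftKey(experimental$chain, experimental$resnum,
                  experimental$atom)
  if (anyDuplicated(ek))
    stop("duplicate experimental shift records")
  pk <- .shiftKey(predicted$chain, predicted$resnum, predicted$atom)
  unmatched <- setdiff(unique(pk), ek)
  if (length(unmatched))
    stop("predicted series without experimental match: ",
         paste(head(unmatched, 5L), collapse = "; "),
         if (length(unmatched) > 5L) " ...")
  list(pk = pk, ek = ek)
}

#' Chi-square agreement between predicted and experimental chemical shifts
#'
#' For each shift the per-frame predictions are first averaged over the
#' ensemble, then the squared deviation from experiment, scaled by the
#' experimental shift, is pooled over the \code{s} shifts of a group:
#' \deqn{\chi^2 = \frac{1}{s-1} \sum_{j=1}^{s}
#'   \frac{(\bar\delta_j - \delta_{exp,j})^2}{\delta_{exp,j}}}
#' Groups are the backbone/side-chain atom types (column \code{atom}),
#' and a pooled \code{"all"} row is always appended.
#'
#' @param predicted long-format data.frame of per-frame predictions:
#'   \code{frame}, \code{chain}, \code{resnum}, \code{atom}, \code{shift}
#'   (ppm)
#' @param experimental data.frame of experimental shifts: \code{chain},
#'   \code{resnum}, \code{atom}, \code{shift} (ppm, nonzero)
#' @param groupByAtomType compute one value per atom type in addition to
#'   the pooled value (default TRUE)
#' @return data.frame with columns \code{group}, \code{chi2}, \code{s}
#' @examples
#' exp <- data.frame(chain = "A", resnum = 1:2, atom = "CA", shift = 4)
#' pred <- data.frame(frame = 1, chain = "A", resnum = 1:2, atom = "CA",
#'                    shift = c(5, 3))
#' chi2Shifts(pred, exp)   # pooled chi2 = 0.5
#' @export
chi2Shifts <- function(predicted, experimental, groupByAtomType = TRUE) {
  keys <- .checkShiftTables(predicted, experimental)
  fm <- tapply(predicted$shift, keys$pk, mean)
  idx <- match(names(fm), keys$ek)
  dexp <- experimental$shift[idx]
  atom <- experimental$atom[idx]
  terms <- (as.numeric(fm) - dexp)^2 / dexp
  groups <- if (groupByAtomType) split(terms, atom) else list()
  groups <- c(groups, list(all = terms))
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    s <- length(x)
    if (s < 2L)
      stop("group '", g, "' has fewer than 2 shifts; chi-square undefined")
    data.frame(group = g, chi2 = sum(x) / (s - 1L), s = s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square along cumulative frame windows
#'
#' Recomputes [chi2Shifts()] using only frames up to each window end,
#' tracing convergence of the predicted shifts toward experiment along the
#' ensemble (flattening curves indicate stationarity).
#'
#' @param predicted,experimental as in [chi2Shifts()]
#' @param windowEnds increasing vector of frame indices; each must not
#'   exceed the largest frame index present
#' @param groupByAtomType as in [chi2Shifts()]
#' @return data.frame with columns \code{windowEnd}, \code{group},
#'   \code{chi2}, \code{s}
#' @export
runningChi2 <- function(predicted, experimental, windowEnds,
                        groupByAtomType = TRUE) {
  stopifnot(length(windowEnds) >= 1L, !is.unsorted(windowEnds))
  maxf <- max(predicted$frame)
  if (any(windowEnds > maxf))
    stop("window end beyond last frame (", maxf, ")")
  rows <- lapply(windowEnds, function(w) {
    sub <- predicted[predicted$frame <= w, , drop = FALSE]
    cbind(windowEnd = w,
          chi2Shifts(sub, experimental, groupByAtomType))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize an NOE restraint by sequence and chain context
#'
#' Different chains give \code{"intermolecular"}; within a chain, partners
#' separated by more than four residues in the primary sequence are
#' \code{"long"}, otherwise \code{"short"}. Vectorised.
#'
#' @param chainA,resA,chainB,resB chain labels and residue numbers of the
#'   two partner atoms
#' @return character vector in \code{short}, \code{long},
#'   \code{intermolecular}
#' @export
categorizeRestraint <- function(chainA, resA, chainB, resB) {
  ifelse(chainA != chainB, "intermolecular",
         ifelse(abs(resA - resB) > 4L, "long", "short"))
}

.checkNoeTable <- function(restraints) {
  need <- c("chain_a", "res_a", "atom_a", "chain_b", "res_b", "atom_b",
            "distance_nm")
  miss <- setdiff(need, names(restraints))
  if (length(miss))
    stop("restraint table lacks column(s): ", paste(miss, collapse = ", "))
  same <- restraints$chain_a == restraints$chain_b &
    restraints$res_a == restraints$res_b &
    restraints$atom_a == restraints$atom_b
  if (any(same)) stop("restraint with identical partner atoms")
  if (any(restraints$distance_nm <= 0))
    stop("restraint distances must be > 0")
  restraints
}

#' Ensemble-average NOE distance differences
#'
#' For every restraint, the per-frame distance between the two atoms is
#' averaged over the ensemble — arithmetically by default, or with
#' \eqn{\langle d^{-6}\rangle^{-1/6}} averaging under the spectroscopic
#' convention — and the experimental distance is subtracted. Differences
#' are signed (the experimental value is treated as a target distance, not
#' an upper bound).
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param restraints data.frame with columns \code{chain_a}, \code{res_a},
#'   \code{atom_a}, \code{chain_b}, \code{res_b}, \code{atom_b},
#'   \code{distance_nm} and optionally \code{category}
#' @param averaging \code{"linear"} (default) or \code{"r6"}
#' @return the restraint table with added columns \code{d_avg},
#'   \code{diff} (both nm) and \code{category} (computed with
#'   [categorizeRestraint()] when absent)
#' @export
noeDifferences <- function(ensemble, restraints,
                           averaging = c("linear", "r6")) {
  averaging <- match.arg(averaging)
  restraints <- .checkNoeTable(restraints)
  at <- ensemble@atoms
  akey <- .shiftKey(at$chain, at$resnum, at$atom)
  ia <- match(.shiftKey(restraints$chain_a, restraints$res_a,
                        restraints$atom_a), akey)
  ib <- match(.shiftKey(restraints$chain_b, restraints$res_b,
                        restraints$atom_b), akey)
  bad <- which(is.na(ia) | is.na(ib))
  if (length(bad))
    stop("restraint atom(s) absent from ensemble, first offending ",
         "restraint: row ", bad[1L], " (",
         restraints$chain_a[bad[1L]], ":", restraints$res_a[bad[1L]], ":",
         restraints$atom_a[bad[1L]], " - ",
         restraints$chain_b[bad[1L]], ":", restraints$res_b[bad[1L]], ":",
         restraints$atom_b[bad[1L]], ")")
  diffs <- ensemble@coords[ia, , , drop = FALSE] -
    ensemble@coords[ib, , , drop = FALSE]
  d <- sqrt(apply(diffs^2, c(1L, 3L), sum))   # restraints x frames
  d_avg <- if (averaging == "linear") rowMeans(d)
           else rowMeans(d^(-6))^(-1 / 6)
  restraints$d_avg <- d_avg
  restraints$diff <- d_avg - restraints$distance_nm
  if (is.null(restraints$category))
    restraints$category <- categorizeRestraint(
      restraints$chain_a, restraints$res_a,
      restraints$chain_b, restraints$res_b)
  restraints
}

#' Read/write tabular NOE restraints
#'
#' Tab-separated table with columns \code{chain_a}, \code{res_a},
#' \code{atom_a}, \code{chain_b}, \code{res_b}, \code{atom_b},
#' \code{distance_nm} (and optionally \code{category}).
#' @param path file path
#' @return validated restraint data.frame
#' @export
readNoeTable <- function(path)
  .checkNoeTable(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))

#' @rdname readNoeTable
#' @param restraints restraint data.frame to write
#' @export
writeNoeTable <- function(restraints, path) {
  write.table(restraints, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## C-alpha fluctuation eigenvectors after least-squares superposition of
## every frame onto the ensemble mean structure (two fitting passes).
.caModes <- function(ensemble, nModes) {
  at <- ensemble@atoms
  idx <- which(at$atom == "CA")
  if (!length(idx)) stop("ensemble has no CA atoms")
  nfr <- nFrames(ensemble)
  if (nfr < nModes)
    stop(sprintf("need at least %d frames for %d modes, got %d",
                 nModes, nModes, nfr))
  xyz <- matrix(NA_real_, nfr, 3L * length(idx))
  for (f in seq_len(nfr))
    xyz[f, ] <- as.vector(t(ensemble@coords[idx, , f]))
  inds <- seq_len(ncol(xyz))
  fitted <- bio3d::fit.xyz(xyz[1L, ], xyz, inds, inds)
  for (i in 1:2)
    fitted <- bio3d::fit.xyz(colMeans(fitted), fitted, inds, inds)
  ev <- eigen(cov(fitted), symmetric = TRUE)
  key <- paste(at$chain[idx], at$resnum[idx])
  list(vectors = ev$vectors[, seq_len(nModes), drop = FALSE], key = key)
}

#' Root mean square inner product between two ensembles
#'
#' Overlap between the subspaces spanned by the first \code{nModes}
#' principal components of the C-alpha fluctuation covariance matrices of
#' two ensembles (frames superposed onto each ensemble's mean structure
#' first):
#' \deqn{RMSIP = \sqrt{\frac{1}{n}\sum_i\sum_j (v_i \cdot w_j)^2}}
#' 1 means identical essential subspaces, 0 orthogonal ones.
#'
#' @param ensembleA,ensembleB \linkS4class{ConformationalEnsemble}s sharing
#'   the same C-alpha atoms (chain/residue-number match); each needs at
#'   least \code{nModes} frames
#' @param nModes number of leading modes to compare (default 20)
#' @return numeric in [0, 1]
#' @export
rmsip <- function(ensembleA, ensembleB, nModes = 20L) {
  a <- .caModes(ensembleA, nModes)
  b <- .caModes(ensembleB, nModes)
  if (!identical(a$key, b$key))
    stop("ensembles have mismatched CA atom sets")
  ip <- crossprod(a$vectors, b$vectors)
  sqrt(sum(ip^2) / nModes)
}

#' Histidine tautomer assignment from the CD2 carbon shift
#'
#' A ring CD2 chemical shift below 122 ppm indicates the Nε2-H tautomer;
#' 122 ppm or above indicates Nδ1-H (strict-less-than boundary).
#'
#' @param cd2Shift CD2 shift(s), ppm (vectorised)
#' @return character vector, \code{"Ne2-H"} or \code{"Nd1-H"}
#' @export
hisTautomer <- function(cd2Shift) {
  stopifnot(all(is.finite(cd2Shift)))
  ifelse(cd2Shift < 122, "Ne2-H", "Nd1-H")
}
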