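#' Construct a ConformationalEnsemble from components
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' Coordinates are taken as already being in nanometres.
#'
#' @param coords numeric array \code{nAtoms x 3 x nFrames} (nm).
#' @param atoms data.frame with \code{chain}, \code{resnum}, \code{resname},
#'   \code{atom} and optionally \code{element} (derived from the atom name
#'   when absent).
#' @param masses named numeric vector of element masses (amu); defaults to
#'   standard unified masses for H, C, N, O, S, P.
#' @param massOverrides named numeric vector mapping specific atom names to
#'   masses, overriding the element table (for force-field-specific mass
#'   definitions).
#' @return a \linkS4class{ConformationalEnsemble}
#' @export
conformationalEnsemble <- function(coords, atoms,
                                   masses = defaultMassTable(),
                                   massOverrides = numeric(0)) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (is.null(atoms$element))
    atoms$element <- elementFromAtomName(atoms$atom)
  atoms$chain <- as.character(atoms$chain)
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  rownames(atoms) <- NULL
  bad <- setdiff(unique(atoms$resname), .STANDARD_AA3)
  if (length(bad))
    stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  new("ConformationalEnsemble", coords = coords, atoms = atoms,
      masses = masses, massOverrides = massOverrides)
}

#' Standard element mass table
#'
#' Unified atomic masses (amu) for the elements found in standard amino
#' acids. Per-atom-name deviations (e.g. force-field united atoms) are
#' expressed as overrides on the ensemble, not by editing this table.
#' @return named numeric vector
#' @export
defaultMassTable <- function() .DEFAULT_MASSES

## Element symbol from a PDB atom name: strip digits/primes, take the
## leading letter ("1HB" -> H, "CB" -> C, "OXT" -> O).
elementFromAtomName <- function(atom) {
  a <- gsub("[0-9']", "", atom)
  toupper(substr(a, 1L, 1L))
}

.atomMasses <- function(ensemble, idx = seq_len(nAtoms(ensemble))) {
  at <- ensemble@atoms[idx, , drop = FALSE]
  m <- unname(ensemble@masses[at$element])
  if (length(ensemble@massOverrides)) {
    hit <- match(at$atom, names(ensemble@massOverrides))
    m[!is.na(hit)] <- unname(ensemble@massOverrides[hit[!is.na(hit)]])
  }
  if (anyNA(m))
    stop("no mass known for element(s): ",
         paste(unique(at$element[is.na(m)]), collapse = ", "))
  m
}

#' Read a multi-model PDB file into a ConformationalEnsemble
#'
#' Each MODEL block becomes one frame (a file without MODEL records is a
#' single-frame ensemble). All models must share the same atoms in the same
#' order; the first model that deviates is named in the error. Coordinates
#' are converted from the file's angstroms to nanometres. Parsing of the
#' coordinate records is delegated to \code{bio3d::read.pdb}; the
#' model-consistency pre-scan is done here so that malformed files fail
#' with an informative message rather than a scrambled coordinate matrix.
#'
#' @param path path to a PDB file (ATOM records; HETATM ignored).
#' @param massOverrides optional named numeric vector of per-atom-name
#'   masses.
#' @return a \linkS4class{ConformationalEnsemble}
#' @examples
#' pdb <- system.file("extdata", "toy_dimer_2model.pdb", package = "psnscan")
#' ens <- readEnsemblePDB(pdb)
#' nFrames(ens)
#' @export
readEnsemblePDB <- function(path, massOverrides = numeric(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts)) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    sig <- lapply(seq_along(model_starts), function(i) {
      sel <- is_atom & seq_along(lines) > model_starts[i] &
        seq_along(lines) < model_ends[i]
      ## atom identity: name + altloc + residue + chain + resnum
      substr(lines[sel], 13L, 27L)
    })
    for (i in seq_along(sig)[-1L]) {
      if (length(sig[[i]]) != length(sig[[1L]]))
        stop(sprintf(
          "model %d has %d atoms but model 1 has %d (file %s)",
          i, length(sig[[i]]), length(sig[[1L]]), path))
      if (!identical(sig[[i]], sig[[1L]]))
        stop(sprintf("model %d atom records differ from model 1 (file %s)",
                     i, path))
    }
  }
  multi <- length(model_starts) > 1L
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  sel <- pdb$atom$type == "ATOM"
  atoms <- data.frame(chain = pdb$atom$chain[sel],
                      resnum = pdb$atom$resno[sel],
                      resname = pdb$atom$resid[sel],
                      atom = pdb$atom$elety[sel],
                      stringsAsFactors = FALSE)
  ele <- pdb$atom$elesy[sel]
  atoms$element <- ifelse(is.na(ele) | !nzchar(trimws(ele)),
                          elementFromAtomName(atoms$atom), trimws(ele))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nfr <- nrow(xyz)
  natom_all <- length(sel)
  keep_xyz <- rep(sel, each = 3L)
  na <- sum(sel)
  coords <- array(NA_real_, c(na, 3L, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(xyz[f, keep_xyz], ncol = 3L, byrow = TRUE)
  coords <- coords / 10          # angstrom -> nm
  conformationalEnsemble(coords, atoms, massOverrides = massOverrides)
}

#' Write a ConformationalEnsemble as a multi-model PDB file
#'
#' Inverse of [readEnsemblePDB()]: nm coordinates are written back in
#' angstroms (PDB's native unit, 3 decimals).
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  at <- ensemble@atoms
  nfr <- nFrames(ensemble)
  xyz <- matrix(NA_real_, nfr, 3L * nAtoms(ensemble))
  for (f in seq_len(nfr))
    xyz[f, ] <- as.vector(t(ensemble@coords[, , f])) * 10
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = at$resnum, resid = at$resname,
                   chain = at$chain, elety = at$atom,
                   eleno = seq_len(nrow(at)))
  invisible(path)
}

#' Read an ensemble from a plain multi-frame XYZ table
#'
#' Escape-hatch format for synthetic data: a tab-separated table with
#' columns \code{frame}, \code{chain}, \code{resnum}, \code{resname},
#' \code{atom}, \code{x}, \code{y}, \code{z}, coordinates in nm. Frames
#' must share the same atom composition in the same order.
#'
#' @param path path to the table
#' @return a \linkS4class{ConformationalEnsemble}
#' @export
readEnsembleXYZ <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  frames <- sort(unique(d$frame))
  parts <- split(d, factor(d$frame, levels = frames))
  sig <- lapply(parts, function(p)
    paste(p$chain, p$resnum, p$resname, p$atom))
  for (i in seq_along(sig)[-1L])
    if (!identical(sig[[i]], sig[[1L]]))
      stop("frame ", frames[i], " atom composition differs from frame ",
           frames[1L])
  na <- nrow(parts[[1L]])
  coords <- array(NA_real_, c(na, 3L, length(parts)))
  for (f in seq_along(parts))
    coords[, , f] <- as.matrix(parts[[f]][, c("x", "y", "z")])
  atoms <- parts[[1L]][, c("chain", "resnum", "resname", "atom")]
  conformationalEnsemble(coords, atoms)
}

#' Write an ensemble as a plain multi-frame XYZ table
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param path output file (tab-separated, nm)
#' @return \code{path}, invisibly
#' @export
writeEnsembleXYZ <- function(ensemble, path) {
  at <- ensemble@atoms
  nfr <- nFrames(ensemble)
  out <- do.call(rbind, lapply(seq_len(nfr), function(f)
    data.frame(frame = f, chain = at$chain, resnum = at$resnum,
               resname = at$resname, atom = at$atom,
               x = ensemble@coords[, 1L, f],
               y = ensemble@coords[, 2L, f],
               z = ensemble@coords[, 3L, f])))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Side-chain centre of mass of one residue, per frame
#'
#' Mass-weighted mean of the side-chain atom coordinates in every frame.
#' The side chain is everything except the backbone atoms
#' (N, CA, C, O, OXT and backbone hydrogens); by default hydrogens are
#' excluded as well, leaving heavy atoms only. Glycine has no side-chain
#' heavy atom and is rejected explicitly.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param chain chain label
#' @param resnum residue number
#' @param includeHydrogens include side-chain hydrogens in the COM
#' @return numeric matrix \code{nFrames x 3} (nm)
#' @export
sidechainCOM <- function(ensemble, chain, resnum, includeHydrogens = FALSE) {
  at <- ensemble@atoms
  idx <- which(at$chain == chain & at$resnum == resnum)
  if (!length(idx))
    stop(sprintf("residue %s:%s not found in ensemble", chain, resnum))
  if (at$resname[idx[1L]] == "GLY")
    stop(sprintf("residue %s:%s is glycine: excluded residue (no side chain)",
                 chain, resnum))
  idx <- .sidechainAtomIdx(ensemble, idx, includeHydrogens)
  if (!length(idx))
    stop(sprintf("residue %s:%s has no side-chain atoms", chain, resnum))
  m <- .atomMasses(ensemble, idx)
  w <- m / sum(m)
  t(apply(ensemble@coords[idx, , , drop = FALSE], 3L,
          function(fr) colSums(fr * w)))
}

.sidechainAtomIdx <- function(ensemble, idx, includeHydrogens) {
  at <- ensemble@atoms
  keep <- !(at$atom[idx] %in% .BACKBONE_ATOMS)
  if (!includeHydrogens) keep <- keep & at$element[idx] != "H"
  idx[keep]
}

## Side-chain COMs for all non-glycine residues: residues x 3 x frames.
## Shared by the PSN builder; returns residue table as attribute.
allSidechainCOMs <- function(ensemble, includeHydrogens = FALSE) {
  rt <- residueTable(ensemble)
  rt <- rt[rt$resname != "GLY", , drop = FALSE]
  rownames(rt) <- NULL
  at <- ensemble@atoms
  akey <- paste(at$chain, at$resnum)
  rkey <- paste(rt$chain, rt$resnum)
  coms <- array(NA_real_, c(nrow(rt), 3L, nFrames(ensemble)))
  for (r in seq_len(nrow(rt))) {
    idx <- which(akey == rkey[r])
    idx <- .sidechainAtomIdx(ensemble, idx, includeHydrogens)
    if (!length(idx))
      stop("residue ", rkey[r], " has no side-chain atoms")
    m <- .atomMasses(ensemble, idx)
    w <- m / sum(m)
    coms[r, , ] <- apply(ensemble@coords[idx, , , drop = FALSE], 3L,
                         function(fr) colSums(fr * w))
  }
  attr(coms, "residues") <- rt
  coms
}

#' Equally spaced frame indices
#'
#' Indices of \code{k} frames equally spaced over \code{1..n}, always
#' including the first and last frame; \code{k = 1} returns the first frame
#' (endpoint convention). Index \code{i} is \code{round((i-1)(n-1)/(k-1))+1}.
#'
#' @param n total frame count
#' @param k number of frames to keep, \code{1 <= k <= n}
#' @return integer vector of length \code{k}
#' @export
subsampleIndices <- function(n, k) {
  if (k < 1L || k > n)
    stop(sprintf("k must be between 1 and the frame count (%d), got %s",
                 n, k))
  if (k == 1L) return(1L)
  as.integer(round((seq_len(k) - 1) * (n - 1) / (k - 1))) + 1L
}

#' Subsample an ensemble to k equally spaced frames
#'
#' Keeps \code{k} frames equally spaced in time, first and last included,
#' preserving order (e.g. 501 frames from 5001 keeps every 10th frame).
#' Idempotent for a fixed \code{k}.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param k number of frames to keep
#' @return a \linkS4class{ConformationalEnsemble} with \code{k} frames
#' @export
subsampleFrames <- function(ensemble, k) {
  idx <- subsampleIndices(nFrames(ensemble), k)
  initialize(ensemble,
             coords = ensemble@coords[, , idx, drop = FALSE])
}
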