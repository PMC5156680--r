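## Hand-rolled PDB text for malformed-input tests (the writers can only
## produce well-formed files).

pdbAtomLine <- function(serial, atom, resname, chain, resnum, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, strtrim(sprintf(" %s", atom), 4L), resname, chain,
          resnum, x, y, z)
}

pdbModelText <- function(model, atoms) {
  c(sprintf("MODEL     %4d", model),
    vapply(seq_len(nrow(atoms)), function(i)
      with(atoms[i, ], pdbAtomLine(i, atom, resname, chain, resnum,
                                   x, y, z)),
      character(1)),
    "ENDMDL")
}

## Two alanines on chain A with CB side chains; coordinates in angstrom.
toyAtoms <- function(shift = 0) {
  data.frame(atom = rep(c("N", "CA", "CB"), 2L),
             resname = "ALA", chain = "A",
             resnum = rep(1:2, each = 3L),
             x = c(0, 1, 2, 5, 6, 7) + shift,
             y = c(0, 0, 1, 0, 0, 1),
             z = 0)
}

## Minimal in-code ensemble: explicit atoms/coords in nm, optional
## per-atom-name mass overrides.
tinyEnsemble <- function(coordList, atoms, massOverrides = numeric(0)) {
  coords <- array(NA_real_, c(nrow(atoms), 3L, length(coordList)))
  for (f in seq_along(coordList)) coords[, , f] <- coordList[[f]]
  conformationalEnsemble(coords, atoms, massOverrides = massOverrides)
}

## Two-residue ensemble whose side-chain COM (single CB atom) distance is
## exactly d[f] in frame f -- for NOE averaging checks.
pairDistanceEnsemble <- function(d) {
  atoms <- data.frame(chain = "A", resnum = c(1L, 10L),
                      resname = "ALA", atom = c("CB", "CB"))
  tinyEnsemble(lapply(d, function(df)
    rbind(c(0, 0, 0), c(df, 0, 0))), atoms)
}
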