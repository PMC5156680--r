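#' Contact specification for synthetic dimer ensembles
#'
#' Ground-truth plant for [makeDimerEnsemble()]: a residue pair, the
#' fraction of frames in which it must be in contact, and the two
#' distances realising the contacted/separated states. The second residue
#' of each spec is the one that is moved.
#'
#' @param chainA,resA anchor residue (stays at its base position)
#' @param chainB,resB mobile residue (translated per frame)
#' @param persistence target contact persistence in [0, 1]
#' @param contactNm side-chain COM distance in contact frames
#'   (default 0.45 nm, inside the usual 0.5 nm cutoff)
#' @param separatedNm distance in the remaining frames (default 0.8 nm)
#' @return one-row data.frame; rbind several to plant several contacts
#' @export
contactSpec <- function(chainA, resA, chainB, resB, persistence,
                        contactNm = 0.45, separatedNm = 0.8) {
  stopifnot(persistence >= 0, persistence <= 1, contactNm < separatedNm,
            contactNm > 0)
  data.frame(chainA = chainA, resA = as.integer(resA),
             chainB = chainB, resB = as.integer(resB),
             persistence = persistence, contactNm = contactNm,
             separatedNm = separatedNm, stringsAsFactors = FALSE)
}

## Minimal residue template (nm offsets from the residue base point):
## backbone N/CA/C/O plus a single CB side-chain pseudo-atom, so COM and
## contact logic are exercised without rotamer realism. Glycine omits CB.
.RESIDUE_TEMPLATE <- data.frame(
  atom = c("N", "CA", "C", "O", "CB"),
  dx = c(-0.15, 0, 0.15, 0.15, 0),
  dy = c(0.10, 0, 0.10, 0.25, -0.15),
  dz = c(0, 0, 0, 0, 0))

.CONTACT_DIRECTIONS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))

#' Synthetic two-chain ensemble with planted contact persistences
#'
#' Builds a toy dimer whose residues sit on a coarse grid far apart (3 nm
#' spacing, 8 nm between chains), then translates the mobile residue of
#' each [contactSpec()] so that the pair's side-chain COM distance equals
#' the contact distance in exactly \code{round(persistence * nFrames)}
#' frames (chosen by a seeded permutation, so small-ensemble persistence
#' is exact) and the separated distance otherwise. Isotropic Gaussian
#' coordinate noise is added last. Multiple specs may share an anchor
#' (planting hubs); a mobile residue may appear in only one spec.
#'
#' @param nFrames number of frames (>= 1)
#' @param residuesPerChain residues per chain (chains "A" and "B")
#' @param contactSpecs data.frame of [contactSpec()] rows, or NULL
#' @param noiseSd isotropic coordinate noise sd, nm (default 0)
#' @param glycines optional data.frame(chain, resnum) of residues to build
#'   as glycine (no side-chain atom)
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and this seed
#' @return a \linkS4class{ConformationalEnsemble}
#' @examples
#' ens <- makeDimerEnsemble(20, 4,
#'   contactSpec("A", 1, "B", 1, persistence = 0.5), seed = 7)
#' psnEdges(buildPsn(ens))   # one edge, occurrence 0.5
#' @export
makeDimerEnsemble <- function(nFrames, residuesPerChain = 10L,
                              contactSpecs = NULL, noiseSd = 0,
                              glycines = NULL, seed = 1L) {
  stopifnot(nFrames >= 1L, residuesPerChain >= 1L, noiseSd >= 0)
  chains <- c("A", "B")
  rt <- expand.grid(resnum = seq_len(residuesPerChain), chain = chains,
                    stringsAsFactors = FALSE)[, c("chain", "resnum")]
  rt$resname <- "ALA"
  if (!is.null(glycines))
    rt$resname[match(paste(glycines$chain, glycines$resnum),
                     paste(rt$chain, rt$resnum))] <- "GLY"
  base <- cbind(3 * (rt$resnum - 1L),
                8 * (match(rt$chain, chains) - 1L),
                0)
  atoms <- do.call(rbind, lapply(seq_len(nrow(rt)), function(r) {
    tpl <- .RESIDUE_TEMPLATE
    if (rt$resname[r] == "GLY") tpl <- tpl[tpl$atom != "CB", ]
    data.frame(chain = rt$chain[r], resnum = rt$resnum[r],
               resname = rt$resname[r], atom = tpl$atom,
               x = base[r, 1] + tpl$dx, y = base[r, 2] + tpl$dy,
               z = base[r, 3] + tpl$dz, stringsAsFactors = FALSE)
  }))
  rkey <- paste(rt$chain, rt$resnum)

  specs <- contactSpecs
  if (!is.null(specs) && nrow(specs)) {
    akey <- paste(specs$chainA, specs$resA)
    mkey <- paste(specs$chainB, specs$resB)
    if (any(akey == mkey))
      stop("a contact spec must reference two distinct residues")
    pair <- paste(pmin(akey, mkey), pmax(akey, mkey))
    if (anyDuplicated(pair))
      stop("conflicting contact specs for residue pair ",
           pair[duplicated(pair)][1L])
    if (anyDuplicated(mkey))
      stop("mobile residue used by more than one spec: ",
           mkey[duplicated(mkey)][1L])
    if (any(mkey %in% akey))
      stop("residue cannot be both mobile and anchor: ",
           intersect(mkey, akey)[1L])
    missing <- setdiff(c(akey, mkey), rkey)
    if (length(missing))
      stop("contact spec references unknown residue(s): ",
           paste(missing, collapse = ", "))
    gly <- rkey[rt$resname == "GLY"]
    if (any(c(akey, mkey) %in% gly))
      stop("contact specs cannot involve glycine (no side chain)")
  }

  withr::with_seed(seed, {
    coords <- array(rep(as.matrix(atoms[, c("x", "y", "z")]), nFrames),
                    c(nrow(atoms), 3L, nFrames))
    if (!is.null(specs) && nrow(specs)) {
      akey <- paste(specs$chainA, specs$resA)
      mkey <- paste(specs$chainB, specs$resB)
      dirUse <- integer(0)
      for (k in seq_len(nrow(specs))) {
        nContact <- round(specs$persistence[k] * nFrames)
        inContact <- logical(nFrames)
        inContact[sample.int(nFrames)[seq_len(nContact)]] <- TRUE
        ## next unused direction for this anchor
        used <- sum(akey[seq_len(k)] == akey[k])
        if (used > nrow(.CONTACT_DIRECTIONS))
          stop("too many contacts planted on anchor ", akey[k])
        u <- .CONTACT_DIRECTIONS[used, ]
        aCB <- which(paste(atoms$chain, atoms$resnum) == akey[k] &
                       atoms$atom == "CB")
        mIdx <- which(paste(atoms$chain, atoms$resnum) == mkey[k])
        mCB <- mIdx[atoms$atom[mIdx] == "CB"]
        for (f in seq_len(nFrames)) {
          d <- if (inContact[f]) specs$contactNm[k] else specs$separatedNm[k]
          target <- coords[aCB, , f] + d * u
          shift <- target - coords[mCB, , f]
          coords[mIdx, , f] <- sweep(coords[mIdx, , f, drop = FALSE][, , 1L],
                                     2L, shift, `+`)
        }
      }
    }
    if (noiseSd > 0)
      coords <- coords + rnorm(length(coords), sd = noiseSd)
    conformationalEnsemble(coords, atoms[, c("chain", "resnum", "resname",
                                             "atom")])
  })
}

#' Synthetic saturation-mutagenesis scan with planted hotspots
#'
#' Draws Gaussian free-energy records around a planted truth: hotspot
#' positions get true means above the deleterious threshold (by at least
#' \code{hotspotMargin}) for \code{hotspotFraction} of their 19
#' substitutions, all other cells stay below \code{threshold -
#' hotspotMargin}. Records are one per conformer x run per cell.
#'
#' @param positions integer vector of scan positions
#' @param wt wild-type one-letter codes, one per position (default:
#'   cycled alphabet)
#' @param hotspots subset of \code{positions} planted as hotspots
#' @param chains \code{NA} for a monomer scan or a chain vector (e.g.
#'   \code{c("A", "B")}) for a dimer scan duplicating every site per chain
#' @param nConformers,nRuns records per cell = conformers x runs
#'   (defaults 20 x 5)
#' @param noiseSd record noise sd, kcal/mol (default 0.2)
#' @param threshold,hotspotMargin,hotspotFraction hotspot planting
#'   geometry (defaults 1.6, 1.0, 0.9)
#' @param scope recorded on the records (\code{"stability"} or
#'   \code{"binding"})
#' @param seed RNG seed
#' @return list with \code{records} (data.frame for [aggregateScan()]),
#'   \code{truth} (long data.frame: chain, position, wt, mut, mean) and
#'   \code{hotspots}
#' @export
makeDdgScan <- function(positions, wt = NULL, hotspots = integer(0),
                        chains = NA_character_, nConformers = 20L,
                        nRuns = 5L, noiseSd = 0.2, threshold = 1.6,
                        hotspotMargin = 1.0, hotspotFraction = 0.9,
                        scope = c("stability", "binding"), seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(nConformers >= 1L, nRuns >= 1L, noiseSd >= 0,
            all(hotspots %in% positions))
  aa <- sort(unname(.AA3_TO_1))
  if (is.null(wt))
    wt <- aa[(seq_along(positions) - 1L) %% 20L + 1L]
  stopifnot(length(wt) == length(positions))
  withr::with_seed(seed, {
    truth <- do.call(rbind, lapply(seq_along(positions), function(i) {
      muts <- setdiff(aa, wt[i])
      if (positions[i] %in% hotspots) {
        nHot <- ceiling(hotspotFraction * 19)
        mean <- c(threshold + hotspotMargin + runif(nHot),
                  runif(19 - nHot, -0.5, threshold - hotspotMargin))
      } else {
        mean <- runif(19, -0.5, threshold - hotspotMargin)
      }
      data.frame(position = positions[i], wt = wt[i], mut = muts,
                 mean = mean)
    }))
    truth <- do.call(rbind, lapply(chains, function(ch)
      cbind(chain = ch, truth)))
    rownames(truth) <- NULL
    reps <- expand.grid(conformer = seq_len(nConformers),
                        run = seq_len(nRuns))
    n <- nrow(truth)
    records <- truth[rep(seq_len(n), each = nrow(reps)), , drop = FALSE]
    records$conformer <- rep(reps$conformer, n)
    records$run <- rep(reps$run, n)
    records$ddg <- records$mean + rnorm(nrow(records), sd = noiseSd)
    records$mean <- NULL
    records$scope <- scope
    rownames(records) <- NULL
    list(records = records, truth = truth, hotspots = hotspots)
  })
}

#' Synthetic chemical-shift data as truth plus frame noise
#'
#' The experimental table is the truth itself; the predicted per-frame
#' series are the truth plus independent Gaussian noise, so the
#' chi-square statistic has a known closed-form expectation
#' \eqn{(s/(s-1)) \cdot mean(\sigma^2 / (n \delta))}.
#'
#' @param truth data.frame with \code{chain}, \code{resnum}, \code{atom},
#'   \code{shift} (ppm, nonzero)
#' @param nFrames number of predicted frames
#' @param noiseSd per-frame prediction noise sd, ppm
#' @param seed RNG seed
#' @return list with \code{experimental} and \code{predicted} (long
#'   format), ready for [chi2Shifts()]
#' @export
makeShiftData <- function(truth, nFrames, noiseSd = 0, seed = 1L) {
  stopifnot(nFrames >= 1L, noiseSd >= 0, all(truth$shift != 0))
  withr::with_seed(seed, {
    predicted <- truth[rep(seq_len(nrow(truth)), each = nFrames),
                       c("chain", "resnum", "atom", "shift")]
    predicted$frame <- rep(seq_len(nFrames), nrow(truth))
    predicted$shift <- predicted$shift + rnorm(nrow(predicted),
                                               sd = noiseSd)
    rownames(predicted) <- NULL
    list(experimental = truth, predicted = predicted)
  })
}

#' Synthetic NOE restraint set drawn from an ensemble
#'
#' Samples atom pairs from the ensemble in each sequence-context category
#' (exact requested counts), sets each experimental distance to the
#' pair's linear ensemble-average distance plus Gaussian jitter, and
#' labels categories with the same rule as [categorizeRestraint()] — so
#' with zero jitter the linear-average distance differences are exactly
#' zero.
#'
#' @param ensemble a \linkS4class{ConformationalEnsemble}
#' @param nLong,nShort,nIntermolecular requested restraints per category
#' @param jitterSd distance jitter sd, nm (default 0)
#' @param seed RNG seed
#' @return restraint data.frame (see [readNoeTable()]) with
#'   \code{category}
#' @export
makeNoeSet <- function(ensemble, nLong, nShort, nIntermolecular,
                       jitterSd = 0, seed = 1L) {
  at <- ensemble@atoms
  rt <- residueTable(ensemble)
  rkey <- paste(rt$chain, rt$resnum)
  atomsOf <- split(seq_len(nrow(at)), paste(at$chain, at$resnum))
  atomsOf <- atomsOf[rkey]
  nAt <- lengths(atomsOf)

  pairsFor <- function(category) {
    idx <- expand.grid(a = seq_len(nrow(rt)), b = seq_len(nrow(rt)))
    idx <- idx[idx$a <= idx$b, ]
    cat <- categorizeRestraint(rt$chain[idx$a], rt$resnum[idx$a],
                               rt$chain[idx$b], rt$resnum[idx$b])
    same <- idx$a == idx$b
    keep <- cat == category & (!same | category == "short")
    idx <- idx[keep, , drop = FALSE]
    npairs <- ifelse(idx$a == idx$b, nAt[idx$a] * (nAt[idx$a] - 1L) / 2L,
                     nAt[idx$a] * nAt[idx$b])
    idx$npairs <- npairs
    idx[idx$npairs > 0L, , drop = FALSE]
  }

  sampleCategory <- function(category, n) {
    if (n == 0L) return(NULL)
    cand <- pairsFor(category)
    if (!nrow(cand) || sum(cand$npairs) < n)
      stop(sprintf(
        "insufficient eligible pairs for category '%s': need %d, have %d",
        category, n, if (nrow(cand)) sum(cand$npairs) else 0L))
    picked <- character(0)
    rows <- list()
    while (length(picked) < n) {
      m <- 2L * (n - length(picked)) + 10L
      ri <- sample.int(nrow(cand), m, replace = TRUE,
                       prob = cand$npairs)
      for (r in ri) {
        ia <- atomsOf[[cand$a[r]]]
        ib <- atomsOf[[cand$b[r]]]
        pa <- ia[sample.int(length(ia), 1L)]
        pb <- ib[sample.int(length(ib), 1L)]
        if (pa == pb) next
        key <- paste(min(pa, pb), max(pa, pb))
        if (key %in% picked) next
        picked <- c(picked, key)
        rows[[length(rows) + 1L]] <- c(min(pa, pb), max(pa, pb))
        if (length(picked) == n) break
      }
    }
    do.call(rbind, rows)
  }

  withr::with_seed(seed, {
    sel <- rbind(sampleCategory("long", nLong),
                 sampleCategory("short", nShort),
                 sampleCategory("intermolecular", nIntermolecular))
    ia <- sel[, 1L]; ib <- sel[, 2L]
    diffs <- ensemble@coords[ia, , , drop = FALSE] -
      ensemble@coords[ib, , , drop = FALSE]
    d_avg <- rowMeans(sqrt(apply(diffs^2, c(1L, 3L), sum)))
    dist_exp <- d_avg + if (jitterSd > 0)
      rnorm(length(d_avg), sd = jitterSd) else 0
    dist_exp <- pmax(dist_exp, 1e-6)
    out <- data.frame(chain_a = at$chain[ia], res_a = at$resnum[ia],
                      atom_a = at$atom[ia], chain_b = at$chain[ib],
                      res_b = at$resnum[ib], atom_b = at$atom[ib],
                      distance_nm = dist_exp)
    out$category <- categorizeRestraint(out$chain_a, out$res_a,
                                        out$chain_b, out$res_b)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic variant-predictor score table with planted consensus classes
#'
#' Draws, for every mutation, one score per method on the side of that
#' method's published cutoff dictated by its planted class:
#' \code{"deleterious-consensus"} (all methods deleterious),
#' \code{"neutral-consensus"} (all neutral) or \code{"mixed"} (each
#' method random, forced to contain at least one verdict of each kind).
#'
#' @param mutations character vector of mutation labels (e.g. "P58L")
#' @param classes planted class per mutation
#' @param seed RNG seed
#' @return data.frame with \code{mutation} and the seven method columns,
#'   ready for [consensusClassify()]
#' @export
makePredictorTable <- function(mutations, classes, seed = 1L) {
  stopifnot(length(mutations) == length(classes),
            all(classes %in% c("deleterious-consensus",
                               "neutral-consensus", "mixed")))
  thr <- predictorThresholds()
  numMethods <- setdiff(names(thr), "align_gvgd")
  neutralClasses <- c("C0", "C15", "C25", "C35")
  drawScore <- function(method, deleterious) {
    rule <- thr[[method]]
    offset <- runif(1L, 0.2, 2)
    towardDel <- if (rule$direction == "lt") rule$cut - offset
                 else rule$cut + offset
    towardNeu <- if (rule$direction == "lt") rule$cut + offset
                 else rule$cut - offset
    if (deleterious) towardDel else towardNeu
  }
  withr::with_seed(seed, {
    rows <- lapply(seq_along(mutations), function(i) {
      del <- switch(classes[i],
                    "deleterious-consensus" = rep(TRUE, 7L),
                    "neutral-consensus" = rep(FALSE, 7L),
                    "mixed" = {
                      v <- runif(7L) < 0.5
                      if (all(v)) v[sample.int(7L, 1L)] <- FALSE
                      if (!any(v)) v[sample.int(7L, 1L)] <- TRUE
                      v
                    })
      row <- data.frame(mutation = mutations[i])
      for (k in seq_along(numMethods))
        row[[numMethods[k]]] <- drawScore(numMethods[k], del[k])
      row$align_gvgd <- if (del[7L])
        sample(thr$align_gvgd$classes, 1L)
      else sample(neutralClasses, 1L)
      row
    })
    do.call(rbind, rows)
  })
}

#' Ground truth for a synthetic paired tumor/normal count cohort
#'
#' Per-gene baselines and tumor log2 fold changes, a negative-binomial
#' dispersion, and per-gene loadings on a shared per-patient latent
#' factor: the planted correlation between the log2 expression changes of
#' two genes is the product of their loadings (e.g. loadings
#' \code{sqrt(0.9)} on both genes plant a change-correlation of 0.9).
#'
#' @param baseline named per-gene mean counts (> 0)
#' @param log2FC per-gene tumor log2 fold change
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param loadings per-gene latent-factor loadings in [-1, 1]
#' @param changeSd total sd of each gene's per-patient log2 change
#'   (default 0.4)
#' @param nPatients number of tumor/normal pairs
#' @return list of class \code{"countsTruth"}
#' @export
countsTruth <- function(baseline, log2FC = 0, dispersion = 0.002,
                        loadings = 0, changeSd = 0.4, nPatients = 50L) {
  g <- length(baseline)
  log2FC <- rep_len(log2FC, g)
  loadings <- rep_len(loadings, g)
  stopifnot(all(baseline > 0), dispersion > 0, all(abs(loadings) <= 1),
            changeSd >= 0, nPatients >= 1L,
            !is.null(names(baseline)))
  structure(list(baseline = baseline, log2FC = log2FC,
                 dispersion = dispersion, loadings = loadings,
                 changeSd = changeSd, nPatients = nPatients),
            class = "countsTruth")
}

#' Synthetic paired tumor/normal count matrix
#'
#' Negative-binomial counts for \code{nPatients} tumor/normal pairs.
#' Normal samples draw around each gene's baseline; tumor samples draw
#' around \code{baseline * 2^change} where each gene's per-patient log2
#' change is \code{log2FC + changeSd * (loading * z + sqrt(1 - loading^2)
#' * e)} with a shared patient factor \code{z} — planting both the median
#' shifts and the change-correlations that the annotation operations
#' recover.
#'
#' @param truth a [countsTruth()] object
#' @param seed RNG seed
#' @return a \linkS4class{PairedCountMatrix}; the truth is kept in
#'   \code{metadata()}
#' @export
makePairedCounts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "countsTruth"))
  g <- length(truth$baseline)
  p <- truth$nPatients
  withr::with_seed(seed, {
    z <- rnorm(p)
    eps <- matrix(rnorm(g * p), g, p)
    change <- truth$log2FC + truth$changeSd *
      (truth$loadings %o% z +
         sqrt(1 - truth$loadings^2) * eps)
    size <- 1 / truth$dispersion
    normal <- matrix(rnbinom(g * p, mu = rep(truth$baseline, p),
                             size = size), g, p)
    tumorMu <- truth$baseline * 2^change
    tumor <- matrix(rnbinom(g * p, mu = as.vector(tumorMu), size = size),
                    g, p)
    counts <- cbind(tumor, normal)
    rownames(counts) <- names(truth$baseline)
    colnames(counts) <- c(paste0("P", seq_len(p), "_T"),
                          paste0("P", seq_len(p), "_N"))
    out <- pairedCountMatrix(
      counts,
      condition = rep(c("tumor", "normal"), each = p),
      patient = rep(paste0("P", seq_len(p)), 2L))
    S4Vectors::metadata(out)$truth <- truth
    out
  })
}
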