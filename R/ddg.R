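#' Empirical correction parameters for predicted free-energy changes
#'
#' Linear calibration mapping force-field-predicted stability changes onto
#' the experimental scale, plus a reference unfolding free energy for the
#' wild type. The defaults are the published calibration of predicted vs
#' experimental stability changes (slope 0.877 = 1/1.14, intercept
#' 0.068 = 0.078/1.14 kcal/mol) and a 5 kcal/mol wild-type unfolding free
#' energy, a typical value for small helical domains.
#'
#' @param m slope (> 0)
#' @param b intercept, kcal/mol
#' @param dguWT wild-type experimental unfolding free energy, kcal/mol
#' @return list of class \code{"correctionParams"}
#' @export
correctionParams <- function(m = 0.877, b = 0.068, dguWT = 5.0) {
  stopifnot(m > 0, is.finite(b), is.finite(dguWT))
  structure(list(m = m, b = b, dguWT = dguWT),
            class = "correctionParams")
}

#' Rescale a predicted free-energy change to the experimental scale
#'
#' Applies the linear calibration \code{m * ddg + b}, i.e. the inverse of
#' the fitted relation predicted = -0.078 + 1.14 * experimental.
#'
#' @param ddg predicted stability change(s), kcal/mol (vectorised)
#' @param params a [correctionParams()] object
#' @return corrected value(s), kcal/mol
#' @examples
#' correctDdg(0)      # the intercept, 0.068
#' correctDdg(1.062)  # 1.000
#' @export
correctDdg <- function(ddg, params = correctionParams()) {
  stopifnot(all(is.finite(ddg)))
  params$m * ddg + params$b
}

#' Estimated unfolding free energy of a mutant
#'
#' \code{dguWT + m * ddg + b} by default — the corrected stability change
#' added to the wild-type unfolding free energy, exactly as the source
#' calibration writes it. Because a destabilising (positive) change would
#' conventionally \emph{lower} the unfolding free energy, the physically
#' conventional subtractive form \code{dguWT - (m * ddg + b)} is available
#' via \code{convention = "subtractive"}; it is never substituted silently.
#'
#' @param ddg predicted stability change(s), kcal/mol
#' @param params a [correctionParams()] object
#' @param convention \code{"additive"} (as published) or
#'   \code{"subtractive"}
#' @return estimated unfolding free energy, kcal/mol
#' @export
unfoldingDG <- function(ddg, params = correctionParams(),
                        convention = c("additive", "subtractive")) {
  convention <- match.arg(convention)
  corr <- correctDdg(ddg, params)
  if (convention == "additive") params$dguWT + corr
  else params$dguWT - corr
}

#' Classify a mean free-energy change as neutral or deleterious
#'
#' A mutation is deleterious when its mean stability change exceeds the
#' threshold, taken as twice the typical 0.8 kcal/mol prediction error of
#' the energy function (1.6 kcal/mol). The boundary is strict by default:
#' exactly 1.6 is neutral.
#'
#' @param ddg mean free-energy change(s), kcal/mol (vectorised)
#' @param threshold kcal/mol (default 1.6)
#' @param inclusive count \code{ddg == threshold} as deleterious
#' @return character vector, \code{"neutral"} or \code{"deleterious"}
#' @export
classifyMutation <- function(ddg, threshold = 1.6, inclusive = FALSE) {
  stopifnot(all(is.finite(ddg)))
  del <- if (inclusive) ddg >= threshold else ddg > threshold
  ifelse(del, "deleterious", "neutral")
}

#' Cross-classify stability and binding effects
#'
#' Four-way category from the two threshold tests: mutations that leave
#' the monomer stable but break the dimer interface are
#' \code{"binding-only"} (the pattern behind interface-specific
#' substitutions), and so on.
#'
#' @param stabilityDdg,bindingDdg mean free-energy changes, kcal/mol
#'   (vectorised, recycled)
#' @param threshold kcal/mol (default 1.6)
#' @param inclusive boundary convention, as in [classifyMutation()]
#' @return character vector in \code{neutral}, \code{stability-only},
#'   \code{binding-only}, \code{both}
#' @export
categorizeEffects <- function(stabilityDdg, bindingDdg, threshold = 1.6,
                              inclusive = FALSE) {
  s <- classifyMutation(stabilityDdg, threshold, inclusive) == "deleterious"
  b <- classifyMutation(bindingDdg, threshold, inclusive) == "deleterious"
  out <- rep("neutral", length(s))
  out[s & !b] <- "stability-only"
  out[!s & b] <- "binding-only"
  out[s & b] <- "both"
  out
}

.checkDdgRecords <- function(records) {
  need <- c("wt", "position", "mut", "conformer", "run", "ddg")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("record table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$wt == records$mut))
    stop("records with wild-type == mutant are not valid mutations")
  if (!all(is.finite(records$ddg)))
    stop("non-finite ddg values in records")
  if (is.null(records$chain)) records$chain <- NA_character_
  records
}

#' Aggregate per-conformer, per-run scan records into a ScanMatrix
#'
#' Pools every record for a (site, substitution) cell — all conformers and
#' all independent runs together — into an arithmetic mean and a sample
#' standard deviation. A complete saturation scan has all 19 substitutions
#' at every site; gaps are a hard error listing the missing cells.
#'
#' @param records data.frame of scan records with columns \code{wt}
#'   (one-letter), \code{position}, \code{mut} (one-letter),
#'   \code{conformer}, \code{run}, \code{ddg} (kcal/mol) and optionally
#'   \code{chain} (dimer scans) and \code{scope}.
#' @param scope \code{"stability"} or \code{"binding"}; when the records
#'   carry a \code{scope} column they are filtered to it first.
#' @param requireComplete error when any of the 19 substitutions is missing
#'   at a site (default TRUE)
#' @return a \linkS4class{ScanMatrix}
#' @export
aggregateScan <- function(records, scope = c("stability", "binding"),
                          requireComplete = TRUE) {
  scope <- match.arg(scope)
  if (!is.null(records$scope)) {
    records <- records[records$scope == scope, , drop = FALSE]
    if (!nrow(records)) stop("no records with scope '", scope, "'")
  }
  records <- .checkDdgRecords(records)
  skey <- paste(records$chain, records$position, sep = "\r")
  sites <- records[!duplicated(skey),
                   c("chain", "position", "wt"), drop = FALSE]
  sites <- sites[order(sites$chain, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  if (anyDuplicated(paste(sites$chain, sites$position)))
    stop("inconsistent wild-type codes within a site")
  aa <- sort(unname(.AA3_TO_1))
  nS <- nrow(sites)
  means <- sds <- matrix(NA_real_, nS, 20L, dimnames = list(NULL, aa))
  counts <- matrix(0L, nS, 20L, dimnames = list(NULL, aa))
  row <- match(skey, paste(sites$chain, sites$position, sep = "\r"))
  col <- match(records$mut, aa)
  if (anyNA(col)) stop("unknown mutant residue code in records")
  cell <- (col - 1L) * nS + row
  agg <- split(records$ddg, cell)
  ids <- as.integer(names(agg))
  means[ids] <- vapply(agg, mean, numeric(1))
  sds[ids] <- vapply(agg, function(x)
    if (length(x) > 1L) sd(x) else 0, numeric(1))
  counts[ids] <- lengths(agg)
  wtcol <- match(sites$wt, aa)
  if (anyNA(wtcol)) stop("unknown wild-type residue code")
  wtcells <- cbind(seq_len(nS), wtcol)
  if (any(counts[wtcells] > 0L))
    stop("records mutating a position to its own wild type are not cells")
  if (requireComplete) {
    expected <- matrix(TRUE, nS, 20L)
    expected[wtcells] <- FALSE
    gaps <- which(expected & counts == 0L, arr.ind = TRUE)
    if (nrow(gaps)) {
      lab <- paste0(sites$wt[gaps[, 1L]], sites$position[gaps[, 1L]],
                    aa[gaps[, 2L]],
                    ifelse(is.na(sites$chain[gaps[, 1L]]), "",
                           paste0(" (chain ", sites$chain[gaps[, 1L]], ")")))
      stop("incomplete scan; missing cell(s): ",
           paste(head(lab, 10L), collapse = ", "),
           if (nrow(gaps) > 10L) sprintf(" ... and %d more", nrow(gaps) - 10L))
    }
  }
  means[wtcells] <- NA_real_
  sds[wtcells] <- NA_real_
  new("ScanMatrix", sites = sites, means = means, sds = sds,
      counts = counts, scope = scope)
}

#' Number of substitution cells in a ScanMatrix
#' @param scan a \linkS4class{ScanMatrix}
#' @return integer: filled (position, substitution) cells
#' @export
scanCellCount <- function(scan) sum(!is.na(scanMeans(scan)))

#' Long-format view of a ScanMatrix
#'
#' One row per (site, substitution) cell, suitable for export or heatmap
#' plotting.
#' @param scan a \linkS4class{ScanMatrix}
#' @return data.frame: chain, position, wt, mut, mean, sd, n
#' @export
scanToLong <- function(scan) {
  s <- scanSites(scan)
  aa <- colnames(scanMeans(scan))
  idx <- which(!is.na(scanMeans(scan)), arr.ind = TRUE)
  out <- data.frame(chain = s$chain[idx[, 1L]],
                    position = s$position[idx[, 1L]],
                    wt = s$wt[idx[, 1L]],
                    mut = aa[idx[, 2L]],
                    mean = scanMeans(scan)[idx],
                    sd = scanSds(scan)[idx],
                    n = scanCounts(scan)[idx])
  out <- out[order(out$chain, out$position, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structural hotspot positions of a scan
#'
#' Positions where at least \code{minFraction} of the 19 substitutions are
#' deleterious — sensitive sites where most substitutions are not
#' tolerated. Requires a complete matrix (no missing substitution cells).
#'
#' @param scan a complete \linkS4class{ScanMatrix}
#' @param threshold deleterious threshold, kcal/mol (default 1.6)
#' @param minFraction minimum deleterious fraction (default 0.5)
#' @param inclusive boundary convention, as in [classifyMutation()]
#' @return data.frame (chain, position, wt, deleteriousFraction) sorted by
#'   descending fraction
#' @export
hotspotPositions <- function(scan, threshold = 1.6, minFraction = 0.5,
                             inclusive = FALSE) {
  m <- scanMeans(scan)
  s <- scanSites(scan)
  if (any(rowSums(!is.na(m)) != 19L))
    stop("scan matrix is incomplete; aggregate a full saturation scan first")
  del <- if (inclusive) m >= threshold else m > threshold
  frac <- rowSums(del, na.rm = TRUE) / 19
  keep <- frac >= minFraction
  out <- data.frame(chain = s$chain[keep], position = s$position[keep],
                    wt = s$wt[keep], deleteriousFraction = frac[keep])
  out <- out[order(-out$deleteriousFraction, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tabular scan-record file
#'
#' Canonical input: one record per row, tab-separated, with columns
#' \code{wt}, \code{position}, \code{mut}, \code{conformer}, \code{run},
#' \code{ddg} and optionally \code{chain}, \code{scope}.
#' @param path file path
#' @return validated data.frame of records
#' @export
readDdgTable <- function(path) {
  .checkDdgRecords(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Thin parser for FoldX-style "Dif" output
#'
#' Reads the energy-difference table written per run by the BuildModel
#' step: a header block followed by tab-separated rows whose first column
#' is the mutant model file and second column the total energy difference.
#' The mutation identity is not stored in that file, so the mutation list
#' (in run order) must be supplied.
#'
#' @param path Dif-style file
#' @param mutations character vector like \code{"PA58L"} or a data.frame
#'   with \code{wt}, \code{position}, \code{mut} (and optionally
#'   \code{chain}), one entry per data row of the file
#' @param conformer,run indices recorded on the returned rows
#' @return data.frame of scan records (see [readDdgTable()])
#' @export
readFoldxDif <- function(path, mutations, conformer = 1L, run = 1L) {
  lines <- readLines(path)
  first <- grep("\t-?[0-9.]", lines)[1L]
  if (is.na(first)) stop("no data rows found in ", path)
  d <- read.table(text = lines[first:length(lines)], sep = "\t",
                  stringsAsFactors = FALSE)
  ddg <- as.numeric(d[[2L]])
  if (is.character(mutations))
    mutations <- data.frame(
      wt = substr(mutations, 1L, 1L),
      chain = substr(mutations, 2L, 2L),
      position = as.integer(gsub("[^0-9]", "", mutations)),
      mut = substr(mutations, nchar(mutations), nchar(mutations)))
  if (nrow(mutations) != length(ddg))
    stop(sprintf("mutation list has %d entries but file has %d data rows",
                 nrow(mutations), length(ddg)))
  .checkDdgRecords(cbind(mutations, conformer = conformer, run = run,
                         ddg = ddg))
}
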