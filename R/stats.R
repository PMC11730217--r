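## Reaction-propensity geometry statistics over conformer ensembles:
## interatomic distance series and their probability distributions,
## pi-stacking classification of the donor/acceptor ring pair, and
## carboxylate-to-hydroxyl proximity for the acidic variants.

#' DistanceSeries: per-frame interatomic distances
#'
#' @slot values numeric distances, Angstrom, one per frame (frame order
#'   preserved).
#' @slot pair character(2), \code{"resid/NAME"} labels of the atom pair.
#' @slot condition condition label of the source ensemble.
#' @aliases DistanceSeries
#' @exportClass DistanceSeries
setClass("DistanceSeries",
         representation(values = "numeric", pair = "character",
                        condition = "character"))

setValidity("DistanceSeries", function(object) {
  if (!all(is.finite(object@values))) return("distances must be finite")
  if (any(object@values <= 0))
    return("coincident atoms: zero distance in series")
  TRUE
})

#' @describeIn DistanceSeries-utils the distance values (Angstrom).
#' @export
seriesValues <- function(series) series@values

#' Distance series accessors
#' @param series a \code{DistanceSeries}.
#' @name DistanceSeries-utils
NULL

setMethod("show", "DistanceSeries", function(object) {
  cat(sprintf("DistanceSeries %s -- %s (%s): %d frames, %.2f .. %.2f A\n",
              object@pair[1L], object@pair[2L], object@condition,
              length(object@values), min(object@values), max(object@values)))
})

#' DistributionSummary: normalized histogram of a distance series
#'
#' @slot breaks bin edges, Angstrom (contiguous).
#' @slot probabilities per-bin probabilities (sum to 1).
#' @slot mode center of the maximum-probability bin (leftmost on ties),
#'   Angstrom.
#' @slot mean arithmetic mean of the raw series, Angstrom.
#' @slot interdecile 90th minus 10th percentile of the raw series,
#'   Angstrom.
#' @aliases DistributionSummary
#' @exportClass DistributionSummary
setClass("DistributionSummary",
         representation(breaks = "numeric", probabilities = "numeric",
                        mode = "numeric", mean = "numeric",
                        interdecile = "numeric"))

setMethod("show", "DistributionSummary", function(object) {
  cat(sprintf(paste0("DistributionSummary: %d bins, mode %.2f A, ",
                     "mean %.2f A, interdecile %.2f A\n"),
              length(object@probabilities), object@mode, object@mean,
              object@interdecile))
})

.seriesFrom <- function(x) {
  if (is(x, "DistanceSeries")) x@values
  else if (is.numeric(x)) x
  else stop("expected a DistanceSeries or a numeric vector")
}

#' Interatomic distance series over an ensemble
#'
#' Euclidean distance between two atoms, one value per frame, frame order
#' preserved.
#'
#' @param ens a \code{ConformerEnsemble}.
#' @param a,b atom selectors \code{c(resid, "NAME")}, e.g.
#'   \code{c(375, "OH")} for the acceptor Ozeta and \code{c(341, "CB")}
#'   for the donor Cbeta.
#' @return A \code{\linkS4class{DistanceSeries}}.
#' @export
pairDistanceSeries <- function(ens, a, b) {
  stopifnot(is(ens, "ConformerEnsemble"))
  ia <- atomIndex(ens@structure, as.integer(a[[1L]]), a[[2L]])
  ib <- atomIndex(ens@structure, as.integer(b[[1L]]), b[[2L]])
  pa <- match(ia, ens@mobile)
  pb <- match(ib, ens@mobile)
  fixedXYZ <- coords(ens@structure)
  vals <- vapply(ens@frames, function(f) {
    xa <- if (is.na(pa)) fixedXYZ[ia, ] else f[pa, ]
    xb <- if (is.na(pb)) fixedXYZ[ib, ] else f[pb, ]
    sqrt(sum((xa - xb)^2))
  }, numeric(1L))
  new("DistanceSeries", values = vals,
      pair = c(paste0(a[[1L]], "/", a[[2L]]), paste0(b[[1L]], "/", b[[2L]])),
      condition = ens@condition)
}

#' Normalized distance distribution
#'
#' Histogram of a distance series on contiguous bins of width
#' \code{binWidth} (edges aligned to multiples of the width), normalized
#' to unit mass.  The mode is the center of the maximum-probability bin,
#' leftmost on ties; mean and interdecile spread are computed from the raw
#' series.
#'
#' @param series a \code{DistanceSeries} or numeric vector (Angstrom).
#' @param binWidth bin width, Angstrom (> 0).
#' @return A \code{\linkS4class{DistributionSummary}}.
#' @export
distanceDistribution <- function(series, binWidth = 0.25) {
  v <- .seriesFrom(series)
  if (length(v) == 0L) stop("empty distance series")
  stopifnot(binWidth > 0)
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (breaks[length(breaks)] < max(v)) breaks <- c(breaks, hi + binWidth)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  p <- counts / sum(counts)
  modeBin <- which.max(p)  # leftmost maximum
  new("DistributionSummary", breaks = breaks, probabilities = p,
      mode = (breaks[modeBin] + breaks[modeBin + 1L]) / 2,
      mean = mean(v),
      interdecile = unname(diff(quantile(v, c(0.1, 0.9)))))
}

#' Fraction of frames within a reactive distance cutoff
#'
#' @param series a \code{DistanceSeries} or numeric vector.
#' @param cutoff distance cutoff, Angstrom (> 0).
#' @return Fraction in [0, 1]; monotone non-decreasing in \code{cutoff}.
#' @export
reactiveFraction <- function(series, cutoff) {
  stopifnot(cutoff > 0)
  v <- .seriesFrom(series)
  if (length(v) == 0L) stop("empty distance series")
  mean(v <= cutoff)
}

#' Classify the stacking geometry of two aromatic rings
#'
#' Ring centroids are the means of the six ring atoms; the interplanar
#' angle is the acute angle between best-fit plane normals.  The pair is
#' \code{"parallel"} when the centroid distance is at most
#' \code{dContact} and the angle is below \code{parallelMax},
#' \code{"perpendicular"} (T-shaped) when within contact and above
#' \code{perpendicularMin}, otherwise \code{"none"}.  Defaults place the
#' contact cutoff at 5.0 Angstrom around the observed pi-contact distance
#' of about 3.6 Angstrom, with 30/60-degree angle bands.
#'
#' @param x a \code{ProteinStructure} (a single frame).
#' @param ringA,ringB residue indices; tyrosine-like residues use the ring
#'   atoms CG/CD1/CD2/CE1/CE2/CZ, other residues the atoms C1-C6.
#' @param dContact contact distance cutoff, Angstrom.
#' @param parallelMax,perpendicularMin angle thresholds, degrees.
#' @param planarityTol maximum RMS out-of-plane residual, Angstrom.
#' @return A list with elements \code{label}, \code{distance} (Angstrom)
#'   and \code{angle} (degrees in [0, 90]).
#' @export
classifyStacking <- function(x, ringA, ringB, dContact = 5.0,
                             parallelMax = 30, perpendicularMin = 60,
                             planarityTol = 0.2) {
  ringXYZ <- function(resid) {
    a <- atoms(x)
    nm <- if (residueName(x, resid) %in% c("TYR", "TYD", "IYR", "PHE"))
      .ringAtomNames else paste0("C", 1:6)
    i <- which(a$resid == resid & a$name %in% nm)
    if (length(i) != 6L)
      stop(sprintf("residue %d does not contain a six-atom ring (%s)",
                   resid, paste(nm, collapse = " ")))
    as.matrix(a[i, c("x", "y", "z")])
  }
  pa <- fitPlane(ringXYZ(ringA))
  pb <- fitPlane(ringXYZ(ringB))
  if (pa$residual > planarityTol || pb$residual > planarityTol)
    stop(sprintf("non-planar ring (RMS out-of-plane residual %.3f A > %.2f A)",
                 max(pa$residual, pb$residual), planarityTol))
  d <- sqrt(sum((pa$center - pb$center)^2))
  cosang <- abs(sum(pa$normal * pb$normal))
  angle <- rad2deg(acos(pmin(1, cosang)))
  label <- if (d <= dContact && angle < parallelMax) "parallel"
  else if (d <= dContact && angle > perpendicularMin) "perpendicular"
  else "none"
  list(label = label, distance = d, angle = angle)
}

#' Per-frame stacking labels over an ensemble
#'
#' Applies \code{\link{classifyStacking}} to the donor/acceptor ring pair
#' of every frame.
#'
#' @param ens a \code{ConformerEnsemble}.
#' @param ringA,ringB residue indices (defaults: donor 341, acceptor 375).
#' @param ... thresholds passed to \code{\link{classifyStacking}}.
#' @return data.frame with columns \code{frame}, \code{label},
#'   \code{distance}, \code{angle}.
#' @export
stackingLabels <- function(ens, ringA = 341L, ringB = 375L, ...) {
  stopifnot(is(ens, "ConformerEnsemble"))
  rows <- lapply(seq_len(nFrames(ens)), function(i) {
    r <- classifyStacking(frameStructure(ens, i), ringA, ringB, ...)
    data.frame(frame = i, label = r$label, distance = r$distance,
               angle = r$angle)
  })
  do.call(rbind, rows)
}

#' Carboxylate-to-acceptor-hydroxyl proximity distribution
#'
#' Distance between the acceptor tyrosine's hydroxyl oxygen (Ozeta, PDB
#' atom OH of residue 375) and the carboxylate carbon of the acidic
#' residue 374: Cdelta for glutamate, Cgamma for aspartate.  Only the E
#' and D variants carry a carboxylate; other variants raise an error.
#'
#' @param ens a \code{ConformerEnsemble}.
#' @param binWidth histogram bin width, Angstrom.
#' @return A \code{\linkS4class{DistributionSummary}}.
#' @export
carboxylateProximity <- function(ens, binWidth = 0.25) {
  stopifnot(is(ens, "ConformerEnsemble"))
  rn <- residueName(ens@structure, 374L)
  carbon <- switch(rn, GLU = "CD", ASP = "CG",
                   stop(sprintf(paste0("not applicable: residue 374 is %s, ",
                                       "which has no carboxylate"), rn)))
  series <- pairDistanceSeries(ens, c(375L, "OH"), c(374L, carbon))
  distanceDistribution(series, binWidth = binWidth)
}
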