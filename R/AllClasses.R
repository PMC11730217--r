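## Central S4 containers.  A ProteinStructure holds one set of Cartesian
## coordinates as an atom table; a ConformerEnsemble holds a reference
## structure plus per-frame coordinates of its mobile atoms.

#' ProteinStructure: an atom table with coordinates
#'
#' Holds an ordered collection of atom records (element, PDB atom name,
#' residue name/index, chain, Cartesian coordinates in Angstrom) together
#' with a title.  Residue numbering is 1-based author numbering; the
#' engineered acceptor tail always occupies residues 371-376 and the donor
#' tyrosine is numbered 341.
#'
#' @slot atoms data.frame with columns \code{element}, \code{name},
#'   \code{resname}, \code{resid} (integer), \code{chain}, \code{x},
#'   \code{y}, \code{z}.
#' @slot title character(1).
#' @aliases ProteinStructure
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(atoms = "data.frame", title = "character"),
         prototype(atoms = data.frame(), title = ""))

.validProteinStructure <- function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)
  need <- c("element", "name", "resname", "resid", "chain", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("all atom coordinates must be finite")
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    if (any(diff(r) < 0L))
      return(sprintf("residue indices must be non-decreasing within chain '%s'", ch))
  }
  key <- paste(a$chain, a$resid, a$name)
  if (anyDuplicated(key))
    return(sprintf("duplicated atom name within a residue: %s",
                   key[anyDuplicated(key)][1L]))
  tyd <- a$resname == "TYD"
  if (any(tyd)) {
    for (id in unique(a$resid[tyd])) {
      ni <- sum(a$element[tyd & a$resid == id] == "I")
      if (ni != 2L)
        return(sprintf("TYD residue %d must contain exactly two iodines (found %d)",
                       id, ni))
    }
  }
  TRUE
}
setValidity("ProteinStructure", .validProteinStructure)

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame of atom records (see
#'   \code{\linkS4class{ProteinStructure}}).
#' @param title optional title string.
#' @return A \code{ProteinStructure}.
#' @export
proteinStructure <- function(atoms, title = "") {
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, title = as.character(title))
}

#' @describeIn proteinStructure the atom table of a structure.
#' @param x a \code{ProteinStructure}.
#' @export
atoms <- function(x) x@atoms

#' @describeIn proteinStructure number of atoms.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn proteinStructure coordinates as an n x 3 matrix (Angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a structure
#' @param x a \code{ProteinStructure}.
#' @param value n x 3 numeric matrix.
#' @return The updated structure.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nAtoms(x), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  validObject(x)
  x
}

#' Locate one atom by residue index and atom name
#'
#' @param x a \code{ProteinStructure}.
#' @param resid residue index (author numbering).
#' @param name PDB atom name, e.g. \code{"CB"}, \code{"OH"}.
#' @return Integer row index into \code{atoms(x)}.
#' @export
atomIndex <- function(x, resid, name) {
  i <- which(x@atoms$resid == resid & x@atoms$name == name)
  if (length(i) != 1L) {
    avail <- x@atoms$name[x@atoms$resid == resid]
    stop(sprintf("atom %s/%d not found; residue %d has atoms: %s",
                 name, resid, resid,
                 if (length(avail)) paste(avail, collapse = " ") else "<none>"))
  }
  i
}

#' @describeIn atomIndex coordinates of one atom as a 3-vector.
#' @export
atomXYZ <- function(x, resid, name) {
  unlist(x@atoms[atomIndex(x, resid, name), c("x", "y", "z")], use.names = FALSE)
}

#' @describeIn atomIndex 3-letter residue name at an index.
#' @export
residueName <- function(x, resid) {
  r <- unique(x@atoms$resname[x@atoms$resid == resid])
  if (length(r) != 1L) stop(sprintf("residue %d absent or ambiguous", resid))
  r
}

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat(sprintf("ProteinStructure '%s': %d atoms, %d residues\n",
              object@title, nrow(a), length(unique(paste(a$chain, a$resid)))))
  if (nrow(a) > 0L)
    cat(sprintf("  residues %d-%d, chains: %s\n", min(a$resid), max(a$resid),
                paste(unique(a$chain), collapse = " ")))
})

#' ConformerEnsemble: frames of mobile-atom coordinates
#'
#' A conformational ensemble produced by the torsion Metropolis sampler.
#' Frames store coordinates only for the mobile atoms (the flexible tail
#' 371-376 and the donor side chain); the remaining scaffold coordinates
#' are those of the reference structure.
#'
#' @slot structure the reference \code{ProteinStructure}.
#' @slot mobile integer indices (rows of the atom table) of mobile atoms.
#' @slot frames list of m x 3 coordinate matrices, one per frame.
#' @slot condition one of \code{"Y_distal"}, \code{"DIT_distal"},
#'   \code{"DIT_proximal"}.
#' @slot seed integer seed the ensemble was generated with.
#' @slot energies numeric per-frame potential energy, kcal/mol.
#' @slot acceptanceRate fraction of accepted Monte Carlo moves.
#' @aliases ConformerEnsemble
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
         representation(structure = "ProteinStructure", mobile = "integer",
                        frames = "list", condition = "character",
                        seed = "integer", energies = "numeric",
                        acceptanceRate = "numeric"))

.validConformerEnsemble <- function(object) {
  n <- length(object@frames)
  if (n == 0L) return("ensemble must contain at least one frame")
  m <- length(object@mobile)
  ok <- vapply(object@frames, function(f)
    is.matrix(f) && nrow(f) == m && ncol(f) == 3L && all(is.finite(f)), logical(1L))
  if (!all(ok)) return("all frames must be finite m x 3 matrices on one manifest")
  if (length(object@energies) != n) return("one energy per frame required")
  if (!all(is.finite(object@energies))) return("frame energies must be finite")
  if (!object@condition %in% c("Y_distal", "DIT_distal", "DIT_proximal"))
    return("condition must be Y_distal, DIT_distal or DIT_proximal")
  TRUE
}
setValidity("ConformerEnsemble", .validConformerEnsemble)

#' @describeIn ConformerEnsemble-utils number of frames.
#' @export
nFrames <- function(ens) length(ens@frames)

#' Ensemble accessors
#'
#' @param ens a \code{ConformerEnsemble}.
#' @param i frame number.
#' @name ConformerEnsemble-utils
NULL

#' @describeIn ConformerEnsemble-utils condition label.
#' @export
condition <- function(ens) ens@condition

#' @describeIn ConformerEnsemble-utils per-frame energies (kcal/mol).
#' @export
frameEnergies <- function(ens) ens@energies

#' @describeIn ConformerEnsemble-utils full-structure coordinates with
#'   frame \code{i} substituted at the mobile atoms.
#' @export
frameCoords <- function(ens, i) {
  xyz <- coords(ens@structure)
  xyz[ens@mobile, ] <- ens@frames[[i]]
  xyz
}

#' @describeIn ConformerEnsemble-utils the structure of frame \code{i} as a
#'   \code{ProteinStructure}.
#' @export
frameStructure <- function(ens, i) {
  s <- ens@structure
  coords(s) <- frameCoords(ens, i)
  s
}

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d frames, condition %s, seed %d\n",
              length(object@frames), object@condition, object@seed))
  cat(sprintf("  %d mobile atoms; energy range %.2f .. %.2f kcal/mol; acceptance %.2f\n",
              length(object@mobile), min(object@energies), max(object@energies),
              object@acceptanceRate))
})

#' ConservationProfile: per-column statistics of an alignment
#'
#' @slot frequencies residue x column matrix of per-column frequencies over
#'   non-gap symbols (columns sum to 1, or 0 for all-gap columns).
#' @slot consensus character vector, modal non-gap residue per column
#'   (\code{"-"} for all-gap columns).
#' @slot score numeric per-column conservation score in [0, 1]: the modal
#'   frequency (1 iff the column is invariant, 0 for all-gap columns).
#' @slot tie logical per column: TRUE where the modal residue was tied and
#'   the alphabetically first was reported.
#' @aliases ConservationProfile
#' @exportClass ConservationProfile
setClass("ConservationProfile",
         representation(frequencies = "matrix", consensus = "character",
                        score = "numeric", tie = "logical"))

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile: %d columns, mean conservation %.3f\n",
              length(object@score), mean(object@score)))
  cs <- paste(object@consensus, collapse = "")
  if (nchar(cs) > 60) cs <- paste0(substr(cs, 1, 57), "...")
  cat("  consensus: ", cs, "\n", sep = "")
})

#' @describeIn ConservationProfile-utils consensus string.
#' @export
consensusString <- function(profile) paste(profile@consensus, collapse = "")

#' Conservation profile accessors
#' @param profile a \code{ConservationProfile}.
#' @name ConservationProfile-utils
NULL

#' @describeIn ConservationProfile-utils per-column conservation scores.
#' @export
conservationScores <- function(profile) profile@score
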