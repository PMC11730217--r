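## Model construction: graft the engineered hexapeptide acceptor tail onto
## a scaffold C-terminus in an extended conformation, edit tyrosines to
## mono-/di-iodotyrosine, and mutate the residue preceding the acceptor.

#' Build configuration for tail grafting
#'
#' Backbone torsions of the built tail default to the extended beta-sheet
#' configuration (phi = -120, psi = 120 degrees, omega trans); bond lengths
#' and angles are ideal values.  The aryl carbon-iodine bond length used
#' when iodinating tyrosines defaults to 2.10 Angstrom.
#'
#' @param phi,psi,omega backbone dihedrals, degrees in (-180, 180].
#' @param cIBondLength aryl C-I bond length, Angstrom.
#' @param clashCutoff heavy-atom overlap distance treated as a steric
#'   clash, Angstrom.
#' @return A list of class \code{BuildConfig}.
#' @export
buildConfig <- function(phi = -120, psi = 120, omega = 180,
                        cIBondLength = 2.10, clashCutoff = 2.0) {
  stopifnot(all(c(phi, psi, omega) > -180 & c(phi, psi, omega) <= 180),
            cIBondLength > 0, clashCutoff > 0)
  structure(list(phi = phi, psi = psi, omega = omega,
                 cIBondLength = cIBondLength, clashCutoff = clashCutoff,
                 backbone = .BB,
                 units = c(distance = "angstrom", angle = "degrees")),
            class = "BuildConfig")
}

#' Specify a precursor tail variant
#'
#' The engineered acceptor tail is the hexapeptide SGSXYS (author numbering
#' 371-376) where position 374 (X) is the residue preceding the acceptor
#' tyrosine Y375.
#'
#' @param x374 one of \code{"E"}, \code{"D"}, \code{"K"}, \code{"S"}.
#' @return A list of class \code{VariantSpec} with fields \code{x374},
#'   \code{tail} and \code{label}.
#' @export
makeVariant <- function(x374 = c("E", "D", "K", "S")) {
  x374 <- match.arg(x374)
  structure(list(x374 = x374,
                 tail = paste0("SGS", x374, "YS"),
                 label = paste0("MBP-", x374, "374")),
            class = "VariantSpec")
}

## Place the backbone + side chain of one residue appended after the
## residue with backbone coordinates (prevN, prevCA, prevC).  psiPrev is
## the psi torsion assigned to the preceding residue (placing this N).
.appendResidueAtoms <- function(prevN, prevCA, prevC, resname, resid, chain,
                                phi, psiPrev, omega, chis = NULL) {
  bb <- .BB
  N <- nerfPlace(prevN, prevCA, prevC, bb$cN, bb$angCaCN, psiPrev)
  CA <- nerfPlace(prevCA, prevC, N, bb$nCa, bb$angCNCa, omega)
  C <- nerfPlace(prevC, N, CA, bb$caC, bb$angNCaC, phi)
  ## O is placed trans to the *next* N; use the intended psi of this residue
  df <- data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
                   x = c(N[1L], CA[1L], C[1L]), y = c(N[2L], CA[2L], C[2L]),
                   z = c(N[3L], CA[3L], C[3L]))
  sc <- .buildSideChain(resname, N, CA, C, chis)
  df <- rbind(df, sc)
  df$resname <- resname
  df$resid <- resid
  df$chain <- chain
  df[, c("element", "name", "resname", "resid", "chain", "x", "y", "z")]
}

.placeO <- function(resAtoms, psi) {
  N <- unlist(resAtoms[resAtoms$name == "N", c("x", "y", "z")])
  CA <- unlist(resAtoms[resAtoms$name == "CA", c("x", "y", "z")])
  C <- unlist(resAtoms[resAtoms$name == "C", c("x", "y", "z")])
  O <- nerfPlace(N, CA, C, .BB$cO, .BB$angCaCO, wrapAngle(psi + 180))
  o <- resAtoms[resAtoms$name == "C", , drop = FALSE]
  o$name <- "O"; o$element <- "O"
  o$x <- O[1L]; o$y <- O[2L]; o$z <- O[3L]
  ## keep O directly after C
  i <- which(resAtoms$name == "C")
  rbind(resAtoms[seq_len(i), , drop = FALSE], o,
        resAtoms[-seq_len(i), , drop = FALSE])
}

## Minimum heavy-atom distance between two coordinate blocks.
.minHeavyDist <- function(xyzA, elA, xyzB, elB) {
  ha <- elA != "H"; hb <- elB != "H"
  if (!any(ha) || !any(hb)) return(Inf)
  a <- xyzA[ha, , drop = FALSE]; b <- xyzB[hb, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Append the extended acceptor tail to a scaffold
#'
#' Grafts the six-residue tail of \code{variant} onto the C-terminal
#' residue of \code{scaffold}, renumbered 371-376, in the extended
#' configuration of \code{cfg} (phi/psi measured on the built residues
#' reproduce the configured values to numerical precision).  If the built
#' tail clashes sterically with the scaffold the build is retried with
#' alternative omega values before failing.
#'
#' @param scaffold a \code{ProteinStructure} whose C-terminal residue has a
#'   complete backbone (N, CA, C).
#' @param variant a \code{VariantSpec} from \code{\link{makeVariant}}, or
#'   \code{NULL}/empty tail to return the scaffold unchanged.
#' @param cfg a \code{\link{buildConfig}}.
#' @return A \code{ProteinStructure} with residues 371-376 appended.
#' @export
appendExtendedTail <- function(scaffold, variant = makeVariant("E"),
                               cfg = buildConfig()) {
  stopifnot(is(scaffold, "ProteinStructure"))
  if (is.null(variant) || !nzchar(variant$tail)) return(scaffold)
  letters1 <- strsplit(variant$tail, "")[[1L]]
  if (length(letters1) != 6L || letters1[5L] != "Y")
    stop("tail must be the hexapeptide SGSXYS (position 5 = Y)")
  a <- atoms(scaffold)
  lastRes <- a$resid[nrow(a)]
  lastChain <- a$chain[nrow(a)]
  rr <- which(a$resid == lastRes & a$chain == lastChain)
  missing <- setdiff(c("N", "CA", "C"), a$name[rr])
  if (length(missing))
    stop(sprintf("scaffold C-terminal residue %d lacks backbone atoms: %s",
                 lastRes, paste(missing, collapse = " ")))
  getp <- function(rows, nm) unlist(a[rows[a$name[rows] == nm][1L],
                                      c("x", "y", "z")], use.names = FALSE)
  scafXYZ <- as.matrix(a[a$resid != lastRes | a$chain != lastChain,
                         c("x", "y", "z")])
  scafEl <- a$element[a$resid != lastRes | a$chain != lastChain]

  buildTail <- function(omega) {
    prevN <- getp(rr, "N"); prevCA <- getp(rr, "CA"); prevC <- getp(rr, "C")
    tail <- list()
    for (k in seq_along(letters1)) {
      resname <- .ONE_TO_THREE[[letters1[k]]]
      res <- .appendResidueAtoms(prevN, prevCA, prevC, resname, 370L + k,
                                 lastChain, cfg$phi, cfg$psi, omega)
      res <- .placeO(res, cfg$psi)
      tail[[k]] <- res
      prevN <- unlist(res[res$name == "N", c("x", "y", "z")], use.names = FALSE)
      prevCA <- unlist(res[res$name == "CA", c("x", "y", "z")], use.names = FALSE)
      prevC <- unlist(res[res$name == "C", c("x", "y", "z")], use.names = FALSE)
    }
    do.call(rbind, tail)
  }

  for (omega in unique(c(cfg$omega, -150, 150, -120))) {
    tail <- buildTail(omega)
    dmin <- .minHeavyDist(as.matrix(tail[, c("x", "y", "z")]), tail$element,
                          scafXYZ, scafEl)
    if (dmin >= cfg$clashCutoff) {
      out <- proteinStructure(rbind(a, tail), title = scaffold@title)
      attr(out, "variant") <- variant$label
      return(out)
    }
  }
  stop(sprintf("tail build failed: unresolvable steric clash (< %.1f A) with scaffold",
               cfg$clashCutoff))
}

#' Edit a tyrosine to mono- or di-iodotyrosine
#'
#' Replaces the ring Heps1 (and for \code{count = 2} also Heps2) hydrogen by
#' an iodine named I1 (I2) placed along the Ceps-H unit vector at the
#' configured aryl C-I bond length.  The residue is renamed IYR (mono) or
#' TYD (di).  All other atoms are untouched.  Missing ring hydrogens are
#' reconstructed from the ring geometry first.
#'
#' @param x a \code{ProteinStructure}.
#' @param resid residue index of a TYR residue.
#' @param count 1 (mono) or 2 (di).
#' @param cfg a \code{\link{buildConfig}} supplying the C-I bond length.
#' @return The edited \code{ProteinStructure}.
#' @export
iodinateTyrosine <- function(x, resid, count = 2L, cfg = buildConfig()) {
  stopifnot(is(x, "ProteinStructure"), count %in% c(1L, 2L))
  rn <- residueName(x, resid)
  if (rn %in% c("TYD", "IYR"))
    stop(sprintf("residue %d is already iodinated (%s)", resid, rn))
  if (rn != "TYR")
    stop(sprintf("residue %d is %s, not TYR", resid, rn))
  a <- atoms(x)
  rr <- which(a$resid == resid)
  ## reconstruct missing ring hydrogens from ring geometry
  for (he in c("HE1", "HE2")) {
    if (!he %in% a$name[rr]) {
      cd <- if (he == "HE1") "CD1" else "CD2"
      ce <- if (he == "HE1") "CE1" else "CE2"
      p <- nerfPlace(atomXYZ(x, resid, "CG"), atomXYZ(x, resid, cd),
                     atomXYZ(x, resid, ce), 1.08, 119.5, 180)
      newRow <- a[rr[1L], , drop = FALSE]
      newRow$name <- he; newRow$element <- "H"
      newRow$x <- p[1L]; newRow$y <- p[2L]; newRow$z <- p[3L]
      a <- rbind(a[seq_len(max(rr)), , drop = FALSE], newRow,
                 if (max(rr) < nrow(a)) a[(max(rr) + 1L):nrow(a), , drop = FALSE])
      rr <- which(a$resid == resid)
    }
  }
  targets <- if (count == 2L) c(HE1 = "I1", HE2 = "I2") else c(HE1 = "I1")
  for (he in names(targets)) {
    hi <- rr[a$name[rr] == he]
    ce <- rr[a$name[rr] == (if (he == "HE1") "CE1" else "CE2")]
    ceXYZ <- unlist(a[ce, c("x", "y", "z")], use.names = FALSE)
    hXYZ <- unlist(a[hi, c("x", "y", "z")], use.names = FALSE)
    p <- ceXYZ + cfg$cIBondLength * unitv(hXYZ - ceXYZ)
    a$name[hi] <- targets[[he]]
    a$element[hi] <- "I"
    a$x[hi] <- p[1L]; a$y[hi] <- p[2L]; a$z[hi] <- p[3L]
  }
  a$resname[rr] <- if (count == 2L) "TYD" else "IYR"
  proteinStructure(a, title = x@title)
}

#' Mutate a residue's side chain
#'
#' Backbone atoms (N, CA, C, O) are preserved bit-identically; the side
#' chain is rebuilt from ideal geometry in the first clash-free rotamer
#' (chi1 fall-back list, remaining chis at their defaults).  Mutating a
#' residue to itself returns the structure unchanged.
#'
#' @param x a \code{ProteinStructure}.
#' @param resid residue index.
#' @param to 1-letter target code, one of E, D, K, S, F, A, Y.
#' @param clashCutoff heavy-atom clash distance, Angstrom.
#' @return The mutated \code{ProteinStructure}.
#' @export
mutateResidue <- function(x, resid, to, clashCutoff = 2.0) {
  stopifnot(is(x, "ProteinStructure"))
  if (!to %in% names(.ONE_TO_THREE))
    stop(sprintf("unsupported target residue '%s' (use one of %s)", to,
                 paste(names(.ONE_TO_THREE), collapse = " ")))
  target <- .ONE_TO_THREE[[to]]
  current <- residueName(x, resid)
  if (current == target) return(x)
  a <- atoms(x)
  rr <- which(a$resid == resid)
  bbNames <- c("N", "CA", "C", "O")
  missing <- setdiff(c("N", "CA", "C"), a$name[rr])
  if (length(missing))
    stop(sprintf("residue %d lacks backbone atoms: %s", resid,
                 paste(missing, collapse = " ")))
  bbRows <- rr[a$name[rr] %in% bbNames]
  N <- atomXYZ(x, resid, "N"); CA <- atomXYZ(x, resid, "CA")
  C <- atomXYZ(x, resid, "C")
  otherXYZ <- as.matrix(a[-rr, c("x", "y", "z")])
  otherEl <- a$element[-rr]
  chis0 <- .DEFAULT_CHI[[target]]
  candidates <- if (is.null(chis0)) list(NULL) else
    lapply(unique(c(chis0[1L], .CHI1_FALLBACK)), function(c1) {
      ch <- chis0; ch[1L] <- c1; ch })
  for (chis in candidates) {
    sc <- .buildSideChain(target, N, CA, C, chis)
    ok <- nrow(sc) == 0L ||
      .minHeavyDist(as.matrix(sc[, c("x", "y", "z")]), sc$element,
                    otherXYZ, otherEl) >= clashCutoff
    if (ok) {
      if (nrow(sc)) {
        sc$resname <- target
        sc$resid <- a$resid[rr[1L]]
        sc$chain <- a$chain[rr[1L]]
        sc <- sc[, c("element", "name", "resname", "resid", "chain",
                     "x", "y", "z")]
      }
      newRes <- rbind(a[bbRows, , drop = FALSE],
                      if (nrow(sc)) sc)
      newRes$resname <- target
      out <- rbind(if (min(rr) > 1L) a[seq_len(min(rr) - 1L), , drop = FALSE],
                   newRes,
                   if (max(rr) < nrow(a)) a[(max(rr) + 1L):nrow(a), , drop = FALSE])
      return(proteinStructure(out, title = x@title))
    }
  }
  stop(sprintf("no clash-free rotamer found for %d%s", resid, to))
}

#' Measure a dihedral angle in a structure
#'
#' @param x a \code{ProteinStructure}.
#' @param sel list of four \code{c(resid, "NAME")} atom selectors.
#' @return Angle in degrees in (-180, 180], IUPAC sign convention.
#' @export
measureDihedral <- function(x, sel) {
  stopifnot(length(sel) == 4L)
  p <- lapply(sel, function(s) atomXYZ(x, as.integer(s[[1L]]), s[[2L]]))
  if (length(unique(vapply(p, paste, character(1L), collapse = ","))) != 4L)
    stop("the four selected atoms must be distinct")
  dihedralAngle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
}

#' @describeIn measureDihedral backbone phi of residue \code{resid}
#'   (requires the preceding residue in chain order).
#' @param resid residue index.
#' @export
measurePhi <- function(x, resid) {
  prev <- .precedingResidue(x, resid)
  measureDihedral(x, list(c(prev, "C"), c(resid, "N"), c(resid, "CA"),
                          c(resid, "C")))
}

#' @describeIn measureDihedral backbone psi of residue \code{resid}
#'   (requires the following residue in chain order).
#' @export
measurePsi <- function(x, resid) {
  nxt <- .followingResidue(x, resid)
  measureDihedral(x, list(c(resid, "N"), c(resid, "CA"), c(resid, "C"),
                          c(nxt, "N")))
}

.precedingResidue <- function(x, resid) {
  a <- atoms(x)
  ch <- a$chain[match(resid, a$resid)]
  resids <- unique(a$resid[a$chain == ch])
  i <- match(resid, resids)
  if (is.na(i) || i == 1L) stop(sprintf("residue %d has no predecessor", resid))
  resids[i - 1L]
}

.followingResidue <- function(x, resid) {
  a <- atoms(x)
  ch <- a$chain[match(resid, a$resid)]
  resids <- unique(a$resid[a$chain == ch])
  i <- match(resid, resids)
  if (is.na(i) || i == length(resids))
    stop(sprintf("residue %d has no successor", resid))
  resids[i + 1L]
}
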