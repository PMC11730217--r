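## Internal-coordinate residue templates used by the chain builder and the
## mutation/iodination editors.  Geometry is ideal (Engh-Huber-like bond
## lengths and angles); side-chain atoms are defined as NeRF entries
## (reference atom triple, bond length, bond angle, dihedral).  Dihedrals
## are either fixed numbers or symbolic chi references ("chi1" .. "chi4",
## optionally with an offset).  Hydrogens are omitted except the tyrosine
## ring Heps1/Heps2, which anchor iodination.

.BB <- list(
  nCa = 1.458, caC = 1.525, cN = 1.329, cO = 1.231,
  angCaCN = 116.2, angCNCa = 121.7, angNCaC = 111.2, angCaCO = 120.8,
  ## L-configuration CB placement: refs (N, C, CA), improper N-C-CA-CB
  cbBond = 1.530, cbAngle = 110.1, cbImproper = 122.6)

.scEntry <- function(name, element, refs, bond, angle, dih, chi = NA_integer_,
                     offset = 0) {
  list(name = name, element = element, refs = refs, bond = bond,
       angle = angle, dih = dih, chi = chi, offset = offset)
}

## Per-residue side-chain definitions beyond CB.  refs are atom names within
## the residue (backbone N/CA/C allowed).
.SIDECHAINS <- list(
  GLY = list(),
  ALA = list(),
  SER = list(
    .scEntry("OG", "O", c("N", "CA", "CB"), 1.417, 110.8, NA, chi = 1L)),
  GLU = list(
    .scEntry("CG",  "C", c("N", "CA", "CB"),  1.520, 114.1, NA, chi = 1L),
    .scEntry("CD",  "C", c("CA", "CB", "CG"), 1.516, 112.6, NA, chi = 2L),
    .scEntry("OE1", "O", c("CB", "CG", "CD"), 1.249, 118.4, NA, chi = 3L),
    .scEntry("OE2", "O", c("CB", "CG", "CD"), 1.249, 118.4, NA, chi = 3L,
             offset = 180)),
  ASP = list(
    .scEntry("CG",  "C", c("N", "CA", "CB"),  1.516, 112.6, NA, chi = 1L),
    .scEntry("OD1", "O", c("CA", "CB", "CG"), 1.249, 118.4, NA, chi = 2L),
    .scEntry("OD2", "O", c("CA", "CB", "CG"), 1.249, 118.4, NA, chi = 2L,
             offset = 180)),
  LYS = list(
    .scEntry("CG", "C", c("N", "CA", "CB"),  1.520, 114.1, NA, chi = 1L),
    .scEntry("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, NA, chi = 2L),
    .scEntry("CE", "C", c("CB", "CG", "CD"), 1.520, 111.3, NA, chi = 3L),
    .scEntry("NZ", "N", c("CG", "CD", "CE"), 1.489, 111.9, NA, chi = 4L)),
  TYR = list(
    .scEntry("CG",  "C", c("N", "CA", "CB"),   1.512, 113.9, NA, chi = 1L),
    .scEntry("CD1", "C", c("CA", "CB", "CG"),  1.389, 120.98, NA, chi = 2L),
    .scEntry("CD2", "C", c("CA", "CB", "CG"),  1.389, 120.98, NA, chi = 2L,
             offset = 180),
    .scEntry("CE1", "C", c("CB", "CG", "CD1"), 1.389, 121.0, 180),
    .scEntry("CE2", "C", c("CB", "CG", "CD2"), 1.389, 121.0, 180),
    .scEntry("CZ",  "C", c("CG", "CD1", "CE1"), 1.381, 119.8, 0),
    .scEntry("OH",  "O", c("CD1", "CE1", "CZ"), 1.376, 119.9, 180),
    .scEntry("HE1", "H", c("CG", "CD1", "CE1"), 1.08, 119.5, 180),
    .scEntry("HE2", "H", c("CG", "CD2", "CE2"), 1.08, 119.5, 180))
)
.SIDECHAINS$PHE <- .SIDECHAINS$TYR[
  vapply(.SIDECHAINS$TYR, function(e) e$name != "OH", logical(1L))]
## iodinated tyrosines share the tyrosine skeleton; iodines are created by
## iodinateTyrosine(), never built de novo, but the templates are needed for
## bond derivation and torsion axes.
.SIDECHAINS$TYD <- .SIDECHAINS$TYR
.SIDECHAINS$IYR <- .SIDECHAINS$TYR

## Ring-closure bonds not implied by the NeRF parent relation.
.EXTRA_BONDS <- list(
  TYR = rbind(c("CZ", "CE2")),
  PHE = rbind(c("CZ", "CE2")),
  TYD = rbind(c("CZ", "CE2"), c("I1", "CE1"), c("I2", "CE2")),
  IYR = rbind(c("CZ", "CE2"), c("I1", "CE1")))

.N_CHI <- c(GLY = 0L, ALA = 0L, SER = 1L, ASP = 2L, GLU = 3L, LYS = 4L,
            TYR = 2L, PHE = 2L, TYD = 2L, IYR = 2L)

## Starting rotamer and fall-back list (chi1 alternatives; later chis keep
## their defaults).
.DEFAULT_CHI <- list(
  SER = -65, ASP = c(-65, -20), GLU = c(-65, 180, -20),
  LYS = c(-65, 180, 180, 180), TYR = c(-65, 90), PHE = c(-65, 90),
  TYD = c(-65, 90), IYR = c(-65, 90))
.CHI1_FALLBACK <- c(-65, 180, 65, -90, 90, 120)

.THREE_TO_ONE <- c(GLY = "G", ALA = "A", SER = "S", ASP = "D", GLU = "E",
                   LYS = "K", TYR = "Y", PHE = "F", TYD = "Y", IYR = "Y")
.ONE_TO_THREE <- setNames(names(.THREE_TO_ONE)[1:8], .THREE_TO_ONE[1:8])

.knownResidue <- function(resname) resname %in% names(.SIDECHAINS)

## Build the side-chain atoms of one residue given backbone coordinates.
## Returns a data.frame (name, element, x, y, z); empty for GLY.
.buildSideChain <- function(resname, xyzN, xyzCA, xyzC, chis = NULL) {
  if (!.knownResidue(resname))
    stop(sprintf("no template for residue '%s'", resname))
  entries <- .SIDECHAINS[[resname]]
  pos <- list(N = xyzN, CA = xyzCA, C = xyzC)
  out <- list()
  if (resname != "GLY") {
    pos$CB <- nerfPlace(xyzN, xyzC, xyzCA, .BB$cbBond, .BB$cbAngle,
                        .BB$cbImproper)
    out[[1L]] <- data.frame(name = "CB", element = "C",
                            x = pos$CB[1L], y = pos$CB[2L], z = pos$CB[3L])
  }
  if (is.null(chis)) chis <- .DEFAULT_CHI[[resname]]
  for (e in entries) {
    dih <- if (is.na(e$chi)) e$dih else chis[e$chi] + e$offset
    p <- nerfPlace(pos[[e$refs[1L]]], pos[[e$refs[2L]]], pos[[e$refs[3L]]],
                   e$bond, e$angle, dih)
    pos[[e$name]] <- p
    out[[length(out) + 1L]] <- data.frame(name = e$name, element = e$element,
                                          x = p[1L], y = p[2L], z = p[3L])
  }
  if (length(out) == 0L)
    data.frame(name = character(), element = character(),
               x = numeric(), y = numeric(), z = numeric())
  else do.call(rbind, out)
}

## Intra-residue bonds as a 2-column matrix of atom names.
.residueBonds <- function(resname) {
  b <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (!.knownResidue(resname)) return(b)
  if (resname != "GLY") b <- rbind(b, c("CA", "CB"))
  for (e in .SIDECHAINS[[resname]])
    b <- rbind(b, c(e$refs[3L], e$name))
  if (!is.null(.EXTRA_BONDS[[resname]]))
    b <- rbind(b, .EXTRA_BONDS[[resname]])
  b
}

## Covalent bond list of a whole structure as a 2-column matrix of row
## indices into the atom table.  Consecutive residues within a chain are
## peptide-bonded in table order (author numbering may contain gaps).
deriveBonds <- function(x) {
  a <- atoms(x)
  idx <- function(resRows, nm) resRows[match(nm, a$name[resRows])]
  bonds <- list()
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    resids <- unique(a$resid[rows])
    prevC <- NA_integer_
    for (r in resids) {
      rr <- rows[a$resid[rows] == r]
      tmpl <- .residueBonds(a$resname[rr[1L]])
      i <- idx(rr, tmpl[, 1L])
      j <- idx(rr, tmpl[, 2L])
      keep <- !is.na(i) & !is.na(j)
      if (any(keep)) bonds[[length(bonds) + 1L]] <- cbind(i[keep], j[keep])
      ni <- idx(rr, "N")
      if (!is.na(prevC) && !is.na(ni))
        bonds[[length(bonds) + 1L]] <- cbind(prevC, ni)
      prevC <- idx(rr, "C")
    }
  }
  if (length(bonds) == 0L) return(matrix(integer(), ncol = 2L))
  do.call(rbind, bonds)
}

## Adjacency list from a bond matrix.
.adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

## Atoms on the far side of the bond a-b (connected to b with the edge
## removed); used to define torsion moving sets.
.downstreamAtoms <- function(adj, a, b) {
  seen <- rep(FALSE, length(adj))
  seen[a] <- TRUE
  queue <- b
  seen[b] <- TRUE
  out <- integer()
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    nb <- adj[[v]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  setdiff(out, b)
}
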