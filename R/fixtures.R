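## Synthetic fixture generators.  Everything the pipeline consumes can be
## produced here deterministically: the mini scaffold carrying the donor
## tyrosine, idealized ring pairs of known stacking geometry, a
## thyroglobulin-like alignment with planted acceptor motifs, and species
## free-energy tables encoding the qualitative orderings of the coupling
## thermodynamics.  Energy magnitudes are synthetic throughout and are
## tagged as such.

## Build a fresh chain from per-residue (resname, phi, psi) specs.
.buildChain <- function(resnames, resids, phis, psis, chain = "A",
                        clashCutoff = 2.0) {
  n <- length(resnames)
  stopifnot(length(resids) == n, length(phis) == n, length(psis) == n)
  bb <- .BB
  ## first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(bb$nCa, 0, 0)
  th <- deg2rad(bb$angNCaC)
  C <- CA + bb$caC * c(-cos(th), sin(th), 0)
  placed <- list()
  sideChainWithFallback <- function(resname, N, CA, C, priorXYZ, priorEl) {
    chis0 <- .DEFAULT_CHI[[resname]]
    cands <- if (is.null(chis0)) list(NULL) else
      lapply(unique(c(chis0[1L], .CHI1_FALLBACK)), function(c1) {
        ch <- chis0; ch[1L] <- c1; ch })
    for (chis in cands) {
      sc <- .buildSideChain(resname, N, CA, C, chis)
      if (nrow(sc) == 0L || is.null(priorXYZ) ||
          .minHeavyDist(as.matrix(sc[, c("x", "y", "z")]), sc$element,
                        priorXYZ, priorEl) >= clashCutoff)
        return(sc)
    }
    stop(sprintf("no clash-free rotamer for built %s", resname))
  }
  firstRes <- data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
                         x = c(N[1L], CA[1L], C[1L]),
                         y = c(N[2L], CA[2L], C[2L]),
                         z = c(N[3L], CA[3L], C[3L]))
  firstRes <- rbind(firstRes, sideChainWithFallback(resnames[1L], N, CA, C,
                                                    NULL, NULL))
  firstRes$resname <- resnames[1L]
  firstRes$resid <- resids[1L]
  firstRes$chain <- chain
  firstRes <- firstRes[, c("element", "name", "resname", "resid", "chain",
                           "x", "y", "z")]
  placed[[1L]] <- .placeO(firstRes, psis[1L])
  prevN <- N; prevCA <- CA; prevC <- C
  for (k in 2L:n) {
    prior <- do.call(rbind, placed)
    res <- .appendResidueAtoms(prevN, prevCA, prevC, "GLY", resids[k], chain,
                               phis[k], psis[k - 1L], 180)
    ## backbone placed as GLY; now add the real side chain with fall-back
    res$resname <- resnames[k]
    Nk <- unlist(res[res$name == "N", c("x", "y", "z")], use.names = FALSE)
    CAk <- unlist(res[res$name == "CA", c("x", "y", "z")], use.names = FALSE)
    Ck <- unlist(res[res$name == "C", c("x", "y", "z")], use.names = FALSE)
    sc <- sideChainWithFallback(resnames[k], Nk, CAk, Ck,
                                as.matrix(prior[, c("x", "y", "z")]),
                                prior$element)
    if (nrow(sc)) {
      sc$resname <- resnames[k]
      sc$resid <- resids[k]
      sc$chain <- chain
      sc <- sc[, c("element", "name", "resname", "resid", "chain",
                   "x", "y", "z")]
      res <- rbind(res, sc)
    }
    placed[[k]] <- .placeO(res, psis[k])
    prevN <- Nk; prevCA <- CAk; prevC <- Ck
  }
  proteinStructure(do.call(rbind, placed))
}

#' Synthetic mini scaffold with an exposed donor tyrosine
#'
#' An idealized 25-residue alpha helix (phi = -57, psi = -47) whose
#' C-terminal residue is a solvent-exposed tyrosine numbered 341 (the
#' donor), followed by a short extended glycine linker, leaving the
#' C-terminus ready for grafting of the acceptor tail (which
#' \code{\link{appendExtendedTail}} numbers 371-376).  Deterministic; no
#' external data required.
#'
#' @return A \code{ProteinStructure}.
#' @export
makeScaffold <- function() {
  helixN <- 25L
  resnames <- c(rep("ALA", helixN - 1L), "TYR", rep("GLY", 3L))
  resids <- c(seq_len(helixN) + (341L - helixN), 342L, 343L, 344L)
  phis <- c(rep(-57, helixN), rep(-120, 3L))
  psis <- c(rep(-47, helixN), rep(120, 3L))
  s <- .buildChain(resnames, resids, phis, psis)
  s@title <- "synthetic mini-scaffold (donor Y341)"
  s
}

#' Idealized aromatic ring pair of known stacking geometry
#'
#' Two regular six-carbon rings (radius 1.39 Angstrom).  For
#' \code{"parallel-offset"} the second ring is rotated about an in-plane
#' axis by \code{angle} degrees and displaced along the first ring's normal
#' by \code{separation}; \code{"t-shaped"} is the same construction with
#' the rotation fixed at 90 degrees.  \code{\link{classifyStacking}} on the
#' result recovers the requested centroid separation and interplanar angle
#' to numerical precision.
#'
#' @param separation centroid-centroid distance, Angstrom (> 0).
#' @param angle interplanar angle, degrees in [0, 90].
#' @param geometry \code{"parallel-offset"} or \code{"t-shaped"}.
#' @return A \code{ProteinStructure} with two RNG residues (atoms C1-C6).
#' @export
makeRingPair <- function(separation, angle = 0,
                         geometry = c("parallel-offset", "t-shaped")) {
  geometry <- match.arg(geometry)
  stopifnot(separation > 0)
  if (angle < 0 || angle > 90)
    stop("interplanar angle must be in [0, 90] degrees")
  if (geometry == "t-shaped") angle <- 90
  hex <- function() {
    th <- deg2rad(seq(0, 300, by = 60))
    cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  }
  a1 <- hex()
  a2 <- rotateAboutAxis(hex(), c(0, 0, 0), c(1, 0, 0), angle)
  a2 <- sweep(a2, 2L, c(0, 0, separation), `+`)
  df <- function(xyz, resid) data.frame(
    element = "C", name = paste0("C", 1:6), resname = "RNG",
    resid = resid, chain = "A", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  proteinStructure(rbind(df(a1, 1L), df(a2, 2L)),
                   title = sprintf("ring pair %s sep=%.2f angle=%.1f",
                                   geometry, separation, angle))
}

#' Synthetic thyroglobulin-like alignment with planted acceptor motifs
#'
#' Emulates an alignment of vertebrate thyroglobulin-like sequences:
#' uniform random background over the 20 standard residues with acceptor
#' tyrosine columns planted at \code{motifCols}, each preceded by an acidic
#' column of the stated type (E or D) at the stated per-site conservation
#' level (fraction of sequences carrying the planted residue; the
#' remainder are random).  Defaults mirror an alignment of 15 vertebrate
#' sequences of about 2700 columns with acceptor sites near human
#' thyroglobulin positions 24 (E-type), 1310 and 2573 (D-type).
#'
#' @param nSeqs number of sequences (>= 2).
#' @param nCols alignment length.
#' @param motifCols acceptor (tyrosine) column indices (each >= 2).
#' @param motifTypes per-site preceding-residue type, \code{"E"} or
#'   \code{"D"}.
#' @param conservation per-site conservation fraction in (0, 1].
#' @param seed integer seed; the alignment is reproducible bit-exactly.
#' @return An \code{AAStringSet} of aligned sequences.
#' @export
makeTgLikeAlignment <- function(nSeqs = 15L, nCols = 2700L,
                                motifCols = c(24L, 1310L, 2573L),
                                motifTypes = c("E", "D", "D"),
                                conservation = c(1, 0.85, 0.85),
                                seed = 1L) {
  stopifnot(nSeqs >= 2L, length(motifTypes) == length(motifCols),
            length(conservation) == length(motifCols),
            all(motifTypes %in% c("E", "D")),
            all(conservation > 0 & conservation <= 1))
  if (any(motifCols < 2L))
    stop("motif column 1 has no predecessor column; use columns >= 2")
  if (any(motifCols > nCols))
    stop("motif columns must lie within the alignment")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  set.seed(seed)
  m <- matrix(sample(aa, nSeqs * nCols, replace = TRUE), nrow = nSeqs)
  for (k in seq_along(motifCols)) {
    keep <- runif(nSeqs) <= conservation[k]
    m[keep, motifCols[k]] <- "Y"
    m[keep, motifCols[k] - 1L] <- motifTypes[k]
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("synthetic_tg_%02d", seq_len(nSeqs))
  Biostrings::AAStringSet(seqs)
}

#' Synthetic species free-energy tables for the coupling ledger
#'
#' Generates self-consistent species tables whose ledger evaluation
#' reproduces a stated qualitative scenario.  All magnitudes are synthetic
#' (kcal/mol) and encode only orderings and signs; they are not
#' quantum-chemistry values.
#'
#' Scenarios: \code{"radical-vs-anionic"} (the sequential coupling step is
#' markedly more favourable on the radical pathway than on the anionic
#' one), \code{"exergonic-concerted"} (the concerted coupling to T4 plus
#' dehydroalanine is exergonic for all four tail variants), and
#' \code{"variant-ranking"} (concerted coupling free energies order the
#' variants E < D < K < S, most favourable first).
#'
#' @param scenario one of the scenario names above.
#' @return A data.frame with columns \code{species}, \code{energy},
#'   \code{charge}, \code{spin} and attribute \code{provenance =
#'   "synthetic"}.
#' @seealso \code{\link{couplingLedger}} for the matching reaction ledger.
#' @export
makeEnergyTable <- function(scenario = c("radical-vs-anionic",
                                         "exergonic-concerted",
                                         "variant-ranking")) {
  scenario <- match.arg(scenario)
  tab <- switch(scenario,
    "radical-vs-anionic" = data.frame(
      species = c("dit-pair-radical", "alpha-intermediate-radical",
                  "dit-pair-anionic", "alpha-intermediate-anionic"),
      energy = c(0, -3.0, 0, 12.0),
      charge = c(0L, 0L, -1L, -1L),
      spin = c("diradical", "radical", "closed-shell", "closed-shell")),
    "exergonic-concerted" = {
      v <- c("E", "D", "K", "S")
      data.frame(
        species = c(paste0("reactant-pair-", v), paste0("t4-dha-", v)),
        energy = c(rep(0, 4L), c(-9.5, -8.5, -8.0, -7.0)),
        charge = 0L,
        spin = c(rep("diradical", 4L), rep("closed-shell", 4L)))
    },
    "variant-ranking" = {
      v <- c("E", "D", "K", "S")
      data.frame(
        species = c(paste0("reactant-pair-", v), paste0("t4-dha-", v)),
        energy = c(rep(0, 4L), c(-12.0, -10.5, -9.0, -7.5)),
        charge = 0L,
        spin = c(rep("diradical", 4L), rep("closed-shell", 4L)))
    })
  attr(tab, "provenance") <- "synthetic"
  tab
}

#' Write a species free-energy table to TSV
#'
#' @param tab a species table (see \code{\link{readSpeciesEnergies}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSpeciesEnergies <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# synthetic species free energies (kcal/mol);",
               "# magnitudes encode qualitative orderings only"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reaction ledger matching a synthetic scenario table
#'
#' @param scenario as in \code{\link{makeEnergyTable}}.
#' @return A ledger (see \code{\link{makeLedger}}) whose pathways evaluate
#'   against the matching \code{makeEnergyTable} output.
#' @export
couplingLedger <- function(scenario = c("radical-vs-anionic",
                                        "exergonic-concerted",
                                        "variant-ranking")) {
  scenario <- match.arg(scenario)
  stage <- function(from, to) data.frame(species = c(from, to),
                                         coef = c(-1, 1))
  if (scenario == "radical-vs-anionic") {
    makeLedger(list(
      "sequential-radical" = list(stage("dit-pair-radical",
                                        "alpha-intermediate-radical")),
      "sequential-anionic" = list(stage("dit-pair-anionic",
                                        "alpha-intermediate-anionic"))))
  } else {
    v <- c("E", "D", "K", "S")
    pathways <- lapply(v, function(x)
      list(stage(paste0("reactant-pair-", x), paste0("t4-dha-", x))))
    names(pathways) <- paste0("concerted-", v)
    makeLedger(pathways)
  }
}
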