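## Torsion-space Metropolis Monte Carlo sampler with a simple
## implicit-solvent energy.  This is the package's stand-in for the
## molecular-dynamics stage: it samples the same degrees of freedom whose
## distributional statistics the analysis consumes (backbone and
## side-chain torsions of the flexible acceptor tail 371-376 plus the
## donor-tyrosine chi1/chi2), with the scaffold frozen.

#' Sampler configuration
#'
#' @param temperature Kelvin.
#' @param nSteps number of Monte Carlo steps.
#' @param burnIn steps discarded before recording (default 10\% of
#'   \code{nSteps}).
#' @param stride record one frame every \code{stride} steps after burn-in.
#' @param seed integer RNG seed; a fixed seed gives a bit-identical
#'   ensemble.
#' @param moveWidth named numeric: maximum torsion perturbation (degrees,
#'   uniform in +/- width) per torsion class.
#' @param jumpProb probability that a move proposes a full-range torsion
#'   jump (uniform in +/- 180 degrees) instead of a local perturbation;
#'   the mixture keeps the proposal symmetric while letting the chain hop
#'   between the extended and contact basins.
#' @param regrowProb probability that a move re-randomizes every mobile
#'   torsion at once (each by an independent uniform full-range jump,
#'   applied in chain order); a symmetric compound proposal that
#'   decorrelates the tail conformation wholesale.
#' @param dielectricFactor distance-dependent dielectric
#'   \eqn{\epsilon(r) = k r}; default k = 4 (cheap aqueous screening).
#' @param ljScale,chargeScale multipliers on the Lennard-Jones and Coulomb
#'   terms (set to 0 to switch a term off).
#' @param stackingWell attractive Gaussian well between the donor and
#'   acceptor aromatic ring centroids, a coarse mean-force stand-in for
#'   the aromatic contact preference: \code{depth} kcal/mol (0 disables),
#'   \code{r0} Angstrom (centred at the pi-contact distance) and
#'   \code{width} Angstrom.
#' @return A list of class \code{SamplerConfig}.
#' @export
samplerConfig <- function(temperature = 300, nSteps = 5000L, burnIn = NULL,
                          stride = 10L, seed = 1L,
                          moveWidth = c(backbone = 25, sidechain = 60),
                          jumpProb = 0.2, regrowProb = 0.05,
                          dielectricFactor = 4,
                          ljScale = 1, chargeScale = 1,
                          stackingWell = list(depth = 4.0, r0 = 3.6,
                                              width = 3.0)) {
  if (is.null(burnIn)) burnIn <- as.integer(nSteps %/% 10L)
  stopifnot(temperature > 0, nSteps > burnIn, burnIn >= 0, stride >= 1L)
  if (length(moveWidth) == 1L && is.null(names(moveWidth)))
    moveWidth <- c(backbone = unname(moveWidth), sidechain = unname(moveWidth))
  stopifnot(jumpProb >= 0, jumpProb <= 1, regrowProb >= 0, regrowProb <= 1)
  structure(list(temperature = temperature, nSteps = as.integer(nSteps),
                 burnIn = as.integer(burnIn), stride = as.integer(stride),
                 seed = as.integer(seed), moveWidth = moveWidth,
                 jumpProb = jumpProb, regrowProb = regrowProb,
                 dielectricFactor = dielectricFactor, ljScale = ljScale,
                 chargeScale = chargeScale, stackingWell = stackingWell,
                 units = c(distance = "angstrom", energy = "kcal/mol",
                           temperature = "K")),
            class = "SamplerConfig")
}

## Lennard-Jones parameters by element (sigma A, epsilon kcal/mol); crude
## but adequate for a sterics-plus-screened-electrostatics stand-in.
.LJ_TABLE <- data.frame(
  element = c("C", "N", "O", "H", "I", "S"),
  sigma = c(3.40, 3.25, 2.96, 2.45, 3.98, 3.56),
  eps = c(0.086, 0.170, 0.210, 0.015, 0.400, 0.250))

## Smeared partial charges (units e) for the few polar groups that matter
## for the acid-tyrosine proximity statistics; all other atoms neutral.
.assignCharges <- function(a) {
  q <- numeric(nrow(a))
  q[a$name == "N"] <- -0.40
  q[a$name == "CA"] <- 0.40
  q[a$name == "C"] <- 0.50
  q[a$name == "O"] <- -0.50
  q[a$resname == "GLU" & a$name %in% c("OE1", "OE2")] <- -0.60
  q[a$resname == "GLU" & a$name == "CD"] <- 0.20
  q[a$resname == "ASP" & a$name %in% c("OD1", "OD2")] <- -0.60
  q[a$resname == "ASP" & a$name == "CG"] <- 0.20
  q[a$resname == "LYS" & a$name == "NZ"] <- 1.00
  tyr <- a$resname %in% c("TYR", "TYD", "IYR")
  q[tyr & a$name == "OH"] <- -0.30
  q[tyr & a$name == "CZ"] <- 0.30
  q[a$name %in% c("I1", "I2")] <- -0.05
  q[a$resname %in% c("TYD", "IYR") & a$name %in% c("CE1", "CE2")] <- 0.05
  q
}

.ringAtomNames <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

.ringIndices <- function(x, resid) {
  a <- atoms(x)
  i <- which(a$resid == resid & a$name %in% .ringAtomNames)
  if (length(i) == 6L) i else NULL
}

## Precompute the nonbonded pair model.  `mobile = NULL` means all pairs;
## otherwise only pairs involving at least one mobile atom.  Pairs at bond
## graph separation 1 or 2 are excluded; 1-4 pairs and beyond are counted
## in full.
.buildEnergyModel <- function(x, cfg, mobile = NULL) {
  a <- atoms(x)
  n <- nrow(a)
  bonds <- deriveBonds(x)
  adj <- .adjacency(bonds, n)
  excl <- new.env(hash = TRUE, size = 4L * n)
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    n2 <- unique(unlist(adj[n1]))
    for (j in unique(c(n1, n2))) if (j != i)
      assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  pp <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pp[, 1L]; j <- pp[, 2L]
  if (!is.null(mobile)) {
    keep <- (i %in% mobile) | (j %in% mobile)
    i <- i[keep]; j <- j[keep]
  }
  keys <- paste(i, j)
  keep <- !vapply(keys, exists, logical(1L), envir = excl, inherits = FALSE)
  i <- i[keep]; j <- j[keep]
  li <- match(a$element, .LJ_TABLE$element)
  if (anyNA(li))
    stop(sprintf("no Lennard-Jones parameters for element(s): %s",
                 paste(unique(a$element[is.na(li)]), collapse = " ")))
  sig <- .LJ_TABLE$sigma[li]
  eps <- .LJ_TABLE$eps[li]
  q <- .assignCharges(a)
  rings <- NULL
  sw <- cfg$stackingWell
  if (!is.null(sw) && sw$depth > 0) {
    rA <- .ringIndices(x, 341L)
    rB <- .ringIndices(x, 375L)
    if (!is.null(rA) && !is.null(rB)) rings <- list(a = rA, b = rB)
  }
  eps4 <- 4 * sqrt(eps[i] * eps[j]) * cfg$ljScale
  cq <- .COULOMB_KCAL * q[i] * q[j] * cfg$chargeScale / cfg$dielectricFactor
  list(i = i, j = j,
       sig2 = ((sig[i] + sig[j]) / 2)^2,
       eps4 = eps4, cq = cq,
       ## a fully switched-off potential (no LJ, no charges, no well) is a
       ## constant zero: skip the pair sweep entirely
       zero = all(eps4 == 0) && all(cq == 0) && is.null(rings),
       rings = rings, stackingWell = sw)
}

.evalEnergy <- function(m, xyz) {
  if (isTRUE(m$zero)) return(0)
  dx <- xyz[m$i, 1L] - xyz[m$j, 1L]
  dy <- xyz[m$i, 2L] - xyz[m$j, 2L]
  dz <- xyz[m$i, 3L] - xyz[m$j, 3L]
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < 1e-12)) return(Inf)
  s6 <- (m$sig2 / r2)^3
  e <- sum(m$eps4 * (s6 * s6 - s6)) + sum(m$cq / r2)
  if (!is.null(m$rings)) {
    d <- sqrt(sum((colMeans(xyz[m$rings$a, , drop = FALSE]) -
                   colMeans(xyz[m$rings$b, , drop = FALSE]))^2))
    sw <- m$stackingWell
    e <- e - sw$depth * exp(-(d - sw$r0)^2 / (2 * sw$width^2))
  }
  e
}

#' Nonbonded potential energy of a structure
#'
#' Pairwise Lennard-Jones plus Coulomb with a distance-dependent
#' dielectric over all nonbonded pairs (bond-graph separation of three
#' bonds or more), plus the optional ring-stacking well when both the
#' donor (341) and acceptor (375) aromatic rings are present.
#' Deterministic; overlapping atoms give \code{Inf}, not an error.
#'
#' @param x a \code{ProteinStructure}.
#' @param xyz optional replacement coordinate matrix.
#' @param cfg a \code{\link{samplerConfig}}.
#' @return Energy in kcal/mol.
#' @export
nonbondedEnergy <- function(x, xyz = NULL, cfg = samplerConfig()) {
  m <- .buildEnergyModel(x, cfg)
  .evalEnergy(m, if (is.null(xyz)) coords(x) else xyz)
}

## Torsion definitions for the mobile degrees of freedom.
.CHI_AXES <- list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"))

.torsionList <- function(x, adj) {
  a <- atoms(x)
  tryIdx <- function(resid, nm) {
    i <- which(a$resid == resid & a$name == nm)
    if (length(i) == 1L) i else NA_integer_
  }
  tors <- list()
  addTorsion <- function(name, class, ai, bi) {
    if (is.na(ai) || is.na(bi)) return()
    moving <- .downstreamAtoms(adj, ai, bi)
    if (length(moving) == 0L) return()
    tors[[length(tors) + 1L]] <<- list(name = name, class = class,
                                       a = ai, b = bi, moving = moving)
  }
  addChis <- function(resid, nChi, upto = nChi) {
    rn <- a$resname[match(resid, a$resid)]
    if (rn == "SER") axes <- list(c("CA", "CB"))
    else axes <- .CHI_AXES
    for (k in seq_len(min(nChi, upto)))
      addTorsion(sprintf("chi%d_%d", k, resid), "sidechain",
                 tryIdx(resid, axes[[k]][1L]), tryIdx(resid, axes[[k]][2L]))
  }
  for (resid in intersect(371:376, unique(a$resid))) {
    addTorsion(sprintf("phi_%d", resid), "backbone",
               tryIdx(resid, "N"), tryIdx(resid, "CA"))
    addTorsion(sprintf("psi_%d", resid), "backbone",
               tryIdx(resid, "CA"), tryIdx(resid, "C"))
    rn <- a$resname[match(resid, a$resid)]
    if (rn %in% names(.N_CHI)) addChis(resid, .N_CHI[[rn]])
  }
  if (341L %in% a$resid) addChis(341L, 2L)  # donor chi1/chi2 only
  tors
}

#' Sample a conformational ensemble of the engineered site
#'
#' Metropolis Monte Carlo over the torsions of the acceptor tail (371-376,
#' phi/psi and side-chain chis) and the donor side chain (chi1/chi2 of
#' 341), with the scaffold frozen.  One torsion is perturbed per step by a
#' symmetric uniform move; acceptance follows \eqn{\exp(-\Delta E / k T)}.
#' Frames are recorded every \code{stride} steps after burn-in.
#'
#' Conditions: \code{"Y_distal"} (no iodines, started from the built
#' extended conformation), \code{"DIT_distal"} (both tyrosines
#' di-iodinated, started extended) and \code{"DIT_proximal"} (di-iodinated
#' at the most probable proximal conformation of a prior non-iodinated
#' ensemble; orchestrate via \code{\link{selectProximalFrame}} and
#' \code{\link{iodinateTyrosine}}, or pass \code{start}).
#'
#' @param x the precursor model (a \code{ProteinStructure} containing the
#'   tail 371-376 and the donor 341).
#' @param condition one of \code{"Y_distal"}, \code{"DIT_distal"},
#'   \code{"DIT_proximal"}.
#' @param cfg a \code{\link{samplerConfig}}.
#' @param start optional starting coordinate matrix (defaults to the
#'   model's own coordinates).
#' @return A \code{\linkS4class{ConformerEnsemble}}.
#' @export
sampleEnsemble <- function(x, condition = c("Y_distal", "DIT_distal",
                                            "DIT_proximal"),
                           cfg = samplerConfig(), start = NULL) {
  condition <- match.arg(condition)
  stopifnot(is(x, "ProteinStructure"))
  a <- atoms(x)
  if (!all(c(371:376, 341L) %in% a$resid))
    stop("model must contain the tail residues 371-376 and the donor 341")
  donorRes <- residueName(x, 341L)
  acceptorRes <- residueName(x, 375L)
  if (condition == "Y_distal") {
    if (donorRes != "TYR" || acceptorRes != "TYR")
      stop("Y_distal requires non-iodinated tyrosines at 341 and 375")
  } else {
    if (donorRes != "TYD" || acceptorRes != "TYD")
      stop(sprintf("%s requires di-iodinated (TYD) tyrosines at 341 and 375",
                   condition))
  }
  bonds <- deriveBonds(x)
  adj <- .adjacency(bonds, nrow(a))
  tors <- .torsionList(x, adj)
  if (length(tors) == 0L) stop("no mobile torsions found")
  manifest <- sort(unique(unlist(lapply(tors, `[[`, "moving"))))
  mFull <- .buildEnergyModel(x, cfg)
  mMob <- .buildEnergyModel(x, cfg, mobile = manifest)
  xyz <- if (is.null(start)) coords(x) else start
  stopifnot(nrow(xyz) == nrow(a))
  eFull <- .evalEnergy(mFull, xyz)
  eMob <- .evalEnergy(mMob, xyz)
  eConst <- eFull - eMob
  if (!is.finite(eConst))
    stop("starting conformation has overlapping frozen atoms")
  kT <- .GAS_CONSTANT_KCAL * cfg$temperature
  set.seed(cfg$seed)
  nFramesOut <- (cfg$nSteps - cfg$burnIn) %/% cfg$stride
  frames <- vector("list", nFramesOut)
  energies <- numeric(nFramesOut)
  nAcc <- 0L
  nAccBurn <- 0L
  k <- 0L
  for (step in seq_len(cfg$nSteps)) {
    if (cfg$regrowProb > 0 && runif(1L) < cfg$regrowProb) {
      ## compound move: re-randomize every mobile torsion
      newXYZ <- xyz
      for (t in tors) {
        delta <- runif(1L, -180, 180)
        newXYZ[t$moving, ] <- rotateAboutAxis(newXYZ[t$moving, , drop = FALSE],
                                              newXYZ[t$a, ],
                                              newXYZ[t$b, ] - newXYZ[t$a, ],
                                              delta)
      }
    } else {
      t <- tors[[sample.int(length(tors), 1L)]]
      w <- if (cfg$jumpProb > 0 && runif(1L) < cfg$jumpProb) 180
           else cfg$moveWidth[[t$class]]
      delta <- runif(1L, -w, w)
      newXYZ <- xyz
      newXYZ[t$moving, ] <- rotateAboutAxis(xyz[t$moving, , drop = FALSE],
                                            xyz[t$a, ],
                                            xyz[t$b, ] - xyz[t$a, ],
                                            delta)
    }
    eNew <- .evalEnergy(mMob, newXYZ)
    if (is.finite(eNew) &&
        (eNew <= eMob || runif(1L) < exp(-(eNew - eMob) / kT))) {
      xyz <- newXYZ
      eMob <- eNew
      nAcc <- nAcc + 1L
      if (step <= cfg$burnIn) nAccBurn <- nAccBurn + 1L
    }
    if (step > cfg$burnIn && (step - cfg$burnIn) %% cfg$stride == 0L) {
      k <- k + 1L
      frames[[k]] <- xyz[manifest, , drop = FALSE]
      energies[k] <- eMob + eConst
    }
  }
  if (cfg$burnIn > 0L && nAccBurn == 0L)
    warning(sprintf(paste0("no moves accepted during burn-in (%d steps; ",
                           "T = %g K, move widths %s): the starting ",
                           "conformation may be strained"),
                    cfg$burnIn, cfg$temperature,
                    paste(cfg$moveWidth, collapse = "/")))
  new("ConformerEnsemble", structure = x, mobile = manifest,
      frames = frames[seq_len(k)], condition = condition, seed = cfg$seed,
      energies = energies[seq_len(k)],
      acceptanceRate = nAcc / cfg$nSteps)
}

#' Select the most probable proximal frame of an ensemble
#'
#' Finds the frames whose acceptor-Ozeta to donor-Cbeta distance falls in
#' the modal bin of the ensemble's distance distribution, and among those
#' returns the lowest-energy frame (deterministic tie rule).
#'
#' @param ens a \code{ConformerEnsemble}.
#' @param binWidth histogram bin width, Angstrom.
#' @return A list with elements \code{index} (frame number),
#'   \code{energy} (kcal/mol) and \code{structure} (the frame as a
#'   \code{ProteinStructure}).
#' @export
selectProximalFrame <- function(ens, binWidth = 0.25) {
  stopifnot(is(ens, "ConformerEnsemble"))
  if (nFrames(ens) == 0L) stop("empty ensemble")
  if (nFrames(ens) == 1L)
    return(list(index = 1L, energy = ens@energies[1L],
                structure = frameStructure(ens, 1L)))
  series <- pairDistanceSeries(ens, c(375L, "OH"), c(341L, "CB"))
  d <- distanceDistribution(series, binWidth = binWidth)
  v <- seriesValues(series)
  lo <- d@mode - binWidth / 2
  hi <- d@mode + binWidth / 2
  inMode <- which(v >= lo & v < hi)
  if (length(inMode) == 0L) inMode <- which.min(abs(v - d@mode))
  best <- inMode[which.min(ens@energies[inMode])]
  list(index = best, energy = ens@energies[best],
       structure = frameStructure(ens, best))
}
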