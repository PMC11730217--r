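## Thermodynamic layer: phenol-referenced pKa of iodotyrosines,
## pH-dependent deprotonation, and signed free-energy bookkeeping for the
## sequential vs concerted iodotyrosine-coupling pathways.

#' Phenol-referenced pKa model
#'
#' The pKa of an iodinated tyrosine phenol group is estimated from a
#' reference compound (phenol, pKa 10) plus the deprotonation free-energy
#' shift of the species relative to that reference:
#' \deqn{pKa = pKa_{ref} + \Delta\Delta G / (\ln 10 \, R \, T)}
#' with R in kcal/(mol K).
#'
#' @param referencePka reference compound pKa (default 10, phenol).
#' @param temperature Kelvin (default 298.15).
#' @param ddG named numeric vector of deprotonation free-energy shifts
#'   relative to the reference, kcal/mol.  The defaults for MIT
#'   (mono-iodotyrosine) and DIT (3,5-di-iodotyrosine) are the shifts
#'   corresponding to one and two ring iodines.
#' @return A list of class \code{PkaModel}.
#' @export
pkaModel <- function(referencePka = 10, temperature = 298.15,
                     ddG = c(MIT = -2.10, DIT = -4.64)) {
  stopifnot(temperature > 0)
  structure(list(referencePka = referencePka, temperature = temperature,
                 ddG = ddG,
                 units = c(energy = "kcal/mol", temperature = "K")),
            class = "PkaModel")
}

#' pKa of a species from the thermodynamic cycle
#'
#' @param model a \code{\link{pkaModel}}.
#' @param species species name present in \code{model$ddG}.
#' @return Numeric pKa.
#' @examples
#' m <- pkaModel()
#' pkaFromCycle(m, "DIT")   # about 6.60
#' pkaFromCycle(m, "MIT")   # about 8.46
#' @export
pkaFromCycle <- function(model, species) {
  stopifnot(inherits(model, "PkaModel"))
  if (!species %in% names(model$ddG))
    stop(sprintf("no deprotonation free-energy shift for species '%s'", species))
  model$referencePka +
    model$ddG[[species]] / (log(10) * .GAS_CONSTANT_KCAL * model$temperature)
}

#' Deprotonated fraction at a given pH
#'
#' Henderson-Hasselbalch ionization fraction
#' \eqn{f = 1 / (1 + 10^{pKa - pH})}.
#'
#' @param pka acid dissociation constant (pKa units).
#' @param ph solution pH.
#' @return Fraction in (0, 1); vectorized.
#' @export
deprotonatedFraction <- function(pka, ph) {
  1 / (1 + 10^(pka - ph))
}

#' Construct a reaction ledger
#'
#' A ledger maps pathway names to ordered reaction stages.  Each stage is a
#' data.frame with columns \code{species} and \code{coef} (stoichiometric
#' sign: negative for consumed, positive for formed species).  A
#' single-stage pathway is the concerted route; a multi-stage pathway is
#' sequential, with the first stage forming the intermediate.
#'
#' @param pathways named list; each element a list of stage data.frames.
#' @return A list of class \code{ReactionLedger}.
#' @export
makeLedger <- function(pathways) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  for (pw in pathways)
    for (st in pw)
      stopifnot(is.data.frame(st), all(c("species", "coef") %in% names(st)))
  structure(list(pathways = pathways), class = "ReactionLedger")
}

#' Signed reaction free energy of a pathway
#'
#' Evaluates products-minus-reactants over the pathway's stages:
#' \eqn{\Delta G = \sum_i c_i G_i} per stage, summed over stages.  For a
#' sequential (multi-stage) pathway the per-stage free energies (the first
#' being the intermediate-formation step) are attached as attribute
#' \code{"steps"}.  Each stage must be charge-balanced by its declared
#' signs.
#'
#' @param ledger a \code{\link{makeLedger}}.
#' @param energies species table (see \code{\link{readSpeciesEnergies}} or
#'   \code{\link{makeEnergyTable}}).
#' @param pathway pathway name.
#' @return Numeric free energy, kcal/mol; multi-stage pathways carry a
#'   \code{"steps"} attribute.
#' @export
reactionDeltaG <- function(ledger, energies, pathway) {
  stopifnot(inherits(ledger, "ReactionLedger"))
  if (!pathway %in% names(ledger$pathways))
    stop(sprintf("unknown pathway '%s' (have: %s)", pathway,
                 paste(names(ledger$pathways), collapse = ", ")))
  stages <- ledger$pathways[[pathway]]
  stepDG <- vapply(stages, function(st) {
    miss <- setdiff(st$species, energies$species)
    if (length(miss))
      stop(sprintf("unbalanced ledger: species missing from the energy table: %s",
                   paste(miss, collapse = ", ")))
    row <- match(st$species, energies$species)
    if ("charge" %in% names(energies)) {
      qsum <- sum(st$coef * energies$charge[row])
      if (abs(qsum) > 1e-9)
        stop(sprintf("pathway '%s': stage is not charge-balanced (net %+g)",
                     pathway, qsum))
    }
    sum(st$coef * energies$energy[row])
  }, numeric(1L))
  total <- sum(stepDG)
  if (length(stepDG) > 1L) attr(total, "steps") <- stepDG
  total
}

#' Rank tail variants by concerted coupling free energy
#'
#' @param dg2 named numeric vector of concerted free energies for the four
#'   variants \code{E}, \code{D}, \code{K}, \code{S} (kcal/mol).
#' @return Character vector of variant letters, most favourable (lowest
#'   free energy) first.  Ties are broken by the declared order E, D, K, S
#'   and flagged via attribute \code{"tie" = TRUE}.
#' @export
rankVariants <- function(dg2) {
  declared <- c("E", "D", "K", "S")
  miss <- setdiff(declared, names(dg2))
  if (length(miss))
    stop(sprintf("missing variants: %s", paste(miss, collapse = ", ")))
  dg2 <- dg2[declared]
  ord <- order(dg2, match(names(dg2), declared))
  out <- names(dg2)[ord]
  if (anyDuplicated(dg2)) attr(out, "tie") <- TRUE
  out
}
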