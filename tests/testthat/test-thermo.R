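test_that("the phenol-referenced cycle reproduces the iodotyrosine pKa drop", {
  m <- pkaModel(referencePka = 10, temperature = 298.15,
                ddG = c(MIT = -2.10, DIT = -4.64, ref = 0))
  expect_equal(pkaFromCycle(m, "ref"), 10)
  expect_equal(round(pkaFromCycle(m, "MIT"), 2), 8.46)
  expect_equal(round(pkaFromCycle(m, "DIT"), 2), 6.60)
  expect_error(pkaFromCycle(m, "T4"), "no deprotonation")
})

test_that("pKa is strictly increasing in the free-energy shift", {
  shifts <- seq(-6, 2, by = 0.5)
  m <- pkaModel(ddG = setNames(shifts, paste0("s", seq_along(shifts))))
  pk <- vapply(names(m$ddG), function(s) pkaFromCycle(m, s), numeric(1L))
  expect_true(all(diff(pk) > 0))
})

test_that("deprotonated fraction follows the ionization closed form", {
  expect_equal(deprotonatedFraction(6.60, 6.60), 0.5)
  expect_equal(deprotonatedFraction(6.60, 7.4), 1 / (1 + 10^-0.8))
  expect_lt(deprotonatedFraction(6.60, 5.0), 0.05)
  ## symmetry about the midpoint, strict monotonicity in pH
  for (x in c(0.3, 1, 2.5))
    expect_equal(deprotonatedFraction(6.6, 6.6 + x) +
                 deprotonatedFraction(6.6, 6.6 - x), 1)
  ph <- seq(3, 10, by = 0.25)
  expect_true(all(diff(deprotonatedFraction(7, ph)) > 0))
})

test_that("reaction free energies are signed products-minus-reactants sums", {
  energies <- data.frame(
    species = c("A", "B", "C"), energy = c(-100, -107.5, -112),
    charge = 0L, spin = "closed-shell")
  ledger <- makeLedger(list(
    ab = list(data.frame(species = c("A", "B"), coef = c(-1, 1))),
    bc = list(data.frame(species = c("B", "C"), coef = c(-1, 1))),
    ac = list(data.frame(species = c("A", "C"), coef = c(-1, 1))),
    seq = list(data.frame(species = c("A", "B"), coef = c(-1, 1)),
               data.frame(species = c("B", "C"), coef = c(-1, 1)))))
  expect_equal(reactionDeltaG(ledger, energies, "ab"), -7.5)
  ## identical product and reactant energies give zero
  same <- data.frame(species = c("A", "B"), energy = c(-5, -5),
                     charge = 0L, spin = "closed-shell")
  expect_equal(unname(reactionDeltaG(makeLedger(list(
    p = list(data.frame(species = c("A", "B"), coef = c(-1, 1))))),
    same, "p")), 0)
  ## Hess additivity over concatenated pathways
  expect_equal(reactionDeltaG(ledger, energies, "ab") +
               reactionDeltaG(ledger, energies, "bc"),
               reactionDeltaG(ledger, energies, "ac"))
  seqDG <- reactionDeltaG(ledger, energies, "seq")
  expect_equal(as.numeric(seqDG), reactionDeltaG(ledger, energies, "ac"))
  expect_equal(attr(seqDG, "steps"), c(-7.5, -4.5))
  ## missing species are listed; charge imbalance is rejected
  expect_error(reactionDeltaG(ledger, energies[-2L, ], "ab"), "B")
  charged <- energies
  charged$charge <- c(-1L, 0L, 0L)
  expect_error(reactionDeltaG(ledger, charged, "ab"), "charge-balanced")
})

test_that("variant ranking orders by concerted free energy with declared ties", {
  expect_equal(rankVariants(c(E = -10, D = -9, K = -8, S = -7)),
               c("E", "D", "K", "S"))
  expect_equal(rankVariants(c(S = -7, K = -8, D = -9, E = -10)),
               c("E", "D", "K", "S"))
  r <- rankVariants(c(E = -5, D = -5, K = -5, S = -5))
  expect_equal(as.character(r), c("E", "D", "K", "S"))
  expect_true(attr(r, "tie"))
  expect_equal(as.character(rankVariants(c(E = -7, D = -8, K = -9, S = -10))),
               c("S", "K", "D", "E"))
  expect_error(rankVariants(c(E = -1, D = -2, K = -3)), "missing variants: S")
})

test_that("synthetic scenario tables encode the stated pathway orderings", {
  tab <- makeEnergyTable("radical-vs-anionic")
  led <- couplingLedger("radical-vs-anionic")
  expect_identical(attr(tab, "provenance"), "synthetic")
  expect_lt(reactionDeltaG(led, tab, "sequential-radical"),
            reactionDeltaG(led, tab, "sequential-anionic"))

  tab <- makeEnergyTable("exergonic-concerted")
  led <- couplingLedger("exergonic-concerted")
  for (v in c("E", "D", "K", "S"))
    expect_lt(reactionDeltaG(led, tab, paste0("concerted-", v)), 0)

  tab <- makeEnergyTable("variant-ranking")
  led <- couplingLedger("variant-ranking")
  dg2 <- vapply(c("E", "D", "K", "S"), function(v)
    reactionDeltaG(led, tab, paste0("concerted-", v)), numeric(1L))
  expect_equal(as.character(rankVariants(dg2)), c("E", "D", "K", "S"))
})

test_that("the packaged species table round-trips through the TSV reader", {
  path <- system.file("extdata", "species_energies_synthetic.tsv",
                      package = "iodosite")
  tab <- readSpeciesEnergies(path)
  expect_true(all(c("species", "energy", "charge", "spin") %in% names(tab)))
  expect_true("dit-deprotonation-by-E374" %in% tab$species)
  expect_equal(tab$energy[tab$species == "dit-deprotonation-by-E374"], 4.0)
})
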