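offConfig <- function(...) {
  samplerConfig(ljScale = 0, chargeScale = 0,
                stackingWell = list(depth = 0, r0 = 3.6, width = 1), ...)
}

test_that("the pair energy matches its closed forms", {
  ## two neutral carbons at r = sigma: the Lennard-Jones term vanishes
  two <- proteinStructure(data.frame(
    element = "C", name = c("X1", "X2"), resname = "UNK", resid = 1:2,
    chain = "A", x = c(0, 3.40), y = 0, z = 0))
  expect_equal(nonbondedEnergy(two), 0, tolerance = 1e-12)
  ## two unit charges at large separation: the Coulomb term tends to zero
  charged <- proteinStructure(data.frame(
    element = "N", name = c("NZ", "NZ"), resname = "LYS", resid = 1:2,
    chain = "A", x = c(0, 1e6), y = 0, z = 0))
  expect_lt(abs(nonbondedEnergy(charged)), 1e-9)
  ## overlapping atoms give infinite energy, not an exception
  overlap <- two
  overlap@atoms$x[2L] <- 0
  expect_identical(nonbondedEnergy(overlap), Inf)
})

test_that("the energy equals a brute-force pairwise sum oracle", {
  ## mixed neutral elements plus two charged centres; the oracle below
  ## re-derives every term from its own constants
  set.seed(3)
  n <- 10L
  a <- data.frame(
    element = c(sample(c("C", "N", "O"), 8L, replace = TRUE), "N", "O"),
    name = c(paste0("X", 1:8), "NZ", "OE1"),
    resname = c(rep("UNK", 8L), "LYS", "GLU"),
    resid = 1:10, chain = "A",
    x = runif(n, 0, 7), y = runif(n, 0, 7), z = runif(n, 0, 7))
  s <- proteinStructure(a)
  sig <- c(C = 3.40, N = 3.25, O = 2.96)
  eps <- c(C = 0.086, N = 0.170, O = 0.210)
  q <- ifelse(a$name == "NZ", 1, ifelse(a$name == "OE1", -0.60, 0))
  oracle <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    r2 <- sum((unlist(a[i, c("x", "y", "z")]) -
               unlist(a[j, c("x", "y", "z")]))^2)
    sij <- ((sig[[a$element[i]]] + sig[[a$element[j]]]) / 2)^2 / r2
    oracle <- oracle +
      4 * sqrt(eps[[a$element[i]]] * eps[[a$element[j]]]) * (sij^6 - sij^3) +
      332.0637 * q[i] * q[j] / (4 * r2)
  }
  expect_equal(nonbondedEnergy(s), oracle, tolerance = 1e-9)
})

test_that("degenerate moves leave every frame at the start", {
  m <- cachedModel("E")
  cfg <- samplerConfig(nSteps = 200L, stride = 10L, seed = 2L,
                       moveWidth = 0, jumpProb = 0, regrowProb = 0)
  ens <- sampleEnsemble(m, "Y_distal", cfg)
  start <- coords(m)[ens@mobile, ]
  for (i in seq_len(nFrames(ens)))
    expect_identical(ens@frames[[i]], start)
})

test_that("a fixed seed reproduces the ensemble bit-identically", {
  m <- cachedModel("E")
  cfg <- samplerConfig(nSteps = 600L, stride = 10L, seed = 42L)
  e1 <- sampleEnsemble(m, "Y_distal", cfg)
  e2 <- sampleEnsemble(m, "Y_distal", cfg)
  expect_identical(e1@frames, e2@frames)
  expect_identical(e1@energies, e2@energies)
  cfg$seed <- 43L
  e3 <- sampleEnsemble(m, "Y_distal", cfg)
  expect_false(identical(e1@frames, e3@frames))
})

test_that("stored frame energies equal the recomputed potential", {
  m <- cachedModel("D")
  cfg <- samplerConfig(nSteps = 400L, stride = 20L, seed = 9L)
  ens <- sampleEnsemble(m, "Y_distal", cfg)
  for (i in seq_len(nFrames(ens)))
    expect_equal(frameEnergies(ens)[i],
                 nonbondedEnergy(m, frameCoords(ens, i), cfg),
                 tolerance = 1e-9)
})

test_that("conditions are matched against the iodination state", {
  m <- cachedModel("E")
  d <- cachedIodinated("E")
  expect_error(sampleEnsemble(m, "DIT_distal"), "TYD")
  expect_error(sampleEnsemble(d, "Y_distal"), "non-iodinated")
  ens <- sampleEnsemble(d, "DIT_distal",
                        samplerConfig(nSteps = 200L, stride = 20L))
  expect_s4_class(ens, "ConformerEnsemble")
  expect_equal(condition(ens), "DIT_distal")
})

test_that("free torsions show no systematic drift over seeds", {
  ## with the potential off, symmetric proposals must not push a torsion's
  ## circular mean away from uniformity
  m <- cachedModel("E")
  iN <- atomIndex(m, 374L, "N"); iCA <- atomIndex(m, 374L, "CA")
  iCB <- atomIndex(m, 374L, "CB"); iCG <- atomIndex(m, 374L, "CG")
  sinSum <- 0
  for (seed in 1:10) {
    cfg <- offConfig(nSteps = 1500L, burnIn = 0L, stride = 5L, seed = seed)
    ens <- sampleEnsemble(m, "Y_distal", cfg)
    chi <- vapply(seq_len(nFrames(ens)), function(k) {
      xyz <- frameCoords(ens, k)
      dihedralAngle(xyz[iN, ], xyz[iCA, ], xyz[iCB, ], xyz[iCG, ])
    }, numeric(1L))
    sinSum <- sinSum + mean(sin(iodosite:::deg2rad(chi)))
  }
  expect_lt(abs(sinSum / 10), 0.15)
})

test_that("the proximal frame is the lowest-energy frame of the modal bin", {
  ## bimodal construction: a narrow heavy mode near 4 A, a broad light
  ## tail at 10-14 A
  ens <- syntheticEnsemble(
    distances = c(4.05, 4.10, 4.12, 4.08, 4.11, 4.07, 10, 11, 12, 13),
    energies = c(3, 2, 1, 5, 6, 7, -10, -10, -10, -10))
  sel <- selectProximalFrame(ens, binWidth = 0.25)
  expect_equal(sel$index, 3L)  # in-mode frame with the lowest energy
  expect_equal(sel$energy, 1)
  ## a single-frame ensemble returns that frame
  one <- syntheticEnsemble(5, energies = 0.5)
  expect_equal(selectProximalFrame(one)$index, 1L)
  ## explicit tie rule: two frames in the modal bin, energies 1 and 2
  tie <- syntheticEnsemble(c(4.05, 4.10, 9), energies = c(2, 1, 0))
  expect_equal(selectProximalFrame(tie, binWidth = 0.25)$index, 2L)
})

test_that("proximal iodination restarts from the selected frame", {
  m <- cachedModel("E")
  yEns <- sampleEnsemble(m, "Y_distal",
                         samplerConfig(nSteps = 800L, stride = 10L,
                                       seed = 3L))
  sel <- selectProximalFrame(yEns)
  prox <- iodinateTyrosine(iodinateTyrosine(sel$structure, 341L), 375L)
  ens <- sampleEnsemble(prox, "DIT_proximal",
                        samplerConfig(nSteps = 300L, stride = 10L,
                                      seed = 3L))
  expect_equal(condition(ens), "DIT_proximal")
  expect_true(all(is.finite(frameEnergies(ens))))
})

test_that("ensembles are broad with a populated contact state", {
  ## pooled over three replicas per variant, the acceptor-hydroxyl to
  ## donor-Cbeta distance is widely spread and visits the sub-6-Angstrom
  ## contact region; a qualitative smoke property of the stand-in sampler,
  ## not a reproduction of molecular dynamics
  for (v in c("E", "D", "K", "S")) {
    pooled <- unlist(lapply(1:3, function(seed) {
      ens <- sampleEnsemble(cachedModel(v), "Y_distal",
                            samplerConfig(nSteps = 20000L, stride = 10L,
                                          seed = seed))
      seriesValues(pairDistanceSeries(ens, c(375L, "OH"), c(341L, "CB")))
    }))
    expect_gt(unname(diff(quantile(pooled, c(0.1, 0.9)))), 3)
    expect_gt(mean(pooled < 6), 0)
  }
})
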