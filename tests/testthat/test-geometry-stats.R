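test_that("pair distances are per-frame Euclidean norms", {
  ens <- syntheticEnsemble(c(5, 8, 11))
  ser <- pairDistanceSeries(ens, c(375L, "OH"), c(341L, "CB"))
  expect_equal(seriesValues(ser), c(5, 8, 11))
  ## 3-4-5 triangle on a hand-made two-atom frame set
  two <- proteinStructure(data.frame(
    element = "C", name = c("A1", "B1"), resname = "UNK", resid = 1:2,
    chain = "A", x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  ens2 <- new("ConformerEnsemble", structure = two, mobile = 1:2,
              frames = list(coords(two)), condition = "Y_distal",
              seed = 0L, energies = 0, acceptanceRate = 1)
  expect_equal(seriesValues(pairDistanceSeries(ens2, c(1, "A1"),
                                               c(2, "B1"))), 5)
  expect_error(pairDistanceSeries(ens2, c(1, "XX"), c(2, "B1")),
               "has atoms")
  ## coincident atoms violate the positive-distance invariant
  bad <- ens2
  bad@frames[[1L]][2L, ] <- bad@frames[[1L]][1L, ]
  expect_error(pairDistanceSeries(bad, c(1, "A1"), c(2, "B1")),
               "coincident|zero distance")
})

test_that("distance series match a brute-force per-frame oracle", {
  ens <- quickEnsemble(nSteps = 300L, seed = 5L)
  ser <- seriesValues(pairDistanceSeries(ens, c(375L, "OH"), c(341L, "CB")))
  oracle <- vapply(seq_len(nFrames(ens)), function(i) {
    xyz <- frameCoords(ens, i)
    a <- xyz[atomIndex(ens@structure, 375L, "OH"), ]
    b <- xyz[atomIndex(ens@structure, 341L, "CB"), ]
    sqrt(sum((a - b)^2))
  }, numeric(1L))
  expect_equal(ser, oracle, tolerance = 1e-12)
})

test_that("distance distributions are normalized histograms with stated moments", {
  d <- distanceDistribution(rep(4, 50), binWidth = 0.5)
  expect_equal(sum(d@probabilities), 1, tolerance = 1e-12)
  expect_equal(sum(d@probabilities > 0), 1L)
  expect_lt(abs(d@mode - 4), 0.5)  # mode within its bin convention

  d <- distanceDistribution(c(3, 9), binWidth = 1)
  expect_equal(sort(d@probabilities[d@probabilities > 0]), c(0.5, 0.5))

  set.seed(10)
  draws <- abs(rnorm(10000, 8, 1))
  d <- distanceDistribution(draws, binWidth = 0.25)
  expect_lt(abs(d@mean - 8), 3 / sqrt(10000))
  expect_error(distanceDistribution(numeric(), 0.25), "empty")
  expect_error(distanceDistribution(c(1, 2), -1))
})

test_that("histogram mass is conserved for arbitrary series", {
  set.seed(11)
  for (i in 1:20) {
    v <- runif(sample(1:500, 1L), 0.5, 30)
    d <- distanceDistribution(v, binWidth = runif(1, 0.05, 2))
    expect_equal(sum(d@probabilities), 1, tolerance = 1e-12)
    expect_true(all(diff(d@breaks) > 0))
  }
})

test_that("stacking classification follows the distance and angle bands", {
  r <- classifyStacking(makeRingPair(3.6, 0), 1L, 2L)
  expect_equal(r$label, "parallel")
  expect_equal(r$distance, 3.6, tolerance = 1e-6)
  expect_equal(r$angle, 0, tolerance = 1e-6)

  r <- classifyStacking(makeRingPair(5.0, geometry = "t-shaped"), 1L, 2L)
  expect_equal(r$label, "perpendicular")
  expect_equal(r$angle, 90, tolerance = 1e-6)

  expect_equal(classifyStacking(makeRingPair(12, 0), 1L, 2L)$label, "none")
  ## intermediate angles within contact fall in neither band
  expect_equal(classifyStacking(makeRingPair(4, 45), 1L, 2L)$label, "none")
})

test_that("stacking labels are symmetric, exclusive and planarity-guarded", {
  for (pars in list(c(3.6, 0), c(4.5, 90), c(4, 45), c(9, 10))) {
    rp <- makeRingPair(pars[1L], pars[2L],
                       geometry = if (pars[2L] == 90) "t-shaped"
                                  else "parallel-offset")
    ab <- classifyStacking(rp, 1L, 2L)
    ba <- classifyStacking(rp, 2L, 1L)
    expect_equal(ab$label, ba$label)
    expect_equal(ab$distance, ba$distance, tolerance = 1e-9)
    expect_equal(ab$angle, ba$angle, tolerance = 1e-9)
    expect_true(ab$label %in% c("parallel", "perpendicular", "none"))
  }
  bent <- makeRingPair(3.6, 0)
  bent@atoms$z[3L] <- bent@atoms$z[3L] + 1.2  # push one ring atom out of plane
  expect_error(classifyStacking(bent, 1L, 2L), "non-planar")
})

test_that("the tyrosine ring pair of a model frame is classifiable", {
  m <- cachedModel("E")
  r <- classifyStacking(m, 341L, 375L)
  expect_true(r$label %in% c("parallel", "perpendicular", "none"))
  expect_true(r$distance > 0 && r$angle >= 0 && r$angle <= 90)
})

test_that("reactive fractions count frames within the cutoff", {
  ens <- syntheticEnsemble(c(3, 5, 7, 9))
  ser <- pairDistanceSeries(ens, c(375L, "OH"), c(341L, "CB"))
  expect_equal(reactiveFraction(ser, 6), 0.5)
  expect_equal(reactiveFraction(ser, 100), 1.0)
  expect_equal(reactiveFraction(ser, 0.5), 0.0)
  ## monotone non-decreasing in the cutoff
  cuts <- seq(1, 12, by = 0.5)
  fr <- vapply(cuts, function(ct) reactiveFraction(ser, ct), numeric(1L))
  expect_true(all(diff(fr) >= 0))
})

test_that("carboxylate proximity resolves the variant-specific carbon", {
  ## E-variant: a hand-placed single frame 4.2 A from the glutamate Cdelta
  model <- cachedModel("E")
  iOH <- atomIndex(model, 375L, "OH")
  cd <- atomXYZ(model, 374L, "CD")
  dir <- iodosite:::unitv(atomXYZ(model, 375L, "OH") - cd)
  ens <- new("ConformerEnsemble", structure = model, mobile = iOH,
             frames = list(matrix(cd + 4.2 * dir, 1L, 3L)),
             condition = "Y_distal", seed = 0L, energies = 0,
             acceptanceRate = 1)
  d <- carboxylateProximity(ens)
  expect_equal(sum(d@probabilities), 1)
  expect_equal(max(d@probabilities), 1)   # all mass in the 4.2 A bin
  expect_lt(abs(d@mode - 4.2), 0.25)
  ## D resolves to Cgamma, S has no carboxylate
  ensD <- quickEnsemble("D", nSteps = 100L)
  expect_s4_class(carboxylateProximity(ensD), "DistributionSummary")
  ensS <- quickEnsemble("S", nSteps = 100L)
  expect_error(carboxylateProximity(ensS), "not applicable")
})
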