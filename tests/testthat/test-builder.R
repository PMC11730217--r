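test_that("the built tail carries the configured extended backbone torsions", {
  m <- cachedModel("E")
  expect_equal(residueName(m, 374L), "GLU")
  expect_equal(residueName(m, 375L), "TYR")
  for (r in 371:376) expect_equal(measurePhi(m, r), -120, tolerance = 1e-8)
  for (r in 371:375) expect_equal(measurePsi(m, r), 120, tolerance = 1e-8)
  ## a different build configuration is honoured just as exactly
  cfg <- buildConfig(phi = -139, psi = 135)
  m2 <- appendExtendedTail(makeScaffold(), makeVariant("D"), cfg)
  expect_equal(measurePhi(m2, 373L), -139, tolerance = 1e-8)
  expect_equal(measurePsi(m2, 373L), 135, tolerance = 1e-8)
})

test_that("an empty tail spec returns the scaffold unchanged", {
  s <- makeScaffold()
  v <- makeVariant("E")
  v$tail <- ""
  expect_identical(appendExtendedTail(s, v), s)
  expect_identical(appendExtendedTail(s, NULL), s)
})

test_that("internal-coordinate placement round-trips random dihedrals", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    r <- runif(1, 1, 2)
    th <- runif(1, 45, 135)
    phi <- runif(1, -180, 180)
    d <- iodosite:::nerfPlace(a, b, c, r, th, phi)
    err <- abs(iodosite:::wrapAngle(dihedralAngle(a, b, c, d) - phi))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("building then measuring recovers random phi/psi pairs", {
  set.seed(4)
  for (i in 1:12) {
    phi <- runif(1, -179, 180)
    psi <- runif(1, -179, 180)
    m <- appendExtendedTail(makeScaffold(), makeVariant("S"),
                            buildConfig(phi = phi, psi = psi))
    expect_equal(measurePhi(m, 373L), phi, tolerance = 1e-6)
    expect_equal(measurePsi(m, 373L), psi, tolerance = 1e-6)
  }
})

test_that("dihedral measurement uses the standard sign convention", {
  sq <- proteinStructure(data.frame(
    element = "C", name = paste0("C", 1:4), resname = "UNK",
    resid = 1:4, chain = "A",
    x = c(1, 0, 0, 1), y = c(0, 0, 1, 1), z = 0))
  expect_equal(measureDihedral(sq, list(c(1, "C1"), c(2, "C2"),
                                        c(3, "C3"), c(4, "C4"))), 0)
  tr <- sq
  tr@atoms$x[4L] <- -1
  expect_equal(measureDihedral(tr, list(c(1, "C1"), c(2, "C2"),
                                        c(3, "C3"), c(4, "C4"))), 180)
  lin <- sq
  lin@atoms$x[1L] <- 0  # first three points collinear
  lin@atoms$y[1L] <- -1
  expect_error(measureDihedral(lin, list(c(1, "C1"), c(2, "C2"),
                                         c(3, "C3"), c(4, "C4"))),
               "collinear")
})

test_that("iodination is a local edit producing the expected atoms", {
  m <- cachedModel("E")
  d <- iodinateTyrosine(m, 375L, count = 2L)
  expect_equal(residueName(d, 375L), "TYD")
  expect_equal(nAtoms(d), nAtoms(m))  # -2 H +2 I
  expect_equal(sum(atoms(d)$element[atoms(d)$resid == 375L] == "I"), 2L)
  expect_equal(sqrt(sum((atomXYZ(d, 375L, "CE1") - atomXYZ(d, 375L, "I1"))^2)),
               2.10, tolerance = 1e-6)
  expect_equal(sqrt(sum((atomXYZ(d, 375L, "CE2") - atomXYZ(d, 375L, "I2"))^2)),
               2.10, tolerance = 1e-6)
  ## atoms outside the residue are bit-identical
  keep <- atoms(m)$resid != 375L
  expect_identical(coords(d)[keep, ], coords(m)[keep, ])
  ## mono-iodination keeps Heps2 and renames to the mono-iodo code
  mono <- iodinateTyrosine(m, 375L, count = 1L)
  expect_equal(residueName(mono, 375L), "IYR")
  expect_equal(sum(atoms(mono)$element[atoms(mono)$resid == 375L] == "I"), 1L)
  expect_true("HE2" %in% atoms(mono)$name[atoms(mono)$resid == 375L])
  ## error contracts
  expect_error(iodinateTyrosine(m, 374L), "not TYR")
  expect_error(iodinateTyrosine(d, 375L), "already iodinated")
  ## a configurable bond length is honoured
  d21 <- iodinateTyrosine(m, 375L, cfg = buildConfig(cIBondLength = 2.05))
  expect_equal(sqrt(sum((atomXYZ(d21, 375L, "CE1") -
                         atomXYZ(d21, 375L, "I1"))^2)),
               2.05, tolerance = 1e-6)
})

test_that("mutation rebuilds only the side chain", {
  m <- cachedModel("E")
  d <- mutateResidue(m, 374L, "D")
  expect_equal(residueName(d, 374L), "ASP")
  for (nm in c("N", "CA", "C", "O"))
    expect_identical(atomXYZ(d, 374L, nm), atomXYZ(m, 374L, nm))
  expect_true("CG" %in% atoms(d)$name[atoms(d)$resid == 374L])
  expect_false("CD" %in% atoms(d)$name[atoms(d)$resid == 374L])
  ## tyrosine-to-phenylalanine removes the hydroxyl oxygen
  f <- mutateResidue(m, 375L, "F")
  expect_equal(residueName(f, 375L), "PHE")
  expect_false("OH" %in% atoms(f)$name[atoms(f)$resid == 375L])
  ## identity mutation is a no-op
  expect_identical(mutateResidue(m, 374L, "E"), m)
  expect_error(mutateResidue(m, 374L, "W"), "unsupported")
})

test_that("variant models share identical backbones and differ only at 374", {
  ref <- cachedModel("E")
  bbSel <- atoms(ref)$name %in% c("N", "CA", "C", "O")
  for (v in c("D", "K", "S")) {
    m <- cachedModel(v)
    sel <- atoms(m)$name %in% c("N", "CA", "C", "O")
    expect_equal(coords(m)[sel, ], coords(ref)[bbSel, ], tolerance = 1e-12)
    diffRes <- setdiff(unique(atoms(m)$resid), 374L)
    for (r in diffRes)
      expect_identical(atoms(m)$name[atoms(m)$resid == r],
                       atoms(ref)$name[atoms(ref)$resid == r])
  }
})
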