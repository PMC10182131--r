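test_that("SASA of isolated and non-occluding atoms is the analytic sphere area", {
  # single carbon, probe 1.4: area of a 3.1 A sphere
  m1 <- makeModel(c(0, 0, 0))
  expect_equal(sasaPerResidue(m1)[["1"]], 4 * pi * 3.1^2, tolerance = 0.02)
  # two atoms far apart: no occlusion, each the isolated value
  m2 <- makeModel(rbind(c(0, 0, 0), c(100, 0, 0)), resno = c(1, 2))
  s <- sasaPerResidue(m2)
  expect_equal(unname(s), rep(4 * pi * 3.1^2, 2), tolerance = 0.02)
  expect_error(sasaPerResidue(makeModel(matrix(numeric(), 0, 3))), "no atoms")
})

test_that("a fully caged atom has zero accessible area", {
  # 26 neighbors on the 3x3x3 grid shell at 2 A spacing bury the center
  grid <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                z = c(-2, 0, 2)))
  center <- which(rowSums(grid^2) == 0)
  xyz <- rbind(grid[center, ], grid[-center, ])
  m <- makeModel(xyz, resno = seq_len(27))
  s <- sasaPerResidue(m)
  expect_equal(s[["1"]], 0, tolerance = 1e-9)
})

test_that("quadrature SASA agrees with a Monte-Carlo oracle on random configurations", {
  set.seed(101)
  for (rep in 1:4) {
    n <- sample(5:30, 1)
    xyz <- matrix(runif(3 * n, 0, 8), ncol = 3)
    elem <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    m <- makeModel(xyz, resno = seq_len(n), element = elem)
    got <- sum(sasaPerResidue(m, nSpherePoints = 960))
    oracle <- sum(mcSasaOracle(m, nPoints = 6000))
    expect_equal(got, oracle, tolerance = 0.03)
  }
})

test_that("adding an occluding atom never increases any SASA", {
  set.seed(7)
  xyz <- matrix(runif(30, 0, 6), ncol = 3)
  m <- makeModel(xyz, resno = seq_len(10))
  base <- sasaPerResidue(m)
  withExtra <- makeModel(rbind(xyz, runif(3, 0, 6)), resno = seq_len(11))
  s2 <- sasaPerResidue(withExtra)
  expect_true(all(s2[as.character(1:10)] <= base + 1e-9))
})

test_that("clash score counts non-bonded overlaps per 1000 atoms", {
  # carbons in residues 1 and 5 at 2.9 A: overlap 0.5 >= 0.4 -> one clash
  m2 <- makeModel(rbind(c(0, 0, 0), c(20, 0, 0), c(30, 0, 0), c(40, 0, 0),
                        c(2.9, 0, 0)), resno = 1:5)
  expect_equal(clashScore(m2), 1000 * 1 / 5)
  # same geometry at 3.1 A: overlap 0.3 < 0.4, no clash
  m3 <- makeModel(rbind(c(0, 0, 0), c(20, 0, 0), c(30, 0, 0), c(40, 0, 0),
                        c(3.1, 0, 0)), resno = 1:5)
  expect_equal(clashScore(m3), 0)
  # all atoms >= 5 A apart: zero
  m4 <- makeModel(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), resno = 1:3)
  expect_equal(clashScore(m4), 0)
  # same-residue and adjacent-residue contacts never count
  m5 <- makeModel(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), resno = c(1, 1, 2))
  expect_equal(clashScore(m5), 0)
  expect_error(clashScore(m4, overlapCutoff = 0), "> 0")
})

test_that("clash score is invariant under rigid-body motion", {
  set.seed(33)
  xyz <- matrix(runif(45, 0, 5), ncol = 3)
  m <- makeModel(xyz, resno = rep(1:5, each = 3))
  ref <- clashScore(m)
  theta <- 0.8
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  xyz2 <- sweep(xyz %*% rot, 2, c(10, -4, 2), "+")
  m2 <- makeModel(xyz2, resno = rep(1:5, each = 3))
  expect_equal(clashScore(m2), ref)
  expect_gt(ref, 0)  # the random cluster must actually contain clashes
})

test_that("relative SASA normalizes by the reference maximum and clamps", {
  expect_equal(relativeSasa(0, "ALA"), 0)
  expect_equal(relativeSasa(129.0, "ALA"), 100)
  expect_equal(relativeSasa(2 * 129.0, "ALA"), 100)  # clamped
  expect_equal(relativeSasa(104.0 / 2, "GLY"), 50)
  expect_error(relativeSasa(10, "XYZ"), "unknown residue")
  expect_error(relativeSasa(-1, "ALA"), ">= 0")
})

test_that("confidence binning partitions [0, 100] with the stated boundaries", {
  expect_identical(binConfidence(c(0, 49.99, 50, 69.9, 70, 90, 90.0001, 100)),
                   c("<50", "<50", "50-70", "50-70", "70-90", "70-90",
                     ">90", ">90"))
  # every score maps to exactly one bin
  grid <- seq(0, 100, by = 0.5)
  bins <- binConfidence(grid)
  expect_true(all(bins %in% c("<50", "50-70", "70-90", ">90")))
  expect_identical(length(bins), length(grid))
  expect_error(binConfidence(-1), "\\[0, 100\\]")
  expect_error(binConfidence(100.5), "\\[0, 100\\]")
})

test_that("domain membership uses 0-based half-open intervals", {
  tr <- domainTrack(0, 10)
  expect_true(inDomain(1, tr))    # residue 1 -> coordinate 0
  expect_true(inDomain(10, tr))   # coordinate 9, still inside
  expect_false(inDomain(11, tr))  # coordinate 10, half-open end
  expect_false(inDomain(5, domainTrack()))
  expect_error(inDomain(0, tr), ">= 1")
  # overlapping intervals merge on construction
  tr2 <- domainTrack(c(0, 5, 30), c(10, 20, 40))
  expect_identical(nrow(tr2@intervals), 2L)
  expect_true(all(inDomain(1:20, tr2)))
  expect_false(inDomain(25, tr2))
})
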