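cmp <- fixtureCompounds()

test_that("compound masses follow count x voxel volume x density", {
  # a million API voxels at 28 um and 1447.2 kg/m^3 weigh ~31.77 mg
  m <- VoxelMatrix(array(1L, c(100, 100, 100)), 0.028)
  masses <- compoundMasses(m, cmp[1:2])
  expect_equal(unname(masses["theophylline"]),
               1e6 * 0.028^3 * 1.4472, tolerance = 1e-12)
  expect_equal(unname(masses["ethyl cellulose"]), 0)
  # empty matrix: all masses zero
  empty <- VoxelMatrix(array(0L, c(3, 3, 3)), 0.028)
  expect_true(all(compoundMasses(empty, cmp[1:2]) == 0))
  # scaling law: doubling the voxel edge multiplies every mass by 8
  m2 <- VoxelMatrix(voxelLabels(m), 0.056)
  expect_equal(unname(compoundMasses(m2, cmp[1:2])),
               unname(8 * masses), tolerance = 1e-12)
})

test_that("compound masses are additive over disjoint voxel partitions", {
  set.seed(11)
  for (rep in 1:5) {
    m <- randomLabelMatrix(c(5, 6, 4), seed = rep)
    lab <- voxelLabels(m)
    split <- array(sample(c(TRUE, FALSE), length(lab), replace = TRUE),
                   dim(lab))
    a <- lab; a[!split] <- 0L
    b <- lab; b[split] <- 0L
    mA <- compoundMasses(VoxelMatrix(a, 0.028), cmp[1:2])
    mB <- compoundMasses(VoxelMatrix(b, 0.028), cmp[1:2])
    expect_equal(mA + mB, compoundMasses(m, cmp[1:2]),
                 tolerance = 1e-12)
  }
})

test_that("a label without a Compound is an error", {
  m <- VoxelMatrix(array(c(0L, 1L, 31L), c(3, 1, 1)), 0.028)
  expect_error(compoundMasses(m, cmp["api"]), "31")
})

test_that("image porosity counts air over the evaluation region", {
  expect_equal(imagePorosity(VoxelMatrix(array(0L, c(2, 2, 2)), 0.028)),
               100)
  expect_equal(imagePorosity(VoxelMatrix(array(1L, c(2, 2, 2)), 0.028)),
               0)
  # generated matrix: porosity matches the generator's recorded air
  # fraction exactly (same counting), within one voxel's worth of the
  # nominal target
  p <- GenerationParams(c(10, 20, 20), 0.1, 1.8, 0.9,
                        targets = c(theophylline = 0.5,
                                    `ethyl cellulose` = 0.7),
                        seed = 3L)
  g <- generateDistributed(p, cmp[1:2])
  gt <- voxelMetadata(g)$groundTruth
  expect_equal(imagePorosity(g, region = "cylinder"),
               100 * gt$airFractionCylinder, tolerance = 1e-12)
})

test_that("recovery rates reproduce the worked tablet records", {
  # matrix T7 of the 25/75 batch, tablet 3: virtual 73.3/329.2 mg against
  # real 86.9/329.5 mg -> 84.3 % API, 99.9 % excipient at 1 d.p.
  fx <- synthTabletFixture(73.3, 329.2, 86.9, 329.5, seed = 5L)
  rep7 <- recoveryReport(fx$matrix, cmp[1:2], fx$spec,
                         region = "cylinder")
  rr <- recoveryRates(rep7)
  expect_equal(unname(rr["api"]), 84.3)
  expect_equal(unname(rr["ex"]), 99.9)
  # matrix T4: virtual excipient 323.8 mg vs real 329.5 -> 98.3 %
  fx4 <- synthTabletFixture(96.1, 323.8, 86.9, 329.5, seed = 6L)
  rr4 <- recoveryRates(recoveryReport(fx4$matrix, cmp[1:2], fx4$spec,
                                      region = "cylinder"))
  expect_equal(unname(rr4["ex"]), 98.3)
  # identical virtual and real masses: every recovery is 100 %
  fxEq <- synthTabletFixture(86.9, 329.5, 86.9, 329.5, seed = 7L)
  rrEq <- recoveryRates(recoveryReport(fxEq$matrix, cmp[1:2], fxEq$spec,
                                       region = "cylinder"))
  expect_true(all(rrEq == 100))
})

test_that("total recovery is the mass-weighted combination of component recoveries", {
  set.seed(21)
  for (i in 1:20) {
    rApi <- runif(1, 50, 150); rEx <- runif(1, 100, 400)
    vApi <- runif(1, 40, 160); vEx <- runif(1, 90, 410)
    recApi <- 100 * vApi / rApi
    recEx <- 100 * vEx / rEx
    recTot <- 100 * (vApi + vEx) / (rApi + rEx)
    expect_equal(recTot,
                 (rApi * recApi + rEx * recEx) / (rApi + rEx),
                 tolerance = 1e-12)
  }
})

test_that("zero real masses are rejected", {
  fx <- synthTabletFixture(5, 8, 5, 8, dim = c(10L, 30L, 30L),
                           diameter = 4, height = 1.4, voxelEdge = 0.15)
  badSpec <- fx$spec
  badSpec@apiMass <- 0
  expect_error(recoveryReport(fx$matrix, cmp[1:2], badSpec), "positive")
})

test_that("desirability is the geometric mean with annihilating zeros", {
  expect_equal(desirabilityScore(rep(100, 6)), 1)
  expect_equal(desirabilityScore(c(100, 100, 100, 100, 100, 75)), 0)
  # component values (1,1,1,1,1,0.5): ramp gives 0.5 at 87.5 % recovery
  expect_equal(desirabilityScore(c(100, 100, 100, 100, 100, 87.5)),
               0.5^(1 / 6), tolerance = 1e-12)
})

test_that("desirability is permutation-invariant and monotone per component", {
  set.seed(33)
  for (i in 1:20) {
    rec <- runif(6, 76, 124)
    expect_equal(desirabilityScore(rec),
                 desirabilityScore(sample(rec)), tolerance = 1e-12)
    # moving one component toward 100 never decreases the score
    j <- sample.int(6, 1)
    closer <- rec
    closer[j] <- 100 + (rec[j] - 100) * 0.5
    expect_gte(desirabilityScore(closer), desirabilityScore(rec))
  }
})

test_that("composition report serialises to a plain data frame", {
  fx <- synthTabletFixture(5, 8, 5, 8, dim = c(10L, 30L, 30L),
                           diameter = 4, height = 1.4, voxelEdge = 0.15)
  rep0 <- recoveryReport(fx$matrix, cmp[1:2], fx$spec,
                         region = "cylinder")
  df <- as.data.frame(rep0)
  expect_true(all(c("recovery_api", "desirability") %in% df$parameter))
  expect_true(is.numeric(df$value))
})

test_that("half-up rounding breaks ties away from zero", {
  expect_equal(roundHalfUp(84.35, 1), 84.4)
  expect_equal(roundHalfUp(99.85, 1), 99.9)
  expect_equal(roundHalfUp(-1.25, 1), -1.3)
})
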