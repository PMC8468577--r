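cmp <- fixtureCompounds()

targetsDG <- c(theophylline = 88.6, `ethyl cellulose` = 316.2)
paramsDG <- function(mode = "distributed", nSeeds = 1L, seed = 1L)
  GenerationParams(c(24L, 80L, 80L), 0.15, 11.28, 3.5,
                   targets = targetsDG, mode = mode, nSeeds = nSeeds,
                   seed = seed)

test_that("distributed generation hits the target masses within one voxel-mass", {
  m <- generateDistributed(paramsDG(seed = 2L), cmp[1:2])
  masses <- compoundMasses(m, cmp[1:2])
  vm <- 0.15^3 * c(1447.2, 1139.9) * 1e-3
  expect_lt(abs(masses[["theophylline"]] - 88.6), vm[1])
  expect_lt(abs(masses[["ethyl cellulose"]] - 316.2), vm[2])
  # everything outside the cylinder stays air
  mask <- cylinderMask(m)
  expect_true(all(voxelLabels(m)[!mask] == 0L))
})

test_that("generation is deterministic given the seed", {
  m1 <- generateDistributed(paramsDG(seed = 9L), cmp[1:2])
  m2 <- generateDistributed(paramsDG(seed = 9L), cmp[1:2])
  expect_identical(voxelLabels(m1), voxelLabels(m2))
  m3 <- generateDistributed(paramsDG(seed = 10L), cmp[1:2])
  expect_false(identical(voxelLabels(m1), voxelLabels(m3)))
  ps <- GenerationParams(c(12L, 24L, 24L), 0.1, 2.0, 1.0,
                         targets = c(theophylline = 0.8,
                                     `ethyl cellulose` = 1.2),
                         mode = "seed_grow", nSeeds = 4L, seed = 3L)
  g1 <- generateSeedGrow(ps, cmp[1:2])
  g2 <- generateSeedGrow(ps, cmp[1:2])
  expect_identical(voxelLabels(g1), voxelLabels(g2))
})

test_that("zero targets give an all-air cylinder and infeasible targets error", {
  p0 <- GenerationParams(c(10L, 20L, 20L), 0.1, 1.8, 0.9,
                         targets = c(theophylline = 0,
                                     `ethyl cellulose` = 0))
  m0 <- generateDistributed(p0, cmp[1:2])
  expect_true(all(voxelLabels(m0) == 0L))
  pBig <- GenerationParams(c(10L, 20L, 20L), 0.1, 1.8, 0.9,
                           targets = c(theophylline = 50,
                                       `ethyl cellulose` = 50))
  expect_error(generateDistributed(pBig, cmp[1:2]), "infeasible")
  expect_error(generateSeedGrow(pBig, cmp[1:2]), "infeasible")
})

test_that("targets filling the whole cylinder give zero interparticular porosity", {
  edge <- 0.1
  p <- GenerationParams(c(10L, 20L, 20L), edge, 1.8, 0.9,
                        targets = c(theophylline = 0.01,
                                    `ethyl cellulose` = 0.01))
  nCyl <- sum(cylinderMask(generateDistributed(p, cmp[1:2])))
  vmApi <- edge^3 * 1447.2e-3
  vmEx <- edge^3 * 1139.9e-3
  nApi <- floor(nCyl / 2)
  full <- GenerationParams(c(10L, 20L, 20L), edge, 1.8, 0.9,
                           targets = c(theophylline = nApi * vmApi,
                                       `ethyl cellulose` =
                                         (nCyl - nApi) * vmEx))
  mFull <- generateDistributed(full, cmp[1:2])
  expect_equal(imagePorosity(mFull, region = "cylinder"), 0)
})

test_that("a single seed grows into one 6-connected cluster", {
  p <- GenerationParams(c(12L, 20L, 20L), 0.1, 1.6, 1.0,
                        targets = c(theophylline = 0.12,
                                    `ethyl cellulose` = 0.15),
                        mode = "seed_grow", nSeeds = 1L, seed = 11L)
  m <- generateSeedGrow(p, cmp[1:2])
  expect_true(isSingleCluster6(voxelLabels(m), 1L))
  expect_true(isSingleCluster6(voxelLabels(m), 31L))
  gt <- voxelMetadata(m)$groundTruth$counts
  expect_equal(unname(sum(voxelLabels(m) == 1L)),
               unname(gt["theophylline"]))
})

test_that("seed-and-grow hits the target masses within one voxel-mass", {
  p <- GenerationParams(c(16L, 32L, 32L), 0.12, 3.0, 1.6,
                        targets = c(theophylline = 1.4,
                                    `ethyl cellulose` = 2.2),
                        mode = "seed_grow", nSeeds = 6L, seed = 4L)
  m <- generateSeedGrow(p, cmp[1:2])
  masses <- compoundMasses(m, cmp[1:2])
  vm <- 0.12^3 * c(1447.2, 1139.9) * 1e-3
  expect_lt(abs(masses[["theophylline"]] - 1.4), vm[1])
  expect_lt(abs(masses[["ethyl cellulose"]] - 2.2), vm[2])
})

test_that("nSeeds at the required voxel count degenerates to pure placement", {
  edge <- 0.1
  vmApi <- edge^3 * 1447.2e-3
  vmEx <- edge^3 * 1139.9e-3
  p <- GenerationParams(c(10L, 20L, 20L), edge, 1.8, 0.9,
                        targets = c(theophylline = 40 * vmApi,
                                    `ethyl cellulose` = 60 * vmEx),
                        mode = "seed_grow", nSeeds = 100L, seed = 5L)
  m <- generateSeedGrow(p, cmp[1:2])
  expect_equal(sum(voxelLabels(m) == 1L), 40)
  expect_equal(sum(voxelLabels(m) == 31L), 60)
})

test_that("an enclosed compound aborts growth with a named error", {
  # a 9-voxel line: single-seed clusters of two compounds growing toward
  # targets that jointly fill the line; whichever cluster gets walled in
  # by the other must abort with the compound named
  vmA <- 1447.2e-3; vmE <- 1139.9e-3     # voxel masses at 1 mm edge
  p <- GenerationParams(c(9L, 1L, 1L), 1, 1, 9,
                        targets = c(`ethyl cellulose` = 6 * vmE,
                                    theophylline = 3 * vmA),
                        mode = "seed_grow", nSeeds = 1L, seed = 1L)
  expect_error(generateSeedGrow(p, list(cmp$ex, cmp$api)),
               "ethyl cellulose.*enclosed|enclosed.*ethyl cellulose")
  # a feasible single-compound fill of the same line succeeds
  pOk <- GenerationParams(c(9L, 1L, 1L), 1, 1, 9,
                          targets = c(theophylline = 9 * vmA,
                                      `ethyl cellulose` = 0),
                          mode = "seed_grow", nSeeds = 1L, seed = 1L)
  m <- generateSeedGrow(pOk, cmp[1:2])
  expect_equal(sum(voxelLabels(m) == 1L), 9)
})

test_that("densify removes in-cylinder air, keeps the voxel ratio, and is idempotent", {
  p <- GenerationParams(c(12L, 24L, 24L), 0.1, 2.0, 1.0,
                        targets = c(theophylline = 1.0,
                                    `ethyl cellulose` = 1.0), seed = 8L)
  m <- generateDistributed(p, cmp[1:2])
  before <- c(sum(voxelLabels(m) == 1L), sum(voxelLabels(m) == 31L))
  for (mode in c("distributed", "seed_grow")) {
    dn <- densify(m, mode, seed = 21L)
    expect_equal(imagePorosity(dn, region = "cylinder"), 0)
    # pre-existing compound voxels preserved
    expect_true(all(voxelLabels(dn)[voxelLabels(m) == 1L] == 1L))
    expect_true(all(voxelLabels(dn)[voxelLabels(m) == 31L] == 31L))
    # voxel-count ratio maintained within one voxel
    after <- c(sum(voxelLabels(dn) == 1L), sum(voxelLabels(dn) == 31L))
    expected <- before / sum(before) * sum(after)
    expect_true(all(abs(after - expected) <= 1))
  }
  dn <- densify(m, "distributed", seed = 21L)
  expect_identical(voxelLabels(densify(dn, "distributed", seed = 22L)),
                   voxelLabels(dn))
  # determinism
  expect_identical(voxelLabels(densify(m, "distributed", seed = 21L)),
                   voxelLabels(dn))
})

test_that("seed-grow composition approaches distributed placement as seeds grow many", {
  # with one voxel per seed the seed-grow layout is itself a uniform
  # random placement; compare in-cylinder mixing statistics
  edge <- 0.1
  vmApi <- edge^3 * 1447.2e-3
  tApi <- 200 * vmApi
  pD <- GenerationParams(c(12L, 24L, 24L), edge, 2.0, 1.0,
                         targets = c(theophylline = tApi,
                                     `ethyl cellulose` = 0), seed = 31L)
  pG <- GenerationParams(c(12L, 24L, 24L), edge, 2.0, 1.0,
                         targets = c(theophylline = tApi,
                                     `ethyl cellulose` = 0),
                         mode = "seed_grow", nSeeds = 200L, seed = 31L)
  mD <- generateDistributed(pD, cmp[1:2])
  mG <- generateSeedGrow(pG, cmp[1:2])
  # same occupancy; slice-profile of counts should be statistically alike
  expect_equal(sum(voxelLabels(mG) == 1L), sum(voxelLabels(mD) == 1L))
  profD <- apply(voxelLabels(mD) == 1L, 1, sum)
  profG <- apply(voxelLabels(mG) == 1L, 1, sum)
  expect_lt(max(abs(profD - profG)), 40)  # both ~uniform over 12 slices
})
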