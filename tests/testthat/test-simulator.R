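cmp <- fixtureCompounds()

smallConfig <- function(iterations = 6000L, samplingInterval = 300, ...)
  SimulationConfig(cmp, iterations = iterations,
                   samplingInterval = samplingInterval, timeStep = 1,
                   ...)

test_that("wettability is a strict 90-degree contact-angle threshold", {
  probes <- list(Compound(31L, "ec measured", 1139.9,
                          contactAngle = 93.2),
                 Compound(32L, "ec adjusted", 1139.9, contactAngle = 89),
                 Compound(33L, "boundary", 1139.9, contactAngle = 90),
                 Compound(1L, "api no angle", 1447.2, solubility = 10))
  w <- checkWettability(probes)
  expect_false(w[["ec measured"]])   # 93.2 deg: cannot be wetted
  expect_true(w[["ec adjusted"]])    # 89 deg: wettable
  expect_false(w[["boundary"]])      # strict inequality at 90
  expect_true(w[["api no angle"]])
})

test_that("a pure-API tablet dissolves completely with exact mass balance", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- 1L
  m <- VoxelMatrix(lab, 0.1)
  prof <- simulateDissolution(m, smallConfig())
  rel <- profileReleased(prof)
  expect_true(all(diff(rel) >= 0))
  expect_equal(rel[length(rel)], 100, tolerance = 0.1)
  init <- attr(prof, "initialApiMass")
  remaining <- attr(prof, "remainingApiMass")
  released <- init * rel[length(rel)] / 100
  expect_equal(released + remaining, init, tolerance = 1e-9 * init)
})

test_that("API walled in by unwettable dense excipient plateaus below 100%", {
  lab <- array(0L, c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 31L    # shell block
  lab[4:5, 4:5, 4:5] <- 1L     # 8 enclosed API voxels
  lab[1, 1:2, 1:2] <- 1L       # 4 exposed API voxels
  m <- VoxelMatrix(lab, 0.1)
  sealed <- cmp
  sealed$ex@contactAngle <- 93.2
  sealed$ex@intraPorosity <- 0
  prof <- simulateDissolution(m, SimulationConfig(
    sealed, iterations = 8000L, samplingInterval = 400, timeStep = 1))
  rel <- profileReleased(prof)
  expect_true(all(diff(rel) >= 0))
  n <- length(rel)
  expect_lt(rel[n], 100)
  expect_equal(rel[n], rel[n - 4])            # plateau reached
  expect_equal(rel[n], 100 * 4 / 12, tolerance = 0.01)
  # mass balance also holds on the plateau
  init <- attr(prof, "initialApiMass")
  expect_equal(init * rel[n] / 100 + attr(prof, "remainingApiMass"),
               init, tolerance = 1e-9 * init)
})

test_that("a wettable porous excipient shell lets the medium percolate", {
  lab <- array(0L, c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 31L
  lab[4:5, 4:5, 4:5] <- 1L
  m <- VoxelMatrix(lab, 0.1)
  porous <- cmp
  porous$ex@contactAngle <- 89
  porous$ex@intraPorosity <- 20    # e.g. from the porosity correction
  prof <- simulateDissolution(m, SimulationConfig(
    porous, iterations = 12000L, samplingInterval = 600, timeStep = 1,
    wettingTime = 60))
  rel <- profileReleased(prof)
  expect_equal(rel[length(rel)], 100, tolerance = 0.5)
})

test_that("insoluble compounds are never released", {
  lab <- array(31L, c(4, 4, 4))
  m <- VoxelMatrix(lab, 0.1)
  expect_error(simulateDissolution(m, smallConfig()), "soluble")
  # mixed: release never exceeds the API share
  lab[2:3, 2:3, 2:3] <- 1L
  prof <- simulateDissolution(VoxelMatrix(lab, 0.1),
                              smallConfig(iterations = 4000L))
  expect_true(all(profileReleased(prof) <= 100 + 1e-9))
})

test_that("higher solubility weakly accelerates release", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- 1L
  m <- VoxelMatrix(lab, 0.1)
  run <- function(sol) {
    cc <- cmp
    cc$api@solubility <- sol
    profileReleased(simulateDissolution(m, SimulationConfig(
      cc, iterations = 4000L, samplingInterval = 200, timeStep = 1)))
  }
  slow <- run(10.09)
  fast <- run(20.18)
  firstAbove <- function(v, q) which(v >= q)[1]
  for (q in c(25, 50, 75))
    expect_lte(firstAbove(fast, q), firstAbove(slow, q))
})

test_that("an exterior-connected API cluster releases fully (percolation)", {
  lab <- array(0L, c(10, 6, 6))
  lab[1:9, 3, 3] <- 1L                        # rod reaching a face
  prof <- simulateDissolution(VoxelMatrix(lab, 0.1),
                              smallConfig(iterations = 4000L,
                                          samplingInterval = 200))
  expect_equal(max(profileReleased(prof)), 100, tolerance = 0.1)
})

test_that("uncovered labels are rejected with the grey value named", {
  lab <- array(c(1L, 77L), c(2, 2, 2))
  lm <- c(`1` = "compound", `77` = "compound")
  m <- VoxelMatrix(lab, 0.1, labelMap = lm)
  expect_error(simulateDissolution(m, smallConfig()), "77")
})
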