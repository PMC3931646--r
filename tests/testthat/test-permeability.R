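test_that("ramp averaging cancels antisymmetric offsets", {
  v <- seq(-20, 20, by = 0.5)
  up <- Sweep(seq_along(v), v, v + 1)
  down <- Sweep(seq_along(v), rev(v), rev(v) - 1)
  iv <- averageRamps(up, down, grid = v)
  expect_equal(iv$current_pA, v, tolerance = 1e-12)

  same <- averageRamps(up, up, grid = v)
  expect_equal(same$current_pA, v + 1)

  # GHK-shaped limbs with capacitive offsets of opposite sign
  pair <- standardSolutions(1)
  shape <- ghkNetCurrent(v, pair, 17.2) * 50
  upg <- Sweep(seq_along(v), v, shape + 3)
  downg <- Sweep(seq_along(v), rev(v), rev(shape) - 3)
  ivg <- averageRamps(upg, downg, grid = v)
  expect_equal(ivg$current_pA, shape, tolerance = 1e-9)

  far <- Sweep(1:3, c(100, 110, 120), c(1, 2, 3))
  expect_error(averageRamps(up, far), "non-overlapping")
})

test_that("reversal estimation linearizes around the zero crossing", {
  v <- seq(-15, 15, by = 0.25)
  line <- data.frame(voltage_mV = v, current_pA = 2.5 * (v + 4.02))
  expect_equal(estimateReversal(line), -4.02, tolerance = 1e-9)

  pair <- standardSolutions(1)
  truth <- ghkReversal(pair, 17.2)
  ghkIV <- data.frame(voltage_mV = v,
                      current_pA = ghkNetCurrent(v, pair, 17.2) * 40)
  expect_equal(estimateReversal(ghkIV, window = 5), truth,
               tolerance = 0.05)

  pos <- data.frame(voltage_mV = v, current_pA = v^2 + 1)
  expect_error(estimateReversal(pos), "no reversal")
})

test_that("activities: infinite dilution, Davies formula and fixed table", {
  dilute <- IonSolution("Na", 1e-9, 1)
  a <- solutionActivities(dilute, activityModel())
  expect_equal(unname(a["Na"]), 1e-9 / 1000, tolerance = 1e-6)

  # Davies gammas equal a direct one-line evaluation at the solution's
  # ionic strength
  s <- IonSolution(c("Na", "Ca", "Cl"), c(120, 1, 122), c(1, 2, -1))
  I <- (0.120 * 1 + 0.001 * 4 + 0.122 * 1) / 2
  expect_equal(ionicStrength(s), I)
  act <- solutionActivities(s, activityModel(), temperature = 295)
  A <- 1.82483e6 * ((87.74 - 0.40008 * 21.85 + 9.398e-4 * 21.85^2 -
                       1.41e-6 * 21.85^3) * 295)^-1.5
  gDirect <- function(z) 10^(-A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  expect_equal(unname(act["Na"]), gDirect(1) * 0.120, tolerance = 1e-9)
  expect_equal(unname(act["Ca"]), gDirect(2) * 0.001, tolerance = 1e-9)

  fx <- activityModel("fixed", c(Na = 0.77, Ca = 0.55, Cl = 0.77))
  af <- solutionActivities(s, fx)
  expect_equal(unname(af["Ca"]), 5.5e-4)
  expect_error(solutionActivities(s, activityModel("fixed", c(Na = 0.77))),
               "no activity coefficient")
})

test_that("GHK reversal: symmetric zero, Nernst limit, bisection oracle", {
  ctrl <- standardSolutions(0)
  expect_lt(abs(ghkReversal(ctrl, 5)), 1e-9)

  # Na-only with out/in activity ratio 10 reduces to the Nernst form
  p <- SolutionPair(IonSolution("Na", 12, 1), IonSolution("Na", 120, 1))
  m1 <- activityModel("fixed", c(Na = 1))
  expect_equal(ghkReversal(p, 0, m1), thermalVoltage(295) * log(10),
               tolerance = 1e-9)

  # agreement with an independently coded bisection solver
  test <- standardSolutions(1)
  aIn <- solutionActivities(test@inner, activityModel(), 295)
  aOut <- solutionActivities(test@outer, activityModel(), 295)
  for (r in c(0.5, 17.2)) {
    eOracle <- oracleBisectErev(aIn[["Na"]], aOut[["Na"]], aIn[["Ca"]], 0,
                                r, thermalVoltage(295))
    expect_equal(ghkReversal(test, r), eOracle, tolerance = 1e-6)
  }

  # returned root nulls the net current
  e <- ghkReversal(test, 17.2)
  expect_lt(abs(ghkNetCurrent(e, test, 17.2)), 1e-10)

  noPerm <- SolutionPair(IonSolution("Cl", 120, -1),
                         IonSolution("Cl", 120, -1))
  expect_error(ghkReversal(noPerm, 1), "no permeant")
})

test_that("forward/inverse permeability round trip is exact", {
  ctrl <- standardSolutions(0)
  test <- standardSolutions(1)
  for (model in list(activityModel(),
                     activityModel("fixed",
                                   c(Na = 0.77, Ca = 0.55, Cl = 0.77)))) {
    for (r in c(0.5, 1.5, 5, 17.2, 50)) {
      dE <- ghkReversal(test, r, model) - ghkReversal(ctrl, r, model)
      res <- permeabilityRatioFromShift(dE, ctrl, test, model)
      expect_equal(permeabilityRatio(res), r, tolerance = 1e-6)
      expect_equal(reversalShift(res), dE, tolerance = 1e-9)
    }
  }
})

test_that("shift is strictly decreasing in the permeability ratio", {
  ctrl <- standardSolutions(0)
  test <- standardSolutions(1)
  rs <- c(0, 0.5, 1.5, 5, 17.2, 50, 200)
  shifts <- vapply(rs, function(r)
    ghkReversal(test, r) - ghkReversal(ctrl, r), numeric(1))
  expect_true(all(diff(shifts) < 0))
})

test_that("zero shift and inconsistent sign are handled per contract", {
  ctrl <- standardSolutions(0)
  test <- standardSolutions(1)
  fx <- activityModel("fixed", c(Na = 0.77, Ca = 0.55, Cl = 0.77))
  res0 <- permeabilityRatioFromShift(0, ctrl, test, fx)
  expect_identical(permeabilityRatio(res0), 0)
  # internal Ca2+ addition shifts E_rev negative; a positive measured
  # shift cannot be produced by any r >= 0
  expect_error(permeabilityRatioFromShift(2, ctrl, test, fx),
               "inconsistent")
  notFree <- SolutionPair(IonSolution(c("Na", "Ca"), c(120, 1), c(1, 2)),
                          IonSolution("Na", 120, 1))
  expect_error(permeabilityRatioFromShift(-1, notFree, test), "Ca2\\+-free")
})

test_that("results are invariant to which limb is labeled ascending", {
  p <- presetChannelParams("cA3+hB3")
  pr <- simulateRampPair(p)
  l <- splitRampLimbs(pr$test)
  e1 <- estimateReversal(averageRamps(l$ascending, l$descending))
  e2 <- estimateReversal(averageRamps(l$descending, l$ascending))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("calibrated fixed-gamma table reproduces its anchor ratios", {
  ctrl <- standardSolutions(0)
  test <- standardSolutions(1)
  # self-consistency: anchors generated by the model itself are
  # recovered exactly (gamma_Ca is identifiable from one anchor)
  fx <- activityModel("fixed", c(Na = 0.77, Ca = 0.45, Cl = 0.77))
  dE <- ghkReversal(test, 10, fx) - ghkReversal(ctrl, 10, fx)
  cal <- calibrateGammaCa(dE, 10, ctrl, test)
  expect_equal(unname(cal@gamma["Ca"]),
               0.45 * unname(cal@gamma["Na"]) / 0.77, tolerance = 1e-3)
  rhat <- permeabilityRatio(permeabilityRatioFromShift(dE, ctrl, test, cal))
  expect_equal(rhat, 10, tolerance = 1e-4)
})
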