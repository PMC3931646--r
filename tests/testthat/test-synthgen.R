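test_that("Hill gating: half-saturation, zero-ligand and saturation limits", {
  p <- presetChannelParams("cA3")
  rs <- simulateDoseResponse(p, stepProtocol(levels = 60, duration = 50),
                             "cGMP", c(p@k05cGMP, 1e7))
  i <- vapply(sweepList(rs), steadyStateCurrent, numeric(1))
  # sweeps ordered: baseline, K0.5, saturating
  expect_equal(i[1], 0)
  expect_equal(i[2] / i[3], 0.5, tolerance = 1e-9)

  # concentration -> 0: net current -> 0 at every level
  rs0 <- simulateDoseResponse(p, stepProtocol(duration = 20), "cGMP", 1e-12)
  for (lev in c(-80, 0, 80)) {
    act <- sweepList(filterSweeps(rs0, concentration_uM = 1e-12,
                                  voltage_mV = lev))[[1]]
    expect_lt(abs(steadyStateCurrent(act)), 1e-9)
  }
})

test_that("open probability is bounded and monotone in concentration", {
  cs <- sort(stats::runif(50, 0, 5000))
  for (nh in c(1, 2.4, 4)) {
    po <- openProbability(cs, 10.3, nh)
    expect_true(all(po >= 0 & po <= 1))
    expect_true(all(diff(po) >= 0))
  }
})

test_that("noiseless currents equal the analytic gating x I-V product", {
  p <- presetChannelParams("cA3")
  pair <- standardSolutions(0)
  # independent reconstruction of the generator's unitary I-V
  base <- function(V) ghkNetCurrent(V, pair, p@pCaOverPNa)
  beta <- log(p@rectificationRatio * abs(base(60)) / abs(base(-60))) / 120
  scale <- p@unitaryConductance / 1000 /
    ((base(1e-3) - base(-1e-3)) / 2e-3)
  rs <- simulateDoseResponse(p, stepProtocol(duration = 10), "cGMP", 30)
  for (s in sweepList(filterSweeps(rs, concentration_uM = 30))) {
    V <- s@meta$voltage_mV
    expected <- p@nChannels * openProbability(30, p@k05cGMP, p@nhcGMP) *
      scale * base(V) * exp(-beta * V)
    if (abs(expected) > 0)
      expect_equal(steadyStateCurrent(s), expected, tolerance = 1e-9)
  }
})

test_that("requested rectification ratio is realized exactly", {
  for (rect in c(1.25, 1.6, 2.2)) {
    p <- ChannelParams(rectificationRatio = rect)
    rs <- simulateDoseResponse(p, stepProtocol(levels = c(-60, 60),
                                               duration = 20),
                               "cGMP", 1e6)
    i <- vapply(sweepList(filterSweeps(rs, concentration_uM = 1e6)),
                steadyStateCurrent, numeric(1))
    v <- vapply(sweepList(filterSweeps(rs, concentration_uM = 1e6)),
                function(s) s@meta$voltage_mV, numeric(1))
    expect_equal(abs(i[v == -60]) / abs(i[v == 60]), rect,
                 tolerance = 1e-6)
  }
})

test_that("fixed seed reproduces recordings bit-identically", {
  p <- presetChannelParams("cA3")
  mk <- function() simulateDoseResponse(
    p, stepProtocol(levels = -60, duration = 50), "cGMP", c(10, 100),
    noiseModel(sd = 5, leakConductance = 0.1, seed = 123))
  a <- mk(); b <- mk()
  expect_identical(lapply(sweepList(a), sweepCurrent),
                   lapply(sweepList(b), sweepCurrent))
})

test_that("cA3 preset reproduces the saturating cAMP/cGMP current ratio", {
  p <- presetChannelParams("cA3")
  noise <- noiseModel(sd = 0.02 * 450, seed = 11)   # ~2 percent of Imax
  rs <- simulatePatchSet(p, noise = noise)
  m <- patchMetrics(rs)
  expect_equal(m$efficacy, 0.19, tolerance = 0.05)
  expect_equal(m$diltiazem_ratio, 0.79, tolerance = 0.05)
})

test_that("ramp pair zero crossing sits at the forward GHK reversal", {
  ctrl <- standardSolutions(0)
  test <- standardSolutions(1)
  p <- presetChannelParams("cA3+hB3")   # PCa/PNa 17.2
  pr <- simulateRampPair(p, control = ctrl, test = test)
  truth <- ghkReversal(test, p@pCaOverPNa)
  v <- sweepVoltage(pr$test); i <- sweepCurrent(pr$test)
  o <- order(v); v <- v[o]; i <- i[o]
  k <- which(diff(sign(i)) != 0)[1]
  crossing <- v[k] + (v[k + 1] - v[k]) * (-i[k]) / (i[k + 1] - i[k])
  # within the ramp's voltage sampling resolution
  expect_lt(abs(crossing - truth), 0.01)

  # symmetric Na control, no Ca: crossing at 0 mV
  vc <- sweepVoltage(pr$control); ic <- sweepCurrent(pr$control)
  oc <- order(vc); vc <- vc[oc]; ic <- ic[oc]
  kc <- which(diff(sign(ic)) != 0)[1]
  cross0 <- vc[kc] + (vc[kc + 1] - vc[kc]) * (-ic[kc]) / (ic[kc + 1] - ic[kc])
  expect_lt(abs(cross0), 1e-6)

  # closed loop: estimate + inversion recovers the requested ratio
  erev <- vapply(pr, function(s) {
    l <- splitRampLimbs(s)
    estimateReversal(averageRamps(l$ascending, l$descending))
  }, numeric(1))
  rhat <- permeabilityRatio(permeabilityRatioFromShift(
    erev[["test"]] - erev[["control"]], ctrl, test))
  expect_equal(rhat, 17.2, tolerance = 0.02)

  # inconsistent temperatures are refused
  warm <- standardSolutions(1, temperature = 300)
  expect_error(simulateRampPair(p, control = ctrl, test = warm),
               "temperature")
})

test_that("ratio 0 with a fixed activity table leaves the crossing at 0", {
  p <- ChannelParams(pCaOverPNa = 1e-12)  # effectively impermeant Ca
  m <- activityModel("fixed", c(Na = 0.77, Ca = 0.55, Cl = 0.77))
  pr <- simulateRampPair(p, control = standardSolutions(0),
                         test = standardSolutions(1), model = m)
  v <- sweepVoltage(pr$test); i <- sweepCurrent(pr$test)
  o <- order(v); v <- v[o]; i <- i[o]
  k <- which(diff(sign(i)) != 0)[1]
  crossing <- v[k] + (v[k + 1] - v[k]) * (-i[k]) / (i[k + 1] - i[k])
  expect_lt(abs(crossing), 1e-6)
})

test_that("generator rejects invalid inputs", {
  p <- presetChannelParams("cA3")
  expect_error(simulateDoseResponse(p, stepProtocol(), "cGMP", numeric()),
               "empty")
  expect_error(simulateDoseResponse(p, stepProtocol(), "cGMP", c(10, -1)),
               "positive")
  expect_error(simulateDoseResponse(p, rampProtocol(), "cGMP", 10),
               "step protocol")
  expect_error(ChannelParams(campEfficacy = 1.2), "fraction")
  expect_error(stepProtocol(levels = 300), "200 mV")
})

test_that("sweep text format round-trips data and metadata", {
  p <- presetChannelParams("cA3")
  rs <- simulateDoseResponse(p, stepProtocol(levels = c(-60, 60),
                                             duration = 20),
                             "cGMP", 100, noiseModel(sd = 3, seed = 5))
  dir <- withr::local_tempdir()
  writeRecordingSet(rs, dir)
  back <- readRecordingSet(dir)
  expect_equal(length(back), length(rs))
  for (k in seq_len(length(rs))) {
    expect_equal(sweepCurrent(back[[k]]), sweepCurrent(rs[[k]]))
    expect_equal(back[[k]]@meta$concentration_uM,
                 rs[[k]]@meta$concentration_uM)
    expect_equal(back[[k]]@meta$voltage_mV, rs[[k]]@meta$voltage_mV)
  }
})

test_that("bundle ensembles realize requested distances and round-trip PDB", {
  sites <- data.frame(chain = "A", resno = c(1, 2),
                      resname = c("LYS", "ASP"))
  co <- array(0, dim = c(2, 3, 2))
  co[, , 1] <- rbind(c(0, 0, 0), c(3, 0, 0))
  co[, , 2] <- rbind(c(0, 0, 0), c(4, 0, 0))
  ens <- generateBundleEnsemble(bundleSpec(sites, co))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  back <- loadEnsemble(f)
  expect_equal(nFrames(back), 2)
  d1 <- sqrt(sum((frameCoords(back, 1)[1, ] - frameCoords(back, 1)[2, ])^2))
  expect_equal(d1, 3.0, tolerance = 1e-9)
  m <- meanDistanceMap(back, window = 1.0)
  expect_equal(unname(m@maps$A["ASP2", "LYS1"]), 3.5, tolerance = 1e-9)

  # frames at 2.0 and 4.0 Angstrom average to 3.0
  co24 <- co
  co24[2, 1, 1] <- 2
  e24 <- generateBundleEnsemble(bundleSpec(sites, co24))
  m24 <- meanDistanceMap(e24, window = 1.0)
  expect_equal(unname(m24@maps$A["ASP2", "LYS1"]), 3.0, tolerance = 1e-9)

  # random spec: all pairwise distances preserved through PDB I/O
  spec <- randomBundleSpec(nSites = 20, nFrames = 5, seed = 77)
  e0 <- generateBundleEnsemble(spec)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(e0, f2)
  e1 <- loadEnsemble(f2)
  for (fr in 1:5) {
    d0 <- as.matrix(stats::dist(frameCoords(e0, fr)))
    d1 <- as.matrix(stats::dist(frameCoords(e1, fr)))
    expect_lt(max(abs(d0 - d1)), 1e-3)
  }
  expect_error(bundleSpec(data.frame(chain = "A", resno = c(1, 1),
                                     resname = c("LYS", "ASP")),
                          array(0, dim = c(2, 3, 1))),
               "clashing")
})

test_that("motif FASTA generator places the Tri-Asp pattern exactly", {
  fa <- generateMotifFasta(3, motifStart = 252, length = 300, seed = 9)
  hits <- scanTriAsp(fa)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$p1 == 252 & hits$p2 == 256 & hits$p3 == 262))

  one <- generateMotifFasta(1, motifStart = 1, length = 11, seed = 2)
  h1 <- scanTriAsp(one)
  expect_equal(h1$p1, 1)

  expect_equal(length(generateMotifFasta(0, 252, 300)), 0)
  expect_error(generateMotifFasta(1, motifStart = 295, length = 300),
               "too close")
})
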