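test_that("ensemble loading: frame counts and coordinate fidelity", {
  spec <- randomBundleSpec(nSites = 10, nFrames = 5, seed = 5)
  ens <- generateBundleEnsemble(spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, f)
  back <- loadEnsemble(f)
  expect_equal(nFrames(back), 5)
  expect_equal(back@xyz, ens@xyz, tolerance = 1e-9)   # pre-quantized

  one <- generateBundleEnsemble(randomBundleSpec(4, 1, seed = 6))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(one, f1)
  expect_equal(nFrames(loadEnsemble(f1)), 1)

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(loadEnsemble(empty), "malformed|empty|frames")
  expect_error(loadEnsemble("does-not-exist.pdb"), "no such file")
})

test_that("charged-site selection follows the charge-atom rule", {
  sites <- data.frame(chain = "A", resno = c(1, 2),
                      resname = c("LYS", "ASP"))
  co <- array(rnorm(6), dim = c(2, 3, 1))
  ens <- generateBundleEnsemble(bundleSpec(sites, co))
  sel <- selectChargedSites(ens)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$elety[sel$resid == "LYS"], "NZ")
  expect_equal(sel$elety[sel$resid == "ASP"], "CG")
  expect_equal(sel$sign, c(1, -1))

  # ensemble with no charged residues
  atoms <- data.frame(chain = "A", resno = 1, resid = "GLY", elety = "CA")
  gly <- new("StructureEnsemble", atoms = atoms,
             xyz = matrix(0, 1, 3), midplaneZ = 0)
  expect_equal(nrow(selectChargedSites(gly)), 0)

  # Asp lacking its CG atom: zero sites, one warning record
  atoms2 <- data.frame(chain = "A", resno = 1, resid = "ASP",
                       elety = "CB")
  bad <- new("StructureEnsemble", atoms = atoms2,
             xyz = matrix(0, 1, 3), midplaneZ = 0)
  expect_warning(sel2 <- selectChargedSites(bad), "charge atom")
  expect_equal(nrow(sel2), 0)
  expect_equal(nrow(attr(sel2, "missing")), 1)
  expect_equal(attr(sel2, "missing")$missing_atom, "CG")
})

test_that("mean distance map equals the brute-force oracle", {
  for (seed in 1:3) {
    spec <- randomBundleSpec(nSites = 20, nFrames = 5,
                             chains = c("A", "B"), seed = seed)
    ens <- generateBundleEnsemble(spec)
    sites <- selectChargedSites(ens)
    frames <- 4:5  # trailing window
    map <- meanDistanceMap(ens, sites, window = frames)
    for (ch in names(map@maps)) {
      sub <- sites[sites$chain == ch, , drop = FALSE]
      oracle <- oracleMeanDistances(ens, sub, frames)
      expect_equal(map@maps[[ch]],
                   oracle[rownames(map@maps[[ch]]),
                          colnames(map@maps[[ch]]), drop = FALSE],
                   tolerance = 1e-12)
    }
    # pairing = "all" against the oracle over all sites (site labels can
    # repeat across chains, so compare by position, not name)
    mapAll <- meanDistanceMap(ens, sites, window = frames,
                              pairing = "all")
    oracleAll <- oracleMeanDistances(ens, sites, frames)
    expect_equal(unname(mapAll@maps$all), unname(oracleAll),
                 tolerance = 1e-12)
  }
})

test_that("distance map is invariant to frame order and rigid motion", {
  spec <- randomBundleSpec(nSites = 12, nFrames = 6, seed = 8)
  ens <- generateBundleEnsemble(spec)
  sites <- selectChargedSites(ens)
  m0 <- meanDistanceMap(ens, sites, window = 1.0)

  # permute frames (full window: mean is order-free)
  perm <- ens
  perm@xyz <- ens@xyz[c(3, 1, 6, 2, 5, 4), , drop = FALSE]
  m1 <- meanDistanceMap(perm, sites, window = 1.0)
  expect_equal(m1@maps, m0@maps, tolerance = 1e-12)

  # rigid rotation + translation of every frame
  R <- oracleRotation(c(1, 2, 3), 0.7)
  moved <- applyRigid(ens, R, c(5, -3, 12))
  m2 <- meanDistanceMap(moved, sites, window = 1.0)
  for (ch in names(m0@maps))
    expect_equal(m2@maps[[ch]], m0@maps[[ch]], tolerance = 1e-6)

  # full-window mean equals the mean of per-frame maps
  perFrame <- lapply(1:6, function(f)
    meanDistanceMap(ens, sites, window = c(f, f))@maps[[1]])
  expect_equal(Reduce(`+`, perFrame) / 6, m0@maps[[1]],
               tolerance = 1e-12)

  # single-frame averaging returns that frame's distances
  d2 <- meanDistanceMap(ens, sites, window = c(2, 2))
  oracle2 <- oracleMeanDistances(ens, sites[sites$chain == "A", ], 2)
  expect_equal(d2@maps[["A"]], oracle2, tolerance = 1e-12)

  expect_error(meanDistanceMap(ens, sites, window = 7L), "frame range")
})

test_that("salt-bridge calling uses a closed threshold and sorts stably", {
  sites <- data.frame(chain = "A", resno = 1:4,
                      resname = c("LYS", "ASP", "ARG", "GLU"))
  co <- array(0, dim = c(4, 3, 1))
  co[, , 1] <- rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0), c(14, 0, 0))
  ens <- generateBundleEnsemble(bundleSpec(sites, co))
  map <- meanDistanceMap(ens, window = 1.0)
  br <- detectSaltBridges(map, cutoff = 4.0)
  # ASP2-LYS1 at 3.0 and GLU4-ARG3 at 4.0 (exactly at the cutoff)
  expect_equal(nrow(br), 2)
  expect_equal(br$mean_distance_A, c(3, 4))
  expect_equal(br$res_neg, c("ASP2", "GLU4"))
  expect_error(detectSaltBridges(map, cutoff = 0), "positive")

  # dense random map equals a brute-force filter
  ens2 <- generateBundleEnsemble(randomBundleSpec(24, 4, seed = 12,
                                                  box = c(8, 8, 8)))
  map2 <- meanDistanceMap(ens2, window = 1.0)
  br2 <- detectSaltBridges(map2, cutoff = 6)
  tab <- distanceMapTable(map2)
  expect_equal(nrow(br2), sum(tab$mean_distance_A <= 6))
  expect_true(all(br2$mean_distance_A <= 6))
  expect_true(!is.unsorted(br2$mean_distance_A))
})

test_that("cluster partition matches union-find and labels by depth", {
  # two disjoint bridged pairs, one above and one below the midplane
  sites <- data.frame(chain = "A", resno = 1:4,
                      resname = c("LYS", "ASP", "ARG", "GLU"))
  co <- array(0, dim = c(4, 3, 1))
  co[, , 1] <- rbind(c(0, 0, 10), c(3, 0, 10),
                     c(0, 0, -10), c(3, 0, -10))
  ens <- generateBundleEnsemble(bundleSpec(sites, co, midplaneZ = 0))
  sel <- selectChargedSites(ens)
  map <- meanDistanceMap(ens, sel, window = 1.0)
  cl <- partitionClusters(detectSaltBridges(map, 4), sel, ens)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$label[cl$resno %in% 1:2],
               rep("extracellular", 2))
  expect_equal(cl$label[cl$resno %in% 3:4],
               rep("intracellular", 2))

  # empty bridge list: every site its own singleton cluster
  cl0 <- partitionClusters(detectSaltBridges(map, 0.1), sel, ens)
  expect_equal(length(unique(cl0$cluster)), 4)

  # random graph vs an independent union-find oracle
  ens2 <- generateBundleEnsemble(randomBundleSpec(30, 3, seed = 21,
                                                  box = c(10, 10, 10)))
  sel2 <- selectChargedSites(ens2)
  map2 <- meanDistanceMap(ens2, sel2, window = 1.0)
  br2 <- detectSaltBridges(map2, 7)
  cl2 <- partitionClusters(br2, sel2, ens2)
  keys <- paste(sel2$chain, paste0(sel2$resid, sel2$resno), sep = ":")
  edges <- cbind(paste(br2$chain, br2$res_neg, sep = ":"),
                 paste(br2$chain, br2$res_pos, sep = ":"))
  oracle <- oracleComponents(keys, edges)
  # same partition up to component relabeling
  expect_equal(length(unique(cl2$cluster)), length(unique(oracle)))
  expect_true(all(tapply(oracle, cl2$cluster,
                         function(x) length(unique(x))) == 1))
})

test_that("extracellular cluster membership of the charged bundle fixture", {
  # upper (extracellular) and lower (intracellular) charge clusters of
  # an S1-S4-like bundle; numbering follows the canine A3 subunit
  upper <- data.frame(
    chain = "P4",
    resno = c(266, 286, 221, 225, 288, 264, 291, 259, 294, 297),
    resname = c("ASP", "GLU", "ASP", "ASP", "ARG", "LYS", "ARG", "LYS",
                "LYS", "ARG"),
    helix = c(1, 2, 2, 2, 3, 1, 3, 3, 4, 4),
    z = 12)
  lower <- data.frame(
    chain = "P4",
    resno = c(231, 300, 303, 249, 255, 252, 304, 248, 235, 237),
    resname = c("ASP", "GLU", "GLU", "ASP", "LYS", "ARG", "ARG", "LYS",
                "ARG", "ARG"),
    helix = c(2, 4, 4, 3, 3, 3, 4, 3, 2, 2),
    z = -12)
  spec <- fourHelixBundle(rbind(upper, lower), nFrames = 4, radius = 4,
                          jitter = 0.1, midplaneZ = 0, seed = 33)
  ens <- generateBundleEnsemble(spec)
  sel <- selectChargedSites(ens)
  map <- meanDistanceMap(ens, sel, window = 1.0)
  cl <- partitionClusters(detectSaltBridges(map, 8), sel, ens)
  expect_equal(unique(cl$label[cl$resno %in% upper$resno]),
               "extracellular")
  expect_equal(unique(cl$label[cl$resno %in% lower$resno]),
               "intracellular")
  # the two depth groups never merge into one component
  expect_gte(length(unique(cl$cluster)), 2)
})
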