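# The synthetic-patient generator: geometry, fields, observations, contracts.

test_that("prostate meshes are valid, deterministic, and sized as requested", {
  m1 <- makeProstateMesh(c(12, 10, 11), elementSize = 5)
  m2 <- makeProstateMesh(c(12, 10, 11), elementSize = 5)
  expect_identical(m1@nodes, m2@nodes)
  expect_identical(m1@tets, m2@tets)
  expect_true(validObject(m1))
  expect_error(makeProstateMesh(c(12, 0, 11)), "positive")
  expect_error(makeProstateMesh(c(12, 10, 11), elementSize = -1), "> 0")
})

test_that("lesion mask volume approximates the sphere volume", {
  m <- makeProstateMesh(c(14, 12, 13), elementSize = 2.5)
  r <- 6
  f <- makeBiomarkerFields(m, tumourCentre = c(0, -3, 0), tumourRadius = r,
                           seed = 1)
  maskVol <- regionSummary(m, rep(0, nElements(m)), f$mask)$volume
  expect_lt(abs(maskVol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.1)
})

test_that("biomarker fields honour their levels, noise switch and seed", {
  m <- makeProstateMesh(c(12, 10, 11), elementSize = 5)
  # zero noise: piecewise-constant fields at the requested levels
  f0 <- makeBiomarkerFields(m, c(0, -2, 0), 5, cellularityNoise = 0,
                            ktransLogSD = 0, seed = 2)
  expect_equal(sort(unique(f0$cellularity)), c(0.5, 0.6))
  expect_equal(unique(f0$ktrans), 15000)
  expect_equal(f0$cellularity[f0$mask], rep(0.6, sum(f0$mask)))

  # reproducible per seed; different seeds differ
  fa <- makeBiomarkerFields(m, c(0, -2, 0), 5, seed = 7)
  fb <- makeBiomarkerFields(m, c(0, -2, 0), 5, seed = 7)
  fc <- makeBiomarkerFields(m, c(0, -2, 0), 5, seed = 8)
  expect_identical(fa$cellularity, fb$cellularity)
  expect_false(identical(fa$cellularity, fc$cellularity))
  expect_true(all(fa$ktrans > 0))
  expect_true(all(fa$cellularity >= 0 & fa$cellularity <= 1))

  expect_error(makeBiomarkerFields(m, c(100, 0, 0), 5, seed = 1),
               "no element centroid")
})

test_that("tumour cellularity exceeds prostate cellularity by construction", {
  m <- makeProstateMesh(c(12, 10, 11), elementSize = 5)
  higher <- vapply(1:50, function(s) {
    f <- makeBiomarkerFields(m, c(0, -2, 0), 5, seed = s)
    mean(f$cellularity[f$mask]) > mean(f$cellularity)
  }, logical(1))
  expect_gte(mean(higher), 0.95)
})

test_that("observations are exact without noise and non-negative with it", {
  pat <- smallPatient()
  true <- modelParams()
  obs <- makeObservations(pat, true, followUpDates = c(50, 100), seed = 9)
  fu <- obs$patient@followUp
  ref <- summarizeAt(obs$trajectory, c(50, 100))
  expect_equal(fu$prostateVolume, ref$prostateVolume)
  expect_equal(fu$tumourVolume, ref$tumourVolume)
  expect_equal(fu$tumourCellularity, ref$tumourCellularity)
  # appended PSA measurements equal the simulated serum values
  post <- obs$patient@psaDates > 0
  expect_equal(obs$patient@psaValues[post],
               summarizeAt(obs$trajectory,
                           obs$patient@psaDates[post])$serumPSA)

  # with noise: perturbed but physical
  obsN <- makeObservations(pat, true, followUpDates = c(50, 100),
                           volumeNoise = 0.1, cellularityNoise = 0.05,
                           psaNoise = 0.5, seed = 9)
  expect_false(identical(obsN$patient@followUp$prostateVolume,
                         fu$prostateVolume))
  expect_true(all(obsN$patient@psaValues >= 0))
  expect_true(all(obsN$patient@followUp$prostateCellularity >= 0))
  expect_error(makeObservations(pat, true, followUpDates = c(-10, 50)),
               "> 0")
})

test_that("generated patients satisfy every downstream precondition", {
  for (s in c(2, 12)) {
    pat <- smallPatient(seed = s)
    expect_true(validObject(pat))
    expect_true(any(pat@tumourMask) && any(!pat@tumourMask))
    expect_true(all(pat@ktrans >= 0))
    expect_gte(pat@pt, 0)
    # the full loop runs on it
    traj <- simulateGrowth(pat, modelParams(), simConfig(tFinal = 20))
    expect_s4_class(traj, "Trajectory")
    expect_true(all(is.finite(as.matrix(observables(traj)))))
  }
})
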