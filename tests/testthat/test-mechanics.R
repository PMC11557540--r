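# Growth kinematics, mixture stiffness, and the incremental FE solve.

test_that("growth stretch law follows its two branches", {
  mech <- tableMech
  k <- 0.57
  # no mass change -> no stretch
  expect_equal(growthStretch(1, 1, 1, mech, k), 1)
  # 10% mass loss with kd1 = 3 -> lambda = 0.7
  expect_equal(growthStretch(0.9, 1, 1, mech, k), 0.7)
  # saturated growth branch tends to kv1 + kv2 = 1.05
  expect_equal(growthStretch(50 * 0.57, 1, 1, mech, k), 1.05, tolerance = 1e-3)
  # severe loss is floored
  expect_equal(growthStretch(0.1, 1, 1, mech, k), 0.1)
  # continuity-rescaled branch starts from 1
  expect_equal(growthStretch(1 + 1e-12, 1, 1e3, mech, k, continuous = TRUE),
               1, tolerance = 1e-6)
})

test_that("element eigenstrain aggregates stretches by grown volume fraction", {
  caps <- tableCaps
  # all constituents unstretched
  dT0 <- elementEigenstrain(list(t = 1, h = 1, s = 1),
                            list(rhoT = 100, rhoH = 100, rhoS = 0.5), caps)
  expect_equal(dT0, 0)
  # single constituent: dT = lambda - 1 and Jg = lambda^3
  dT <- elementEigenstrain(list(t = 1.05, h = 1, s = 1),
                           list(rhoT = 500, rhoH = 0, rhoS = 0), caps)
  expect_equal(dT, 0.05)
  expect_equal((1 + dT)^3, 1.05^3)
  # empty element
  expect_equal(elementEigenstrain(list(t = 2, h = 2, s = 2),
                                  list(rhoT = 0, rhoH = 0, rhoS = 0), caps), 0)
})

test_that("mixture modulus weighs constituents by capacity fraction", {
  caps <- tableCaps
  mech <- tableMech
  expect_equal(mixtureModulus(list(rhoT = 0, rhoH = 0, rhoS = caps@rhoCS),
                              caps, mech), 30)
  expect_equal(mixtureModulus(list(rhoT = 0, rhoH = caps@rhoCH,
                                   rhoS = caps@rhoCS), caps, mech), 35)
  # floor guard
  expect_equal(mixtureModulus(list(rhoT = 0, rhoH = 0, rhoS = 0), caps, mech),
               mech@Emin)
})

test_that("free uniform expansion is stress-free with J = (1+dT)^3", {
  m <- makeProstateMesh(c(8, 7, 7.5), elementSize = 3)
  ne <- nElements(m)
  mech <- mechanicsParams(Kstiffness = 0, Ktangential = 0)
  dT <- 0.05
  sol <- solveElasticity(m, rep(dT, ne), rep(10, ne), mech, pinRigid = TRUE)
  expect_equal(sol$J, rep((1 + dT)^3, ne), tolerance = 1e-3)
  expect_equal(sol$Je, rep(1, ne), tolerance = 1e-3)
  # stresses vanish relative to E * dT
  expect_lt(max(abs(sol$stress)), 1e-3 * 10 * dT)
  # without springs or pinning the system is singular
  expect_error(solveElasticity(m, rep(dT, ne), rep(10, ne), mech),
               "singular system")
})

test_that("sphere with foundation springs matches the radial closed form", {
  R0 <- 10; E <- 10; nu <- 0.4; Kf <- 14; dT <- 0.05
  m <- makeProstateMesh(c(R0, R0, R0), elementSize = 2.5)
  ne <- nElements(m)
  mech <- mechanicsParams(Eh = E, nu = nu, Kstiffness = Kf,
                          Ktangential = 1e-6 * Kf)
  sol <- solveElasticity(m, rep(dT, ne), rep(E, ne), mech)
  # closed form: u = A r with A = 3 Kb dT / (3 Kb + Kf R)
  Kb <- E / (3 * (1 - 2 * nu))
  A <- 3 * Kb * dT / (3 * Kb + Kf * R0)
  r <- sqrt(rowSums(m@nodes^2))
  sel <- r > 0.5 * R0
  ur <- rowSums(sol$u * m@nodes)[sel] / r[sel]
  expect_equal(median(ur / r[sel]), A, tolerance = 0.02)
})

test_that("superposed cellular/stromal assemblies equal the mixture assembly", {
  set.seed(7)
  m <- makeProstateMesh(c(7, 6, 6.5), elementSize = 3)
  ne <- nElements(m)
  caps <- tableCaps
  mech <- tableMech
  dens <- list(rhoT = runif(ne) * caps@rhoCT * 0.3,
               rhoH = runif(ne) * caps@rhoCH * 0.5,
               rhoS = runif(ne) * caps@rhoCS * 0.6)
  dT <- runif(ne, -0.02, 0.05)
  Emix <- mixtureModulus(dens, caps, mech)
  Ecells <- mech@Et * dens$rhoT / caps@rhoCT + mech@Eh * dens$rhoH / caps@rhoCH
  Estroma <- mech@Es * dens$rhoS / caps@rhoCS
  s1 <- solveElasticity(m, dT, Emix, mech)
  s2 <- solveElasticity(m, dT, list(Ecells, Estroma), mech)
  expect_equal(s2$u, s1$u, tolerance = 1e-10)
  expect_equal(s2$J, s1$J, tolerance = 1e-10)

  # degenerate single-material case
  s3 <- solveElasticity(m, dT, list(Emix, 0 * Emix + 0), mech)
  expect_equal(s3$u, s1$u, tolerance = 1e-10)
})

test_that("density update conserves mass across the elastic map", {
  m <- makeProstateMesh(c(7, 6, 6.5), elementSize = 3)
  ne <- nElements(m)
  set.seed(1)
  dT <- runif(ne, -0.05, 0.05)
  E <- runif(ne, 5, 30)
  sol <- solveElasticity(m, dT, E, tableMech)
  rhoG <- list(rhoT = runif(ne) * 1e3)
  rho <- updateDensities(rhoG, sol$Je)
  V0 <- elementVolumes(m)
  V <- elementVolumes(tetMesh(sol$newNodes, m@tets))
  expect_equal(sum(rhoG$rhoT * V0 * sol$Jg), sum(rho$rhoT * V),
               tolerance = 1e-10)
  # simple division identity
  expect_equal(updateDensities(list(x = 1000), 1.05^3)$x, 1000 / 1.157625)
  expect_error(updateDensities(list(x = 1), c(0, 1)), "Je must be > 0")
})

test_that("cached and uncached elasticity solves agree", {
  m <- makeProstateMesh(c(7, 6, 6.5), elementSize = 3)
  ne <- nElements(m)
  set.seed(2)
  dT <- runif(ne, 0, 0.03)
  E <- runif(ne, 5, 30)
  cache <- new.env(parent = emptyenv())
  s1 <- solveElasticity(m, dT, E, tableMech)
  s2 <- solveElasticity(m, dT, E, tableMech, cache = cache)
  s3 <- solveElasticity(m, dT, E, tableMech, cache = cache)  # update path
  expect_equal(s2$u, s1$u, tolerance = 1e-12)
  expect_equal(s3$u, s1$u, tolerance = 1e-12)
})
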