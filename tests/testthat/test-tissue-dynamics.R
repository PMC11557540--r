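# Constituent reaction dynamics and per-element oxygen equilibria.

test_that("reaction rate implements gated logistic growth and hypoxic death", {
  g <- tableGrowth
  caps <- tableCaps

  # quiescence: oxygen between the death and proliferation thresholds
  expect_equal(reactionRate(1200, 3200, "t", g, caps), 0)
  # saturation: density at the corrected capacity, abundant oxygen
  expect_equal(reactionRate(g@k * caps@rhoCT, 4124, "t", g, caps), 0)
  # worked value: tumour cells, rho 1200, abundant oxygen
  expect_equal(reactionRate(1200, 4124, "t", g, caps),
               1200 * 4.03e-3 * (57000 - 1200) / 57000, tolerance = 1e-12)
  # healthy cells proliferate at half the rate (beta damping)
  expect_equal(reactionRate(1200, 4124, "h", g, caps),
               1200 * 4.03e-3 / 2 * (g@k * caps@rhoCH - 1200) /
                 (g@k * caps@rhoCH))
  # hypoxia: first-order death
  expect_equal(reactionRate(1000, 100, "t", g, caps), -1000 * g@kd)
  # Heaviside convention H(0) = 0: no proliferation or death exactly at the
  # thresholds
  expect_equal(reactionRate(1000, g@thetaP[["t"]], "t", g, caps), 0)
  expect_equal(reactionRate(1000, g@thetaD[["t"]], "t", g, caps), 0)
})

test_that("population steps stay within [0, k rho_c] and converge logistically", {
  g <- tableGrowth
  caps <- tableCaps
  dens <- list(rhoT = 1200, rhoH = 30e3, rhoS = 0.5)

  # oxygen inside the quiescent band of every constituent present (healthy:
  # 3300-4000, stroma: 3900-4000)
  dq <- populationStep(list(rhoT = 0, rhoH = 30e3, rhoS = 0.5), 3950, 10, g, caps)
  expect_equal(dq, list(rhoT = 0, rhoH = 30e3, rhoS = 0.5))

  # deep hypoxia: every constituent decays by 1 - kd dt = 0.8
  dd <- populationStep(dens, 0, 10, g, caps)
  expect_equal(unname(unlist(dd)), 0.8 * unname(unlist(dens)))

  # abundant oxygen: tumour density converges to k rhoCT and never exceeds it
  rho <- 1200
  for (i in 1:2000)
    rho <- populationStep(list(rhoT = rho, rhoH = 0, rhoS = 0), 4124, 10,
                          g, caps)$rhoT
  expect_equal(rho, g@k * caps@rhoCT, tolerance = 1e-6)

  # a density initialized above the corrected capacity relaxes instead of
  # being truncated
  over <- 1.1 * g@k * caps@rhoCH
  o1 <- populationStep(list(rhoT = 0, rhoH = over, rhoS = 0), 4124, 10,
                       g, caps)$rhoH
  expect_lt(o1, over)
  expect_gt(o1, g@k * caps@rhoCH)
})

test_that("oxygen equilibrium solves the supply/consumption balance", {
  ox <- tableOxygen
  caps <- tableCaps

  # acellular perfused element equilibrates exactly at the blood level
  expect_identical(
    oxygenEquilibrium(list(rhoT = 0, rhoH = 0, rhoS = 0), 1.44, ox, caps),
    ox@rhoBO)
  # avascular element stays at zero
  expect_equal(
    oxygenEquilibrium(list(rhoT = 100, rhoH = 0, rhoS = 0), 0, ox, caps), 0)

  # full tumour at KTrans = 1/day: equals the positive root found by an
  # independent bracketing root solver
  dens <- list(rhoT = caps@rhoCT, rhoH = 0, rhoS = 0)
  got <- oxygenEquilibrium(dens, 1, ox, caps)
  oracle <- uniroot(function(x) 1 * (ox@rhoBO - x) -
                      ox@Ao[["t"]] * x / (ox@ko[["t"]] + x),
                    c(0, ox@rhoBO), tol = 1e-12)$root
  expect_equal(got, oracle, tolerance = 1e-8)

  # monotonicity: more cells -> less oxygen
  fr <- seq(0, 1, by = 0.1)
  eq <- oxygenEquilibrium(list(rhoT = fr * caps@rhoCT, rhoH = fr * caps@rhoCH,
                               rhoS = fr * 0), rep(5000, 11), ox, caps)
  expect_true(all(diff(eq) < 0))
  expect_true(all(eq > 0 & eq <= ox@rhoBO))
})

test_that("time-marching oxygen transport agrees with the algebraic root", {
  ox <- tableOxygen
  caps <- tableCaps
  set.seed(42)
  n <- 8
  dens <- list(rhoT = runif(n) * caps@rhoCT, rhoH = runif(n) * caps@rhoCH,
               rhoS = numeric(n))
  kt <- 10^runif(n, 0, 4)
  alg <- oxygenEquilibrium(dens, kt, ox, caps, method = "algebraic")
  mar <- oxygenEquilibrium(dens, kt, ox, caps, method = "marching")
  expect_equal(mar, alg, tolerance = 1e-6)
})
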