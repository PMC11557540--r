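# PSA exponential trend fitting and the multiscale tissue/serum scheme.

test_that("exponential PSA fits are exact on exact data", {
  t <- c(0, 100, 300)
  f <- fitExponentialPSA(t, 2 * exp(0.001 * t))
  expect_equal(f$a, 2, tolerance = 1e-10)
  expect_equal(f$b, 0.001, tolerance = 1e-10)
  expect_equal(f$predict(200), 2 * exp(0.2), tolerance = 1e-9)

  # constant series -> flat trend
  fc <- fitExponentialPSA(c(0, 50, 80), c(3, 3, 3))
  expect_equal(c(fc$a, fc$b), c(3, 0))

  expect_error(fitExponentialPSA(0, 4), "at least two")
  expect_error(fitExponentialPSA(c(0, 10), c(1, -2)), "> 0")
  expect_error(fitExponentialPSA(c(10, 0), c(1, 2)), "increasing")
})

test_that("noisy exponential trends are recovered within their standard error", {
  t <- seq(0, 550, by = 50)
  b <- 1.5e-3
  cover <- vapply(1:200, function(s) {
    set.seed(s)
    y <- 4 * exp(b * t) * exp(rnorm(length(t), 0, 0.2))
    f <- fitExponentialPSA(t, y)
    abs(f$b - b) < 3 * f$se_b
  }, logical(1))
  expect_gte(mean(cover), 0.99)
})

test_that("tissue PSA initialization solves the per-element equilibrium", {
  caps <- tableCaps
  # no production, gamma = 0: tissue equals serum
  p0 <- psaParams(alphaT = 1e-9, alphaH = 0, gamma = 0, gammaS = 0, warn = FALSE)
  expect_equal(initTissuePSA(4, list(rhoT = 0, rhoH = 0), 1, p0, caps), 4)
  # avascular element: P = S / gamma
  p1 <- psaParams(alphaT = 0.5, alphaH = 0, gamma = 0.01, warn = FALSE)
  expect_equal(initTissuePSA(4, list(rhoT = caps@rhoCT, rhoH = 0), 0, p1, caps),
               0.5 / 0.01)
  # worked value: S = 0.1, KTrans = 1, gamma = 1, Ps0 = 4 -> (0.1 + 4)/2
  p2 <- psaParams(alphaT = 0.1, alphaH = 0, gamma = 1, warn = FALSE)
  expect_equal(initTissuePSA(4, list(rhoT = caps@rhoCT, rhoH = 0), 1, p2, caps),
               2.05)
  expect_error(initTissuePSA(4, list(rhoT = 0, rhoH = 0), 0, p0, caps),
               "zero in element")
})

test_that("the three-substep PSA scheme conserves and stays consistent", {
  caps <- tableCaps
  # no production, no decay, single element: P and Ps persist
  p0 <- psaParams(alphaT = 1e-9, alphaH = 0, gamma = 0, gammaS = 0, warn = FALSE)
  st <- psaStep(P = 5, densities = list(rhoT = 0, rhoH = 0), ktrans = 2,
                volumes = 1, dt = 10, psa = p0, caps = caps)
  expect_equal(st$Pstar, 5)
  expect_equal(st$Ps, 5)
  expect_equal(st$P, 5)

  # zero state with zero sources stays zero
  z <- psaStep(0, list(rhoT = 0, rhoH = 0), 2, 1, 10, p0, caps)
  expect_equal(c(z$P, z$Ps), c(0, 0))

  # equilibrium consistency: after substep 4.3 the element equation vanishes
  psa <- psaParams(warn = FALSE)
  set.seed(3)
  dens <- list(rhoT = runif(5) * caps@rhoCT * 0.1, rhoH = runif(5) * caps@rhoCH)
  kt <- runif(5, 1000, 20000)
  st2 <- psaStep(runif(5, 2, 6), dens, kt, runif(5, 5, 20), 10, psa, caps)
  S <- psa@alphaH * dens$rhoH / caps@rhoCH + psa@alphaT * dens$rhoT / caps@rhoCT
  resid <- S - kt * (st2$P - st2$Ps) - psa@gamma * st2$P
  expect_equal(max(abs(resid)), 0, tolerance = 1e-10)

  # monotonicity: a higher tumour production rate never lowers serum PSA
  psaHi <- psaParams(alphaT = 2 * psa@alphaT, alphaH = psa@alphaH,
                     gamma = psa@gamma, gammaS = psa@gammaS, warn = FALSE)
  stHi <- psaStep(runif(5, 2, 6), dens, kt, runif(5, 5, 20), 10, psaHi, caps)
  set.seed(3)  # same P and volumes draws
  dens2 <- list(rhoT = runif(5) * caps@rhoCT * 0.1, rhoH = runif(5) * caps@rhoCH)
  expect_gte(stHi$Ps, st2$Ps)
})

test_that("iterated psaStep converges to its algebraic fixed point", {
  # single element, fixed densities. Eliminating P* from the three substeps,
  # the scheme's fixed point solves the linear system
  #   (K + gamma) P - K Ps            = S
  #   (1 + K dt) gamma P + gammaS Ps  = (1 + K dt) S
  # (independent derivation; note this is NOT the steady state of the
  # two-compartment ODE pair - the stationary serum substep slaves serum to
  # tissue, so the fixed point sits at P ~ S/gamma when K dt >> 1).
  caps <- tableCaps
  psa <- psaParams(warn = FALSE)
  dens <- list(rhoT = 0.1 * caps@rhoCT, rhoH = 0.5 * caps@rhoCH)
  K <- 5000
  dt <- 10
  S <- psa@alphaH * 0.5 + psa@alphaT * 0.1
  A <- rbind(c(K + psa@gamma, -K),
             c((1 + K * dt) * psa@gamma, psa@gammaS))
  fix <- solve(A, c(S, (1 + K * dt) * S))
  P <- 4; Ps <- 4
  for (i in 1:20000) {  # relaxation rate is gamma * dt per step
    st <- psaStep(P, dens, K, 1, dt, psa, caps)
    P <- st$P; Ps <- st$Ps
  }
  expect_equal(P, fix[1], tolerance = 1e-6)
  expect_equal(Ps, fix[2], tolerance = 1e-6)
  expect_equal(P, S / psa@gamma, tolerance = 0.02)
})
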