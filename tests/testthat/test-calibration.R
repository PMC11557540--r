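# Objectives, the trial sampler, Pareto selection and stage separation.

test_that("objective functions match hand arithmetic", {
  expect_equal(relativeErrorObjective(c(2), c(2)), 0)
  expect_equal(relativeErrorObjective(2, 1), 0.5)
  expect_equal(relativeErrorObjective(c(10, 0.5), c(9, 0.6)), 0.15)
  expect_warning(e <- relativeErrorObjective(c(2, 0), c(1, 5)), "excluded")
  expect_equal(e, 0.5)
  expect_error(relativeErrorObjective(1:3, 1:2), "must match")

  expect_equal(maeObjective(c(4, 5), c(4, 5)), 0)
  expect_equal(maeObjective(c(4, 5), c(5, 5)), 0.5)
  expect_equal(maeObjective(c(4, 5, 6), c(4.3, 4.4, 6.9)), 0.6)
})

test_that("the search is reproducible and handles a collapsed space", {
  space <- data.frame(name = c("a", "b"), lower = c(0, 1), upper = c(1, 100),
                      log = c(FALSE, TRUE))
  fn <- function(p) (p[["a"]] - 0.3)^2 + (log10(p[["b"]]) - 1)^2
  r1 <- tpeMinimize(fn, space, 25, seed = 9)
  r2 <- tpeMinimize(fn, space, 25, seed = 9)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$scores, r2$scores)

  # collapsed space: every trial evaluates the same point
  pt <- data.frame(name = c("a", "b"), lower = c(0.4, 2), upper = c(0.4, 2),
                   log = FALSE)
  rp <- tpeMinimize(fn, pt, 8, seed = 1)
  expect_true(all(rp$params$a == 0.4 & rp$params$b == 2))
  expect_equal(diff(range(rp$scores)), 0)

  # failing trials are scored +Inf and the search continues
  fb <- function(p) if (p[["a"]] > 0.8) stop("boom") else p[["a"]]
  rf <- tpeMinimize(fb, space, 15, seed = 2)
  expect_true(any(is.infinite(rf$scores)))
  expect_true(min(rf$scores) < 0.2)
})

test_that("the adaptive sampler beats uniform random search", {
  # smooth curved-valley objective over the growth-parameter box, the same
  # geometry the calibration objective exhibits
  space <- growthParameterSpace()
  fn <- function(p) {
    log(p[["kg"]] / 4.03e-3)^2 + 25 * (p[["k"]] - 0.57)^2 +
      40 * ((p[["k"]] - 0.57) * log(p[["kg"]] / 1e-3))^2 +
      8 * (p[["kv2"]] - 0.08)^2
  }
  wins <- vapply(1:10, function(s) {
    tpe <- min(tpeMinimize(fn, space, 40, seed = s, sampler = "tpe")$scores)
    unif <- min(tpeMinimize(fn, space, 40, seed = s, sampler = "random")$scores)
    tpe < unif
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("Pareto front and min-max selection follow their definitions", {
  fn <- function(p) c(p[["a"]], 1 - p[["a"]])  # the whole diagonal is Pareto
  space <- data.frame(name = "a", lower = 0, upper = 1, log = FALSE)
  r <- tpeMinimize(fn, space, 12, seed = 3)
  expect_equal(sort(r$pareto), seq_len(12))
  # min-max selection picks the trial closest to a = 0.5
  expect_equal(r$best, which.min(abs(r$params$a - 0.5)))

  # dominated rows are excluded
  M <- rbind(c(1, 1), c(2, 2), c(0.5, 3))
  expect_equal(prostasim:::.paretoFront(M), c(1, 3))
})

test_that("growth calibration improves on the starting trials and PSA stage keeps growth fixed", {
  pat <- smallPatient()
  true <- setModelParams(modelParams(), c(kg = 6e-3, k = 0.6, alphaT = 0.1,
                                          alphaH = 5e-3, gamma = 2e-3,
                                          gammaS = 2e-3))
  pat <- makeObservations(pat, true, followUpDates = c(100, 200), seed = 4)$patient
  s1 <- optimizeGrowth(list(pat), nTrials = 14, seed = 5)
  expect_true(is.finite(min(s1$scores)))
  # the adaptive phase improves on the best warm-up trial
  expect_lte(min(s1$scores), min(s1$scores[1:10]))
  expect_true(all(c("kg", "k", "Kstiffness", "kv2") %in% names(s1$selected)))

  s2 <- optimizePSA(list(pat), nTrials = 12, seed = 5,
                    baseParams = s1$selectedParams)
  # stage separation: growth parameters are untouched by stage 2
  expect_identical(s2$selectedParams@growth, s1$selectedParams@growth)
  expect_identical(s2$selectedParams@mechanics, s1$selectedParams@mechanics)
  expect_true(is.finite(min(s2$scores)))
})
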