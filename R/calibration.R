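# Two-stage multi-objective calibration. Stage 1 fits the growth parameters
# (kg, k, Kstiffness, kv2) by minimizing, per patient, the mean relative
# error between simulated and observed follow-up targets (prostate volume,
# tumour volume, mean prostate and tumour cellularity). Stage 2 fixes those
# and fits the PSA parameters (alphaT, alphaH, gamma, gammaS) by minimizing
# the per-patient mean absolute error against the serum PSA series. The
# sampler is a tree-structured Parzen estimator (Latin-hypercube warm-up,
# covariance-aligned candidate proposals scored by the good/bad density
# ratio) finished by a budgeted Nelder-Mead tail; a pure random sampler is
# available as baseline.

#' Mean relative error objective
#'
#' E = (1/n) sum |obs - sim| / |obs| over all targets at all follow-ups.
#' Zero observed values are excluded with a warning (their relative error is
#' undefined).
#'
#' @param observed,simulated matched numeric vectors.
#' @return scalar >= 0; 0 iff simulated == observed on all usable targets.
#' @examples
#' relativeErrorObjective(c(10, 0.5), c(9, 0.6))  # 0.15
#' @export
relativeErrorObjective <- function(observed, simulated) {
  if (length(observed) != length(simulated)) stop("target lists must match")
  keep <- observed != 0
  if (!all(keep)) warning(sum(!keep), " zero observed value(s) excluded")
  if (!any(keep)) stop("no usable targets")
  mean(abs(observed[keep] - simulated[keep]) / abs(observed[keep]))
}

#' Mean absolute error objective
#'
#' MAE = (1/n) sum |obs - sim| (ng/mL); robust to the substantial variability
#' of clinical PSA measurements.
#'
#' @param observed,simulated matched numeric vectors.
#' @return scalar >= 0.
#' @examples
#' maeObjective(c(4, 5, 6), c(4.3, 4.4, 6.9))  # 0.6
#' @export
maeObjective <- function(observed, simulated) {
  if (length(observed) != length(simulated)) stop("series must match")
  mean(abs(observed - simulated))
}

# ---- sampler ----------------------------------------------------------------

.toUnit <- function(v, lower, upper, log.) {
  if (log.) (log(v) - log(lower)) / (log(upper) - log(lower))
  else (v - lower) / (upper - lower)
}

.fromUnit <- function(z, lower, upper, log.) {
  z <- pmin(pmax(z, 0), 1)
  if (log.) exp(log(lower) + z * (log(upper) - log(lower)))
  else lower + z * (upper - lower)
}

.kde <- function(x, pts, bw) {
  if (!length(pts)) return(rep(1, length(x)))
  sapply(x, function(xi) mean(stats::dnorm((xi - pts) / bw)) / bw)
}

# one TPE suggestion. Trials are split into good/bad by score (top 15%, at
# least 3); candidates are drawn around randomly chosen good trials - the
# same centre trial for every parameter, which preserves correlations between
# parameters in the good set - and scored by the product of the per-parameter
# good/bad kernel-density ratios (the expected-improvement surrogate).
.tpeSuggest <- function(X, scores, space, nCandidates = 128, gammaFrac = 0.12) {
  ok <- is.finite(scores)
  nFin <- sum(ok)
  n <- length(scores)
  d <- nrow(space)
  if (nFin < 3L) return(.randomSuggest(space))
  nGood <- min(max(3L, ceiling(gammaFrac * nFin)), nFin - 1L)
  ord <- order(scores)  # failed (Inf) trials sort last and stay in the bad set
  live <- which(space$lower < space$upper)
  Zall <- matrix(0, n, d)
  for (p in live)
    Zall[, p] <- .toUnit(X[[space$name[p]]][ord], space$lower[p],
                         space$upper[p], space$log[p])
  # adaptive suggestions cluster tightly once they exploit; keep only trials
  # that are distinct at ~0.02 of the unit cube when forming the good set, so
  # its density model retains spread instead of collapsing onto one point
  distinct <- !duplicated(round(Zall / 0.02))
  distinct[seq_len(n) > nFin] <- FALSE  # failures can never be "good"
  goodRows <- which(distinct)[seq_len(min(nGood, sum(distinct)))]
  if (length(goodRows) < 3L) goodRows <- seq_len(min(3L, nFin))
  Zg <- Zall[goodRows, , drop = FALSE]
  Zb <- Zall[-goodRows, , drop = FALSE]
  if (!nrow(Zb)) Zb <- Zall
  nGood <- nrow(Zg)
  bad <- seq_len(nrow(Zb))
  # candidate families: draws around good trials with the good set's own
  # covariance (so proposals align with a curved valley), a tight family
  # around the incumbent, and uniform draws (the prior component) so the
  # search can always escape a locally exploited basin
  nUnif <- ceiling(nCandidates / 4)
  nBest <- ceiling(nCandidates / 4)
  nKde <- nCandidates - nUnif - nBest
  Sg <- stats::cov(Zg) + diag(0.03^2, d)
  L <- chol(Sg)
  centres <- sample.int(nGood, nKde, replace = TRUE)
  cand <- rbind(
    Zg[centres, , drop = FALSE] +
      matrix(stats::rnorm(nKde * d), nKde) %*% (0.8 * L),
    Zg[rep(1L, nBest), , drop = FALSE] +
      matrix(stats::rnorm(nBest * d), nBest) %*% (0.4 * L),
    matrix(stats::runif(nUnif * d), nUnif))
  cand <- pmin(pmax(abs(cand), 0), 2 - pmin(abs(cand), 2))  # reflect into [0,1]
  # both densities carry one pseudo-observation of the uniform prior, so the
  # ratio stays bounded below away from the explored region and uniform
  # candidates in unexplored territory can still win (exploration never dies)
  logRatio <- numeric(nCandidates)
  for (p in live) {
    bwg <- max(1.06 * stats::sd(Zg[, p]) * nGood^(-0.2), 0.03, na.rm = TRUE)
    bwb <- max(1.06 * stats::sd(Zb[, p]) * length(bad)^(-0.2), 0.05,
               na.rm = TRUE)
    lg <- (1 + nGood * .kde(cand[, p], Zg[, p], bwg)) / (1 + nGood)
    gb <- (1 + nrow(Zb) * .kde(cand[, p], Zb[, p], bwb)) / (1 + nrow(Zb))
    logRatio <- logRatio + log(lg) - log(gb)
  }
  zbest <- cand[which.max(logRatio), ]
  out <- mapply(.fromUnit, zbest, space$lower, space$upper, space$log)
  names(out) <- space$name
  out
}

# Local refinement of the incumbent best trial for the tail of the trial
# budget: an incremental Nelder-Mead simplex in the unit cube, advanced one
# function evaluation per trial (a state machine held in an environment).
# Deterministic; simplex methods track the thin curved valleys these
# objectives exhibit better than isotropic perturbation.

# start from the d+1 best distinct trials already evaluated (their values are
# known, so no evaluations are spent on simplex construction); degenerate or
# missing directions are filled by axis perturbations of the incumbent
.nmStart <- function(env, Z, V, step = 0.08) {
  d <- ncol(Z)
  keep <- !duplicated(round(Z, 10))
  Z <- Z[keep, , drop = FALSE]
  V <- V[keep]
  ord <- order(V)
  n <- min(length(ord), d + 1L)
  S <- matrix(NA_real_, d + 1L, d)
  vals <- rep(NA_real_, d + 1L)
  S[seq_len(n), ] <- Z[ord[seq_len(n)], , drop = FALSE]
  vals[seq_len(n)] <- V[ord[seq_len(n)]]
  # keep the starting simplex compact: pull distant vertices toward the
  # incumbent (their direction is kept, the value is then unknown -> Inf)
  if (n > 1L) for (i in 2:n) {
    e <- S[i, ] - S[1L, ]
    len <- sqrt(sum(e^2))
    if (len > 0.2) {
      S[i, ] <- .nmClamp(S[1L, ] + e * 0.2 / len)
      vals[i] <- Inf
    }
  }
  if (n < d + 1L) for (i in seq(n + 1L, d + 1L)) {
    z <- S[1L, ]
    z[i - 1L] <- z[i - 1L] + if (z[i - 1L] < 0.5) step else -step
    S[i, ] <- z
    vals[i] <- Inf  # treated as worst until replaced
  }
  # good trials cluster along valleys, which can make the simplex nearly
  # degenerate and stall the search: re-span any direction the edge matrix
  # covers poorly, seeding it from the incumbent (value unknown -> Inf, so it
  # is reflected away first)
  edges <- sweep(S[-1L, , drop = FALSE], 2L, S[1L, ])
  sv <- svd(edges)
  weak <- which(sv$d < 0.05)
  if (length(weak)) {
    repl <- setdiff(order(vals, decreasing = TRUE), 1L)[seq_along(weak)]
    for (m in seq_along(weak)) {
      S[repl[m], ] <- .nmClamp(S[1L, ] + step * sv$v[, weak[m]])
      vals[repl[m]] <- Inf
    }
  }
  env$S <- S
  env$V <- vals
  env$worst <- which.max(env$V)
  cen <- colMeans(env$S[-env$worst, , drop = FALSE])
  env$cen <- cen
  env$pending <- .nmClamp(cen + (cen - env$S[env$worst, ]))
  env$state <- "reflect"
}

.nmClamp <- function(z) pmin(pmax(z, 0), 1)

# propose the next unit-cube point given the current state
.nmPropose <- function(env) {
  if (env$state == "shrink") {
    best <- which.min(env$V)
    z <- .nmClamp(env$S[best, ] + 0.5 * (env$S[env$row, ] - env$S[best, ]))
    env$pending <- z
    return(z)
  }
  # reflect / expand / contract proposals are precomputed in env$pending
  env$pending
}

# fold in the value of the point proposed last and set up the next proposal
.nmUpdate <- function(env, val) {
  d <- ncol(env$S)
  newReflection <- function() {
    env$worst <- which.max(env$V)
    cen <- colMeans(env$S[-env$worst, , drop = FALSE])
    env$cen <- cen
    env$pending <- .nmClamp(cen + (cen - env$S[env$worst, ]))
    env$state <- "reflect"
  }
  be <- 2    # expansion
  bc <- 0.5  # contraction
  switch(env$state,
    reflect = {
      env$fr <- val
      env$xr <- env$pending
      ordV <- sort(env$V)
      if (val < ordV[1L]) {
        env$pending <- .nmClamp(env$cen + be * (env$cen - env$S[env$worst, ]))
        env$state <- "expand"
      } else if (val < ordV[d]) {
        env$S[env$worst, ] <- env$xr
        env$V[env$worst] <- val
        newReflection()
      } else {
        if (val < env$V[env$worst]) {
          env$pending <- .nmClamp(env$cen + bc * (env$xr - env$cen))
          env$cmp <- val
        } else {
          env$pending <- .nmClamp(env$cen - bc * (env$cen - env$S[env$worst, ]))
          env$cmp <- env$V[env$worst]
        }
        env$state <- "contract"
      }
    },
    expand = {
      if (val < env$fr) {
        env$S[env$worst, ] <- env$pending
        env$V[env$worst] <- val
      } else {
        env$S[env$worst, ] <- env$xr
        env$V[env$worst] <- env$fr
      }
      newReflection()
    },
    contract = {
      if (val < env$cmp) {
        env$S[env$worst, ] <- env$pending
        env$V[env$worst] <- val
        newReflection()
      } else {
        env$row <- if (which.min(env$V) == 1L) 2L else 1L
        env$state <- "shrink"
      }
    },
    shrink = {
      env$S[env$row, ] <- env$pending
      env$V[env$row] <- val
      best <- which.min(env$V)
      nxt <- setdiff(seq_len(d + 1L), best)
      nxt <- nxt[nxt > env$row]
      if (length(nxt)) {
        env$row <- nxt[1L]
        env$state <- "shrink"
      } else newReflection()
    })
  invisible(env)
}

.randomSuggest <- function(space) {
  z <- stats::runif(nrow(space))
  out <- mapply(.fromUnit, z, space$lower, space$upper, space$log)
  names(out) <- space$name
  out
}

#' Sequential model-based minimization over a box
#'
#' Evaluates `fn` (which may return a vector of objectives, one per patient)
#' for `nTrials` parameter suggestions. The first `nStartup` trials come from
#' a seeded Latin hypercube, the middle of the budget from the TPE sampler,
#' and the final third from a local (1+1)-ES refinement of the incumbent
#' best trial with shrinking radius (the "random" baseline sampler replaces
#' both adaptive phases by uniform draws). The TPE ranking scalarizes
#' multi-objective scores by their maximum; the full objective vectors are
#' kept for the Pareto analysis. Reproducible: the whole trial sequence is a
#' deterministic function of the seed.
#'
#' @param fn function(named numeric vector) -> numeric vector of objectives;
#'   failures should be signalled by `Inf` entries or errors (caught and
#'   scored +Inf).
#' @param space data.frame with columns name, lower, upper, log.
#' @param nTrials number of trials.
#' @param seed integer seed.
#' @param sampler "tpe" or "random".
#' @param nStartup warm-up trials before the TPE model kicks in.
#' @param nRefine trials reserved for the Nelder-Mead tail (default a third
#'   of the budget).
#' @return list: `params` (data.frame of trial parameters), `objectives`
#'   (matrix, one row per trial), `scores` (max per row), `best` (index of
#'   the min-max trial, ties broken by the sum), `pareto` (indices of the
#'   non-dominated trials).
#' @export
tpeMinimize <- function(fn, space, nTrials, seed = 1L,
                        sampler = c("tpe", "random"), nStartup = 10L,
                        nRefine = NULL) {
  sampler <- match.arg(sampler)
  set.seed(seed)
  nStartup <- min(nStartup, nTrials)
  lhsUnit <- lhs::randomLHS(nStartup, nrow(space))
  X <- as.data.frame(matrix(NA_real_, nTrials, nrow(space)))
  names(X) <- space$name
  objList <- vector("list", nTrials)
  scores <- rep(Inf, nTrials)
  if (is.null(nRefine)) nRefine <- floor(nTrials / 3)
  if (sampler != "tpe") nRefine <- 0L
  nRefine <- min(nRefine, nTrials - nStartup)
  nmEnv <- new.env(parent = emptyenv())
  fromUnitAll <- function(z) {
    v <- mapply(.fromUnit, z, space$lower, space$upper, space$log)
    names(v) <- space$name
    v
  }
  for (tr in seq_len(nTrials)) {
    hist <- seq_len(tr - 1L)
    par <- if (tr <= nStartup) {
      fromUnitAll(lhsUnit[tr, ])
    } else if (sampler == "random") .randomSuggest(space)
    else if (tr > nTrials - nRefine && any(is.finite(scores[hist]))) {
      fin <- hist[is.finite(scores[hist])]
      Z <- matrix(unlist(lapply(fin, function(r) {
        z <- mapply(.toUnit, unlist(X[r, ]), space$lower, space$upper,
                    space$log)
        z[!is.finite(z)] <- 0
        z
      })), ncol = nrow(space), byrow = TRUE)
      if (is.null(nmEnv$state)) {
        .nmStart(nmEnv, Z, scores[fin])
      } else if (tr == nTrials - floor(nRefine / 2) + 1L) {
        # second refinement phase: restart from the most promising trial in a
        # different basin (far from the incumbent), if any looks competitive -
        # local search alone cannot leave the basin the model phase exploited
        b <- which.min(scores[fin])
        dists <- sqrt(rowSums(sweep(Z, 2L, Z[b, ])^2))
        far <- which(dists > 0.25)
        if (length(far) && min(scores[fin][far]) < 3 * scores[fin][b]) {
          alt <- far[which.min(scores[fin][far])]
          near <- which(sqrt(rowSums(sweep(Z, 2L, Z[alt, ])^2)) <= 0.25)
          .nmStart(nmEnv, Z[near, , drop = FALSE], scores[fin][near])
        } else .nmUpdate(nmEnv, scores[tr - 1L])
      } else .nmUpdate(nmEnv, scores[tr - 1L])
      fromUnitAll(.nmPropose(nmEnv))
    } else .tpeSuggest(X[hist, , drop = FALSE], scores[hist], space)
    X[tr, ] <- par
    obj <- tryCatch(fn(par), error = function(e) {
      if (getOption("prostasim.verbose", FALSE))
        message("trial ", tr, " failed: ", conditionMessage(e))
      Inf
    })
    objList[[tr]] <- obj
    scores[tr] <- suppressWarnings(max(obj))
  }
  nObj <- max(lengths(objList))
  objectives <- do.call(rbind, lapply(objList, function(o) rep_len(o, nObj)))
  sums <- rowSums(objectives)
  best <- order(scores, sums)[1L]
  list(params = X, objectives = objectives, scores = scores, best = best,
       pareto = .paretoFront(objectives), seed = seed)
}

# indices of non-dominated rows (minimization)
.paretoFront <- function(M) {
  n <- nrow(M)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])) { dominated <- TRUE; break }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# simulated follow-up targets and the matched observed vector for one patient
.growthTargets <- function(patient) {
  fu <- patient@followUp
  if (!nrow(fu)) stop("patient has no follow-up observations")
  as.numeric(t(as.matrix(fu[, c("prostateVolume", "tumourVolume",
                                "prostateCellularity", "tumourCellularity")])))
}

.roundUp <- function(x, dt) dt * ceiling(x / dt - 1e-9)

#' Stage-1 calibration: growth parameters
#'
#' Multi-objective search over (kg, k, Kstiffness, kv2): one mean-relative-
#' error objective per patient over all follow-up targets. Returns the
#' non-dominated set and the selected compromise trial (minimum of the
#' maximum per-patient objective, ties broken by the sum). Trials whose
#' simulation fails score +Inf and the search continues.
#'
#' @param patients list of [PatientCase-class] with follow-up observations.
#' @param space parameter box (default [growthParameterSpace]).
#' @param nTrials trials (the source protocol uses 60).
#' @param seed integer seed (full trial sequence is reproducible).
#' @param baseParams a [ModelParams-class] supplying all other parameters.
#' @param config a [SimConfig-class]; `tFinal` is raised to cover each
#'   patient's last follow-up.
#' @param sampler "tpe" or "random".
#' @return as [tpeMinimize], plus `selected` (named parameter vector) and
#'   `selectedParams` (a [ModelParams-class] with the selection applied).
#' @export
optimizeGrowth <- function(patients, space = growthParameterSpace(),
                           nTrials = 60L, seed = 1L,
                           baseParams = modelParams(), config = simConfig(),
                           sampler = "tpe") {
  if (!length(patients)) stop("at least one patient is required")
  observed <- lapply(patients, .growthTargets)
  fn <- function(par) {
    params <- setModelParams(baseParams, par)
    vapply(seq_along(patients), function(i) {
      p <- patients[[i]]
      cfg <- config
      cfg@tFinal <- .roundUp(max(p@followUp$date), config@dt)
      traj <- simulateGrowth(p, params, cfg)
      sim <- summarizeAt(traj, p@followUp$date)
      simv <- as.numeric(t(as.matrix(sim[, c("prostateVolume", "tumourVolume",
                                             "prostateCellularity",
                                             "tumourCellularity")])))
      relativeErrorObjective(observed[[i]], simv)
    }, numeric(1))
  }
  res <- tpeMinimize(fn, space, nTrials, seed, sampler)
  res$selected <- unlist(res$params[res$best, ])
  res$selectedParams <- setModelParams(baseParams, res$selected)
  res
}

# serum PSA series for fixed growth inputs: replays only the PSA recursion
# over recorded per-step densities/volumes (PSA does not feed back on growth)
.psaReplay <- function(patient, stepData, dens0, psaP, caps, dt) {
  Ps <- .initialSerumPSA(patient)
  P <- initTissuePSA(Ps, dens0, patient@ktrans, psaP, caps)
  out <- numeric(length(stepData) + 1L)
  out[1L] <- Ps
  for (s in seq_along(stepData)) {
    sd <- stepData[[s]]
    dens <- list(rhoT = sd$rhoT, rhoH = sd$rhoH)
    st <- psaStep(P, dens, patient@ktrans, sd$volumes, dt, psaP, caps)
    P <- st$P
    Ps <- st$Ps
    out[s + 1L] <- Ps
  }
  out
}

#' Stage-2 calibration: PSA parameters
#'
#' Growth parameters stay fixed (stage separation): each patient's growth
#' trajectory is simulated once, and every trial replays only the PSA
#' recursion with candidate (alphaT, alphaH, gamma, gammaS), scoring the mean
#' absolute error against the patient's serum PSA measurements after day 0.
#'
#' @param patients list of [PatientCase-class] with PSA measurements after
#'   the diagnostic MRI.
#' @param space parameter box (default [psaParameterSpace]).
#' @param nTrials trials (the source protocol uses 30).
#' @param seed integer seed.
#' @param baseParams a [ModelParams-class] carrying the stage-1 growth
#'   parameters.
#' @param config a [SimConfig-class].
#' @param sampler "tpe" or "random".
#' @return as [tpeMinimize] plus `selected` and `selectedParams`.
#' @export
optimizePSA <- function(patients, space = psaParameterSpace(), nTrials = 30L,
                        seed = 1L, baseParams = modelParams(),
                        config = simConfig(), sampler = "tpe") {
  caps <- baseParams@capacities
  pre <- lapply(patients, function(p) {
    tDates <- p@psaDates[p@psaDates > 0]
    tVals <- p@psaValues[p@psaDates > 0]
    if (!length(tDates)) stop("patient has no PSA measurements after day 0")
    cfg <- config
    cfg@tFinal <- .roundUp(max(tDates), config@dt)
    cfg@recordStepData <- TRUE
    traj <- simulateGrowth(p, baseParams, cfg)
    list(times = traj@times, stepData = attr(traj@snapshots, "stepData"),
         dens0 = initDensities(p@cellularity, p@tumourMask, p@pt, caps),
         dates = tDates, values = tVals)
  })
  fn <- function(par) {
    psaP <- new("PSAParams", alphaT = par[["alphaT"]], alphaH = par[["alphaH"]],
                gamma = par[["gamma"]], gammaS = par[["gammaS"]])
    vapply(seq_along(patients), function(i) {
      pr <- pre[[i]]
      ps <- .psaReplay(patients[[i]], pr$stepData, pr$dens0, psaP, caps,
                       config@dt)
      sim <- stats::approx(pr$times, ps, xout = pr$dates)$y
      maeObjective(pr$values, sim)
    }, numeric(1))
  }
  # the PSA objective is smooth and effectively low-dimensional (serum decay
  # is dominated by the exchange term), so half the budget goes to the local
  # simplex tail
  res <- tpeMinimize(fn, space, nTrials, seed, sampler,
                     nRefine = floor(nTrials / 2))
  res$selected <- unlist(res$params[res$best, ])
  res$selectedParams <- setModelParams(baseParams, res$selected)
  res
}
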