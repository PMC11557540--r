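# The multiscale time loop. Per 10-day increment: (1) per-element oxygen
# equilibrium, (2) explicit-Euler population step to the grown (incompatible)
# configuration plus growth stretches and eigenstrain, (3) incremental FE
# elasticity solve, geometry update and mass-conserving density rescale,
# (4) multiscale PSA step. Observables are recorded every step.

#' Simulation configuration
#'
#' @slot dt time step (day).
#' @slot tFinal final time (day).
#' @slot oxygenMethod "algebraic" or "marching" (see [oxygenEquilibrium]).
#' @slot stiffnessMode "mixture" (rule-of-mixtures modulus) or "superposed"
#'   (overlapping cellular and stromal element sets sharing nodes; identical
#'   displacements by linearity).
#' @slot snapshotTimes times (day) at which full element states are kept.
#' @slot recordStepData keep per-step densities and volumes (used by the PSA
#'   calibration stage, which re-runs only the PSA recursion).
#' @slot continuousGrowth use the continuity-rescaled growth branch.
#' @export
setClass("SimConfig",
  representation(dt = "numeric", tFinal = "numeric", oxygenMethod = "character",
                 stiffnessMode = "character", snapshotTimes = "numeric",
                 recordStepData = "logical", continuousGrowth = "logical"))

setValidity("SimConfig", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (object@tFinal < object@dt) return("tFinal must be >= dt")
  if (!object@oxygenMethod %in% c("algebraic", "marching"))
    return("oxygenMethod must be 'algebraic' or 'marching'")
  if (!object@stiffnessMode %in% c("mixture", "superposed"))
    return("stiffnessMode must be 'mixture' or 'superposed'")
  TRUE
})

#' @rdname SimConfig-class
#' @param dt,tFinal,oxygenMethod,stiffnessMode,snapshotTimes,recordStepData,continuousGrowth
#'   see the class slots.
#' @export
simConfig <- function(dt = 10, tFinal = 700, oxygenMethod = "algebraic",
                      stiffnessMode = "mixture", snapshotTimes = numeric(0),
                      recordStepData = FALSE, continuousGrowth = FALSE)
  new("SimConfig", dt = dt, tFinal = tFinal, oxygenMethod = oxygenMethod,
      stiffnessMode = stiffnessMode, snapshotTimes = snapshotTimes,
      recordStepData = recordStepData, continuousGrowth = continuousGrowth)

# mean cellularity recovered from densities: the inverse of the
# initialization partition
.cellularityField <- function(densities, caps)
  densities$rhoT / caps@rhoCT + densities$rhoH / caps@rhoCH

.observe <- function(mesh, densities, mask, Ps, caps) {
  cell <- .cellularityField(densities, caps)
  pro <- regionSummary(mesh, cell)
  tum <- regionSummary(mesh, cell, mask)
  data.frame(prostateVolume = pro$volume / 1e3, tumourVolume = tum$volume,
             prostateCellularity = pro$mean, tumourCellularity = tum$mean,
             serumPSA = Ps)
}

# serum PSA at the diagnostic MRI: exponential fit of the measurements up to
# day 0 (a single pre-diagnosis value is used as-is)
.initialSerumPSA <- function(patient) {
  pre <- patient@psaDates <= 0
  if (sum(pre) >= 2)
    fitExponentialPSA(patient@psaDates[pre], patient@psaValues[pre])$predict(0)
  else if (sum(pre) == 1)
    patient@psaValues[pre]
  else stop("no PSA measurement at or before the diagnostic MRI")
}

# One mechanics increment with adaptive load substepping: a strong local
# contraction (sustained hypoxic resorption) can invert elements when applied
# in a single linearized solve, so on inversion the eigenstrain is re-applied
# in m sub-increments with geometry updates in between; the sub-increment
# stretches multiply back to (1 + dT) exactly, so Jg and the mass bookkeeping
# are unchanged.
.mechanicsIncrement <- function(mesh, dT, E, mech, cache) {
  lamTot <- 1 + mech@alpha * dT
  for (nSub in c(1L, 4L, 16L)) {
    nodes <- mesh@nodes
    J <- rep(1, length(dT))
    ok <- TRUE
    dTs <- lamTot^(1 / nSub) - 1
    for (s in seq_len(nSub)) {
      msub <- mesh
      msub@nodes <- nodes
      sol <- tryCatch(solveElasticity(msub, dTs, E, mech, cache = cache),
                      error = function(e) e)
      if (inherits(sol, "error")) {
        if (grepl("inversion", conditionMessage(sol))) { ok <- FALSE; break }
        stop(sol)
      }
      nodes <- sol$newNodes
      J <- J * sol$J
    }
    if (ok) {
      Jg <- lamTot^3
      return(list(newNodes = nodes, J = J, Jg = Jg, Je = J / Jg))
    }
  }
  stop("element inversion persists after load substepping")
}

# the two superposed modulus fields (cellular, stromal); the stromal field is
# bumped so the summed modulus respects the Emin floor exactly as in
# mixtureModulus
.superposedModuli <- function(densities, caps, mech) {
  Ecells <- mech@Et * densities$rhoT / caps@rhoCT +
            mech@Eh * densities$rhoH / caps@rhoCH
  Estroma <- mech@Es * densities$rhoS / caps@rhoCS
  Estroma <- Estroma + pmax(mech@Emin - (Ecells + Estroma), 0)
  list(Ecells, Estroma)
}

#' Run the growth simulation for one patient
#'
#' Initializes densities from the cellularity field and biopsy burden, oxygen
#' by one equilibration (from zero in the marching mode), and tissue PSA in
#' equilibrium with the serum level fitted at day 0, then iterates the
#' multiscale loop until `config@tFinal`. The tumour region is the fixed
#' initial element mask, advected with the mesh.
#'
#' @param patient a [PatientCase-class].
#' @param params a [ModelParams-class].
#' @param config a [SimConfig-class].
#' @return a [Trajectory-class]. The observables data.frame additionally
#'   carries a `massError` column: the per-step maximum relative violation of
#'   mass conservation across the elastic map (0 at t = 0).
#' @export
simulateGrowth <- function(patient, params = modelParams(), config = simConfig()) {
  validObject(patient)
  caps <- params@capacities
  mech <- params@mechanics
  mesh <- patient@mesh
  mask <- patient@tumourMask
  ktrans <- patient@ktrans
  densities <- initDensities(patient@cellularity, mask, patient@pt, caps)

  rhoO <- oxygenEquilibrium(densities, ktrans, params@oxygen, caps,
                            method = config@oxygenMethod)
  Ps <- .initialSerumPSA(patient)
  P <- initTissuePSA(Ps, densities, ktrans, params@psa, caps)

  times <- seq(0, config@tFinal, by = config@dt)
  nSteps <- length(times) - 1L
  obs <- .observe(mesh, densities, mask, Ps, caps)
  obs$massError <- 0
  rows <- vector("list", nSteps + 1L)
  rows[[1L]] <- obs
  snapshots <- list()
  stepData <- if (config@recordStepData) vector("list", nSteps) else NULL
  mechCache <- new.env(parent = emptyenv())

  for (s in seq_len(nSteps)) {
    # (1) fast-timescale oxygen equilibrium
    rhoO <- oxygenEquilibrium(densities, ktrans, params@oxygen, caps,
                              method = config@oxygenMethod, rhoO0 = rhoO)
    # (2) population growth to the incompatible configuration
    rhoG <- populationStep(densities, rhoO, config@dt, params@growth, caps)
    lambdas <- list(
      t = growthStretch(rhoG$rhoT, densities$rhoT, caps@rhoCT, mech,
                        params@growth@k, config@continuousGrowth),
      h = growthStretch(rhoG$rhoH, densities$rhoH, caps@rhoCH, mech,
                        params@growth@k, config@continuousGrowth),
      s = growthStretch(rhoG$rhoS, densities$rhoS, caps@rhoCS, mech,
                        params@growth@k, config@continuousGrowth))
    dT <- elementEigenstrain(lambdas, rhoG, caps)
    # (3) incremental elasticity, geometry update, density rescale
    V0 <- elementVolumes(mesh)
    E <- if (config@stiffnessMode == "mixture")
      mixtureModulus(rhoG, caps, mech) else .superposedModuli(rhoG, caps, mech)
    sol <- tryCatch(.mechanicsIncrement(mesh, dT, E, mech, mechCache),
                    error = function(e)
                      stop("mechanics failed at step ", s, " (t = ", times[s + 1L],
                           " d): ", conditionMessage(e), call. = FALSE))
    mesh@nodes <- sol$newNodes
    densities <- updateDensities(rhoG, sol$Je)
    V <- elementVolumes(mesh)
    massErr <- max(vapply(c("rhoT", "rhoH", "rhoS"), function(nm) {
      mg <- sum(rhoG[[nm]] * V0 * sol$Jg)
      mc <- sum(densities[[nm]] * V)
      if (mg == 0) 0 else abs(mg - mc) / mg
    }, numeric(1)))
    # (4) multiscale PSA update on the current configuration
    ps <- psaStep(P, densities, ktrans, V, config@dt, params@psa, caps)
    P <- ps$P
    Ps <- ps$Ps
    if (anyNA(c(densities$rhoT, densities$rhoH, densities$rhoS, P, Ps)))
      stop("NaN state at step ", s, " (t = ", times[s + 1L], " d)")

    obs <- .observe(mesh, densities, mask, Ps, caps)
    obs$massError <- massErr
    rows[[s + 1L]] <- obs
    if (length(config@snapshotTimes) &&
        any(abs(config@snapshotTimes - times[s + 1L]) < 1e-9))
      snapshots[[as.character(times[s + 1L])]] <-
        new("TissueState", rhoT = densities$rhoT, rhoH = densities$rhoH,
            rhoS = densities$rhoS, rhoO = rhoO, P = P, Ps = Ps)
    if (config@recordStepData)
      stepData[[s]] <- list(rhoT = densities$rhoT, rhoH = densities$rhoH,
                            volumes = V)
  }

  traj <- new("Trajectory", times = times,
              observables = do.call(rbind, rows), snapshots = snapshots,
              finalState = new("TissueState", rhoT = densities$rhoT,
                               rhoH = densities$rhoH, rhoS = densities$rhoS,
                               rhoO = rhoO, P = P, Ps = Ps),
              finalMesh = mesh)
  if (config@recordStepData) attr(traj@snapshots, "stepData") <- stepData
  traj
}

#' Trajectory observables
#'
#' @param trajectory a [Trajectory-class].
#' @return data.frame of observables with a `time` column.
#' @export
observables <- function(trajectory)
  cbind(time = trajectory@times, trajectory@observables)

#' Interpolate trajectory observables at arbitrary dates
#'
#' Linear interpolation in time of every observable column; dates must lie
#' within the simulated range.
#'
#' @param trajectory a [Trajectory-class].
#' @param dates days since the diagnostic MRI.
#' @return data.frame with one row per date.
#' @export
summarizeAt <- function(trajectory, dates) {
  tt <- trajectory@times
  if (any(dates < min(tt) | dates > max(tt)))
    stop("date outside the simulated range [", min(tt), ", ", max(tt), "]")
  cols <- c("prostateVolume", "tumourVolume", "prostateCellularity",
            "tumourCellularity", "serumPSA")
  out <- data.frame(date = dates)
  for (cl in cols)
    out[[cl]] <- stats::approx(tt, trajectory@observables[[cl]], xout = dates)$y
  out
}

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  o <- object@observables
  cat("Trajectory:", n, "time points over", max(object@times), "days\n")
  cat(sprintf("  prostate %.2f -> %.2f cm^3, tumour %.1f -> %.1f mm^3, PSA %.2f -> %.2f ng/mL\n",
              o$prostateVolume[1], o$prostateVolume[n], o$tumourVolume[1],
              o$tumourVolume[n], o$serumPSA[1], o$serumPSA[n]))
})

setMethod("show", "PatientCase", function(object) {
  cat("PatientCase:", nElements(object@mesh), "elements,",
      sum(object@tumourMask), "tumour elements, pt =", object@pt, "\n")
  cat(sprintf("  prostate %.1f cm^3, %d PSA measurements, %d follow-ups\n",
              totalVolume(object@mesh) / 1e3, length(object@psaDates),
              nrow(object@followUp)))
})
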