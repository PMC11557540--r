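# PSA kinetics. Tissue PSA is produced in proportion to the capacity-
# normalized cell densities (tumour cells leak far more than healthy cells),
# decays, and exchanges with blood at the KTrans rate; serum PSA collects the
# volume-integrated exchange and decays. On the 10-day step the exchange is
# much faster than production, so the multiscale scheme estimates the
# produced/decayed tissue PSA (P*), solves the stationary serum level, and
# recalculates the tissue PSA in equilibrium with it.

#' Fit an exponential trend to a serum PSA series
#'
#' Least squares on the log scale: Ps(t) = a exp(b t). Clinical PSA series
#' are noisy but their trajectory is well described by an exponential; the
#' fitted value at the diagnostic MRI date initializes the simulation.
#'
#' @param dates days (numeric, strictly increasing).
#' @param values serum PSA (ng/mL, > 0).
#' @return list with `a`, `b`, `predict(t)` and the residual standard error
#'   of the log fit `sigmaLog`.
#' @examples
#' fitExponentialPSA(c(0, 100, 300), 2 * exp(0.001 * c(0, 100, 300)))
#' @export
fitExponentialPSA <- function(dates, values) {
  if (length(dates) < 2) stop("at least two PSA points are required")
  if (length(values) != length(dates)) stop("dates and values must match")
  if (any(values <= 0)) stop("PSA values must be > 0 for the log-scale fit")
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must be strictly increasing")
  fit <- stats::lm(log(values) ~ dates)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  sm <- if (length(dates) > 2) suppressWarnings(summary(fit)) else NULL
  list(a = a, b = b,
       predict = function(t) a * exp(b * t),
       sigmaLog = if (is.null(sm)) 0 else sm$sigma,
       se_b = if (is.null(sm)) NA_real_ else sm$coefficients[2, 2])
}

# per-element PSA source: S = alphaH rhoH/rhoCH + alphaT rhoT/rhoCT
.psaSource <- function(densities, psa, caps)
  psa@alphaH * densities$rhoH / caps@rhoCH +
  psa@alphaT * densities$rhoT / caps@rhoCT

#' Initial tissue PSA in equilibrium with a serum level
#'
#' Solves the per-element equilibrium S - KTrans (P - Ps0) - gamma P = 0 for
#' P: P = (S + KTrans Ps0) / (KTrans + gamma).
#'
#' @param Ps0 serum PSA at the diagnostic MRI (ng/mL, >= 0).
#' @param densities list of per-element densities.
#' @param ktrans per-element exchange rate (1/day).
#' @param psa a [PSAParams-class].
#' @param caps a [CarryingCapacities-class].
#' @return per-element tissue PSA (ng/mL).
#' @export
initTissuePSA <- function(Ps0, densities, ktrans, psa = psaParams(warn = FALSE),
                          caps = carryingCapacities()) {
  if (Ps0 < 0) stop("Ps0 must be >= 0")
  denom <- ktrans + psa@gamma
  if (any(denom == 0))
    stop("KTrans + gamma is zero in element ", which(denom == 0)[1])
  (.psaSource(densities, psa, caps) + ktrans * Ps0) / denom
}

#' One multiscale PSA step
#'
#' Three sub-steps: (4.1) explicit Euler estimate of the produced/decayed
#' tissue PSA, P* = P + dt (S - gamma P); (4.2) stationary serum level,
#' Ps = sum_e w_e K_e P*_e / (gammaS + sum_e w_e K_e) with volume weights
#' w_e = V_e / sum(V); (4.3) tissue PSA re-equilibrated with the new serum
#' level, P = (S + K Ps) / (K + gamma). The volume weighting makes the serum
#' integral mesh-refinement invariant.
#'
#' @param P per-element tissue PSA at the previous step (ng/mL).
#' @param densities list of per-element densities (current configuration).
#' @param ktrans per-element exchange rate (1/day).
#' @param volumes per-element volumes (mm^3, current configuration).
#' @param dt time step (day).
#' @param psa a [PSAParams-class].
#' @param caps a [CarryingCapacities-class].
#' @return list with `P` (per element), `Ps` (scalar) and `Pstar`.
#' @export
psaStep <- function(P, densities, ktrans, volumes, dt = 10,
                    psa = psaParams(warn = FALSE), caps = carryingCapacities()) {
  S <- .psaSource(densities, psa, caps)
  Pstar <- P + dt * (S - psa@gamma * P)
  w <- volumes / sum(volumes)
  wk <- sum(w * ktrans)
  if (psa@gammaS + wk == 0)
    stop("serum PSA undefined: gammaS + sum(w * KTrans) is zero")
  Ps <- sum(w * ktrans * Pstar) / (psa@gammaS + wk)
  denom <- ktrans + psa@gamma
  if (any(denom == 0))
    stop("KTrans + gamma is zero in element ", which(denom == 0)[1])
  Pnew <- (S + ktrans * Ps) / denom
  list(P = pmax(Pnew, 0), Ps = max(Ps, 0), Pstar = Pstar)
}
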