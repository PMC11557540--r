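# Model parameter records. Defaults follow the published parameter set for
# low-risk prostate cancer under active surveillance: proliferation/death
# rates and oxygen thresholds of the three constituents, Michaelis-Menten
# oxygen consumption, PSA production/decay, linear-elastic moduli and the
# growth-law constants. All rates are stored per day; oxygen consumption
# rates quoted per second in the source literature are converted (x 86400).

#' Default carrying capacities
#'
#' @param rhoCT tumour-cell capacity (cells/mm^3).
#' @param rhoCH healthy-cell capacity (cells/mm^3).
#' @param rhoCS stroma capacity (g/mm^3).
#' @export
carryingCapacities <- function(rhoCT = 100e3, rhoCH = 75e3, rhoCS = 1.50)
  new("CarryingCapacities", rhoCT = rhoCT, rhoCH = rhoCH, rhoCS = rhoCS)

#' Growth-dynamics parameters
#'
#' `beta` damps proliferation by 1/(1+beta): 0 for tumour cells (full rate),
#' 1 for healthy cells; stroma is treated like damped healthy growth toward
#' its own capacity. Oxygen thresholds gate proliferation (above thetaP) and
#' hypoxic death (below thetaD); between them the constituent is quiescent.
#'
#' @param kg proliferation rate (1/day).
#' @param k corrected carrying capacity in (0, 1].
#' @param kd death rate (1/day).
#' @param beta,thetaP,thetaD named numerics over constituents t, h, s
#'   (thresholds in pmol).
#' @export
growthParams <- function(kg = 4.03e-3, k = 0.57, kd = 0.02,
                         beta = c(t = 0, h = 1, s = 1),
                         thetaP = c(t = 3500, h = 4000, s = 4000),
                         thetaD = c(t = 3000, h = 3300, s = 3900))
  new("GrowthParams", kg = kg, k = k, kd = kd, beta = beta,
      thetaP = thetaP, thetaD = thetaD)

#' Oxygen transport parameters
#'
#' @param rhoBO blood oxygen concentration (pmol).
#' @param Ao named maximal consumption rates (pmol/day); the default converts
#'   25.50 pmol/s. Only cells (t, h) consume oxygen; stroma does not.
#' @param ko named half-consumption concentrations (pmol).
#' @param dtd fast-timescale substep (day) for the time-marching mode.
#' @param tol relative-change convergence tolerance of the marching mode.
#' @export
oxygenParams <- function(rhoBO = 4124,
                         Ao = c(t = 25.50 * 86400, h = 25.50 * 86400),
                         ko = c(t = 4.64, h = 4.64),
                         dtd = 1e-4, tol = 1e-8)
  new("OxygenParams", rhoBO = rhoBO, Ao = Ao, ko = ko, dtd = dtd, tol = tol)

#' PSA kinetics parameters
#'
#' Defaults are the calibrated values of the source model. Note the default
#' decay rates lie below the optimization range used for calibration
#' ([psaParameterSpace]); loading such values only triggers a warning.
#'
#' @param alphaT,alphaH production rates (ng/mL/day), alphaT > alphaH.
#' @param gamma,gammaS tissue and serum decay rates (1/day).
#' @param warn warn when decay rates fall outside the calibration range.
#' @export
psaParams <- function(alphaT = 0.96, alphaH = 8.02e-3,
                      gamma = 2.17e-4, gammaS = 1.44e-4, warn = TRUE) {
  if (warn && (gamma < 9e-4 || gamma > 9e-2 || gammaS < 9e-4 || gammaS > 9e-2))
    warning("PSA decay rate outside the usual calibration range [9e-4, 9e-2] /day")
  new("PSAParams", alphaT = alphaT, alphaH = alphaH, gamma = gamma, gammaS = gammaS)
}

#' Mechanics and growth-law parameters
#'
#' @param Et,Eh,Es Young's moduli (kPa).
#' @param nu Poisson ratio.
#' @param Kstiffness elastic-foundation stiffness (kPa/mm) of the surroundings.
#' @param Ktangential tangential foundation stiffness (kPa/mm); small, only to
#'   remove the rigid modes normal springs leave free.
#' @param kv1,kv2,kd1 growth stretch law constants.
#' @param alpha thermal-analogy expansion ratio.
#' @param Emin floor for the mixture modulus (kPa).
#' @export
mechanicsParams <- function(Et = 3, Eh = 5, Es = 30, nu = 0.40,
                            Kstiffness = 14, Ktangential = 1e-4 * Kstiffness,
                            kv1 = 0.95, kv2 = 0.1, kd1 = 3,
                            alpha = 1, Emin = 0.1)
  new("MechanicsParams", Et = Et, Eh = Eh, Es = Es, nu = nu,
      Kstiffness = Kstiffness, Ktangential = Ktangential,
      kv1 = kv1, kv2 = kv2, kd1 = kd1, alpha = alpha, Emin = Emin)

#' Assemble the full model parameter record
#'
#' @param growth,oxygen,psa,mechanics,capacities the parameter groups; any
#'   omitted group takes its defaults.
#' @return a [ModelParams-class].
#' @examples
#' p <- modelParams()
#' p@growth@kg
#' @export
modelParams <- function(growth = growthParams(), oxygen = oxygenParams(),
                        psa = psaParams(warn = FALSE),
                        mechanics = mechanicsParams(),
                        capacities = carryingCapacities())
  new("ModelParams", growth = growth, oxygen = oxygen, psa = psa,
      mechanics = mechanics, capacities = capacities)

#' Replace selected parameters by name
#'
#' Convenience used by the calibration stages: returns a copy of `params`
#' with the named entries (kg, k, Kstiffness, kv2, alphaT, alphaH, gamma,
#' gammaS) replaced.
#'
#' @param params a [ModelParams-class].
#' @param values named numeric vector or list.
#' @export
setModelParams <- function(params, values) {
  values <- as.list(values)
  for (nm in names(values)) {
    v <- values[[nm]]
    switch(nm,
      kg = params@growth@kg <- v,
      k = params@growth@k <- v,
      kd = params@growth@kd <- v,
      Kstiffness = params@mechanics@Kstiffness <- v,
      kv1 = params@mechanics@kv1 <- v,
      kv2 = params@mechanics@kv2 <- v,
      kd1 = params@mechanics@kd1 <- v,
      alphaT = params@psa@alphaT <- v,
      alphaH = params@psa@alphaH <- v,
      gamma = params@psa@gamma <- v,
      gammaS = params@psa@gammaS <- v,
      stop("unknown parameter: ", nm))
  }
  validObject(params@growth)
  validObject(params@mechanics)
  validObject(params@psa)
  params
}

#' Calibration parameter spaces
#'
#' The boxes searched by the two calibration stages. `log = TRUE` parameters
#' are sampled on a log scale (their ranges span decades).
#'
#' @return data.frame with columns name, lower, upper, log.
#' @export
growthParameterSpace <- function()
  data.frame(name = c("kg", "k", "Kstiffness", "kv2"),
             lower = c(1e-3, 0.5, 10, 0.05),
             upper = c(0.1, 0.9, 20, 0.1),
             log = c(TRUE, FALSE, FALSE, FALSE))

#' @rdname growthParameterSpace
#' @export
psaParameterSpace <- function()
  data.frame(name = c("alphaT", "alphaH", "gamma", "gammaS"),
             lower = c(1e-2, 0, 9e-4, 9e-4),
             upper = c(1, 9e-3, 9e-2, 9e-2),
             log = c(TRUE, FALSE, TRUE, TRUE))

setMethod("show", "ModelParams", function(object) {
  g <- object@growth; o <- object@oxygen; p <- object@psa; m <- object@mechanics
  cat("ModelParams\n")
  cat(sprintf("  growth:    kg=%.3g/d  k=%.3g  kd=%.3g/d\n", g@kg, g@k, g@kd))
  cat(sprintf("  oxygen:    rhoBO=%.4g pmol  Ao=%.3g pmol/d  ko=%.3g pmol\n",
              o@rhoBO, o@Ao[["t"]], o@ko[["t"]]))
  cat(sprintf("  psa:       alphaT=%.3g  alphaH=%.3g ng/mL/d  gamma=%.3g  gammaS=%.3g /d\n",
              p@alphaT, p@alphaH, p@gamma, p@gammaS))
  cat(sprintf("  mechanics: E(t,h,s)=(%.3g,%.3g,%.3g) kPa  nu=%.2f  Kstiffness=%.3g kPa/mm\n",
              m@Et, m@Eh, m@Es, m@nu, m@Kstiffness))
  cat(sprintf("  growth law: kv1=%.3g kv2=%.3g kd1=%.3g\n", m@kv1, m@kv2, m@kd1))
})
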