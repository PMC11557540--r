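# Constituent population dynamics and oxygen transport, reduced to
# element-wise ODEs: diffusion is neglected and advection is realized through
# the mechanics-step density update, so each element evolves independently.

.capacityOf <- function(caps, constituent)
  switch(constituent, t = caps@rhoCT, h = caps@rhoCH, s = caps@rhoCS)

#' Constituent reaction rate
#'
#' Logistic proliferation gated by oxygen above the proliferation threshold,
#' and first-order death below the death threshold; in between the
#' constituent is quiescent. The Heaviside gates use the H(0) = 0 convention,
#' so at an exact threshold neither proliferation nor death is active.
#'
#' @param rho constituent density per element (>= 0).
#' @param rhoO oxygen concentration per element (pmol).
#' @param constituent one of "t" (tumour cells), "h" (healthy cells),
#'   "s" (stroma).
#' @param growth a [GrowthParams-class].
#' @param caps a [CarryingCapacities-class].
#' @return d(rho)/dt per element (density units / day).
#' @examples
#' reactionRate(1200, 4124, "t", growthParams(), carryingCapacities())
#' @export
reactionRate <- function(rho, rhoO, constituent = c("t", "h", "s"),
                         growth = growthParams(), caps = carryingCapacities()) {
  constituent <- match.arg(constituent)
  if (any(rho < 0)) stop("densities must be >= 0")
  kc <- growth@k * .capacityOf(caps, constituent)
  beta <- growth@beta[[constituent]]
  prolif <- rho * growth@kg * (1 / (1 + beta)) * (kc - rho) / kc *
    (rhoO > growth@thetaP[[constituent]])
  death <- rho * growth@kd * (rhoO < growth@thetaD[[constituent]])
  prolif - death
}

#' Explicit Euler population step
#'
#' Advances each constituent by one time step of the reaction dynamics. The
#' update is clamped so it can neither turn a density negative nor cross the
#' corrected capacity k * rho_ci from below. A density initialized above the
#' corrected capacity (measured cellularity may exceed k) is not truncated:
#' it relaxes through the negative logistic factor.
#'
#' @param densities list with per-element rhoT, rhoH, rhoS.
#' @param rhoO oxygen per element (pmol).
#' @param dt time step (day); the simulation default is 10 days.
#' @param growth a [GrowthParams-class].
#' @param caps a [CarryingCapacities-class].
#' @return list of grown densities (rhoT, rhoH, rhoS).
#' @export
populationStep <- function(densities, rhoO, dt = 10,
                           growth = growthParams(), caps = carryingCapacities()) {
  if (dt <= 0) stop("dt must be > 0")
  step1 <- function(rho, constituent) {
    kc <- growth@k * .capacityOf(caps, constituent)
    out <- rho + dt * reactionRate(rho, rhoO, constituent, growth, caps)
    pmin(pmax(out, 0), pmax(kc, rho))
  }
  list(rhoT = step1(densities$rhoT, "t"),
       rhoH = step1(densities$rhoH, "h"),
       rhoS = step1(densities$rhoS, "s"))
}

# oxygen balance: supply - consumption at concentration x (vectorised)
.oxygenBalance <- function(x, ktrans, ct, ch, oxygen) {
  ktrans * (oxygen@rhoBO - x) -
    ct * x / (oxygen@ko[["t"]] + x) - ch * x / (oxygen@ko[["h"]] + x)
}

#' Per-element oxygen equilibrium
#'
#' Oxygen exchanges with blood at rate KTrans and is consumed by tumour and
#' healthy cells with Michaelis-Menten kinetics (stroma does not consume).
#' On the fast transport timescale each element reaches the steady state of
#' d(rhoO)/dt = KTrans (rhoBO - rhoO) - sum_i Ao_i rhoO/(ko_i + rhoO)
#' (rho_i/rho_ci) independently (no diffusion). The balance is strictly
#' decreasing in rhoO, so the root is unique and lies in [0, rhoBO].
#'
#' @param densities list with per-element rhoT, rhoH (rhoS ignored).
#' @param ktrans per-element extravasation rate (1/day).
#' @param oxygen an [OxygenParams-class].
#' @param caps a [CarryingCapacities-class].
#' @param method "algebraic" solves the steady-state balance by vectorised
#'   bisection; "marching" integrates the transport ODE from `rhoO0` in
#'   substeps of `oxygen@dtd` until the maximum relative change per substep
#'   falls below `oxygen@tol` (the two must agree; the marching mode exists
#'   as the independent route).
#' @param rhoO0 initial oxygen for the marching mode (default 0, the
#'   first-step initialisation).
#' @return per-element equilibrium oxygen (pmol), in [0, rhoBO].
#' @export
oxygenEquilibrium <- function(densities, ktrans, oxygen = oxygenParams(),
                              caps = carryingCapacities(),
                              method = c("algebraic", "marching"),
                              rhoO0 = NULL) {
  method <- match.arg(method)
  if (any(ktrans < 0)) stop("ktrans must be >= 0")
  ne <- length(densities$rhoT)
  ktrans <- rep_len(ktrans, ne)
  ct <- oxygen@Ao[["t"]] * densities$rhoT / caps@rhoCT
  ch <- oxygen@Ao[["h"]] * densities$rhoH / caps@rhoCH

  if (method == "algebraic") {
    x <- numeric(ne)
    nocells <- (ct + ch) == 0
    x[nocells & ktrans > 0] <- oxygen@rhoBO
    todo <- which(!nocells & ktrans > 0)
    if (length(todo)) {
      lo <- numeric(length(todo))
      hi <- rep(oxygen@rhoBO, length(todo))
      for (i in seq_len(120)) {
        mid <- (lo + hi) / 2
        pos <- .oxygenBalance(mid, ktrans[todo], ct[todo], ch[todo], oxygen) > 0
        lo[pos] <- mid[pos]
        hi[!pos] <- mid[!pos]
      }
      x[todo] <- (lo + hi) / 2
    }
    if (getOption("prostasim.verbose", FALSE)) {
      hyp <- sum(ktrans == 0 & (ct + ch) > 0)
      if (hyp) message(hyp, " avascular element(s) with cells: oxygen -> 0")
    }
    return(x)
  }

  x <- if (is.null(rhoO0)) numeric(ne) else rep_len(rhoO0, ne)
  deriv <- function(t, y, parms)
    list(.oxygenBalance(y, ktrans, ct, ch, oxygen))
  # march in blocks that grow geometrically once the dynamics prove slow;
  # convergence is judged on the change over the final dtd substep of a block
  block <- oxygen@dtd
  for (it in seq_len(200L)) {
    times <- if (block > oxygen@dtd) c(0, block - oxygen@dtd, block)
             else c(0, block)
    sol <- deSolve::ode(y = x, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-10)
    last <- sol[nrow(sol), -1]
    prev <- sol[nrow(sol) - 1, -1]
    x <- pmin(pmax(last, 0), oxygen@rhoBO)
    if (max(abs(last - prev) / pmax(abs(last), 1e-12)) < oxygen@tol) break
    block <- block * 2
  }
  unname(x)
}
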