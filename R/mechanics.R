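# Morphoelastic growth mechanics. Each 10-day increment treats the current
# mesh as reference configuration: per-constituent growth stretches are
# aggregated into an isotropic eigenstrain (the thermal-expansion analogy,
# Jg = (1 + alpha dT)^3), a small-strain linear tetrahedral FE problem with
# elastic-foundation boundary springs is solved, and densities are rescaled
# by the elastic volume ratio so mass is conserved from the grown to the
# current configuration.

#' Growth stretch of one constituent
#'
#' Two-branch law on the grown vs pre-step density: mass loss shrinks the
#' element linearly (rate kd1), mass gain expands it through a bounded
#' sigmoid (kv1 + kv2 at saturation). The branches are intentionally
#' discontinuous at rhoG = rho0+ (the sigmoid exceeds 1 for any positive
#' density); `continuous = TRUE` rescales the growth branch so that growth
#' starts from 1.
#'
#' @param rhoG grown (post-reaction) density per element.
#' @param rho0 pre-step density per element.
#' @param rhoC carrying capacity of the constituent.
#' @param mech a [MechanicsParams-class] (kv1, kv2, kd1).
#' @param k corrected carrying capacity (caps the sigmoid argument scale).
#' @param continuous rescale the growth branch to be continuous at rhoG=rho0.
#' @return per-element growth stretch, floored at 0.1.
#' @examples
#' growthStretch(0.9, 1, 1, mechanicsParams(), 0.57)  # 10% mass loss -> 0.7
#' @export
growthStretch <- function(rhoG, rho0, rhoC, mech = mechanicsParams(),
                          k = growthParams()@k, continuous = FALSE) {
  n <- max(length(rhoG), length(rho0))
  rhoG <- rep_len(rhoG, n)
  rho0 <- rep_len(rho0, n)
  lam <- rep(1, n)
  shrink <- rhoG <= rho0 & rho0 > 0
  lam[shrink] <- 1 + mech@kd1 * (rhoG[shrink] - rho0[shrink]) / rho0[shrink]
  grow <- rhoG > rho0
  sig <- 1 / (1 + exp(-rhoG[grow] / (k * rhoC)))
  lam[grow] <- if (continuous) {
    # shift the growth branch so it departs from 1 at rhoG = rho0
    sig0 <- 1 / (1 + exp(-rho0[grow] / (k * rhoC)))
    1 + mech@kv2 * (sig - sig0)
  } else mech@kv1 + mech@kv2 * sig
  if (getOption("prostasim.verbose", FALSE) && any(rhoG > 0 & rho0 == 0))
    message(sum(rhoG > 0 & rho0 == 0),
            " element(s) grew from zero density: pure growth branch")
  pmax(lam, 0.1)
}

#' Aggregate eigenstrain temperature analogue of an element
#'
#' The constituents deform together; their individual growth stretches are
#' combined with grown-volume-fraction weights w_i = (rhoG_i/rhoC_i) /
#' sum_j (rhoG_j/rhoC_j), and the isotropic eigenstrain is dT = lambda - 1
#' (so Jg = (1 + alpha dT)^3 with alpha = 1). Empty elements get dT = 0.
#'
#' @param lambdas list of per-element growth stretches (t, h, s).
#' @param densitiesG list of grown densities (rhoT, rhoH, rhoS).
#' @param caps a [CarryingCapacities-class].
#' @return per-element dT.
#' @export
elementEigenstrain <- function(lambdas, densitiesG, caps = carryingCapacities()) {
  ft <- densitiesG$rhoT / caps@rhoCT
  fh <- densitiesG$rhoH / caps@rhoCH
  fs <- densitiesG$rhoS / caps@rhoCS
  tot <- ft + fh + fs
  lam <- ifelse(tot > 0,
                (ft * lambdas$t + fh * lambdas$h + fs * lambdas$s) /
                  pmax(tot, .Machine$double.xmin),
                1)
  lam - 1
}

#' Rule-of-mixtures element stiffness
#'
#' E = Et rhoT/rhoCT + Eh rhoH/rhoCH + Es rhoS/rhoCS, floored at Emin.
#'
#' @param densities list of per-element densities (rhoT, rhoH, rhoS).
#' @param caps a [CarryingCapacities-class].
#' @param mech a [MechanicsParams-class].
#' @return per-element Young's modulus (kPa).
#' @export
mixtureModulus <- function(densities, caps = carryingCapacities(),
                           mech = mechanicsParams()) {
  E <- mech@Et * densities$rhoT / caps@rhoCT +
       mech@Eh * densities$rhoH / caps@rhoCH +
       mech@Es * densities$rhoS / caps@rhoCS
  pmax(E, mech@Emin)
}

# constant shape-function gradients and volumes of all tets
.tetGradients <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  cross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                p[, 1] * q[, 2] - p[, 2] * q[, 1])
  det6 <- rowSums(u * cross(v, w))
  g2 <- cross(v, w) / det6
  g3 <- cross(w, u) / det6
  g4 <- cross(u, v) / det6
  list(V = det6 / 6, G = list(-(g2 + g3 + g4), g2, g3, g4))
}

# stiffness triplets for one isotropic material field (vectorised over
# elements): K[3(a-1)+i, 3(b-1)+j] = V (lam Ga_i Gb_j + mu Ga_j Gb_i +
# mu delta_ij Ga.Gb)
.stiffnessTriplets <- function(gr, tets, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V <- gr$V
  G <- gr$G
  ne <- nrow(tets)
  ii <- integer(144L * ne)
  jj <- integer(144L * ne)
  xx <- numeric(144L * ne)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    Ga <- G[[a]]
    Gb <- G[[b]]
    dot <- rowSums(Ga * Gb)
    ra <- 3L * (tets[, a] - 1L)
    rb <- 3L * (tets[, b] - 1L)
    for (i in 1:3) for (j in 1:3) {
      sel <- pos + seq_len(ne)
      ii[sel] <- ra + i
      jj[sel] <- rb + j
      xx[sel] <- V * (lam * Ga[, i] * Gb[, j] + mu * Ga[, j] * Gb[, i] +
                      (i == j) * mu * dot)
      pos <- pos + ne
    }
  }
  list(i = ii, j = jj, x = xx)
}

# eigenstrain load: f_a = V dT (3 lam + 2 mu) grad N_a
.eigenLoad <- function(gr, tets, E, nu, dT, ndof) {
  coef <- gr$V * dT * (3 * E * nu / ((1 + nu) * (1 - 2 * nu)) + E / (1 + nu))
  f <- numeric(ndof)
  for (a in 1:4) for (i in 1:3) {
    s <- rowsum(coef * gr$G[[a]][, i], 3L * (tets[, a] - 1L) + i)
    f[as.integer(rownames(s))] <- f[as.integer(rownames(s))] + s[, 1]
  }
  f
}

# lumped elastic-foundation springs on the boundary triangles: normal
# stiffness Kn plus tangential Kt (rigid-mode regularization), A/3 per node
.springTriplets <- function(nodes, facets, Kn, Kt) {
  fn <- .facetNormals(nodes, facets)
  nh <- fn$normals
  A3 <- fn$areas / 3
  nf <- nrow(facets)
  ii <- integer(27L * nf)
  jj <- integer(27L * nf)
  xx <- numeric(27L * nf)
  pos <- 0L
  for (v in 1:3) for (i in 1:3) for (j in 1:3) {
    sel <- pos + seq_len(nf)
    ii[sel] <- 3L * (facets[, v] - 1L) + i
    jj[sel] <- 3L * (facets[, v] - 1L) + j
    xx[sel] <- A3 * (Kn * nh[, i] * nh[, j] + Kt * ((i == j) - nh[, i] * nh[, j]))
    pos <- pos + nf
  }
  list(i = ii, j = jj, x = xx)
}

# 3-2-1 penalty constraints compatible with homogeneous expansion (test mode
# for spring-free problems): returns triplets
.pinTriplets <- function(nodes, penalty) {
  crossv <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                             p[3] * q[1] - p[1] * q[3],
                             p[1] * q[2] - p[2] * q[1])
  na <- which.min(rowSums(sweep(nodes, 2, colMeans(nodes))^2))
  d <- sweep(nodes, 2, nodes[na, ])
  nb <- which.max(rowSums(d^2))
  e1 <- d[nb, ] / sqrt(sum(d[nb, ]^2))
  perp <- d - outer(drop(d %*% e1), e1)
  nc <- which.max(rowSums(perp^2))
  add <- function(node, dir) {
    idx <- 3L * (node - 1L) + 1:3
    cbind(rep(idx, each = 3), rep(idx, 3), penalty * as.numeric(outer(dir, dir)))
  }
  # node na: fully fixed; node nb: directions perpendicular to the na-nb line;
  # node nc: the normal of the (na, nb, nc) plane. Compatible with any
  # homogeneous expansion centred at na.
  u2 <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p2 <- u2 - sum(u2 * e1) * e1
  p2 <- p2 / sqrt(sum(p2^2))
  p3 <- crossv(e1, p2)
  e2 <- perp[nc, ] / sqrt(sum(perp[nc, ]^2))
  e3 <- crossv(e1, e2)
  m <- rbind(add(na, c(1, 0, 0)), add(na, c(0, 1, 0)), add(na, c(0, 0, 1)),
             add(nb, p2), add(nb, p3), add(nc, e3))
  list(i = as.integer(m[, 1]), j = as.integer(m[, 2]), x = m[, 3])
}

#' Solve the incremental growth elasticity problem
#'
#' Small-strain isotropic linear elasticity on the current mesh with an
#' isotropic eigenstrain dT per element and elastic-foundation boundary
#' springs (normal stiffness `mech@Kstiffness`, tangential
#' `mech@Ktangential`). With `E` a list of several modulus fields the
#' stiffness (and load) of each field is assembled on the same nodes and
#' summed - the two-overlapping-mesh description of cellular and stromal
#' phases; by linearity this equals a single assembly with the summed
#' modulus.
#'
#' @param mesh a [TetMesh-class] (the current configuration).
#' @param dT per-element eigenstrain temperature analogue.
#' @param E per-element Young's modulus (kPa), or a list of modulus fields to
#'   superpose.
#' @param mech a [MechanicsParams-class].
#' @param pinRigid use 3-2-1 penalty constraints instead of boundary springs
#'   (required when both foundation stiffnesses are zero).
#' @param cache optional environment reused across steps of one simulation:
#'   the sparsity pattern, its triplet-aggregation map and the symbolic
#'   Cholesky factorization are constant while the connectivity is, so they
#'   are computed once.
#' @return list with `u` (n x 3 nodal displacements, mm), `J` (per-element
#'   total volume ratio det(I + grad u)), `Jg` ((1 + alpha dT)^3), `Je`
#'   (elastic volume ratio J/Jg), `newNodes`, and `stress` (6 x ne matrix of
#'   element stresses, kPa; rows xx, yy, zz, xy, yz, zx).
#' @export
solveElasticity <- function(mesh, dT, E, mech = mechanicsParams(),
                            pinRigid = FALSE, cache = NULL) {
  Elist <- if (is.list(E)) E else list(E)
  ne <- nElements(mesh)
  for (Ef in Elist)
    if (length(Ef) != ne) stop("each modulus field needs one value per element")
  if (length(dT) != ne) stop("dT needs one value per element")
  ndof <- 3L * nNodes(mesh)
  gr <- .tetGradients(mesh@nodes, mesh@tets)
  trips <- lapply(Elist, function(Ef) .stiffnessTriplets(gr, mesh@tets, Ef, mech@nu))
  f <- Reduce(`+`, lapply(Elist, function(Ef)
    .eigenLoad(gr, mesh@tets, Ef, mech@nu, dT, ndof)))
  if (mech@Kstiffness > 0 || mech@Ktangential > 0)
    trips <- c(trips, list(.springTriplets(mesh@nodes, mesh@surfaceFacets,
                                           mech@Kstiffness, mech@Ktangential)))
  else if (pinRigid)
    trips <- c(trips, list(.pinTriplets(mesh@nodes,
                                        1e8 * max(abs(trips[[1]]$x)))))
  else
    stop("singular system: no boundary springs and rigid modes not pinned")
  ii <- unlist(lapply(trips, `[[`, "i"))
  jj <- unlist(lapply(trips, `[[`, "j"))
  xx <- unlist(lapply(trips, `[[`, "x"))
  if (is.null(cache) || pinRigid) {
    K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
    u <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K), f))
  } else {
    if (is.null(cache$agg)) {
      K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
      Ki <- K@i + 1
      Kj <- rep(seq_len(ndof), diff(K@p))
      pos <- match((jj - 1) * ndof + ii, (Kj - 1) * ndof + Ki)
      cache$agg <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                                        dims = c(length(K@x), length(pos)))
      cache$K <- K
      cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(K),
                                     LDL = FALSE, super = TRUE)
    } else {
      K <- cache$K
      K@x <- as.numeric(cache$agg %*% xx)
      cache$K <- K
      upd <- tryCatch(suppressWarnings(
        Matrix::update(cache$chol, Matrix::forceSymmetric(K))),
        error = function(e) NULL)
      if (!is.null(upd)) cache$chol <- upd else upd <- NA
    }
    u <- as.numeric(Matrix::solve(cache$chol, f))
    # fall back to a direct solve if the updated factorization went bad
    # (near-degenerate elements can defeat the supernodal update)
    if (any(!is.finite(u)))
      u <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K), f))
  }
  U <- matrix(u, ncol = 3, byrow = TRUE)

  # per-element displacement gradient H (3x3, constant), J = det(I + H)
  H <- matrix(0, ne, 9)
  for (a in 1:4) {
    Ua <- U[mesh@tets[, a], , drop = FALSE]
    Ga <- gr$G[[a]]
    # H[i, j] += Ua_i Ga_j, column-major 3x3 flattening
    H <- H + cbind(Ua[, 1] * Ga[, 1], Ua[, 2] * Ga[, 1], Ua[, 3] * Ga[, 1],
                   Ua[, 1] * Ga[, 2], Ua[, 2] * Ga[, 2], Ua[, 3] * Ga[, 2],
                   Ua[, 1] * Ga[, 3], Ua[, 2] * Ga[, 3], Ua[, 3] * Ga[, 3])
  }
  F11 <- 1 + H[, 1]; F21 <- H[, 2]; F31 <- H[, 3]
  F12 <- H[, 4]; F22 <- 1 + H[, 5]; F32 <- H[, 6]
  F13 <- H[, 7]; F23 <- H[, 8]; F33 <- 1 + H[, 9]
  J <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
       F13 * (F21 * F32 - F22 * F31)
  if (any(J <= 0))
    stop(sprintf("element inversion: element %d has J = %.3g",
                 which.min(J), min(J)))
  Jg <- (1 + mech@alpha * dT)^3
  if (any(Jg <= 0))
    stop(sprintf("growth ratio non-positive in element %d", which.min(Jg)))

  # element stresses from the summed modulus: sigma = D (eps - dT I)
  Etot <- Reduce(`+`, Elist)
  lam <- Etot * mech@nu / ((1 + mech@nu) * (1 - 2 * mech@nu))
  mu <- Etot / (2 * (1 + mech@nu))
  exx <- H[, 1] - dT; eyy <- H[, 5] - dT; ezz <- H[, 9] - dT
  gxy <- H[, 4] + H[, 2]; gyz <- H[, 8] + H[, 6]; gzx <- H[, 3] + H[, 7]
  tr <- exx + eyy + ezz
  stress <- rbind(xx = lam * tr + 2 * mu * exx, yy = lam * tr + 2 * mu * eyy,
                  zz = lam * tr + 2 * mu * ezz, xy = mu * gxy,
                  yz = mu * gyz, zx = mu * gzx)

  list(u = U, J = J, Jg = Jg, Je = J / Jg, newNodes = mesh@nodes + U,
       stress = stress)
}

#' Rescale densities from the grown to the current configuration
#'
#' Mass conservation across the elastic map: rho_i = rhoG_i / Je per element,
#' so that rhoG * Vg = rho * V exactly (Vg = V0 Jg, V = V0 J, Je = J/Jg).
#'
#' @param densitiesG list of grown densities (rhoT, rhoH, rhoS).
#' @param Je per-element elastic volume ratio (> 0).
#' @return list of current-configuration densities.
#' @export
updateDensities <- function(densitiesG, Je) {
  if (any(Je <= 0)) stop("Je must be > 0")
  lapply(densitiesG, function(rho) rho / Je)
}
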