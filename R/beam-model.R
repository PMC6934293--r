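# Beam-model assembly: turning a discretized pre-shape centerline plus
# equivalent material into a chain of corotational Timoshenko elements
# with lumped masses, rotary inertias and stress-free rest strains.

# ---- quaternion helpers (w, x, y, z; world_from_body) ----

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_rotate <- function(q, v) {
  u <- q[2:4]
  t <- 2 * c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  v + q[1] * t + c(u[2] * t[3] - u[3] * t[2], u[3] * t[1] - u[1] * t[3],
                   u[1] * t[2] - u[2] * t[1])
}

# parallel-transported orthonormal frames along a node chain; column 1 of
# each rotation matrix is the local tangent (beam axis)
node_frames <- function(nodes) {
  n <- nrow(nodes)
  tang <- rbind(nodes[2, ] - nodes[1, ],
                nodes[pmin(seq_len(n) + 1, n), ] -
                  nodes[pmax(seq_len(n) - 1, 1), ])[-1, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  q <- matrix(0, n, 4)
  t1 <- tang[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  nrm <- ref - sum(ref * t1) * t1
  nrm <- nrm / sqrt(sum(nrm^2))
  for (i in seq_len(n)) {
    ti <- tang[i, ]
    nrm <- nrm - sum(nrm * ti) * ti
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) nrm <- c(0, 0, 1) - ti[3] * ti else nrm <- nrm / nn
    nrm <- nrm / sqrt(sum(nrm^2))
    bi <- c(ti[2] * nrm[3] - ti[3] * nrm[2],
            ti[3] * nrm[1] - ti[1] * nrm[3],
            ti[1] * nrm[2] - ti[2] * nrm[1])
    q[i, ] <- quat_from_matrix(cbind(ti, nrm, bi))
    if (i > 1 && sum(q[i, ] * q[i - 1, ]) < 0) q[i, ] <- -q[i, ]
  }
  q
}

#' Assemble a beam model from a centerline and coil properties
#'
#' Builds the discrete rod: per-node orientation frames (parallel
#' transport, beam axis = local tangent), element section/material
#' constants in the internal mm/mg/ms unit system, lumped masses and rotary
#' inertias, and the rest strain measures that encode the pre-shape memory.
#' The assembled rest configuration is stress-free by construction.
#'
#' @param centerline a `coil_centerline` from [discretize_curve()] or
#'   [make_preshape()]
#' @param props a [coil_beam_properties()]
#' @param rot_inertia_scale multiplier on the lumped rotary inertia
#'   `m * h^2 / 12`; values above 1 slow rotational waves without
#'   affecting quasi-static response
#' @return Object of class `beam_model`.
#' @export
build_beam_model <- function(centerline, props, rot_inertia_scale = 1) {
  stopifnot(inherits(centerline, "coil_centerline"),
            inherits(props, "coil_beam_properties"))
  nodes <- centerline$nodes
  n <- nrow(nodes)
  q <- node_frames(nodes)
  L0 <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                      nodes[-n, , drop = FALSE])^2))
  sect <- props$section
  mat <- props$material
  Eb <- mat$Eb * GPA_TO_INTERNAL
  Gb <- mat$Gb * GPA_TO_INTERNAL
  ne <- n - 1L
  elem <- list(
    nodeA = seq_len(ne), nodeB = seq_len(ne) + 1L,
    L0 = L0,
    EA = rep(Eb * sect$Ab, ne),
    GAs = rep(props$shear_section$lam * Gb * sect$Ab, ne),
    EI = rep(Eb * sect$Ib, ne),
    GJ = rep(Gb * sect$J, ne),
    Gamma0 = matrix(0, ne, 3),
    kappa0 = matrix(0, ne, 3)
  )
  for (e in seq_len(ne)) {
    qi <- q[e, ]; qj <- q[e + 1, ]
    if (sum(qi * qj) < 0) qj <- -qj
    qe <- qi + qj; qe <- qe / sqrt(sum(qe^2))
    d <- nodes[e + 1, ] - nodes[e, ]
    elem$Gamma0[e, ] <- quat_rotate(quat_conj(qe), d) / L0[e]
    rel <- quat_mult(quat_conj(qi), qj)
    if (rel[1] < 0) rel <- -rel
    elem$kappa0[e, ] <- 2 * rel[2:4] / L0[e]
  }
  rho <- props$density$rho_eff
  tributary <- c(L0 / 2, 0) + c(0, L0 / 2)
  mass <- rho * sect$Ab * tributary
  h_node <- c(L0[1], pmax(L0[-ne], L0[-1])[seq_len(max(ne - 1, 0))], L0[ne])
  inertia <- rot_inertia_scale * mass * h_node^2 / 12
  structure(list(nodes = nodes, q = q, elem = elem, mass = mass,
                 inertia = inertia, r_contact = props$secondary$D2 / 2,
                 props = props, h = centerline$h),
            class = "beam_model")
}

#' Straight rod model with explicit section constants
#'
#' A utility constructor for solver verification: a straight chain of
#' `n_el` equal elements along the x axis with directly specified
#' stiffness constants (internal units: mN, mm, mg, ms).  Used for
#' cantilever, oscillator and wave-propagation checks where coil-specific
#' properties would make the relevant time scales inconvenient.
#'
#' @param L rod length (mm)
#' @param n_el element count
#' @param EA,GAs,EI,GJ section stiffness constants (mN, mN, mN*mm^2,
#'   mN*mm^2)
#' @param rho_line mass per unit length (mg/mm)
#' @param rot_inertia_scale multiplier on `m h^2 / 12`
#' @return A `beam_model`.
#' @export
straight_rod_model <- function(L, n_el, EA, GAs, EI, GJ, rho_line,
                               rot_inertia_scale = 1) {
  h <- L / n_el
  nodes <- cbind(seq(0, L, length.out = n_el + 1), 0, 0)
  q <- matrix(rep(c(1, 0, 0, 0), n_el + 1), ncol = 4, byrow = TRUE)
  ne <- n_el
  elem <- list(nodeA = seq_len(ne), nodeB = seq_len(ne) + 1L,
               L0 = rep(h, ne), EA = rep(EA, ne), GAs = rep(GAs, ne),
               EI = rep(EI, ne), GJ = rep(GJ, ne),
               Gamma0 = matrix(rep(c(1, 0, 0), ne), ncol = 3, byrow = TRUE),
               kappa0 = matrix(0, ne, 3))
  mass <- rho_line * c(h / 2, rep(h, ne - 1), h / 2)
  inertia <- rot_inertia_scale * mass * h^2 / 12
  structure(list(nodes = nodes, q = q, elem = elem, mass = mass,
                 inertia = inertia, r_contact = h / 4,
                 props = list(density = list(rho_eff = rho_line),
                              section = list(Ab = 1)),
                 h = h),
            class = "beam_model")
}

#' Combine beam models into one multi-chain model
#'
#' Concatenates node chains so several coils can be simulated together
#' (element connectivity is explicit, so chains remain mechanically
#' independent but interact through self-contact).  All chains share the
#' contact radius of the first coil.
#'
#' @param models list of `beam_model` objects
#' @return A `beam_model` with a `chains` attribute giving each chain's
#'   node index range.
#' @export
combine_models <- function(models) {
  stopifnot(length(models) >= 1)
  if (length(models) == 1) return(models[[1]])
  offset <- 0L
  chains <- list()
  nodes <- NULL; q <- NULL; mass <- NULL; inertia <- NULL
  elem <- list(nodeA = integer(0), nodeB = integer(0), L0 = numeric(0),
               EA = numeric(0), GAs = numeric(0), EI = numeric(0),
               GJ = numeric(0), Gamma0 = matrix(0, 0, 3),
               kappa0 = matrix(0, 0, 3))
  for (k in seq_along(models)) {
    m <- models[[k]]
    n <- nrow(m$nodes)
    chains[[k]] <- c(offset + 1L, offset + n)
    nodes <- rbind(nodes, m$nodes); q <- rbind(q, m$q)
    mass <- c(mass, m$mass); inertia <- c(inertia, m$inertia)
    elem$nodeA <- c(elem$nodeA, m$elem$nodeA + offset)
    elem$nodeB <- c(elem$nodeB, m$elem$nodeB + offset)
    for (f in c("L0", "EA", "GAs", "EI", "GJ"))
      elem[[f]] <- c(elem[[f]], m$elem[[f]])
    elem$Gamma0 <- rbind(elem$Gamma0, m$elem$Gamma0)
    elem$kappa0 <- rbind(elem$kappa0, m$elem$kappa0)
    offset <- offset + n
  }
  out <- structure(list(nodes = nodes, q = q, elem = elem, mass = mass,
                        inertia = inertia,
                        r_contact = models[[1]]$r_contact,
                        props = models[[1]]$props, h = models[[1]]$h),
                   class = "beam_model")
  attr(out, "chains") <- chains
  out
}

#' Total mass of a beam model
#' @param model a `beam_model`
#' @return Mass in mg.
#' @export
model_mass <- function(model) sum(model$mass)

#' Simulation state
#'
#' Holds node kinematics, simulation clock and the cumulative energy
#' ledger.  Created at rest from a model by `sim_state(model)`.
#'
#' @param model a `beam_model`
#' @return Object of class `sim_state`.
#' @export
sim_state <- function(model) {
  n <- nrow(model$nodes)
  structure(list(x = model$nodes, q = model$q,
                 v = matrix(0, n, 3), w = matrix(0, n, 3),
                 time = 0,
                 energy = c(kinetic = 0, strain = 0, contact = 0,
                            dissipated = 0, ext_work = 0),
                 max_penetration = 0,
                 ledger = NULL, status = "ok"),
            class = "sim_state")
}
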