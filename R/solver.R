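# Explicit central-difference solver: configuration, stable time step,
# boundary conditions and the R-facing driver around the C++ kernel.

#' Smooth-step displacement amplitude
#'
#' The quintic ramp used for all displacement boundary conditions: between
#' `t0` and `t1` the amplitude moves from `A0` to `A1` along
#' `A0 + (A1 - A0) * xi^3 (10 - 15 xi + 6 xi^2)` with
#' `xi = clamp((t - t0)/(t1 - t0), 0, 1)`.  First and second derivatives
#' vanish at both ends, so driven nodes start and stop without jerk.
#'
#' @param t time(s) (ms)
#' @param t0,t1 ramp start and end times (ms), `t1 > t0`
#' @param A0,A1 start and end amplitudes
#' @return Amplitude at `t` (vectorized over `t`).
#' @export
smooth_step <- function(t, t0, t1, A0 = 0, A1 = 1) {
  if (t1 <= t0) stop_domain("need t1 > t0")
  xi <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  A0 + (A1 - A0) * xi^3 * (10 - 15 * xi + 6 * xi^2)
}

#' Solver configuration
#'
#' @param alpha mass-proportional Rayleigh damping (1/ms equivalent of the
#'   conventional 1/s value divided by 1000; the default corresponds to
#'   1 s^-1)
#' @param beta stiffness-proportional Rayleigh damping (ms; default
#'   corresponds to 1e-6 s)
#' @param dt_safety stable-time-step safety factor in (0, 1]
#' @param kn normal penalty stiffness (mN/mm); `NULL` selects the default
#'   `10 Eb Ab / D2` when the model is known
#' @param kt tangential penalty stiffness (mN/mm); default `kn / 10`
#' @param mu_self coil-coil friction coefficient
#' @param mu_wall coil-to-aneurysm-wall friction coefficient
#' @param mu_catheter coil-to-catheter friction coefficient
#' @param contact_damping viscous damping ratio of the penalty contacts
#' @param checkpoint_every ledger sampling interval in steps
#' @param self_contact enable coil self contact
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(alpha = 1e-3, beta = 1e-3, dt_safety = 0.9,
                          kn = NULL, kt = NULL, mu_self = 0.2,
                          mu_wall = 0.6, mu_catheter = 0,
                          contact_damping = 0.2,
                          checkpoint_every = 50, self_contact = TRUE) {
  if (alpha < 0 || beta < 0) stop_domain("damping coefficients must be >= 0")
  if (dt_safety <= 0 || dt_safety > 1) stop_domain("dt_safety must be in (0,1]")
  structure(list(alpha = alpha, beta = beta, dt_safety = dt_safety,
                 kn = kn, kt = kt, mu_self = mu_self, mu_wall = mu_wall,
                 mu_catheter = mu_catheter, contact_damping = contact_damping,
                 checkpoint_every = checkpoint_every,
                 self_contact = self_contact),
            class = "solver_config")
}

default_kn <- function(model) {
  # calibrated so static penetration stays a small fraction of D2
  ea <- model$elem$EA[1]
  10 * ea / (2 * model$r_contact)
}

#' Stable explicit time step
#'
#' Bounds the step by the highest element frequency: axial/shear wave
#' transit `2c/h`, the rotational bending/torsion frequency of the lumped
#' rotary inertia, and the contact-spring frequency `sqrt(kn/m)` when
#' contact is possible.  With Rayleigh damping the undamped bound is
#' reduced by the standard factor `sqrt(1 + xi^2) - xi` evaluated at the
#' critical frequency.
#'
#' @param model a `beam_model`
#' @param config a [solver_config()]
#' @param with_contact include the contact-spring frequency bound
#' @return Time step (ms).
#' @export
stable_dt <- function(model, config = solver_config(), with_contact = TRUE) {
  el <- model$elem
  if (any(el$L0 <= 0)) stop_domain("zero-length element")
  ne <- length(el$L0)
  rho_line <- model$props$density$rho_eff * model$props$section$Ab
  cax <- sqrt(pmax(el$EA, el$GAs) / rho_line)
  omega <- 2 * cax / el$L0
  # rotational stiffness seen by a node's rotary inertia
  i_min <- pmin(model$inertia[el$nodeA], model$inertia[el$nodeB])
  k_rot <- 2 * (el$EI + el$GJ) / el$L0 + el$GAs * el$L0 / 2
  omega <- pmax(omega, 2 * sqrt(k_rot / i_min))
  if (with_contact) {
    # factor 4 covers several simultaneous contacts stacking on one node
    kn <- config$kn %||% default_kn(model)
    omega <- pmax(omega, 4 * sqrt(kn / min(model$mass)))
  }
  om <- max(omega)
  xi <- config$alpha / (2 * om) + config$beta * om / 2
  config$dt_safety * (2 / om) * (sqrt(1 + xi^2) - xi)
}

#' Internal beam forces and moments
#'
#' Evaluates the corotational Timoshenko element forces for a state:
#' axial `Eb Ab eps`, shear through the corrected stiffness
#' `lam Gb Ab`, bending `Eb Ib` times the curvature change relative to the
#' rest (pre-shape) curvature, torsion `Gb J`.  Resultants are equal and
#' opposite across each element.
#'
#' @param model a `beam_model`
#' @param x node positions (defaults to the model rest positions)
#' @param q node quaternions (defaults to the rest frames)
#' @return List with `force` (n x 3, mN), `torque` (n x 3, mN*mm), and
#'   elastic `energy` (microjoule).
#' @export
internal_forces <- function(model, x = model$nodes, q = model$q) {
  if (any(!is.finite(x))) stop_domain("NaN/Inf in state positions")
  cpp_internal_forces(x, q, model$elem)
}

#' Displacement boundary condition along a path
#'
#' Drives one node along an arc-length-parameterized polyline path with a
#' smooth-step schedule from `s_from` to `s_to` over `[t0, t1]` (local run
#' time); after `t1` the node is held at `s_to`.
#'
#' @param node driven node index (1-based)
#' @param path k x 3 polyline (mm)
#' @param s_from,s_to start/end arc-length positions on the path (mm)
#' @param t0,t1 ramp window (ms)
#' @return A `path_bc` object.
#' @export
path_bc <- function(node, path, s_from, s_to, t0, t1) {
  path <- as.matrix(path)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  structure(list(node = as.integer(node), path = path, s = c(0, cumsum(seg)),
                 s_from = s_from, s_to = s_to, t0 = t0, t1 = t1),
            class = "path_bc")
}

#' Analytic swept-tube confinement barrier
#'
#' Keeps coil nodes inside a tube of the given inner radius around a
#' polyline centerline; a conical funnel of the given length and slope
#' extends the proximal entrance so a bulky pre-shape can be drawn in.
#' Nodes whose closest path point lies beyond `s_max` (the distal opening)
#' are unconstrained.
#'
#' @param path k x 3 tube centerline (mm)
#' @param radius inner radius (mm)
#' @param mu friction coefficient
#' @param funnel_len,funnel_slope proximal funnel extent (mm) and radial
#'   growth per mm
#' @param s_max arc length of the distal opening (defaults to the path
#'   length)
#' @return A `tube_barrier` object.
#' @export
tube_barrier <- function(path, radius, mu = 0, funnel_len = 0,
                         funnel_slope = 1, s_max = NULL) {
  path <- as.matrix(path)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  structure(list(path = path, s = s, radius = radius, mu = mu,
                 funnel_len = funnel_len, funnel_slope = funnel_slope,
                 s_max = s_max %||% tail(s, 1)),
            class = "tube_barrier")
}

#' Rigid triangulated contact barrier
#'
#' @param surface a `tri_surface` (outward normals)
#' @param mu friction coefficient
#' @param keep `"inside"` (coil stays inside the closed surface, e.g. the
#'   aneurysm sac) or `"front"` (one-sided barrier, coil stays on the
#'   +normal side, e.g. the neck cover)
#' @param thickness activation band (mm) beyond which a node is considered
#'   to have left this barrier's scope
#' @param contact_radius largest coil radius expected against this
#'   barrier (mm); only used to size the conservative contact prunes
#' @return A `mesh_barrier` object.
#' @export
mesh_barrier <- function(surface, mu = 0.6, keep = c("inside", "front"),
                         thickness = 0.5, contact_radius = 0.5) {
  keep <- match.arg(keep)
  stopifnot(inherits(surface, "tri_surface"))
  # sphere prunes about the vertex centroid: a node well inside a closed
  # keep-inside surface, or far from any barrier, cannot be in contact
  cen <- colMeans(surface$vertices)
  dv <- sqrt(colSums((t(surface$vertices) - cen)^2))
  skip_in <- if (keep == "inside") max(min(dv) - 2 * contact_radius, 0) else -1
  skip_out <- max(dv) + 2 * contact_radius
  structure(list(vertices = surface$vertices, triangles = surface$triangles,
                 mu = mu, keep_inside = keep == "inside",
                 thickness = thickness, prune_center = cen,
                 skip_in_r = skip_in, skip_out_r = skip_out),
            class = "mesh_barrier")
}

#' Advance a simulation
#'
#' Runs explicit central-difference integration for `duration` (ms) from
#' `state`, with optional displacement boundary conditions, barriers and
#' constant external nodal forces.  The energy ledger (kinetic, elastic
#' strain, contact-spring, dissipated, external work; microjoule) is
#' accumulated across calls, so packaging / advancement / deployment can
#' be chained on one state.
#'
#' @param model a `beam_model`
#' @param state a `sim_state` (or `NULL` to start at rest)
#' @param duration simulated time (ms)
#' @param config a [solver_config()]
#' @param bcs list of [path_bc()] objects
#' @param tubes list of [tube_barrier()] objects
#' @param meshes list of [mesh_barrier()] objects
#' @param ext_force n x 3 constant external force (mN) or `NULL`
#' @param fixed_nodes indices of fully clamped nodes
#' @param dt time step override (ms); default [stable_dt()]
#' @param store_positions also checkpoint node positions (returned as the
#'   state's `trajectory` list of matrices)
#' @return Updated `sim_state`.
#' @export
run_sim <- function(model, state = NULL, duration, config = solver_config(),
                    bcs = list(), tubes = list(), meshes = list(),
                    ext_force = NULL, fixed_nodes = integer(0), dt = NULL,
                    store_positions = FALSE) {
  state <- state %||% sim_state(model)
  n <- nrow(model$nodes)
  with_contact <- length(tubes) + length(meshes) > 0 || config$self_contact
  dt <- dt %||% stable_dt(model, config, with_contact = with_contact)
  nsteps <- max(1, ceiling(duration / dt))
  kn <- config$kn %||% default_kn(model)
  kt <- config$kt %||% (kn / 10)
  cfg <- list(dt = dt, nsteps = nsteps, alpha = config$alpha,
              beta = config$beta, kn = kn, kt = kt,
              mu_self = config$mu_self, r_contact = model$r_contact,
              checkpoint_every = as.integer(config$checkpoint_every),
              self_contact = isTRUE(config$self_contact),
              self_skip = 2L,
              half_kick_first = state$time == 0,
              contact_damping = config$contact_damping,
              store_positions = isTRUE(store_positions))
  ext <- ext_force %||% matrix(0, n, 3)
  res <- cpp_run_sim(state$x, state$q, state$v, state$w, model$elem,
                     model$mass, model$inertia, cfg, unclass_list(bcs),
                     unclass_list(tubes), unclass_list(meshes), ext,
                     as.integer(fixed_nodes))
  if (!identical(res$status, "ok"))
    stop_domain("solver instability at t = ",
                signif(state$time + res$steps_done * dt, 4),
                " ms (status: ", res$status, "); kinetic energy ",
                signif(res$kinetic_energy, 4))
  led <- as.data.frame(res$ledger)
  if (nrow(led)) {
    led$t <- led$t + state$time
    led$dissipated <- led$dissipated + state$energy[["dissipated"]]
    led$ext_work <- led$ext_work + state$energy[["ext_work"]]
  }
  out <- state
  out$x <- res$x; out$q <- res$q; out$v <- res$v; out$w <- res$w
  out$time <- state$time + nsteps * dt
  out$energy <- c(kinetic = res$kinetic_energy,
                  strain = res$strain_energy,
                  contact = res$contact_energy,
                  dissipated = state$energy[["dissipated"]] + res$dissipated,
                  ext_work = state$energy[["ext_work"]] + res$ext_work)
  out$max_penetration <- max(state$max_penetration, res$max_penetration)
  out$ledger <- rbind(state$ledger, led)
  if (store_positions) out$trajectory <- res$trajectory
  out
}

unclass_list <- function(xs) lapply(xs, unclass)

#' Settle a state under damping
#'
#' Runs the solver with boundary conditions held (or absent) until the
#' kinetic energy falls below `tol` times the strain energy, or `max_time`
#' is reached.  Used between the mechanical steps of coiling.
#'
#' @inheritParams run_sim
#' @param tol kinetic/strain energy ratio at which the state is considered
#'   settled
#' @param max_time settling time cap (ms)
#' @param chunk time per solver call (ms)
#' @return Updated `sim_state`.
#' @export
settle <- function(model, state, config = solver_config(), bcs = list(),
                   tubes = list(), meshes = list(),
                   fixed_nodes = integer(0), tol = 1e-3, max_time = 50,
                   chunk = 5) {
  elapsed <- 0
  repeat {
    state <- run_sim(model, state, chunk, config, bcs = bcs, tubes = tubes,
                     meshes = meshes, fixed_nodes = fixed_nodes)
    elapsed <- elapsed + chunk
    ke <- state$energy[["kinetic"]]
    se <- max(state$energy[["strain"]], 1e-9)
    if (ke < tol * se || elapsed >= max_time) break
  }
  state
}
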