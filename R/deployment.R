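# Orchestration of the three mechanical steps of coiling — packaging into
# the catheter, advancement along the parent artery, deployment into the
# sac — plus rotated-initial-condition ensembles and sequential multi-coil
# treatments.
#
# All steps drive an end node of the coil along the catheter centerline
# with smooth-step displacement schedules; between steps the state is
# settled under damping until kinetic energy is a small fraction of strain
# energy (quasi-static surrogate).

# rotation matrix mapping unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(axis, axis) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
             axis[2], -axis[1], 0), 3, 3) * s_
}

#' Position a pre-shape at the catheter entrance
#'
#' Rigidly transforms a coil centerline so its distal node sits at the
#' proximal tip of the catheter with the coil body trailing behind into
#' the entry funnel, optionally rotated coaxially about the catheter axis
#' (the ensemble initial-condition parameter).
#'
#' @param cl a `coil_centerline`
#' @param catheter a [build_catheter()] result
#' @param rotation_deg coaxial rotation before packaging (degrees)
#' @return The transformed `coil_centerline`.
#' @export
position_preshape <- function(cl, catheter, rotation_deg = 0) {
  nodes <- cl$nodes
  t0 <- catheter$path[2, ] - catheter$path[1, ]
  t0 <- t0 / sqrt(sum(t0^2))
  # start at the funnel mouth so the pre-shape is drawn through the
  # converging cone before entering the tube proper
  entry <- catheter$path[1, ] - t0 * catheter$funnel_len
  axis <- nodes[nrow(nodes), ] - nodes[1, ]
  if (sqrt(sum(axis^2)) < 1e-9) axis <- c(0, 0, 1)
  R <- rotation_between(axis, -t0)        # coil body trails behind entry
  R <- axis_rotation(t0, rotation_deg * pi / 180) %*% R
  ctr <- nodes[1, ]
  nodes <- sweep(sweep(nodes, 2, ctr) %*% t(R), 2, entry, `+`)
  out <- cl
  out$nodes <- nodes
  out
}

catheter_tube_barrier <- function(catheter, mu = 0) {
  # resample the path at ~0.7 mm for the per-step nearest-point queries;
  # the chordal sagitta of the gentle catheter bends is ~0.01 mm, far
  # below the contact tolerances
  p <- catheter$path; s <- catheter$s
  sq <- unique(c(seq(0, tail(s, 1), by = 0.7), tail(s, 1)))
  rp <- cbind(approx(s, p[, 1], xout = sq)$y,
              approx(s, p[, 2], xout = sq)$y,
              approx(s, p[, 3], xout = sq)$y)
  tube_barrier(rp, catheter$inner_radius, mu = mu,
               funnel_len = catheter$funnel_len,
               funnel_slope = catheter$funnel_slope)
}

# arc-length positions of coil nodes along the catheter path
nodes_path_position <- function(state, catheter) {
  pts <- state$x
  segA <- catheter$path[-nrow(catheter$path), , drop = FALSE]
  segB <- catheter$path[-1, , drop = FALSE]
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- rowSums((segA - matrix(pts[i, ], nrow(segA), 3, byrow = TRUE))^2)
    j <- which.min(d2)  # coarse: nearest segment start
    ab <- segB[j, ] - segA[j, ]
    t <- max(0, min(1, sum((pts[i, ] - segA[j, ]) * ab) / sum(ab^2)))
    catheter$s[j] + t * sqrt(sum(ab^2))
  }, numeric(1))
}

#' Package a coil into the catheter
#'
#' Pulls the distal coil node along the catheter centerline by a
#' smooth-step displacement whose total amplitude equals the coil length,
#' drawing the pre-shape through the entry funnel until the whole coil is
#' inside the tube, then settles with the end held.
#'
#' @param model a `beam_model` built from a positioned pre-shape
#' @param catheter a [build_catheter()] result
#' @param config a [solver_config()]
#' @param duration pull time (ms); default paces the pull at about
#'   0.4 mm/ms
#' @param settle_time post-pull settling cap (ms)
#' @return A `sim_state` with attribute `"packaged_energy"`.
#' @export
package_coil <- function(model, catheter, config = solver_config(),
                         duration = NULL, settle_time = 20) {
  l <- sum(model$elem$L0)
  s0 <- -catheter$funnel_len
  duration <- duration %||% ((l - s0) / 0.4)
  tube <- catheter_tube_barrier(catheter, mu = config$mu_catheter)
  bc <- path_bc(1L, catheter$path, s_from = s0, s_to = l, t0 = 0,
                t1 = duration)
  st <- run_sim(model, NULL, duration, config, bcs = list(bc),
                tubes = list(tube))
  # the trailing end of the pre-shape takes a longer route through the
  # entry funnel than the tube axis; keep pulling in short increments
  # until every node is confined in the D2-radius tube
  s_now <- l
  repeat {
    d <- cpp_min_dist_to_segments(st$x,
                                  catheter$path[-nrow(catheter$path), ,
                                                drop = FALSE],
                                  catheter$path[-1, , drop = FALSE])
    if (max(d) <= catheter$inner_radius * 1.02 || s_now >= 1.6 * l) break
    ds <- min(0.1 * l, 1.6 * l - s_now)
    bc <- path_bc(1L, catheter$path, s_from = s_now, s_to = s_now + ds,
                  t0 = 0, t1 = ds / 0.4)
    st <- run_sim(model, st, ds / 0.4, config, bcs = list(bc),
                  tubes = list(tube))
    s_now <- s_now + ds
  }
  hold <- path_bc(1L, catheter$path, s_from = s_now, s_to = s_now,
                  t0 = -2, t1 = -1)
  st <- settle(model, st, config, bcs = list(hold), tubes = list(tube),
               max_time = settle_time)
  attr(st, "packaged_energy") <- st$energy[["strain"]]
  attr(st, "distal_s") <- s_now
  st
}

#' Advance a packaged coil to the aneurysm
#'
#' Pushes the proximal coil node along the catheter by a smooth-step
#' displacement with amplitude equal to the catheter centerline arc length
#' (vessel portion), bringing the distal tip to the orifice end of the
#' tube.
#'
#' @inheritParams package_coil
#' @param state the packaged `sim_state`
#' @return Advanced `sim_state` with attribute `"advanced_energy"`.
#' @export
advance_coil <- function(model, state, catheter, config = solver_config(),
                         duration = NULL, settle_time = 20) {
  n <- nrow(model$nodes)
  l <- sum(model$elem$L0)
  distal_s <- attr(state, "distal_s") %||% l
  # push until the distal tip reaches the orifice end of the tube
  amp <- catheter$total_length - distal_s
  duration <- duration %||% (amp / 0.4)
  tube <- catheter_tube_barrier(catheter, mu = config$mu_catheter)
  prox_s <- distal_s - l
  bc <- path_bc(n, catheter$path, s_from = prox_s, s_to = prox_s + amp,
                t0 = 0, t1 = duration)
  st <- run_sim(model, state, duration, config, bcs = list(bc),
                tubes = list(tube))
  hold <- path_bc(n, catheter$path, s_from = prox_s + amp,
                  s_to = prox_s + amp, t0 = -2, t1 = -1)
  st <- settle(model, st, config, bcs = list(hold), tubes = list(tube),
               max_time = settle_time)
  attr(st, "advanced_energy") <- st$energy[["strain"]]
  attr(st, "proximal_s") <- prox_s + amp
  st
}

#' Deploy a coil into the aneurysm sac
#'
#' Pushes the proximal node until the coil is fully released from the
#' catheter.  The sac wall acts as a rigid keep-inside barrier, and a
#' one-sided neck-cover barrier across the orifice (with a central
#' opening for the catheter, the balloon/stent surrogate) prevents
#' herniation into the parent artery.  After release the coil settles
#' freely and the final configuration is audited.
#'
#' @inheritParams advance_coil
#' @param case an `aneurysm_case`
#' @param extra_models optional list of beam models of previously deployed
#'   coils (their state columns appended via [combine_models()] by the
#'   caller) — see [deploy_treatment()]
#' @return Object of class `deployed_configuration`.
#' @export
deploy_coil <- function(model, state, catheter, case,
                        config = solver_config(), duration = NULL,
                        settle_time = 40) {
  n <- nrow(model$nodes)
  l <- sum(model$elem$L0)
  s_start <- attr(state, "proximal_s") %||%
    (catheter$total_length - catheter$proximal_extension)
  s_end <- catheter$total_length + 2 * model$r_contact
  duration <- duration %||% ((s_end - s_start) / 0.4)
  tube <- catheter_tube_barrier(catheter, mu = config$mu_catheter)
  cover <- neck_cover(case$orifice, toward = case$sac_center,
                      hole_radius = 3 * model$r_contact)
  sac_surf <- case$sac_contact %||% case$sac
  barriers <- list(mesh_barrier(sac_surf, mu = config$mu_wall,
                                keep = "inside", thickness = 1),
                   mesh_barrier(cover, mu = config$mu_wall, keep = "front",
                                thickness = 0.25))
  bc <- path_bc(n, catheter$path, s_from = s_start, s_to = s_end, t0 = 0,
                t1 = duration)
  st <- run_sim(model, state, duration, config, bcs = list(bc),
                tubes = list(tube), meshes = barriers)
  # release the driven end and settle freely in the sac
  st <- settle(model, st, config, tubes = list(tube), meshes = barriers,
               max_time = settle_time)
  finalize_deployment(model, st, catheter, case)
}

finalize_deployment <- function(model, state, catheter, case) {
  x <- state$x
  rc <- model$r_contact
  in_sac <- case$inside_sac(x) > -2 * rc          # inside, neck band of D2
  in_vessel <- case$inside_vessel(x) > 0
  herniated <- in_vessel & case$inside_sac(x) < -2 * rc
  spos <- nodes_path_position(state, catheter)
  dtube <- cpp_min_dist_to_segments(
    x, catheter$path[-nrow(catheter$path), , drop = FALSE],
    catheter$path[-1, , drop = FALSE])
  in_catheter <- spos < catheter$total_length - 1e-6 &
    dtube < catheter$inner_radius
  structure(list(nodes = x, state = state,
                 energy = state$energy,
                 all_in_sac = all(in_sac), n_herniated = sum(herniated),
                 n_in_catheter = sum(in_catheter),
                 herniation = any(herniated)),
            class = "deployed_configuration")
}

#' Treatment plan
#'
#' @param coils list of [coil_spec()] objects, deployed in order
#' @param rotations coaxial pre-packaging rotations (degrees); the
#'   replication ensemble uses 40-degree increments covering a full turn
#' @param technique `"improved"` (mandrel-wound pre-shape, spring
#'   equivalent moduli, explicit advancement) or `"original"` (parametric
#'   pre-shape, platinum moduli, straight catheter at the neck, no
#'   advancement)
#' @param h element length (mm)
#' @param seed integer seed recorded in the provenance hash
#' @param mass_scale uniform density multiplier; enlarges the stable time
#'   step of quasi-static runs (energy ratios, not absolute dynamics, are
#'   meaningful in scaled runs)
#' @return A `treatment_plan`.
#' @export
treatment_plan <- function(coils, rotations = seq(0, 320, by = 40),
                           technique = c("improved", "original"),
                           h = NULL, seed = 1L, mass_scale = 1) {
  technique <- match.arg(technique)
  if (inherits(coils, "coil_spec")) coils <- list(coils)
  structure(list(coils = coils, rotations = rotations,
                 technique = technique, h = h, seed = as.integer(seed),
                 mass_scale = mass_scale),
            class = "treatment_plan")
}

plan_hash <- function(plan, config) {
  key <- paste(utils::capture.output(str(unclass(plan))),
               utils::capture.output(str(unclass(config))), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %%
            .Machine$integer.max)
}

#' Simulate one complete coil deployment
#'
#' Runs the mechanical steps for every coil of a plan in order (earlier
#' coils stay in the sac as deformable contact bodies).  The improved
#' technique packages, advances and deploys through the anatomic catheter;
#' the original technique packages into a straight catheter placed
#' perpendicular to the neck and deploys directly.
#'
#' @param plan a [treatment_plan()]
#' @param case an `aneurysm_case`
#' @param rotation_deg coaxial rotation for this run (degrees)
#' @param config a [solver_config()]
#' @return A `deployed_configuration` (multi-coil: nodes of all coils,
#'   with per-coil chain ranges in `chains`).
#' @export
simulate_deployment <- function(plan, case, rotation_deg = 0,
                                config = solver_config()) {
  placed <- list()   # beam models of already-deployed coils
  placed_x <- list() # their deployed positions
  last <- NULL
  for (ci in seq_along(plan$coils)) {
    spec <- plan$coils[[ci]]
    h <- plan$h %||% spec$D2
    props <- coil_beam_properties(
      spec$D1, spec$D2, spec$l, spec$Ew, spec$Gw, spec$rho_w,
      flex_convention = spec$flex_convention,
      shear_convention = spec$shear_convention,
      shear_lam = spec$shear_lam, calibration = spec$calibration)
    if (plan$technique == "improved") {
      pre <- make_preshape(spec, h = h)
      cath <- build_catheter(case$centerline, spec$D2, spec$l,
                             tip_inset = min(1, case$sac_radius / 3))
    } else {
      pre <- discretize_curve(parametric_preshape(spec$D3, spec$l), h)
      # platinum-wire moduli, straight catheter perpendicular to the neck
      props$material$Eb <- spec$Ew
      props$material$Gb <- spec$Gw
      cath <- straight_neck_catheter(case, spec$D2, spec$l)
    }
    props$density$rho_eff <- props$density$rho_eff * (plan$mass_scale %||% 1)
    pre <- position_preshape(pre, cath, rotation_deg)
    coil_model <- build_beam_model(pre, props)
    if (length(placed)) {
      model <- combine_models(c(list(coil_model), placed))
      st0 <- sim_state(model)
      off <- nrow(coil_model$nodes)
      for (k in seq_along(placed)) {
        nk <- nrow(placed[[k]]$nodes)
        st0$x[off + seq_len(nk), ] <- placed_x[[k]]
        off <- off + nk
      }
    } else {
      model <- coil_model
      st0 <- NULL
    }
    st <- package_coil_state(model, st0, cath, config)
    if (plan$technique == "improved")
      st <- advance_coil(model, st, cath, config)
    dep <- deploy_coil(model, st, cath, case, config)
    placed <- c(list(coil_model), placed)
    placed_x <- c(list(dep$nodes[seq_len(nrow(coil_model$nodes)), ,
                                 drop = FALSE]), placed_x)
    last <- dep
  }
  last$rotation_deg <- rotation_deg
  last$technique <- plan$technique
  last$provenance <- list(hash = plan_hash(plan, config),
                          seed = plan$seed, rotation_deg = rotation_deg)
  last
}

# packaging that tolerates a pre-seeded multi-coil state
package_coil_state <- function(model, st0, catheter, config) {
  if (is.null(st0)) return(package_coil(model, catheter, config))
  l <- sum(model$elem$L0[model$elem$nodeB <= chain_end(model, 1L)])
  s0 <- -catheter$funnel_len
  duration <- (l - s0) / 0.4
  tube <- catheter_tube_barrier(catheter, mu = config$mu_catheter)
  bc <- path_bc(1L, catheter$path, s_from = s0, s_to = l, t0 = 0,
                t1 = duration)
  st <- run_sim(model, st0, duration, config, bcs = list(bc),
                tubes = list(tube))
  hold <- path_bc(1L, catheter$path, s_from = l, s_to = l, t0 = -2, t1 = -1)
  st <- settle(model, st, config, bcs = list(hold), tubes = list(tube))
  attr(st, "packaged_energy") <- st$energy[["strain"]]
  st
}

chain_end <- function(model, k) {
  ch <- attr(model, "chains")
  if (is.null(ch)) nrow(model$nodes) else ch[[k]][2]
}

#' Straight catheter placed perpendicular to the neck
#'
#' The delivery pathway of the original technique: a straight tube along
#' the neck normal, its tip just inside the sac, with no parent-artery
#' segment (no advancement step).
#'
#' @param case an `aneurysm_case`
#' @param coil_D2 coil secondary diameter (mm)
#' @param coil_length coil length (mm)
#' @return A `catheter_tube`.
#' @export
straight_neck_catheter <- function(case, coil_D2, coil_length) {
  oc <- colMeans(case$orifice)
  dirv <- case$sac_center - oc
  dirv <- dirv / sqrt(sum(dirv^2))
  tip <- oc + dirv * min(1, case$sac_radius / 3)
  pathm <- outer(seq(-coil_length - 2, 0, length.out = 40), dirv) +
    matrix(tip, 40, 3, byrow = TRUE)
  seg <- sqrt(rowSums((pathm[-1, ] - pathm[-nrow(pathm), ])^2))
  structure(list(path = pathm, s = c(0, cumsum(seg)),
                 inner_radius = coil_D2, proximal_extension = coil_length,
                 vessel_arclength = 2,
                 total_length = sum(seg), funnel_len = 4 * coil_length / 5,
                 funnel_slope = 1, surface = tube_surface(pathm, coil_D2),
                 centerline = NULL),
            class = "catheter_tube")
}

#' Run a rotated-initial-condition deployment ensemble
#'
#' One deployment per rotation angle of the plan (the replication protocol
#' rotates the coil coaxially in 40-degree increments before packaging,
#' giving 9 runs over a full turn).  Individual run failures are reported
#' per angle; the ensemble continues.
#'
#' @param plan a [treatment_plan()]
#' @param case an `aneurysm_case`
#' @param config a [solver_config()]
#' @return List of class `deployment_ensemble`: `runs` (per-angle
#'   `deployed_configuration` or `try-error`), `rotations`.
#' @export
run_ensemble <- function(plan, case, config = solver_config()) {
  runs <- lapply(plan$rotations, function(th) {
    tryCatch(simulate_deployment(plan, case, rotation_deg = th,
                                 config = config),
             error = function(e) {
               warning("deployment at rotation ", th, " deg failed: ",
                       conditionMessage(e))
               structure(list(message = conditionMessage(e)),
                         class = "deployment_failure")
             })
  })
  structure(list(runs = runs, rotations = plan$rotations,
                 technique = plan$technique),
            class = "deployment_ensemble")
}

#' Export a deployed configuration
#'
#' Writes the final coil centerline as polyline JSON and, optionally, the
#' inflated tube surface as STL.
#'
#' @param dep a `deployed_configuration`
#' @param json_path output JSON path
#' @param stl_path optional STL path for the swept-tube rendering
#' @param r_tube tube radius for the STL (mm)
#' @return `json_path`, invisibly.
#' @export
write_deployed <- function(dep, json_path, stl_path = NULL, r_tube = 0.146) {
  jsonlite::write_json(list(points_mm = dep$nodes,
                            energy = as.list(dep$energy),
                            rotation_deg = dep$rotation_deg %||% NA,
                            herniation = dep$herniation),
                       json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(stl_path))
    write_stl(tube_surface(dep$nodes, r_tube), stl_path)
  invisible(json_path)
}
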