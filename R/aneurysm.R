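# Synthetic aneurysm cases, centerlines, catheters and the neck cover.
#
# Synthetic cases are idealized sidewall or terminal aneurysms: a spherical
# sac joined to a tubular parent artery (straight or planar-arc), with an
# analytic centerline.  They carry both triangulated surfaces (for contact
# and export) and implicit solid definitions (for exact containment
# queries), replacing patient-specific STL models so that the full
# simulation pipeline is testable without imaging data.

#' Vessel centerline
#'
#' @param points k x 3 polyline (mm), ordered proximal (inlet) to the
#'   aneurysm orifice
#' @param orifice_index index of the truncation point at the orifice
#'   (defaults to the last point)
#' @return Object of class `centerline` with points, tangents and
#'   cumulative arc length.
#' @export
centerline <- function(points, orifice_index = nrow(points)) {
  points <- as.matrix(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop_domain("centerline arc length must strictly increase")
  n <- nrow(points)
  tang <- rbind(points[2, ] - points[1, ],
                points[pmin(seq_len(n) + 1, n), ] -
                  points[pmax(seq_len(n) - 1, 1), ])[-1, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, tangents = tang, s = c(0, cumsum(seg)),
                 orifice_index = as.integer(orifice_index)),
            class = "centerline")
}

#' Read / write a centerline as JSON
#' @param path JSON file with fields `points_mm` and `orifice_index`
#' @param cl a `centerline`
#' @return `read_centerline_json`: a `centerline`.
#' @export
read_centerline_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  centerline(raw$points_mm, raw$orifice_index %||% nrow(raw$points_mm))
}

#' @rdname read_centerline_json
#' @export
write_centerline_json <- function(cl, path) {
  jsonlite::write_json(list(points_mm = cl$points,
                            orifice_index = cl$orifice_index),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# minimum discrete radius of curvature of a polyline (circumradius of
# consecutive point triples); returns radius and the arc position of the
# minimum
polyline_min_curv_radius <- function(points) {
  n <- nrow(points)
  if (n < 3) return(list(radius = Inf, s = NA_real_))
  s <- c(0, cumsum(sqrt(rowSums((points[-1, , drop = FALSE] -
                                 points[-n, , drop = FALSE])^2))))
  best <- Inf; sbest <- NA_real_
  for (i in 2:(n - 1)) {
    a <- points[i - 1, ]; b <- points[i, ]; c <- points[i + 1, ]
    ab <- b - a; bc <- c - b; ac <- c - a
    cr <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    area2 <- sqrt(sum(cr^2))
    if (area2 < 1e-12) next
    r <- sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum(ac^2)) / (2 * area2)
    if (r < best) { best <- r; sbest <- s[i] }
  }
  list(radius = best, s = sbest)
}

#' Generate a synthetic aneurysm case
#'
#' Builds an idealized aneurysm: a spherical sac of diameter `sac_diameter`
#' on a tubular parent artery of diameter `vessel_diameter`.  For
#' `type = "sidewall"` the sac sits on the side of a straight or planar-arc
#' vessel; for `type = "terminal"` the sac caps an inflow vessel at a
#' symmetric bifurcation into two lateral branches.  The orifice contour is
#' the analytic sac/vessel intersection curve, the centerline is analytic,
#' and the combined wall surface is polygonized from the implicit union so
#' it is watertight.
#'
#' @param sac_diameter sac diameter (mm)
#' @param vessel_diameter parent vessel diameter (mm); must be smaller than
#'   the sac
#' @param vessel_length upstream vessel length (mm); must be at least the
#'   length of the longest coil to be deployed (checked again at catheter
#'   construction)
#' @param type `"sidewall"` or `"terminal"`
#' @param arc_radius `NULL` for a straight vessel, or the radius (mm) of a
#'   planar-arc vessel path (sidewall only)
#' @param neck_fraction orifice radius as a fraction of the sac radius
#'   (sidewall only)
#' @param mesh_n grid resolution for the implicit union surface
#' @param sphere_subdiv icosphere subdivision of the sac contact surface
#' @return Object of class `aneurysm_case`.
#' @export
make_synthetic_aneurysm <- function(sac_diameter, vessel_diameter,
                                    vessel_length = 25,
                                    type = c("sidewall", "terminal"),
                                    arc_radius = NULL, neck_fraction = 0.5,
                                    mesh_n = 56, sphere_subdiv = 3) {
  type <- match.arg(type)
  rs <- sac_diameter / 2
  rv <- vessel_diameter / 2
  if (sac_diameter <= vessel_diameter)
    stop_domain("sac_diameter must exceed vessel_diameter")

  if (type == "sidewall") {
    a <- neck_fraction * rs          # nominal orifice radius
    zc <- rv + sqrt(rs^2 - a^2)      # sac center height above vessel axis
    sac_center <- c(0, 0, zc)
    # vessel path (x axis or planar arc in the xz plane, bending away from
    # the sac); the orifice sits above x = 0
    if (is.null(arc_radius)) {
      tpath <- seq(-vessel_length, 2 * rs + rv, length.out = 80)
      vpath <- cbind(tpath, 0, 0)
    } else {
      if (arc_radius <= vessel_length / pi)
        stop_domain("arc_radius too small for the requested vessel length")
      ang <- seq(-vessel_length / arc_radius, (2 * rs + rv) / arc_radius,
                 length.out = 120)
      vpath <- cbind(arc_radius * sin(ang), 0, -arc_radius * (1 - cos(ang)))
    }
    # orifice contour: sphere/cylinder intersection (straight vessel) or
    # the plane-cut circle (arc vessel, where the exact curve is not
    # algebraic)
    if (is.null(arc_radius)) {
      phimax <- uniroot(function(p) rs^2 - rv^2 * sin(p)^2 -
                          (rv * cos(p) - zc)^2,
                        c(1e-6, pi / 2))$root
      phi <- seq(-phimax * 0.999, phimax * 0.999, length.out = 32)
      xx <- sqrt(pmax(rs^2 - rv^2 * sin(phi)^2 - (rv * cos(phi) - zc)^2, 0))
      orifice <- rbind(cbind(xx, rv * sin(phi), rv * cos(phi)),
                       cbind(-xx[length(xx):1], rv * sin(rev(phi)),
                             rv * cos(rev(phi))))
    } else {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      zpl <- rv
      ra <- sqrt(rs^2 - (zc - zpl)^2)
      orifice <- cbind(ra * cos(th), ra * sin(th), zpl)
    }
    inside_vessel <- function(p) {
      d <- cpp_min_dist_to_segments(p, vpath[-nrow(vpath), , drop = FALSE],
                                    vpath[-1, , drop = FALSE])
      rv - d
    }
    # centerline: along the vessel, then a smooth bend up to the orifice
    # center (the centerline is truncated at the orifice)
    orifice_center <- colMeans(orifice)
    keep <- vpath[, 1] <= -3 * rv
    base <- vpath[keep, , drop = FALSE]
    pa <- base[nrow(base), ]
    ta <- base[nrow(base), ] - base[nrow(base) - 1, ]
    ta <- ta / sqrt(sum(ta^2))
    tb <- sac_center - orifice_center
    tb <- tb / sqrt(sum(tb^2))
    gap <- sqrt(sum((orifice_center - pa)^2))
    tt <- seq(0, 1, length.out = 24)[-1]
    h00 <- 2 * tt^3 - 3 * tt^2 + 1; h10 <- tt^3 - 2 * tt^2 + tt
    h01 <- -2 * tt^3 + 3 * tt^2;    h11 <- tt^3 - tt^2
    bend <- outer(h00, pa) + outer(h10, ta * gap) +
      outer(h01, orifice_center) + outer(h11, tb * gap)
    cl <- centerline(rbind(base, bend))
    dome_apex <- sac_center + c(0, 0, rs)
    sac_axis <- c(0, 0, -1)   # dome -> neck
  } else {
    # terminal: inflow along +z from below, two branches along +/- x
    zc <- sqrt(rs^2 - rv^2) + 0.5 * rv
    sac_center <- c(0, 0, zc)
    z0 <- zc - sqrt(rs^2 - rv^2)     # orifice circle height
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    orifice <- cbind(rv * cos(th), rv * sin(th), z0)
    branch_len <- 4 * rs
    inside_vessel <- function(p) {
      f_in <- pmin(rv - sqrt(p[, 1]^2 + p[, 2]^2), p[, 3] + vessel_length,
                   z0 + 0.2 * rv - p[, 3])
      f_br <- pmin(rv - sqrt(p[, 2]^2 + p[, 3]^2), p[, 1] + branch_len,
                   branch_len - p[, 1])
      pmax(f_in, f_br)
    }
    vpath <- cbind(0, 0, seq(-vessel_length, z0, length.out = 60))
    cl <- centerline(vpath)
    dome_apex <- sac_center + c(0, 0, rs)
    sac_axis <- c(0, 0, -1)
  }

  inside_sac <- function(p) rs - sqrt(colSums((t(p) - sac_center)^2))
  implicit <- function(p) pmax(inside_sac(p), inside_vessel(p))

  sac_mesh <- icosphere(rs, sphere_subdiv, sac_center)
  sac_contact <- icosphere(rs, max(2, sphere_subdiv - 1), sac_center)
  parent_mesh <- tube_surface(vpath, rv, n_around = 24, capped = TRUE)
  lim <- apply(rbind(vpath + 1.2 * rv, vpath - 1.2 * rv,
                     sac_center + 1.2 * rs, sac_center - 1.2 * rs,
                     if (type == "terminal") rbind(c(4 * rs + rv, rv, rv),
                                                   c(-4 * rs - rv, -rv, -rv))),
               2, range)
  wall <- implicit_surface(implicit, lim[1, ] - 0.5, lim[2, ] + 0.5,
                           n = mesh_n)
  cover <- neck_cover(orifice, toward = sac_center)

  structure(list(sac = sac_mesh, sac_contact = sac_contact,
                 parent = parent_mesh, wall = wall,
                 orifice = orifice, neck_cover = cover, centerline = cl,
                 sac_center = sac_center, sac_radius = rs,
                 vessel_radius = rv, dome_apex = dome_apex,
                 sac_axis = sac_axis, inside_sac = inside_sac,
                 inside_vessel = inside_vessel, implicit = implicit,
                 type = type, provenance = "synthetic"),
            class = "aneurysm_case")
}

#' Triangulate the neck-cover surface
#'
#' Spans the orifice contour with a triangle strip down to a small central
#' hole (default radius zero: full fan).  Clinically this surface stands in
#' for a balloon or stent holding coils in the sac; a nonzero `hole_radius`
#' leaves the opening through which the delivery catheter passes.
#' Triangles are oriented with normals toward the sac (`toward`).
#'
#' @param contour closed polyline (k x 3) of the orifice
#' @param toward a point on the sac side (normals are oriented toward it)
#' @param hole_radius radius (mm) of the central opening left for the
#'   catheter; 0 closes the cover completely
#' @return A `tri_surface`.
#' @export
neck_cover <- function(contour, toward, hole_radius = 0) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop_domain("orifice contour must be a closed polygon")
  if (sqrt(sum((contour[1, ] - contour[nrow(contour), ])^2)) < 1e-9)
    contour <- contour[-nrow(contour), , drop = FALSE]
  n <- nrow(contour)
  cen <- colMeans(contour)
  if (hole_radius > 0) {
    ring <- t(apply(contour, 1, function(p) {
      d <- p - cen
      cen + d / sqrt(sum(d^2)) * hole_radius
    }))
    verts <- rbind(contour, ring)
    idx <- seq_len(n); idx2 <- c(idx[-1], idx[1])
    tris <- rbind(cbind(idx, idx2, idx + n),
                  cbind(idx2, idx2 + n, idx + n))
  } else {
    verts <- rbind(contour, cen)
    idx <- seq_len(n); idx2 <- c(idx[-1], idx[1])
    tris <- cbind(idx, idx2, n + 1L)
  }
  s <- tri_surface(verts, tris)
  nrm <- triangle_normals(s)
  co <- triangle_corners(s)
  mid <- (co$A + co$B + co$C) / 3
  flip <- rowSums(nrm * sweep(-mid, 2, toward, `+`)) < 0
  if (mean(flip) > 0.5) s$triangles <- s$triangles[, c(1, 3, 2)]
  s
}

#' Build the delivery catheter along a centerline
#'
#' The catheter is a swept tube around the (orifice-truncated) centerline
#' with inner radius equal to the coil secondary diameter `D2` (twice the
#' coil radius), extended proximally by a straight segment of length equal
#' to the coil, with a conical entry funnel for packaging.  The centerline
#' curvature is checked against the tube radius.
#'
#' @param cl a [centerline()] truncated at the orifice
#' @param coil_D2 coil secondary diameter (mm); the tube inner radius
#' @param coil_length coil length (mm); sets the proximal extension and is
#'   checked against the upstream centerline length (the vessel must be
#'   truncated no shorter than the longest coil)
#' @param tip_inset how far (mm) the catheter tip reaches past the orifice
#'   into the sac
#' @param funnel_len,funnel_slope entry funnel geometry
#' @param n_around ring resolution of the exported tube surface
#' @return Object of class `catheter_tube` with the confinement barrier,
#'   path, arc lengths and a `tri_surface` for export.
#' @export
build_catheter <- function(cl, coil_D2, coil_length, tip_inset = 0,
                           funnel_len = NULL, funnel_slope = 0.3,
                           n_around = 16) {
  stopifnot(inherits(cl, "centerline"))
  vessel_len <- cl$s[cl$orifice_index]
  if (vessel_len < coil_length)
    stop_domain("centerline length ", signif(vessel_len, 5),
                " mm is shorter than the coil (", coil_length,
                " mm): truncate the vessel no shorter than the longest coil")
  curv <- polyline_min_curv_radius(cl$points)
  if (curv$radius <= coil_D2)
    stop_domain("centerline curvature radius ", signif(curv$radius, 4),
                " mm at s = ", signif(curv$s, 4),
                " mm is below the tube radius ", coil_D2, " mm")
  t0 <- cl$tangents[1, ]
  ext <- outer(seq(-coil_length, 0, length.out = 24)[-24], t0) +
    matrix(cl$points[1, ], 23, 3, byrow = TRUE)
  path <- rbind(ext, cl$points[seq_len(cl$orifice_index), , drop = FALSE])
  if (tip_inset > 0) {
    tend <- cl$tangents[cl$orifice_index, ]
    path <- rbind(path, path[nrow(path), ] + tend * tip_inset)
  }
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  structure(list(path = path, s = s, inner_radius = coil_D2,
                 proximal_extension = coil_length,
                 vessel_arclength = vessel_len + tip_inset,
                 total_length = tail(s, 1),
                 funnel_len = funnel_len %||% 12,
                 funnel_slope = funnel_slope,
                 surface = tube_surface(path, coil_D2, n_around,
                                        capped = FALSE),
                 centerline = cl),
            class = "catheter_tube")
}

#' Save an aneurysm case bundle
#'
#' Writes the case as a directory: STL surfaces, orifice polyline and
#' centerline JSON, plus a manifest.
#'
#' @param case an `aneurysm_case`
#' @param dir output directory (created)
#' @return `dir`, invisibly.
#' @export
write_case_bundle <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stl(case$sac, file.path(dir, "sac.stl"))
  write_stl(case$parent, file.path(dir, "parent.stl"))
  write_stl(case$wall, file.path(dir, "wall.stl"))
  write_stl(case$neck_cover, file.path(dir, "neck_cover.stl"))
  write_centerline_json(case$centerline, file.path(dir, "centerline.json"))
  jsonlite::write_json(
    list(type = case$type, provenance = case$provenance,
         sac_center = case$sac_center, sac_radius = case$sac_radius,
         vessel_radius = case$vessel_radius,
         orifice_mm = case$orifice),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
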