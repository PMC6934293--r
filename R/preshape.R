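# Virtual manufacturing of coil tertiary pre-shapes.
#
# A real embolic coil receives its 3D "pre-shape" by winding the secondary
# structure around a shaped mandrel and heat-treating it.  The simulator
# reproduces this: a mandrel (main cylinder of diameter D3 - 1.5 mm with
# cross-axis cylinders of diameter D3) is constructed, a non-self-
# intersecting curve is wound analytically on its surface, truncated to the
# coil length, and discretized into the beam-element centerline.  A
# parametric spherical-spiral family is provided as a baseline pre-shape
# representing the older, purely mathematical approach.

# ---- space curves (dense polylines with arc-length parameterization) ----

space_curve <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, s = c(0, cumsum(seg))),
            class = "space_curve")
}

#' Arc length of a space curve
#' @param curve a `space_curve` or `coil_centerline`
#' @return Total polyline arc length (mm).
#' @export
arc_length <- function(curve) tail(curve$s, 1)

# interpolate positions at arc-length values sq
curve_point_at <- function(curve, sq) {
  cbind(approx(curve$s, curve$points[, 1], xout = sq)$y,
        approx(curve$s, curve$points[, 2], xout = sq)$y,
        approx(curve$s, curve$points[, 3], xout = sq)$y)
}

# ---- mandrel ----

#' Build a coil-winding mandrel
#'
#' The mandrel consists of a main cylinder of diameter `D3 - 1.5` mm (its
#' axis along z) and `k_cross` cross-axis cylinders of diameter `D3` whose
#' axes are perpendicular to, and intersect, the main axis.  The 1.5 mm
#' reduction of the main diameter compensates for the loops that ride up
#' onto the larger cross cylinders, so the finished pre-shape envelope is
#' close to `D3`.
#'
#' @param D3 tertiary (pre-shape) diameter in mm; must exceed 1.5 mm
#' @param k_cross number of cross-axis cylinders (>= 0)
#' @param spacing axial spacing between cross-cylinder centers (mm); must
#'   exceed `D3` so the cross cylinders do not overlap
#' @param azimuths optional azimuth (rad) of each cross-cylinder axis;
#'   default rotates successive cylinders by the golden angle
#' @return Object of class `mandrel_spec`.
#' @export
build_mandrel <- function(D3, k_cross = 2, spacing = 1.2 * D3,
                          azimuths = NULL) {
  if (D3 <= 1.5)
    stop_domain("D3 must exceed 1.5 mm: the main cylinder has diameter D3 - 1.5 mm")
  if (k_cross < 0) stop_domain("k_cross must be >= 0")
  if (k_cross > 1 && spacing <= D3)
    stop_domain("cross cylinders of diameter D3 overlap at spacing <= D3")
  main_diameter <- D3 - 1.5
  if (is.null(azimuths)) azimuths <- (seq_len(k_cross) - 1) * 2.399963
  if (k_cross > 0 && length(azimuths) != k_cross)
    stop_domain("need one azimuth per cross cylinder")
  z0 <- spacing  # first cross cylinder sits one spacing above the base
  cross <- if (k_cross > 0) {
    data.frame(z = z0 + (seq_len(k_cross) - 1) * spacing,
               azimuth = azimuths, diameter = D3)
  } else {
    data.frame(z = numeric(0), azimuth = numeric(0), diameter = numeric(0))
  }
  main_length <- z0 + k_cross * spacing + spacing
  structure(list(D3 = D3, main_diameter = main_diameter,
                 main_length = main_length, cross = cross),
            class = "mandrel_spec")
}

#' Default winding pattern for a mandrel
#'
#' A main-axis helix interleaved with a wrap passage around each cross
#' cylinder: the curve climbs the main cylinder at the given pitch and, at
#' each cross cylinder, leaves the main surface and rides around the
#' protruding stub from below over its top before resuming the climb
#' above it.
#'
#' @param mandrel a [build_mandrel()] result
#' @param pitch helix pitch on the main cylinder (mm/turn); must be at
#'   least the coil secondary diameter `D2` so adjacent loops of the
#'   inflated coil cannot interpenetrate
#' @param D2 secondary diameter of the coil to be wound (mm)
#' @param handedness +1 (right-handed) or -1 (left-handed)
#' @return Object of class `winding_pattern`.
#' @export
default_winding_pattern <- function(mandrel, D2 = 0.2921,
                                    pitch = max(3 * D2, 0.6),
                                    handedness = 1) {
  if (pitch < D2)
    stop_domain("pitch ", pitch, " < D2 = ", D2,
                ": adjacent loops of the inflated coil would interpenetrate")
  structure(list(pitch = pitch, D2 = D2, handedness = sign(handedness),
                 mandrel = mandrel),
            class = "winding_pattern")
}

# distance from points (n x 3) to an infinite cylinder (point p0, unit axis u)
cyl_radial_dist <- function(x, p0, u) {
  d <- sweep(x, 2, p0)
  along <- drop(d %*% u)
  sqrt(pmax(rowSums(d^2) - along^2, 0))
}

# project points onto the surface of the nearest of the mandrel's cylinders
project_to_mandrel <- function(x, mandrel) {
  Rm <- mandrel$main_diameter / 2
  # candidate distances to each cylinder surface
  dmain <- abs(cyl_radial_dist(x, c(0, 0, 0), c(0, 0, 1)) - Rm)
  best <- list(d = dmain, which = rep(0L, nrow(x)))
  k <- nrow(mandrel$cross)
  if (k > 0) for (i in seq_len(k)) {
    u <- c(cos(mandrel$cross$azimuth[i]), sin(mandrel$cross$azimuth[i]), 0)
    p0 <- c(0, 0, mandrel$cross$z[i])
    di <- abs(cyl_radial_dist(x, p0, u) - mandrel$cross$diameter[i] / 2)
    sel <- di < best$d
    best$d[sel] <- di[sel]; best$which[sel] <- i
  }
  out <- x
  for (j in seq_len(nrow(x))) {
    if (best$which[j] == 0L) {
      p0 <- c(0, 0, 0); u <- c(0, 0, 1); R <- Rm
    } else {
      i <- best$which[j]
      u <- c(cos(mandrel$cross$azimuth[i]), sin(mandrel$cross$azimuth[i]), 0)
      p0 <- c(0, 0, mandrel$cross$z[i]); R <- mandrel$cross$diameter[i] / 2
    }
    d <- x[j, ] - p0
    rad <- d - sum(d * u) * u
    nr <- sqrt(sum(rad^2))
    if (nr > 1e-12) out[j, ] <- x[j, ] + rad / nr * (R - nr)
  }
  out
}

# helix sampled on a cylinder: axis through p0 along unit u, radius R,
# starting azimuth a0 in the (e1,e2) frame orthogonal to u
helix_points <- function(p0, u, R, a0, turns, pitch, hand = 1,
                         samples_per_turn = 120) {
  e1 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  nsamp <- max(8, ceiling(samples_per_turn * abs(turns)))
  t <- seq(0, abs(turns) * 2 * pi, length.out = nsamp + 1)
  ang <- a0 + hand * t
  adv <- pitch * t / (2 * pi)
  p <- outer(cos(ang), e1 * R) + outer(sin(ang), e2 * R) + outer(adv, u)
  sweep(p, 2, p0, `+`)
}

#' Wind a curve on a mandrel surface
#'
#' Constructs the coil pre-shape centerline analytically: helix segments on
#' the main cylinder, a half-wrap passage over each cross-cylinder stub,
#' joined by smooth cylindrical-coordinate ramps (the physical wire also
#' bridges through air between cylinders).  The wound curve never
#' intersects itself when inflated to the coil diameter, which is enforced
#' by the pitch constraint and checked by [min_self_clearance()].
#'
#' @param mandrel a [build_mandrel()] result
#' @param pattern a [default_winding_pattern()]
#' @param samples_per_turn sampling density of the returned polyline
#' @return A `space_curve` lying on the mandrel surface.
#' @export
wind_on_mandrel <- function(mandrel, pattern, samples_per_turn = 120) {
  stopifnot(inherits(mandrel, "mandrel_spec"),
            inherits(pattern, "winding_pattern"))
  Rm <- mandrel$main_diameter / 2
  hand <- pattern$handedness
  pitch <- pattern$pitch
  pieces <- list()
  z <- 0; a0 <- 0
  kcross <- nrow(mandrel$cross)
  zs <- if (kcross > 0) mandrel$cross$z else numeric(0)
  for (i in seq_len(kcross)) {
    # climb the main cylinder until just below the cross cylinder,
    # ending exactly at the stub azimuth so the transition onto the stub
    # is a short in-plane diagonal with no azimuthal travel
    phi_s <- mandrel$cross$azimuth[i]
    ztarget <- zs[i] - mandrel$cross$diameter[i] / 2 - 2 * pattern$D2
    frac <- ((hand * (phi_s - a0)) %% (2 * pi)) / (2 * pi)
    turns <- frac + max(0, floor((ztarget - z) / pitch - frac))
    if (turns < 0.25) turns <- turns + 1
    main_seg <- helix_points(c(0, 0, z), c(0, 0, 1), Rm, a0, turns, pitch,
                             hand, samples_per_turn)
    pieces[[length(pieces) + 1]] <- main_seg
    z <- z + turns * pitch
    a0 <- a0 + hand * turns * 2 * pi
    # half-wrap passage over the protruding stub of the cross cylinder:
    # the curve leaves the main surface, rides around the stub from its
    # underside over its top in the plane of one axial station, and
    # resumes the climb above.  The single-station pass keeps the
    # inflated tube clear of both the main helix and itself.
    u <- c(cos(mandrel$cross$azimuth[i]), sin(mandrel$cross$azimuth[i]), 0)
    Rc <- mandrel$cross$diameter[i] / 2
    s0 <- Rm + 2 * pattern$D2
    wrap <- helix_points(c(0, 0, zs[i]) + s0 * u, u, Rc, a0 = pi,
                         turns = 0.5, pitch = 0, hand = hand,
                         samples_per_turn = samples_per_turn)
    pieces[[length(pieces) + 1]] <- wrap
    z <- zs[i] + Rc + 2 * pattern$D2
    # resume the climb at the stub azimuth (the exit is the mirror of
    # the entry diagonal, directly above the stub)
  }
  # final climb to the top of the mandrel
  turns <- max(1, (mandrel$main_length - z) / pitch)
  pieces[[length(pieces) + 1]] <-
    helix_points(c(0, 0, z), c(0, 0, 1), Rm, a0, turns, pitch, hand,
                 samples_per_turn)
  # join pieces with smooth ramps in cylindrical coordinates about the
  # mandrel axis: radius, azimuth and height interpolate with a quintic
  # smooth step, which is fold-free and tangent-continuous and mirrors
  # how the physical wire bridges between the cylinders
  pts <- pieces[[1]]
  if (length(pieces) > 1) for (i in 2:length(pieces)) {
    a <- pts; b <- pieces[[i]]
    pa <- a[nrow(a), ]; pb <- b[1, ]
    gap <- sqrt(sum((pb - pa)^2))
    if (gap > 1e-9) {
      ra <- sqrt(pa[1]^2 + pa[2]^2); rb2 <- sqrt(pb[1]^2 + pb[2]^2)
      phia <- atan2(pa[2], pa[1]); phib <- atan2(pb[2], pb[1])
      # continue in the azimuthal sense of the incoming tangent so the
      # ramp never doubles back on the piece it leaves
      ta <- pa - a[nrow(a) - 1, ]
      az_sign <- sign(pa[1] * ta[2] - pa[2] * ta[1])
      if (az_sign == 0) az_sign <- hand
      dphi <- (phib - phia) %% (2 * pi)
      if (az_sign < 0) dphi <- dphi - 2 * pi
      if (abs(dphi) < 1e-9) dphi <- 0
      tt <- seq(0, 1, length.out = max(12, ceiling(gap / 0.05)))[-1]
      s5 <- tt^3 * (10 - 15 * tt + 6 * tt^2)
      rr <- ra + (rb2 - ra) * s5
      pp <- phia + dphi * tt
      zz <- pa[3] + (pb[3] - pa[3]) * tt   # steady climb avoids stalls
      blend <- cbind(rr * cos(pp), rr * sin(pp), zz)
      pts <- rbind(pts, blend, b[-1, , drop = FALSE])
    } else {
      pts <- rbind(pts, b[-1, , drop = FALSE])
    }
  }
  space_curve(pts)
}

#' Truncate a curve to a target arc length
#'
#' @param curve a `space_curve`
#' @param l target arc length (mm); the curve must be at least this long
#' @return A `space_curve` of arc length `l` sharing the original start
#'   point.
#' @export
truncate_to_length <- function(curve, l) {
  stopifnot(inherits(curve, "space_curve"))
  L <- arc_length(curve)
  if (l > L * (1 + 1e-9))
    stop_domain("curve length ", signif(L, 6), " mm < requested ", l,
                " mm: wind a longer pattern")
  if (abs(l - L) < 1e-12 * max(1, L)) return(curve)
  keep <- curve$s < l
  pts <- rbind(curve$points[keep, , drop = FALSE], curve_point_at(curve, l))
  space_curve(pts)
}

#' Discretize a curve into a beam-element centerline
#'
#' Nodes are placed at equal arc-length intervals `h`; the final interval
#' absorbs the remainder (shorter than `h`).  The element count is
#' `ceiling(l / h)`.
#'
#' @param curve a `space_curve`
#' @param h element length (mm); must satisfy `h <= l / 4`
#' @return Object of class `coil_centerline`: node matrix, node arc
#'   lengths, `h`, element count.
#' @export
discretize_curve <- function(curve, h) {
  stopifnot(inherits(curve, "space_curve"))
  l <- arc_length(curve)
  if (h <= 0 || h > l / 4)
    stop_domain("element length h must lie in (0, l/4]; got h = ", h,
                " for l = ", signif(l, 6))
  m <- ceiling(l / h)
  sq <- c(seq(0, by = h, length.out = m), l)
  if (sq[m] >= l) { m <- m - 1L; sq <- c(seq(0, by = h, length.out = m), l) }
  nodes <- curve_point_at(curve, sq)
  structure(list(nodes = nodes, s = sq, h = h, n_elements = length(sq) - 1L),
            class = "coil_centerline")
}

#' Spherical-spiral parametric pre-shape (baseline family)
#'
#' A documented stand-in for purely mathematical pre-shapes: a spiral on a
#' sphere of diameter `D3`, with the azimuthal winding rate chosen by
#' bisection so the total arc length equals `l`.  It is a baseline family of
#' this package, not a reproduction of any published parametric coil
#' equations.
#'
#' @param D3 envelope diameter (mm)
#' @param l target arc length (mm)
#' @param n_samples sampling density of the returned curve
#' @return A `space_curve` of arc length within 0.5% of `l`, all points
#'   within `D3/2` of the origin.
#' @export
parametric_preshape <- function(D3, l, n_samples = 2000) {
  if (D3 <= 0 || l <= 0) stop_domain("D3 and l must be positive")
  R <- D3 / 2
  if (l < pi * R) stop_domain("l too short for a spherical spiral of diameter ", D3)
  make <- function(c_rate) {
    th <- seq(1e-4, pi - 1e-4, length.out = n_samples)
    ph <- c_rate * th
    space_curve(R * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
  }
  f <- function(c_rate) arc_length(make(c_rate)) - l
  # arc length grows monotonically with the winding rate
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  c_rate <- uniroot(f, c(0, hi), tol = 1e-10)$root
  curve <- make(c_rate)
  attr(curve, "winding_rate") <- c_rate
  curve
}

#' Minimum clearance between non-adjacent centerline segments
#'
#' Used to verify that a pre-shape does not self-intersect when inflated to
#' the coil's secondary diameter: the value must be at least `D2`.
#'
#' @param x a `space_curve`, `coil_centerline`, or n x 3 point matrix
#' @param window arc-length separation (mm) below which segment pairs are
#'   excluded (nearby stretches of a smooth curve are always close); the
#'   default of about three tube diameters suits wound coil centerlines
#' @return Minimum distance (mm) between any two well-separated segments.
#' @export
min_self_clearance <- function(x, window = 1) {
  pts <- if (is.matrix(x)) x else if (!is.null(x$nodes)) x$nodes else x$points
  polyline_self_clearance(pts, window)
}

#' Export / import a centerline polyline
#'
#' JSON carries `points_mm` (n x 3) and optional metadata; OBJ writes a
#' line-set (`v` records plus `l` polyline record) readable by standard
#' mesh viewers.
#'
#' @param x a `space_curve` or `coil_centerline`
#' @param path output path; format chosen by extension (`.json` or `.obj`)
#' @return `path`, invisibly.
#' @export
write_centerline <- function(x, path) {
  pts <- if (!is.null(x$nodes)) x$nodes else x$points
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
    writeLines(paste("l", paste(seq_len(nrow(pts)), collapse = " ")), con)
  } else {
    jsonlite::write_json(list(points_mm = pts), path, digits = NA)
  }
  invisible(path)
}

#' @rdname write_centerline
#' @param json_path a JSON file written by [write_centerline()]
#' @export
read_centerline <- function(json_path) {
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  space_curve(raw$points_mm)
}

#' Build a coil pre-shape by virtual mandrel winding
#'
#' Full pre-shape pipeline for a coil specification: mandrel construction,
#' winding with the default pattern, truncation to the coil length, and
#' discretization at element length `h`.
#'
#' @param spec a [coil_spec()]
#' @param h element length (mm); default is the coil secondary diameter
#' @param k_cross number of cross-axis mandrel cylinders
#' @param rotation rotation (radians) applied about the z axis, used by
#'   deployment ensembles to vary initial conditions
#' @return A `coil_centerline`.
#' @export
make_preshape <- function(spec, h = spec$D2, k_cross = 2, rotation = 0) {
  mandrel <- build_mandrel(spec$D3, k_cross = k_cross)
  pattern <- default_winding_pattern(mandrel, D2 = spec$D2)
  curve <- wind_on_mandrel(mandrel, pattern)
  if (arc_length(curve) < spec$l) {
    # extend the mandrel until the wound curve is long enough
    grow <- ceiling((spec$l - arc_length(curve)) /
                    (pi * mandrel$main_diameter)) + 2
    mandrel$main_length <- mandrel$main_length + grow * pattern$pitch
    curve <- wind_on_mandrel(mandrel, pattern)
  }
  curve <- truncate_to_length(curve, spec$l)
  if (rotation != 0) {
    cr <- cos(rotation); sr <- sin(rotation)
    Rz <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3, 3)
    curve <- space_curve(curve$points %*% t(Rz))
  }
  discretize_curve(curve, h)
}
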