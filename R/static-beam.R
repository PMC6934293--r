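# Linear-static 3D beam assembly.
#
# A small direct-stiffness solver for space frames of 2-node Timoshenko
# beam elements (6 dof per node).  It serves as an independent
# verification route: a helical spring discretized into straight beam
# segments can be loaded axially and its stiffness compared with the
# closed-form helical-spring rigidity, a check that involves neither the
# rigidity formulas nor the explicit dynamic solver.

beam_stiffness_local <- function(E, G, A, Iy, Iz, J, L, ks = 0.9) {
  GAs <- ks * G * A
  phiy <- 12 * E * Iz / (GAs * L^2)
  phiz <- 12 * E * Iy / (GAs * L^2)
  K <- matrix(0, 12, 12)
  idx <- function(node, dof) (node - 1) * 6 + dof
  ax <- E * A / L
  K[idx(1, 1), idx(1, 1)] <- ax; K[idx(2, 1), idx(2, 1)] <- ax
  K[idx(1, 1), idx(2, 1)] <- -ax; K[idx(2, 1), idx(1, 1)] <- -ax
  tor <- G * J / L
  K[idx(1, 4), idx(1, 4)] <- tor; K[idx(2, 4), idx(2, 4)] <- tor
  K[idx(1, 4), idx(2, 4)] <- -tor; K[idx(2, 4), idx(1, 4)] <- -tor
  # bending about z (displacement y, rotation thz)
  cz <- E * Iz / (L^3 * (1 + phiy))
  dz <- c(idx(1, 2), idx(1, 6), idx(2, 2), idx(2, 6))
  Kb <- cz * matrix(c(12, 6 * L, -12, 6 * L,
                      6 * L, (4 + phiy) * L^2, -6 * L, (2 - phiy) * L^2,
                      -12, -6 * L, 12, -6 * L,
                      6 * L, (2 - phiy) * L^2, -6 * L, (4 + phiy) * L^2),
                    4, 4, byrow = TRUE)
  K[dz, dz] <- K[dz, dz] + Kb
  # bending about y (displacement z, rotation thy) with sign flips
  cy <- E * Iy / (L^3 * (1 + phiz))
  dy <- c(idx(1, 3), idx(1, 5), idx(2, 3), idx(2, 5))
  Kb <- cy * matrix(c(12, -6 * L, -12, -6 * L,
                      -6 * L, (4 + phiz) * L^2, 6 * L, (2 - phiz) * L^2,
                      -12, 6 * L, 12, 6 * L,
                      -6 * L, (2 - phiz) * L^2, 6 * L, (4 + phiz) * L^2),
                    4, 4, byrow = TRUE)
  K[dy, dy] <- K[dy, dy] + Kb
  K
}

#' Linear-static solution of a beam frame
#'
#' Assembles 2-node Timoshenko space-frame elements along a polyline and
#' solves `K u = f` with the listed dofs clamped.
#'
#' @param points n x 3 node coordinates (mm)
#' @param E,G moduli (N/mm^2)
#' @param A,Iy,Iz,J section properties (mm^2, mm^4)
#' @param loads n x 6 matrix of nodal loads (Fx..Mz; N, N*mm)
#' @param clamped node indices with all 6 dof fixed
#' @param ks shear correction factor
#' @return n x 6 matrix of displacements/rotations (mm, rad).
#' @export
static_frame_solve <- function(points, E, G, A, Iy, Iz, J, loads, clamped,
                               ks = 0.9) {
  points <- as.matrix(points)
  n <- nrow(points)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (e in seq_len(n - 1)) {
    p1 <- points[e, ]; p2 <- points[e + 1, ]
    d <- p2 - p1
    L <- sqrt(sum(d^2))
    ex <- d / L
    ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    ey <- ref - sum(ref * ex) * ex; ey <- ey / sqrt(sum(ey^2))
    ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
            ex[1] * ey[2] - ex[2] * ey[1])
    R <- rbind(ex, ey, ez)
    Tm <- matrix(0, 12, 12)
    for (b in 0:3) Tm[b * 3 + 1:3, b * 3 + 1:3] <- R
    Ke <- t(Tm) %*% beam_stiffness_local(E, G, A, Iy, Iz, J, L, ks) %*% Tm
    gdof <- c((e - 1) * 6 + 1:6, e * 6 + 1:6)
    trip_i <- c(trip_i, rep(gdof, each = 12))
    trip_j <- c(trip_j, rep(gdof, times = 12))
    trip_x <- c(trip_x, as.numeric(t(Ke)))
  }
  K <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(6 * n, 6 * n))
  f <- as.numeric(t(loads))
  fix <- as.integer(outer(1:6, (clamped - 1) * 6, `+`))
  free <- setdiff(seq_len(6 * n), fix)
  u <- numeric(6 * n)
  u[free] <- as.numeric(Matrix::solve(K[free, free], f[free]))
  matrix(u, n, 6, byrow = TRUE)
}

#' Brute-force axial stiffness of a discretized helical spring
#'
#' Builds a helix of the primary wire (solid circular section, diameter
#' `D1`), discretizes it into straight beam segments, clamps one end,
#' applies an axial force at the other, and returns the resulting axial
#' stiffness.  This is the independent cross-check for the closed-form
#' compressive rigidity of the coil's secondary structure.
#'
#' @param D1 wire diameter (mm)
#' @param Dm helix (mean coil) diameter (mm)
#' @param n_turns number of active turns
#' @param pitch helix pitch (mm/turn); default tight winding `D1`
#' @param Ew,Gw wire moduli (GPa)
#' @param seg_per_turn straight segments per turn (>= 40 recommended)
#' @return List with `k` (N/mm), `k_times_l` (N, comparable to the
#'   compressive rigidity), `l` (spring length, mm).
#' @export
helix_axial_stiffness <- function(D1, Dm, n_turns = 10, pitch = D1,
                                  Ew = 230, Gw = 82, seg_per_turn = 40) {
  nseg <- n_turns * seg_per_turn
  t <- seq(0, n_turns * 2 * pi, length.out = nseg + 1)
  pts <- cbind(Dm / 2 * cos(t), Dm / 2 * sin(t), pitch * t / (2 * pi))
  A <- pi / 4 * D1^2
  I <- pi / 64 * D1^4
  loads <- matrix(0, nseg + 1, 6)
  loads[nseg + 1, 3] <- 1  # unit axial force (N)
  u <- static_frame_solve(pts, Ew * 1000, Gw * 1000, A, I, I, 2 * I,
                          loads, clamped = 1)
  defl <- u[nseg + 1, 3]
  l <- n_turns * pitch
  list(k = 1 / defl, k_times_l = l / defl, l = l)
}
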