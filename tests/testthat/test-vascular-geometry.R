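# Surfaces, STL I/O, synthetic cases, catheters and the neck cover.

unit_cube <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  tri_surface(v, f)
}

test_that("STL round-trips in both dialects with exact geometry", {
  cube <- unit_cube()
  expect_equal(surface_area(cube), 6)
  expect_true(is_watertight(cube))
  fb <- tempfile(fileext = ".stl"); fa <- tempfile(fileext = ".stl")
  write_stl(cube, fb)
  write_stl(cube, fa, ascii = TRUE)
  rb <- read_stl(fb); ra <- read_stl(fa)
  expect_equal(surface_area(rb), 6, tolerance = 1e-6)
  expect_equal(surface_area(ra), 6, tolerance = 1e-6)
  # both dialects parse to identical triangle sets
  key <- function(s) {
    co <- coildeploy:::triangle_corners(s)
    sort(apply(round(cbind(co$A, co$B, co$C), 6), 1, paste, collapse = ","))
  }
  expect_identical(key(rb), key(ra))
  expect_error(read_stl(tempfile()), "no such file")
  bad <- tempfile(fileext = ".stl")
  writeBin(raw(100), bad)
  expect_error(read_stl(bad), "malformed")
})

test_that("icosphere area converges to the sphere", {
  s <- icosphere(2.5, 3)
  expect_true(is_watertight(s))
  expect_equal(surface_area(s), 4 * pi * 2.5^2, tolerance = 0.01)
  # outward normals: signed volume positive and near sphere volume
  co <- coildeploy:::triangle_corners(s)
  vol <- sum(rowSums(co$A * coildeploy:::cross3(co$B, co$C))) / 6
  expect_equal(vol, 4 / 3 * pi * 2.5^3, tolerance = 0.02)
})

test_that("implicit polygonization is watertight and oriented", {
  f <- function(p) 1 - sqrt(rowSums(p^2))
  s <- implicit_surface(f, c(-1.4, -1.4, -1.4), c(1.4, 1.4, 1.4), n = 24)
  expect_true(is_watertight(s))
  expect_equal(surface_area(s), 4 * pi, tolerance = 0.05)
})

test_that("containment by winding number agrees with ray parity", {
  set.seed(42)
  case <- reduced_case()
  expect_true(is_watertight(case$wall))
  lim <- apply(case$wall$vertices, 2, range)
  p <- cbind(runif(400, lim[1, 1], lim[2, 1]),
             runif(400, lim[1, 2], lim[2, 2]),
             runif(400, lim[1, 3], lim[2, 3]))
  wi <- point_in_surface(case$wall, p)
  rp <- ray_parity_inside(case$wall, p, dir = c(0.21, 0.55, 0.81))
  expect_equal(mean(wi == rp), 1)
  # and both agree with the analytic solid away from the surface skin
  tru <- case$implicit(p)
  far <- abs(tru) > 0.15
  expect_gte(mean(wi[far] == (tru[far] > 0)), 0.995)
})

test_that("synthetic sidewall case has consistent analytic structure", {
  case <- reduced_case()
  # sac sphere area
  expect_equal(surface_area(case$sac), 4 * pi * 2.5^2, tolerance = 0.01)
  # orifice contour lies on both the sphere and the vessel surface
  d_sph <- abs(sqrt(colSums((t(case$orifice) - case$sac_center)^2)) - 2.5)
  expect_lt(max(d_sph), 1e-6)
  d_ves <- abs(sqrt(case$orifice[, 2]^2 + case$orifice[, 3]^2) - 1.5)
  expect_lt(max(d_ves), 1e-6)
  # centerline reaches the orifice center
  endp <- tail(case$centerline$points, 1)
  expect_lt(sqrt(sum((endp - colMeans(case$orifice))^2)), 1e-6)
  expect_error(make_synthetic_aneurysm(3, 3), "exceed")
})

test_that("terminal case is mirror-symmetric across the bifurcation plane", {
  tc <- make_synthetic_aneurysm(5, 3, type = "terminal", mesh_n = 30)
  expect_true(is_watertight(tc$wall))
  set.seed(7)
  p <- cbind(runif(300, -6, 6), runif(300, -3, 3), runif(300, -6, 6))
  pm <- p; pm[, 1] <- -pm[, 1]
  expect_equal(tc$implicit(p) > 0, tc$implicit(pm) > 0)
  # orifice is the analytic sphere/cylinder circle
  expect_equal(sqrt(tc$orifice[, 1]^2 + tc$orifice[, 2]^2),
               rep(1.5, nrow(tc$orifice)), tolerance = 1e-9)
})

test_that("catheter tube respects radius, extension and curvature limits", {
  case <- reduced_case()
  cath <- build_catheter(case$centerline, coil_D2 = 0.2921,
                         coil_length = 20)
  expect_equal(cath$inner_radius, 0.2921)
  expect_equal(cath$proximal_extension, 20)
  # straight centerline: total tube length = vessel + extension
  cl <- centerline(cbind(seq(-25, 0, length.out = 40), 0, 0))
  ct <- build_catheter(cl, 0.2921, 20)
  expect_equal(ct$total_length, 45, tolerance = 1e-6)
  # every tube surface vertex sits at the inner radius from the centerline
  d <- mdist_segments(ct$surface$vertices, ct$path)
  expect_equal(max(abs(d - 0.2921)), 0, tolerance = 1e-6)
  # vessel shorter than the coil violates the truncation rule
  short <- centerline(cbind(seq(-10, 0, length.out = 20), 0, 0))
  expect_error(build_catheter(short, 0.2921, 20), "truncate")
  # curvature radius below the tube radius is rejected with a location
  th <- seq(0, pi, length.out = 60)
  kinked <- centerline(cbind(c(seq(-30, 0, length.out = 60),
                               0.2 * sin(th) + 0.4),
                             0, c(rep(0, 60), 0.2 * (1 - cos(th)))))
  expect_error(build_catheter(kinked, 0.2921, 20), "curvature")
})

test_that("neck cover spans the orifice with sac-facing normals", {
  # circular orifice: cover area approaches the disc
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  contour <- cbind(1.2 * cos(th), 1.2 * sin(th), 0)
  cov <- neck_cover(contour, toward = c(0, 0, 5))
  expect_equal(surface_area(cov), pi * 1.2^2, tolerance = 0.02)
  # boundary vertices coincide with the contour
  expect_true(all(contour %in% cov$vertices))
  nrm <- triangle_normals(cov)
  expect_true(all(nrm[, 3] > 0))
  # annular cover leaves the catheter opening
  cov2 <- neck_cover(contour, toward = c(0, 0, 5), hole_radius = 0.4)
  expect_equal(surface_area(cov2), pi * (1.2^2 - 0.4^2), tolerance = 0.02)
  expect_error(neck_cover(contour[1:2, ], toward = c(0, 0, 1)), "polygon")
})

test_that("case bundles export to a directory with manifest", {
  case <- reduced_case()
  dir <- file.path(tempdir(), "case_bundle")
  write_case_bundle(case, dir)
  expect_true(file.exists(file.path(dir, "sac.stl")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  cl <- read_centerline_json(file.path(dir, "centerline.json"))
  expect_equal(cl$points, case$centerline$points, tolerance = 1e-9,
               ignore_attr = TRUE)
})
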