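# Cross-section extraction, rasterization, coil density, gliding-box
# lacunarity and the standardized distance comparison.

test_that("section planes march from the dome toward the neck at 1 mm", {
  case <- reduced_case()
  planes <- extract_sections(case, n = 4, spacing = 1)
  expect_length(planes, 4)
  for (k in 2:4) {
    gap <- planes[[k]]$origin - planes[[k - 1]]$origin
    expect_equal(sqrt(sum(gap^2)), 1, tolerance = 1e-12)
    expect_equal(planes[[k]]$normal, case$sac_axis)
  }
  # a 5 mm sac cannot host 6 planes at 1 mm spacing
  expect_error(extract_sections(case, n = 6, spacing = 1), "at most")
})

test_that("rasterized capsule slices have the expected areas", {
  case <- reduced_case()
  planes <- extract_sections(case, n = 4)
  pl <- planes[[2]]   # 2 mm below the apex
  D2 <- 0.2921
  # a single straight segment perpendicular to the plane: disc of D2
  seg <- rbind(pl$origin - 2 * pl$normal, pl$origin + 2 * pl$normal)
  img <- rasterize_section(seg, pl, case, D2 = D2, resolution = D2 / 8)
  area <- sum(img$coil) * img$resolution^2
  expect_equal(area, pi * D2^2 / 4, tolerance = 0.05)
  # a segment lying in the plane: elongated band larger than the disc
  u <- c(1, 0, 0)
  seg2 <- rbind(pl$origin - 1 * u, pl$origin + 1 * u)
  img2 <- rasterize_section(seg2, pl, case, D2 = D2)
  expect_gt(sum(img2$coil), sum(img$coil))
  # empty configuration: all-white image
  img0 <- rasterize_section(NULL, pl, case, D2 = D2)
  expect_equal(sum(img0$coil), 0)
  # resolution guard: the tube must span at least 4 pixels
  expect_error(rasterize_section(seg, pl, case, D2 = D2,
                                 resolution = D2 / 2), "D2/4")
})

test_that("coil density is the black fraction of the mask interior", {
  img <- list(coil = matrix(FALSE, 10, 10), mask = matrix(TRUE, 10, 10))
  expect_equal(coil_density(img), 0)
  img$coil[] <- TRUE
  expect_equal(coil_density(img), 1)
  img$coil[] <- FALSE
  img$coil[1:5, 1:5] <- TRUE
  expect_equal(coil_density(img), 0.25)
  expect_error(coil_density(list(coil = img$coil,
                                 mask = matrix(FALSE, 10, 10))), "mask")
})

test_that("lacunarity matches exhaustive enumeration on small images", {
  # the canonical 4x4 case: one black pixel in a corner is covered by
  # exactly one of the nine 2x2 box positions
  img <- matrix(FALSE, 4, 4); img[1, 1] <- TRUE
  lac <- lacunarity(img, box_sizes = 2)
  expect_equal(lac$L, 9, tolerance = 1e-12)
  expect_equal(brute_lacunarity(img, 2), 9)
  # uniform all-black region: Lambda = 1 for any box fully inside
  allb <- matrix(TRUE, 6, 6)
  expect_equal(lacunarity(allb, box_sizes = c(2, 4))$L, 1)
  # sliding implementation equals brute force on random images
  set.seed(99)
  for (trial in 1:12) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    img <- matrix(runif(nr * nc) < 0.3, nr, nc)
    for (r in c(1, 2, 4)) {
      if (r > min(nr, nc)) next
      expect_equal(lacunarity(img, box_sizes = r)$Lambda,
                   brute_lacunarity(img, r), tolerance = 1e-12,
                   info = sprintf("trial %d r %d", trial, r))
    }
  }
  # clustering raises lacunarity at equal coil density
  clustered <- matrix(FALSE, 8, 8); clustered[4:5, 4:5] <- TRUE
  dispersed <- matrix(FALSE, 8, 8)
  dispersed[cbind(c(2, 2, 7, 7), c(2, 7, 2, 7))] <- TRUE
  expect_gt(lacunarity(clustered, box_sizes = 2)$L,
            lacunarity(dispersed, box_sizes = 2)$L)
  # empty image: L = 1 by convention
  expect_equal(lacunarity(matrix(FALSE, 5, 5), box_sizes = 2)$L, 1)
  # oversized boxes are skipped with a warning
  expect_warning(lacunarity(img, box_sizes = c(2, 50)), "skipped")
})

test_that("L >= 1 always, with equality iff box masses are constant", {
  set.seed(5)
  for (i in 1:20) {
    img <- matrix(runif(36) < runif(1), 6, 6)
    L <- lacunarity(img, box_sizes = c(2, 3))$L
    expect_gte(L, 1)
  }
})

test_that("aneurysm averages and standardization behave definitionally", {
  expect_equal(aneurysm_average(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(2, 5)),
               c(CD = 0.3, L = 2))
  # permutation invariance
  expect_equal(aneurysm_average(c(0.5, 0.1, 0.3, 0.2, 0.4), rep(2, 5))[["CD"]],
               0.3)
  set.seed(2)
  pts <- cbind(CD = runif(10), L = 1 + rexp(10))
  z <- standardize_points(pts)
  expect_equal(colMeans(z), c(CD = 0, L = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(CD = 1, L = 1), tolerance = 1e-12)
  # affine invariance
  z2 <- standardize_points(sweep(pts * 3.7, 2, c(5, -2), `+`))
  expect_equal(z, z2, ignore_attr = TRUE, tolerance = 1e-10)
  # two points standardize to +/- 1/sqrt(2) under the sample-sd estimator
  z3 <- standardize_points(cbind(c(1, 3), c(2, 8)))
  expect_equal(abs(as.numeric(z3)), rep(1 / sqrt(2), 4))
  expect_error(standardize_points(cbind(c(1, 1), c(2, 8))), "variance")
})

test_that("Euclidean distances and the dMin/dMax/dAvg summary are exact", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(3, 4), c(0, 0)),
               euclidean_distance(c(0, 0), c(3, 4)))
  # hand-enumerated fixture: dAvg below dMin is possible (centroid)
  ds <- distance_summary(c(1, 0), rbind(c(0, 0), c(2, 0)))
  expect_equal(ds, c(dMin = 1, dMax = 1, dAvg = 0))
  one <- distance_summary(c(1, 1), rbind(c(4, 5)))
  expect_equal(one[["dMin"]], one[["dMax"]])
  expect_equal(one[["dMin"]], one[["dAvg"]])
  same <- distance_summary(c(2, 2), rbind(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(same), c(0, 0, 0))
})

test_that("group comparison runs normality, variance and t tests", {
  same <- suppressWarnings(compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_A - same$mean_B, 0)
  far <- compare_groups(c(0, 0, 0, 0.1), c(10, 10, 10, 10.1))
  expect_lt(far$p_value, 0.001)
  expect_true(far$significant)
  # pooled-variance closed form cross-check
  a <- c(1.1, 1.4, 0.9, 1.2); b <- c(2.0, 2.3, 1.8, 2.2)
  cg <- compare_groups(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  if (cg$equal_var) expect_equal(cg$t_statistic, t_manual, tolerance = 1e-10)
  w <- capture_warnings(compare_groups(c(1, 2), c(3, 4)))
  expect_true(any(grepl("skipped", w)))
  expect_error(compare_groups(1:3, 1:4), "equal length")
})

test_that("the deployed-coil metrics pipeline is a pure function", {
  pipe <- reduced_pipeline()
  cd1 <- coil_distribution(pipe$deployed, pipe$case, n_sections = 4)
  cd2 <- coil_distribution(pipe$deployed, pipe$case, n_sections = 4)
  expect_identical(cd1$per_section, cd2$per_section)
  expect_true(all(cd1$per_section$CD >= 0 & cd1$per_section$CD <= 1))
  expect_true(all(cd1$per_section$L >= 1))
  # CD convergence in resolution
  pl <- extract_sections(pipe$case, n = 4)[[2]]
  img_a <- rasterize_section(pipe$deployed, pl, pipe$case,
                             resolution = 0.2921 / 8)
  img_b <- rasterize_section(pipe$deployed, pl, pipe$case,
                             resolution = 0.2921 / 16)
  expect_equal(coil_density(img_a), coil_density(img_b), tolerance = 0.02)
})

test_that("section images write as PNG with JSON sidecar", {
  skip_if_not_installed("png")
  pipe <- reduced_pipeline()
  pl <- extract_sections(pipe$case, n = 4)[[2]]
  img <- rasterize_section(pipe$deployed, pl, pipe$case)
  fp <- tempfile(fileext = ".png"); fj <- tempfile(fileext = ".json")
  write_section_png(img, fp, fj)
  expect_true(file.exists(fp))
  side <- jsonlite::read_json(fj)
  expect_equal(side$resolution_mm, img$resolution)
})
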