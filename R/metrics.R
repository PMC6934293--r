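# Quantification of deployed coil distributions: sequential intra-
# aneurysmal cross-sections, binary rasterization, coil density (CD),
# gliding-box lacunarity (L), and the standardized CD-L Euclidean-distance
# comparison with univariate statistics.

#' Sequential cross-section planes through the sac
#'
#' Planes perpendicular to the dome-to-neck axis, the first one `spacing`
#' below the dome apex, progressing toward the neck.
#'
#' @param case an `aneurysm_case`
#' @param n number of planes (default 5)
#' @param spacing plane spacing (mm, default 1)
#' @return List of `section_plane` objects (fields `origin`, `normal`,
#'   `index`).
#' @export
extract_sections <- function(case, n = 5, spacing = 1) {
  axis <- case$sac_axis / sqrt(sum(case$sac_axis^2))
  depth_max <- 2 * case$sac_radius
  feasible <- floor(depth_max / spacing - 1e-9)
  if (n > feasible)
    stop_domain("sac of diameter ", 2 * case$sac_radius, " mm admits at most ",
                feasible, " planes at ", spacing, " mm spacing (requested ",
                n, ")")
  lapply(seq_len(n), function(k) {
    structure(list(origin = case$dome_apex + k * spacing * axis,
                   normal = axis, index = k, spacing = spacing),
              class = "section_plane")
  })
}

#' Rasterize a deployed coil on a section plane
#'
#' The coil is drawn as the intersection of the swept tube (radius `D2/2`
#' around each centerline segment) with the plane: a pixel is coil if its
#' 3D center lies within `D2/2` of any centerline segment.  The mask is
#' the sac outline on the *first* section plane, reused for all sections
#' of a deployment (matching the epoxy-block protocol where the
#' first-section outline defines the analysis region).
#'
#' @param nodes deployed coil centerline (n x 3) or a
#'   `deployed_configuration`
#' @param plane a `section_plane`
#' @param case the `aneurysm_case`
#' @param D2 coil secondary diameter (mm)
#' @param resolution pixel size (mm); must be at most `D2/4`; default
#'   `D2/8`
#' @param mask_radius mask disc radius (mm); default derived from the sac
#'   on section 1
#' @return Object of class `binary_image`: logical `coil` and `mask`
#'   matrices, `resolution`, plane metadata.
#' @export
rasterize_section <- function(nodes, plane, case, D2 = 0.2921,
                              resolution = D2 / 8, mask_radius = NULL) {
  if (inherits(nodes, "deployed_configuration")) nodes <- nodes$nodes
  if (resolution > D2 / 4 + 1e-12)
    stop_domain("resolution must be at most D2/4 so the tube spans >= 4 px")
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  # mask: sac outline on the first section plane
  if (is.null(mask_radius)) {
    d1 <- abs(sum((case$dome_apex + plane$spacing * nrm - case$sac_center) *
                    nrm))
    mask_radius <- sqrt(max(case$sac_radius^2 - d1^2, 0))
  }
  # the in-plane mask center: sac center projected onto this plane
  cen <- case$sac_center +
    sum((plane$origin - case$sac_center) * nrm) * nrm
  half <- mask_radius + D2
  px <- seq(-half, half, by = resolution)
  grid2 <- expand.grid(a = px, b = px)
  pts3 <- matrix(cen, nrow(grid2), 3, byrow = TRUE) +
    outer(grid2$a, u) + outer(grid2$b, v)
  mask <- matrix(sqrt(grid2$a^2 + grid2$b^2) <= mask_radius,
                 length(px), length(px))
  if (!is.null(nodes) && nrow(nodes) >= 2) {
    dmin <- cpp_min_dist_to_segments(pts3, nodes[-nrow(nodes), , drop = FALSE],
                                     nodes[-1, , drop = FALSE])
    coil <- matrix(dmin <= D2 / 2, length(px), length(px))
  } else {
    coil <- matrix(FALSE, length(px), length(px))
  }
  structure(list(coil = coil & mask, mask = mask, resolution = resolution,
                 plane = plane, mask_radius = mask_radius),
            class = "binary_image")
}

#' Coil density of a binary cross-section
#'
#' The fraction of the mask interior occupied by coil pixels.
#'
#' @param img a `binary_image` (or a list with logical `coil`, `mask`)
#' @return CD in `[0, 1]`.
#' @export
coil_density <- function(img) {
  total <- sum(img$mask)
  if (total == 0) stop_domain("empty mask")
  sum(img$coil & img$mask) / total
}

#' Gliding-box lacunarity of a binary cross-section
#'
#' For each box size `r`, an `r x r` window slides over every position
#' fully inside the bounding box of the mask; the box mass is the coil
#' (black) pixel count; `Lambda(r) = sigma^2(r)/mu^2(r) + 1`.  The
#' reported lacunarity is the arithmetic mean of `Lambda(r)` over the box
#' size series (default powers of two up to 45% of the mask bounding box).
#' An image with no coil pixels has `L = 1` by convention.
#'
#' @param img a `binary_image` or logical matrix (coil pixels)
#' @param box_sizes integer vector of box edge lengths (pixels)
#' @param mask optional logical matrix delimiting the analysis region
#' @return Object of class `lacunarity_result`: `L`, per-size `Lambda`,
#'   `box_sizes`.
#' @export
lacunarity <- function(img, box_sizes = NULL, mask = NULL) {
  if (inherits(img, "binary_image")) {
    mask <- mask %||% img$mask
    img <- img$coil
  }
  stopifnot(is.matrix(img))
  img <- img * 1L
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  # bounding box of the mask
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  if (is.null(box_sizes)) {
    rmax <- floor(0.45 * min(nr, nc))
    box_sizes <- 2^(1:max(1, floor(log2(max(rmax, 2)))))
    box_sizes <- box_sizes[box_sizes <= max(rmax, 2)]
  }
  if (sum(sub) == 0)
    return(structure(list(L = 1, Lambda = rep(1, length(box_sizes)),
                          box_sizes = box_sizes, note = "no coil pixels"),
                     class = "lacunarity_result"))
  # summed-area table for O(1) box masses
  sat <- apply(apply(sub, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  Lambda <- vapply(box_sizes, function(r) {
    if (r > nr || r > nc) return(NA_real_)
    i <- seq_len(nr - r + 1); j <- seq_len(nc - r + 1)
    m <- sat[i + r, j + r, drop = FALSE] - sat[i, j + r, drop = FALSE] -
      sat[i + r, j, drop = FALSE] + sat[i, j, drop = FALSE]
    mu <- mean(m)
    if (mu == 0) return(1)
    v <- mean(m^2) - mu^2
    v / mu^2 + 1
  }, numeric(1))
  keep <- !is.na(Lambda)
  if (!any(keep)) stop_domain("all box sizes exceed the mask bounding box")
  if (any(!keep))
    warning("box sizes ", paste(box_sizes[!keep], collapse = ", "),
            " exceed the mask bounding box and were skipped")
  structure(list(L = mean(Lambda[keep]), Lambda = Lambda[keep],
                 box_sizes = box_sizes[keep]),
            class = "lacunarity_result")
}

#' Coil distribution of one deployment
#'
#' Rasterizes all section planes and returns per-section CD and L plus
#' the aneurysm-averaged values.
#'
#' @param dep a `deployed_configuration` (or n x 3 node matrix)
#' @param case an `aneurysm_case`
#' @param n_sections,spacing sectioning protocol
#' @param D2,resolution rasterization parameters
#' @return Object of class `coil_distribution` with `per_section`
#'   (data.frame: section, CD, L) and `CD`, `L` (aneurysm averages).
#' @export
coil_distribution <- function(dep, case, n_sections = 5, spacing = 1,
                              D2 = 0.2921, resolution = D2 / 8) {
  planes <- extract_sections(case, n_sections, spacing)
  imgs <- lapply(planes, function(pl)
    rasterize_section(dep, pl, case, D2 = D2, resolution = resolution))
  cd <- vapply(imgs, coil_density, numeric(1))
  lac <- vapply(imgs, function(im) lacunarity(im)$L, numeric(1))
  structure(list(per_section = data.frame(section = seq_len(n_sections),
                                          CD = cd, L = lac),
                 CD = mean(cd), L = mean(lac)),
            class = "coil_distribution")
}

#' Aneurysm-averaged coil distribution
#'
#' Arithmetic mean of per-section CD and L values of one deployment.
#'
#' @param CD,L numeric vectors (one value per cross-section)
#' @return Named vector `c(CD, L)`.
#' @export
aneurysm_average <- function(CD, L) {
  c(CD = mean(CD), L = mean(L))
}

#' Standardize aneurysm-averaged points
#'
#' Z-scores each coordinate over the pooled point set (experiment plus
#' both techniques of one phantom), so CD and L share a scale: each
#' column of the result has mean 0 and standard deviation 1.
#'
#' @param points data.frame or matrix with columns CD and L
#' @return Matrix of standardized coordinates.
#' @export
standardize_points <- function(points) {
  m <- as.matrix(points)
  if (nrow(m) < 2) stop_domain("need at least 2 points to standardize")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop_domain("zero variance in a coordinate; cannot standardize")
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Euclidean distance in standardized CD-L space
#'
#' `d = sqrt((CD_sim - CD_exp)^2 + (L_sim - L_exp)^2)`.
#'
#' @param p_sim,p_exp length-2 vectors (standardized CD, L)
#' @return Distance `d`.
#' @export
euclidean_distance <- function(p_sim, p_exp) {
  sqrt(sum((as.numeric(p_sim) - as.numeric(p_exp))^2))
}

#' Distance summary of a virtual ensemble against an experiment point
#'
#' `dMin`/`dMax` are the smallest/largest of the individual distances from
#' the experiment point to each virtual point; `dAvg` is the distance from
#' the experiment point to the *mean* of the virtual points (and can
#' therefore be smaller than `dMin`).
#'
#' @param p_exp experiment point (standardized CD, L)
#' @param virtual matrix of virtual points (rows)
#' @return Named vector `c(dMin, dMax, dAvg)`.
#' @export
distance_summary <- function(p_exp, virtual) {
  virtual <- rbind(virtual)
  if (nrow(virtual) < 1) stop_domain("need at least one virtual point")
  d <- apply(virtual, 1, euclidean_distance, p_exp = p_exp)
  c(dMin = min(d), dMax = max(d),
    dAvg = euclidean_distance(colMeans(virtual), p_exp))
}

#' Univariate comparison of distance groups between techniques
#'
#' Shapiro-Wilk normality per group, Levene's test of equal variances
#' across groups, then a two-sample Student's t-test (equal variances
#' assumed when Levene's test does not reject).  Significance threshold
#' p < 0.05.
#'
#' @param distances_A,distances_B distance groups (e.g. the four per-
#'   phantom dAvg values of each technique)
#' @param alpha significance level
#' @return Object of class `group_comparison` with group summaries and
#'   the test p-values.
#' @export
compare_groups <- function(distances_A, distances_B, alpha = 0.05) {
  a <- as.numeric(distances_A); b <- as.numeric(distances_B)
  if (length(a) != length(b)) stop_domain("groups must have equal length")
  sw <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) {
      warning("normality test skipped (n < 3 or constant group)")
      return(NA_real_)
    }
    shapiro.test(x)$p.value
  }
  shapiro_p <- c(A = sw(a), B = sw(b))
  lev_p <- if (requireNamespace("car", quietly = TRUE)) {
    g <- factor(rep(c("A", "B"), c(length(a), length(b))))
    car::leveneTest(c(a, b) ~ g)[1, "Pr(>F)"]
  } else {
    # Brown-Forsythe fallback: one-way test on |x - median|
    za <- abs(a - stats::median(a)); zb <- abs(b - stats::median(b))
    if (sd(c(za, zb)) == 0) 1 else t.test(za, zb, var.equal = TRUE)$p.value
  }
  equal_var <- is.na(lev_p) || lev_p >= alpha
  tt <- if (identical(a, b)) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    t.test(a, b, var.equal = equal_var)
  }
  structure(list(
    mean_A = mean(a), sd_A = sd(a), mean_B = mean(b), sd_B = sd(b),
    shapiro_p = shapiro_p, levene_p = lev_p, equal_var = equal_var,
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    significant = tt$p.value < alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group A: %.4f +/- %.4f | Group B: %.4f +/- %.4f\n",
              x$mean_A, x$sd_A, x$mean_B, x$sd_B))
  cat(sprintf("Shapiro-Wilk p: A %.3g, B %.3g; Levene p: %.3g (%s)\n",
              x$shapiro_p[1], x$shapiro_p[2], x$levene_p,
              if (x$equal_var) "equal variances" else "Welch"))
  cat(sprintf("t = %.4f, p = %.4g%s\n", x$t_statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Write a binary section image as PNG with JSON sidecar
#'
#' @param img a `binary_image`
#' @param png_path output PNG (coil black on white); requires the `png`
#'   package
#' @param json_path optional sidecar path (resolution, mask radius)
#' @return `png_path`, invisibly.
#' @export
write_section_png <- function(img, png_path, json_path = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_domain("the png package is required to write PNG sections")
  arr <- 1 - (img$coil & img$mask) * 1  # coil black
  png::writePNG(arr, png_path)
  if (!is.null(json_path))
    jsonlite::write_json(list(resolution_mm = img$resolution,
                              mask_radius_mm = img$mask_radius),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' Tabulate ensemble metrics as CSV-ready data
#'
#' @param ensemble a `deployment_ensemble`
#' @param case the `aneurysm_case`
#' @param ... passed to [coil_distribution()]
#' @return data.frame with one row per (rotation, section).
#' @export
ensemble_metrics <- function(ensemble, case, ...) {
  out <- NULL
  for (k in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[k]]
    if (inherits(run, "deployment_failure")) next
    cdist <- coil_distribution(run, case, ...)
    df <- cdist$per_section
    df$rotation <- ensemble$rotations[k]
    df$technique <- ensemble$technique
    out <- rbind(out, df)
  }
  out
}
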