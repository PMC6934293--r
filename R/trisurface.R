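# Triangulated surfaces: STL I/O, primitive meshes, implicit-surface
# polygonization and containment queries.

#' Construct a triangulated surface
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @return Object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            min(triangles) >= 1, max(triangles) <= nrow(vertices))
  s <- structure(list(vertices = vertices, triangles = triangles),
                 class = "tri_surface")
  a <- triangle_areas(s)
  if (any(a <= 1e-12))
    stop_domain(sum(a <= 1e-12), " degenerate triangles (area <= 1e-12 mm^2)")
  s
}

triangle_corners <- function(s) {
  list(A = s$vertices[s$triangles[, 1], , drop = FALSE],
       B = s$vertices[s$triangles[, 2], , drop = FALSE],
       C = s$vertices[s$triangles[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-triangle areas and normals
#' @param s a `tri_surface`
#' @return `triangle_areas`: numeric vector of areas (mm^2);
#'   `triangle_normals`: m x 3 matrix of unit normals.
#' @export
triangle_areas <- function(s) {
  co <- triangle_corners(s)
  cr <- cross3(co$B - co$A, co$C - co$A)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname triangle_areas
#' @export
triangle_normals <- function(s) {
  co <- triangle_corners(s)
  cr <- cross3(co$B - co$A, co$C - co$A)
  cr / sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param s a `tri_surface`
#' @return Sum of triangle areas (mm^2).
#' @export
surface_area <- function(s) sum(triangle_areas(s))

#' Is a surface watertight?
#'
#' Checks that every edge is shared by exactly two triangles with opposite
#' orientation (closed, orientable, 2-manifold).
#'
#' @param s a `tri_surface`
#' @return Logical.
#' @export
is_watertight <- function(s) {
  tr <- s$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  # orientation: each undirected edge must appear once in each direction
  dir_key <- paste(e[, 1], e[, 2])
  !any(duplicated(dir_key))
}

#' Read and write STL surfaces
#'
#' Both the ASCII and binary STL dialects are supported.  On write the
#' dialect is chosen by `ascii`; on read it is auto-detected.  STL stores
#' one triangle per facet, so shared vertices are merged on read by exact
#' coordinate match (STL files written by this package round-trip exactly;
#' binary STL stores float32, and reading a binary file preserves
#' coordinates to float32 precision).
#'
#' @param path file path
#' @param s a `tri_surface`
#' @param ascii write the ASCII dialect (default binary)
#' @return `read_stl`: a `tri_surface`; `write_stl`: `path` invisibly.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop_domain("no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) stop_domain("malformed STL (", path,
                                       "): file shorter than 80-byte header")
  head_txt <- rawToChar(header[header != as.raw(0)])
  ntri_bin <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri_bin) == 1 && !is.na(ntri_bin) &&
    fsize == 84 + 50 * as.numeric(ntri_bin)
  if (!is_binary && grepl("^\\s*solid", head_txt)) {
    return(read_stl_ascii(path))
  }
  if (!is_binary)
    stop_domain("malformed STL (", path, "): triangle count at byte 80 (",
                ntri_bin, ") inconsistent with file size ", fsize)
  tri_raw <- matrix(0, ntri_bin, 9)
  for (i in seq_len(ntri_bin)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12)
      stop_domain("malformed STL (", path, "): truncated at byte ",
                  84 + (i - 1) * 50)
    tri_raw[i, ] <- rec[4:12]
    readBin(con, "raw", 2)  # attribute byte count
  }
  facets_to_surface(tri_raw)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop_domain("malformed ASCII STL (", path, "): vertex count ",
                length(vl), " not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums)) stop_domain("malformed ASCII STL (", path,
                               "): non-numeric vertex record")
  facets_to_surface(matrix(t(nums), ncol = 9, byrow = TRUE))
}

facets_to_surface <- function(tri_raw) {
  pts <- rbind(tri_raw[, 1:3, drop = FALSE], tri_raw[, 4:6, drop = FALSE],
               tri_raw[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  n <- nrow(tri_raw)
  tri_surface(pts[uniq, , drop = FALSE], cbind(idx[1:n], idx[n + 1:n],
                                               idx[2 * n + 1:n]))
}

#' @rdname read_stl
#' @export
write_stl <- function(s, path, ascii = FALSE) {
  stopifnot(inherits(s, "tri_surface"))
  co <- triangle_corners(s)
  nrm <- triangle_normals(s)
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid surface", con)
    for (i in seq_len(nrow(nrm))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           c(co$A[i, 1], co$B[i, 1], co$C[i, 1]),
                           c(co$A[i, 2], co$B[i, 2], co$C[i, 2]),
                           c(co$A[i, 3], co$B[i, 3], co$C[i, 3])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid surface", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(charToRaw("coildeploy binary STL"),
               raw(80 - nchar("coildeploy binary STL"))), con)
    writeBin(as.integer(nrow(nrm)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(nrm))) {
      writeBin(as.numeric(c(nrm[i, ], co$A[i, ], co$B[i, ], co$C[i, ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; watertight by
#' construction with outward-oriented normals.
#'
#' @param radius sphere radius (mm)
#' @param subdivisions number of 4-to-1 subdivisions (3 gives 1280
#'   triangles)
#' @param center sphere center
#' @return A `tri_surface`.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      edge_mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  tri_surface(sweep(v * radius, 2, center, `+`), f)
}

#' Polygonize an implicit surface by marching tetrahedra
#'
#' Evaluates `f` (positive inside) on a regular grid and extracts the
#' zero-level surface.  Marching tetrahedra produces a closed, watertight
#' triangulation for any implicit solid wholly contained in the box.
#' Triangles are oriented with outward normals.
#'
#' @param f vectorized implicit function: takes an n x 3 matrix, returns n
#'   values, positive inside the solid
#' @param lower,upper corners of the bounding box (mm)
#' @param n grid resolution per axis (scalar or length-3)
#' @return A `tri_surface`.
#' @export
implicit_surface <- function(f, lower, upper, n = 48) {
  n <- rep(n, length.out = 3)
  xs <- seq(lower[1], upper[1], length.out = n[1])
  ys <- seq(lower[2], upper[2], length.out = n[2])
  zs <- seq(lower[3], upper[3], length.out = n[3])
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  vals <- f(grid)
  res <- cpp_marching_tets(vals, as.integer(n), xs, ys, zs)
  orient_outward(tri_surface(res$vertices, res$triangles))
}

# make triangle winding consistent across the mesh (orientation flood
# fill over shared edges), then flip globally if the signed volume is
# negative, so normals point outward
orient_outward <- function(s) {
  tr <- s$triangles
  m <- nrow(tr)
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  tri_of_edge <- rep(seq_len(m), 3)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ord <- order(key)
  key_s <- key[ord]; tri_s <- tri_of_edge[ord]
  first <- !duplicated(key_s)
  # each undirected edge appears twice in a closed 2-manifold
  pair_a <- tri_s[first]
  pair_b <- tri_s[!first]
  nbr <- vector("list", m)
  for (k in seq_along(pair_a)) {
    nbr[[pair_a[k]]] <- c(nbr[[pair_a[k]]], pair_b[k])
    nbr[[pair_b[k]]] <- c(nbr[[pair_b[k]]], pair_a[k])
  }
  dir_edges <- function(t) rbind(tr[t, c(1, 2)], tr[t, c(2, 3)], tr[t, c(3, 1)])
  visited <- logical(m)
  flip <- logical(m)
  queue <- integer(m)
  queue[1] <- 1L; qhead <- 1L; qtail <- 1L
  visited[1] <- TRUE
  while (qhead <= qtail) {
    t0 <- queue[qhead]; qhead <- qhead + 1L
    e0 <- dir_edges(t0)
    if (flip[t0]) e0 <- e0[, c(2, 1)]
    e0key <- paste(e0[, 1], e0[, 2])
    for (t1 in nbr[[t0]]) {
      if (visited[t1]) next
      e1 <- dir_edges(t1)
      # consistent orientation: shared edge traversed in opposite senses
      same_dir <- any(paste(e1[, 1], e1[, 2]) %in% e0key)
      flip[t1] <- same_dir
      visited[t1] <- TRUE
      qtail <- qtail + 1L
      queue[qtail] <- t1
    }
  }
  tr[flip, ] <- tr[flip, c(1, 3, 2)]
  s$triangles <- tr
  # outward: signed volume of the closed surface must be positive
  co <- triangle_corners(s)
  vol <- sum(rowSums(co$A * cross3(co$B, co$C))) / 6
  if (vol < 0) s$triangles <- s$triangles[, c(1, 3, 2)]
  s
}

#' Point containment in a watertight surface
#'
#' The primary test uses the generalized winding number (sum of signed
#' solid angles): points with winding number above 0.5 are inside.  The
#' independent cross-check [ray_parity_inside()] counts ray crossings along
#' a given direction.
#'
#' @param s a watertight `tri_surface`
#' @param points n x 3 matrix
#' @param dir ray direction for the parity test
#' @return Logical vector, `TRUE` for strictly inside points.
#' @export
point_in_surface <- function(s, points) {
  points <- rbind(points)
  cpp_winding_number(s$vertices, s$triangles, points) > 0.5
}

#' @rdname point_in_surface
#' @export
ray_parity_inside <- function(s, points, dir = c(0.57735, 0.57735, 0.57735)) {
  points <- rbind(points)
  cpp_ray_parity(s$vertices, s$triangles, points,
                 dir / sqrt(sum(dir^2))) %% 2L == 1L
}

#' Swept-tube surface along a polyline
#'
#' Builds a tube of constant radius around a polyline using
#' parallel-transported cross-section frames; optionally capped.
#'
#' @param points n x 3 polyline (mm)
#' @param radius tube radius (mm)
#' @param n_around vertices per ring
#' @param capped close the ends with triangle fans
#' @return A `tri_surface`.
#' @export
tube_surface <- function(points, radius, n_around = 16, capped = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2)
  tang <- rbind(points[2, ] - points[1, ],
                (points[pmin(3:n + 0, n), , drop = FALSE] -
                 points[pmax(1:(n - 2), 1), , drop = FALSE]),
                points[n, ] - points[n - 1, ])[1:n, , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  # parallel transport an initial normal
  nrm <- matrix(0, n, 3)
  t1 <- tang[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t1) * t1; nrm[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    nrm[i, ] <- if (nv > 1e-12) v / nv else nrm[i - 1, ]
  }
  bin <- cross3(tang, nrm)
  ang <- seq(0, 2 * pi, length.out = n_around + 1)[-(n_around + 1)]
  verts <- matrix(0, n * n_around, 3)
  for (i in seq_len(n)) {
    ring <- outer(cos(ang), nrm[i, ]) + outer(sin(ang), bin[i, ])
    verts[(i - 1) * n_around + seq_len(n_around), ] <-
      sweep(ring * radius, 2, points[i, ], `+`)
  }
  tris <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) {
    a <- (i - 1) * n_around + seq_len(n_around)
    b <- i * n_around + seq_len(n_around)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    tris <- rbind(tris, cbind(a, b, a2), cbind(a2, b, b2))
  }
  if (capped) {
    c1 <- nrow(verts) + 1L; c2 <- nrow(verts) + 2L
    verts <- rbind(verts, points[1, ], points[n, ])
    a <- seq_len(n_around); a2 <- c(a[-1], a[1])
    b <- (n - 1) * n_around + seq_len(n_around); b2 <- c(b[-1], b[1])
    tris <- rbind(tris, cbind(a2, a, c1), cbind(b, b2, c2))
  }
  tri_surface(verts, tris)
}
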