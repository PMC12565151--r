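#' Triangular surface mesh
#'
#' Minimal triangle-mesh container used throughout the package: vertex
#' coordinates in mm and 1-based face indices.
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @return object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("`vertices` must be n x 3")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Directed edge census. A watertight, consistently oriented mesh has every
# undirected edge used exactly twice, once in each direction.
mesh_edge_census <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(boundary = sum(table(key_und) == 1),
       nonmanifold = sum(table(key_und) > 2),
       duplicated_directed = anyDuplicated(key_dir) > 0)
}

#' Is a mesh closed (watertight) and consistently oriented?
#' @param mesh a `trimesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  cen <- mesh_edge_census(mesh)
  cen$boundary == 0 && cen$nonmanifold == 0 && !cen$duplicated_directed
}

#' Enclosed volume of a closed triangular mesh
#'
#' Divergence-theorem volume: the surface integral
#' `(1/3) * sum over faces of (centroid . normal) * face area`, evaluated as
#' a sum of signed tetrahedra. Requires a watertight, consistently
#' outward-oriented mesh; an open or non-manifold mesh raises an error with a
#' defect report and an inward-oriented mesh (negative volume) is rejected.
#'
#' @param mesh a closed `trimesh` (coordinates in mm).
#' @param check validate closedness/orientation (default TRUE).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  if (check) {
    cen <- mesh_edge_census(mesh)
    if (cen$boundary > 0 || cen$nonmanifold > 0)
      stop(sprintf(paste0("mesh is not closed: %d boundary edge(s), ",
                          "%d non-manifold edge(s)"),
                   cen$boundary, cen$nonmanifold))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
               a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
               a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
  if (check && vol < 0)
    stop("mesh appears inward-oriented (negative signed volume); ",
         "flip face orientation")
  vol
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; the standard closed test
#' surface with near-uniform triangles.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivision passes (faces =
#'   `20 * 4^subdivisions`).
#' @param center length-3 numeric center (mm).
#' @return a closed `trimesh` with outward orientation.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (iter in seq_len(subdivisions)) {
    midkey <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midkey[[key]]
      if (is.null(idx)) {
        m <- (verts[i, ] + verts[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        midkey[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      i <- f[k, 1]; j <- f[k, 2]; l <- f[k, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); d <- midpoint(l, i)
      nf[4 * k - 3, ] <- c(i, a, d)
      nf[4 * k - 2, ] <- c(j, b, a)
      nf[4 * k - 1, ] <- c(l, d, b)
      nf[4 * k, ]     <- c(a, b, d)
    }
    v <- verts
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  trimesh(v, f)
}

# Rotation-minimizing (parallel-transported) orthonormal frames along a
# polyline: tangent T plus normals (N1, N2) with minimal twist.
transport_frames <- function(points) {
  n <- nrow(points)
  tang <- fd_derivative_mat(points, seq_len(n))
  tang <- tang / sqrt(rowSums(tang^2))
  n1 <- matrix(0, n, 3)
  seed <- c(0, 0, 1)
  if (abs(sum(seed * tang[1, ])) > 0.9) seed <- c(0, 1, 0)
  v0 <- seed - sum(seed * tang[1, ]) * tang[1, ]
  n1[1, ] <- v0 / sqrt(sum(v0^2))
  for (i in 2:n) {
    v <- n1[i - 1, ] - sum(n1[i - 1, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    n1[i, ] <- if (nv < 1e-12) n1[i - 1, ] else v / nv
  }
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  list(tangent = tang, n1 = n1, n2 = n2)
}

#' Tube surface mesh around a centerline with elliptical cross-sections
#'
#' Sweeps elliptical cross-sections (semi-axes `a(s)`, `b(s)`) along a
#' polyline using rotation-minimizing frames. The tube wall is closed; the
#' inlet and outlet rings are left open. Ring-to-centerline correspondence is
#' retained in the `ring` attribute (one centerline index per vertex).
#'
#' @param points centerline points (n x 3, mm).
#' @param a,b per-point semi-major/semi-minor axes (mm); scalars recycle.
#' @param n_theta vertices per ring.
#' @return a `trimesh` with attribute `ring`.
#' @export
tube_mesh <- function(points, a, b = a, n_theta = 24) {
  points <- as.matrix(points)
  n <- nrow(points)
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  fr <- transport_frames(points)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ct <- cos(theta); st <- sin(theta)
  verts <- matrix(0, n * n_theta, 3)
  for (i in seq_len(n)) {
    idx <- ((i - 1) * n_theta + 1):(i * n_theta)
    verts[idx, ] <- matrix(points[i, ], n_theta, 3, byrow = TRUE) +
      outer(a[i] * ct, fr$n1[i, ]) + outer(b[i] * st, fr$n2[i, ])
  }
  faces <- matrix(0L, 2 * (n - 1) * n_theta, 3)
  k <- 1
  for (i in seq_len(n - 1)) {
    base0 <- (i - 1) * n_theta
    base1 <- i * n_theta
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      faces[k, ] <- c(base0 + j, base1 + j, base1 + jn); k <- k + 1
      faces[k, ] <- c(base0 + j, base1 + jn, base0 + jn); k <- k + 1
    }
  }
  m <- trimesh(verts, faces)
  attr(m, "ring") <- rep(seq_len(n), each = n_theta)
  m
}
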