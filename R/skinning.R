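#' Cotangent Laplacian and lumped mass matrix of a triangle mesh
#'
#' Standard discrete Laplace-Beltrami building blocks: symmetric cotangent
#' stiffness matrix `L = D - W` with `w_ij = (cot a_ij + cot b_ij) / 2`, and
#' the barycentric lumped mass matrix (one third of incident triangle area
#' per vertex).
#'
#' @param mesh a `trimesh`.
#' @return list with sparse `L` (n x n) and diagonal `M` (n x n).
#' @keywords internal
cotan_laplacian <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  area3 <- numeric(nv)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  farea <- sqrt(rowSums(cr^2)) / 2
  for (cn in corners) {
    i <- f[, cn[1]]; j <- f[, cn[2]]; k <- f[, cn[3]]
    u <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    w <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    cot <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2) * rowSums(w^2) - rowSums(u * w)^2), 1e-300)
    ii <- c(ii, i, j); jj <- c(jj, j, i); ww <- c(ww, cot / 2, cot / 2)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  for (c1 in 1:3) area3[f[, c1]] <- area3[f[, c1]] + farea / 3
  list(L = L, M = Matrix::Diagonal(x = pmax(area3, 1e-300)))
}

#' Solve biharmonic skinning weights under anchor constraints
#'
#' Each centerline segment j gets a scalar field `w_j` over the mesh
#' vertices obtained by minimizing the biharmonic energy `tr(W' Q W)`,
#' `Q = L M^-1 L` (square of the area-normalized cotangent Laplacian),
#' subject to anchor constraints: anchored vertices carry weight 1 for their
#' own segment and 0 for all others. Negative intermediate values are
#' clamped to 0 and rows renormalized to sum to 1, giving convex blending
#' weights.
#'
#' @param mesh a `trimesh` (the vessel wall at the reference phase).
#' @param anchors list of integer vectors, one per segment: the vertex
#'   indices anchored to that segment. Every segment needs at least one
#'   anchor.
#' @return object of class `skinning_weights`: list with `W` (vertex x
#'   segment dense matrix, rows summing to 1), `anchors`, and the maximum
#'   KKT residual `kkt_residual` of the unclamped solve.
#' @export
solve_skinning_weights <- function(mesh, anchors) {
  if (!inherits(mesh, "trimesh")) stop("`mesh` must be a trimesh")
  if (!is.list(anchors) || length(anchors) < 1)
    stop("`anchors` must be a non-empty list of vertex index vectors")
  ns <- length(anchors)
  nv <- nrow(mesh$vertices)
  for (j in seq_len(ns)) {
    if (length(anchors[[j]]) == 0)
      stop(sprintf("segment %d has no anchor vertices; the constraint %s",
                   j, "system would be singular"))
  }
  lm <- cotan_laplacian(mesh)
  Q <- Matrix::t(lm$L) %*% Matrix::solve(lm$M, lm$L)
  Q <- (Q + Matrix::t(Q)) / 2
  fixed <- sort(unique(unlist(anchors)))
  if (any(fixed < 1 | fixed > nv)) stop("anchor index out of range")
  free <- setdiff(seq_len(nv), fixed)
  W <- matrix(0, nv, ns)
  for (j in seq_len(ns)) W[anchors[[j]], j] <- 1
  kkt <- 0
  if (length(free) > 0) {
    Qff <- Q[free, free, drop = FALSE]
    Qfc <- Q[free, fixed, drop = FALSE]
    rhs <- -Qfc %*% W[fixed, , drop = FALSE]
    sol <- as.matrix(Matrix::solve(Qff, rhs))
    W[free, ] <- sol
    res <- as.matrix(Qff %*% sol - rhs)
    kkt <- max(abs(res)) / max(1, max(abs(rhs)))
  }
  W[W < 0] <- 0
  rs <- rowSums(W)
  if (any(rs <= 0))
    stop("some vertices received no positive weight; add anchors")
  W <- W / rs
  structure(list(W = W, anchors = anchors, kkt_residual = kkt),
            class = "skinning_weights")
}

#' Anchor rings for tube meshes
#'
#' Default anchor selection for tubes built by [tube_mesh()]: splits the
#' centerline into `n_segments` equal arc-length spans and anchors, for each
#' span, the ring of vertices nearest its midpoint.
#'
#' @param mesh a `trimesh` with a `ring` attribute.
#' @param n_segments number of centerline segments.
#' @return list of vertex-index vectors, one per segment.
#' @export
ring_anchors <- function(mesh, n_segments) {
  ring <- attr(mesh, "ring")
  if (is.null(ring)) stop("mesh has no `ring` attribute (not a tube_mesh)")
  n <- max(ring)
  mids <- round(seq(1, n, length.out = 2 * n_segments + 1)[seq(2, 2 * n_segments, by = 2)])
  lapply(mids, function(m) which(ring == m))
}

#' Rigid transform constructor
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return list with `R`, `t`, class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("`R` must be 3 x 3")
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("`R` is not a rotation (det != 1 or not orthogonal within 1e-6)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Rotation about an axis
#' @param axis length-3 axis (normalized internally).
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Deform a mesh by linear blend skinning
#'
#' Each deformed vertex is the weight-blended image of the original vertex
#' under the per-segment rigid transforms:
#' `v_i' = sum_j w_ij (R_j v_i + t_j)`. Because rows of `W` sum to 1, a
#' common translation of all segments translates the whole mesh exactly, and
#' a single global rigid motion commutes with the deformation.
#'
#' @param mesh a `trimesh`.
#' @param weights a `skinning_weights` whose `W` has one row per vertex.
#' @param transforms list of `rigid_transform`, one per segment.
#' @return deformed `trimesh` (connectivity unchanged).
#' @export
lbs_deform <- function(mesh, weights, transforms) {
  W <- weights$W
  if (nrow(W) != nrow(mesh$vertices))
    stop("weight rows must match vertex count")
  if (length(transforms) != ncol(W))
    stop("one transform per segment is required")
  for (tr in transforms) {
    if (!inherits(tr, "rigid_transform"))
      stop("transforms must be rigid_transform objects")
  }
  v <- mesh$vertices
  # partition of unity: if every segment moves rigidly with the same
  # transform, apply it once (exact, no blending round-off)
  same <- all(vapply(transforms, function(tr)
    identical(tr$R, transforms[[1]]$R) &&
      identical(tr$t, transforms[[1]]$t), logical(1)))
  if (same) {
    t1 <- transforms[[1]]
    out <- if (identical(t1$R, diag(3)) && identical(t1$t, c(0, 0, 0))) v
           else sweep(v %*% t(t1$R), 2, t1$t, "+")
    m2 <- trimesh(out, mesh$faces)
    attr(m2, "ring") <- attr(mesh, "ring")
    return(m2)
  }
  out <- matrix(0, nrow(v), 3)
  for (j in seq_len(ncol(W))) {
    tj <- transforms[[j]]
    vj <- v %*% t(tj$R)
    vj <- sweep(vj, 2, tj$t, "+")
    out <- out + W[, j] * vj
  }
  m2 <- trimesh(out, mesh$faces)
  attr(m2, "ring") <- attr(mesh, "ring")
  m2
}
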