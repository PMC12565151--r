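#' Read a surface mesh (STL, OBJ or legacy VTK polydata)
#'
#' Plain-text readers for the three mesh formats used by the pipeline.
#' STL facets are merged back into shared vertices by exact coordinate
#' match (ASCII STL stores float32-precision coordinates per facet).
#'
#' @param path file path; format chosen by extension (.stl, .obj, .vtk).
#' @return a `trimesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         obj = read_obj(path),
         vtk = read_vtk(path),
         stop("unknown mesh extension: .", ext))
}

#' Write a surface mesh (STL, OBJ or legacy VTK polydata)
#'
#' @param mesh a `trimesh`.
#' @param path output path; format chosen by extension.
#' @return (invisibly) `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path),
         stop("unknown mesh extension: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*solid", lines[1]))
    stop("corrupt STL: missing 'solid' header in ", path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("corrupt STL: vertex count not a multiple of 3")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (any(!is.finite(nums))) stop("corrupt STL: non-numeric vertex data")
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- pmax(sqrt(rowSums(nrm^2)), 1e-300)
  nrm <- nrm / nl
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid dynffr", con)
  for (k in seq_len(nrow(f))) {
    writeLines(c(sprintf(" facet normal %.9g %.9g %.9g",
                         nrm[k, 1], nrm[k, 2], nrm[k, 3]),
                 "  outer loop",
                 sprintf("   vertex %.9g %.9g %.9g",
                         v[f[k, ], 1], v[f[k, ], 2], v[f[k, ], 3]),
                 "  endloop", " endfacet"), con)
  }
  writeLines("endsolid dynffr", con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("corrupt OBJ: no vertices/faces in ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- vapply(strsplit(p[2:4], "/"), function(q) as.integer(q[1]), 1L)
    idx
  }))
  if (any(!is.finite(verts)) || any(is.na(faces)))
    stop("corrupt OBJ: unparseable data")
  trimesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("corrupt VTK: missing header in ", path)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1) stop("corrupt VTK: POINTS section missing")
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  coords <- numeric(0)
  i <- ip + 1
  while (length(coords) < 3 * np) {
    coords <- c(coords, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  verts <- matrix(coords[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)
  if (length(ig) != 1) stop("corrupt VTK: POLYGONS section missing")
  nf <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
  vals <- integer(0)
  i <- ig + 1
  while (length(vals) < 4 * nf) {
    vals <- c(vals, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  m <- matrix(vals[seq_len(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(m[, 1] != 3)) stop("only triangle polygons are supported")
  trimesh(verts, m[, 2:4] + 1L)
}

write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "dynffr surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(mesh$vertices))), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(mesh$faces),
                     4 * nrow(mesh$faces)), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

#' Write a centerline as CSV
#'
#' Columns `x,y,z,radius` plus `area` when present; full double precision.
#'
#' @param cl a `centerline`.
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x = sprintf("%.17g", cl$points[, 1]),
                   y = sprintf("%.17g", cl$points[, 2]),
                   z = sprintf("%.17g", cl$points[, 3]))
  if (!is.null(cl$radius)) df$radius <- sprintf("%.17g", cl$radius)
  if (!is.null(cl$area)) df$area <- sprintf("%.17g", cl$area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centerline from CSV (columns x,y,z[,radius[,area]])
#' @param path input path.
#' @return a `centerline`.
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("centerline CSV needs columns x,y,z")
  centerline(as.matrix(df[, need]),
             radius = if ("radius" %in% names(df)) df$radius else NULL,
             area = if ("area" %in% names(df)) df$area else NULL)
}

#' Write a phase sequence to disk (meshes + JSON manifest)
#'
#' Numbered mesh files (one per phase, format by extension) plus a JSON
#' manifest recording phase fractions, the seed and the generator
#' parameters; this manifest is what the fusion stage reads back.
#'
#' @param models a `phase_sequence`.
#' @param dir output directory.
#' @param format "stl" or "vtk".
#' @return (invisibly) the manifest path.
#' @export
write_phase_sequence <- function(models, dir, format = "stl") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(models))
  for (i in seq_along(models)) {
    files[i] <- sprintf("phase_%02d.%s", i - 1, format)
    write_mesh(models[[i]]$mesh, file.path(dir, files[i]))
    write_centerline_csv(models[[i]]$centerline,
                         file.path(dir, sprintf("centerline_%02d.csv", i - 1)))
  }
  manifest <- list(schema = "dynffr-phases-v1",
                   n_phases = length(models),
                   phase_fraction = vapply(models, `[[`, numeric(1),
                                           "phase_fraction"),
                   mesh_files = files,
                   seed = attr(models, "seed"),
                   base = attr(models, "base")[c("length", "n_axial",
                                                 "n_theta")],
                   motion = attr(models, "motion"))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
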