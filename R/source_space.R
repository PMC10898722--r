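#' Build a two-hemisphere cortical source space by octahedron subdivision
#'
#' Each hemisphere is modelled as a closed triangulated sphere obtained by
#' recursively subdividing an octahedron and projecting new vertices to the
#' unit sphere, then scaled and translated onto a hemispheric shell inside the
#' inner (brain) compartment of the spherical head model. At subdivision level
#' `level` each hemisphere carries `4^level + 2` vertices, so level 6
#' reproduces the 4098 vertices per hemisphere used with a template cortical
#' surface at standard resolution. Dipole orientations are the outward surface
#' normals (radial from each hemisphere centre), i.e. fixed perpendicular to
#' the surrogate cortical surface.
#'
#' @param level Integer subdivision level, `1 <= level <= 7`. Level 1 is the
#'   plain octahedron (6 vertices per hemisphere).
#' @param shell_radius Radius (m) of each hemispheric shell.
#' @param centers 2 x 3 matrix with the left and right hemisphere centres (m).
#'   The defaults keep every vertex strictly inside the 0.087 m brain
#'   compartment of [head_geometry()].
#' @return An object of class `source_space`: a list with `vertices` (n x 3,
#'   metres), `orientations` (n x 3 unit normals), `hemisphere` (factor
#'   `"left"`/`"right"`), `faces_per_hemi` (triangle index matrix of one
#'   hemisphere mesh, 1-based into that hemisphere's own vertices), `level`,
#'   and the geometry arguments.
#' @examples
#' ss <- build_source_space(3)
#' table(ss$hemisphere)        # 66 vertices per hemisphere
#' @export
build_source_space <- function(level,
                               shell_radius = 0.030,
                               centers = rbind(c(-0.035, 0, 0.040),
                                               c( 0.035, 0, 0.040))) {
  if (!is.numeric(level) || length(level) != 1 || level < 1 || level != round(level))
    stop_invalid("`level` must be a single integer >= 1")
  if (level > 7)
    stop_invalid("`level` > 7 refused (vertex count would exceed 16386 per hemisphere)")
  level <- as.integer(level)

  mesh <- octa_sphere(level)
  n <- nrow(mesh$vertices)

  vert <- rbind(mesh$vertices * shell_radius, mesh$vertices * shell_radius)
  vert[seq_len(n), ] <- sweep(vert[seq_len(n), , drop = FALSE], 2, centers[1, ], "+")
  vert[n + seq_len(n), ] <- sweep(vert[n + seq_len(n), , drop = FALSE], 2, centers[2, ], "+")
  orient <- rbind(mesh$vertices, mesh$vertices)  # radial unit normals, outward

  structure(list(
    vertices = vert,
    orientations = orient,
    hemisphere = factor(rep(c("left", "right"), each = n),
                        levels = c("left", "right")),
    faces_per_hemi = mesh$faces,
    level = level,
    shell_radius = shell_radius,
    centers = centers
  ), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  n <- table(x$hemisphere)
  cat(sprintf("<source_space> level %d: %d + %d vertices (left + right)\n",
              x$level, n[["left"]], n[["right"]]))
  invisible(x)
}

n_sources <- function(space) nrow(space$vertices)

# Unit octahedron sphere mesh after (level - 1) subdivisions.
# Returns vertices (n x 3 on the unit sphere) and faces (m x 3, 1-based).
octa_sphere <- function(level) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0),
             c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (i in seq_len(level - 1)) {
    m <- subdivide_mesh(v, f)
    v <- m$vertices
    f <- m$faces
  }
  list(vertices = v, faces = f)
}

# One 4-to-1 triangle subdivision with edge-midpoint vertices projected to the
# unit sphere. Midpoints are deduplicated through an edge key map so the mesh
# stays closed and the vertex count follows V' = V + E.
subdivide_mesh <- function(v, f) {
  nv <- nrow(v)
  edge_id <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(v)
  next_id <- nv
  midpoint <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- edge_id[[key]]
    if (!is.null(id)) return(id)
    p <- v[i, ] + v[j, ]
    p <- p / sqrt(sum(p^2))
    next_id <<- next_id + 1
    verts[[length(verts) + 1]] <<- p
    edge_id[[key]] <- next_id
    next_id
  }
  nf <- nrow(f)
  newf <- matrix(0L, nf * 4, 3)
  for (k in seq_len(nf)) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[4 * k - 3, ] <- c(a, ab, ca)
    newf[4 * k - 2, ] <- c(b, bc, ab)
    newf[4 * k - 1, ] <- c(c, ca, bc)
    newf[4 * k, ] <- c(ab, bc, ca)
  }
  vmat <- rbind(v, do.call(rbind, verts[-1]))
  list(vertices = vmat, faces = newf)
}
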