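# Regular icosahedron scaffold and its 31 rotational symmetry axes.

#' Regular icosahedron in a fixed orientation
#'
#' Builds the unit icosahedron with vertices at the normalized cyclic
#' permutations of `(0, +-1, +-phi)` (phi the golden ratio). This orientation
#' places the three coordinate axes on 2-fold symmetry axes, the convention
#' used by most structural-biology software for icosahedral objects.
#'
#' @return An object of class `icosahedron` with fields:
#'   * `vertices`: 12 x 3 matrix of unit-length vertex directions,
#'   * `faces`: 20 x 3 matrix of vertex indices, outward-wound
#'     (counter-clockwise seen from outside),
#'   * `edges`: 30 x 2 matrix of vertex index pairs (`v1 < v2`).
#' @examples
#' ico <- build_icosahedron()
#' nrow(ico$vertices) - nrow(ico$edges) + nrow(ico$faces)  # Euler: 2
#' @export
build_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    c(0,  1,  phi), c(0,  1, -phi), c(0, -1,  phi), c(0, -1, -phi)
  )
  verts <- rbind(base, base[, c(3, 1, 2)], base[, c(2, 3, 1)])
  verts <- verts / sqrt(1 + phi^2)

  d <- as.matrix(stats::dist(verts))
  edge_len <- min(d[d > 1e-9])
  adj <- d < edge_len * (1 + 1e-9) & d > 1e-9

  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- NULL

  faces <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    for (c_ in seq_len(12L)) {
      if (c_ > b && adj[a, c_] && adj[b, c_]) {
        faces[[length(faces) + 1L]] <- c(a, b, c_)
      }
    }
  }
  faces <- do.call(rbind, faces)

  # outward winding: normal of (v1, v2, v3) points away from the origin
  for (f in seq_len(nrow(faces))) {
    v <- verts[faces[f, ], ]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(n * colMeans(v)) < 0) faces[f, ] <- faces[f, c(1L, 3L, 2L)]
  }

  stopifnot(nrow(verts) == 12L, nrow(edges) == 30L, nrow(faces) == 20L)
  structure(list(vertices = verts, faces = faces, edges = edges),
            class = "icosahedron")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Global symmetry axes of an icosahedron
#'
#' The icosahedral rotation group has 6 five-fold axes (through opposite
#' vertex pairs), 10 three-fold axes (through opposite face centroids) and
#' 15 two-fold axes (through opposite edge midpoints). An axis is identified
#' with its negation; directions are reported with a canonical sign (first
#' non-zero component positive).
#'
#' @param ico An [build_icosahedron()] object.
#' @return A data frame with columns `order` (5, 3 or 2) and unit direction
#'   components `x`, `y`, `z`; 31 rows.
#' @examples
#' table(symmetry_axes(build_icosahedron())$order)  # 15, 10, 6
#' @export
symmetry_axes <- function(ico) {
  if (!inherits(ico, "icosahedron")) abort_invalid("ico must be an icosahedron")
  five <- ico$vertices
  three <- t(apply(ico$faces, 1L, function(f) colMeans(ico$vertices[f, ])))
  two <- t(apply(ico$edges, 1L, function(e) colMeans(ico$vertices[e, ])))

  canon <- function(m) {
    m <- m / sqrt(rowSums(m^2))
    for (i in seq_len(nrow(m))) {
      lead <- m[i, which(abs(m[i, ]) > 1e-9)[1L]]
      if (lead < 0) m[i, ] <- -m[i, ]
    }
    m <- unique(round(m, 12L))
    m / sqrt(rowSums(m^2))   # re-normalize after the dedup rounding
  }
  five <- canon(five); three <- canon(three); two <- canon(two)
  stopifnot(nrow(five) == 6L, nrow(three) == 10L, nrow(two) == 15L)

  axes <- rbind(five, three, two)
  data.frame(order = rep(c(5L, 3L, 2L), c(6L, 10L, 15L)),
             x = axes[, 1L], y = axes[, 2L], z = axes[, 3L])
}

# Rodrigues rotation matrix about unit axis u by angle theta.
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3L, byrow = TRUE)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' The 60 rotations of the icosahedral group
#'
#' Generated explicitly from the symmetry axes: the identity, four rotations
#' about each 5-fold axis, two about each 3-fold axis and one about each
#' 2-fold axis (1 + 24 + 20 + 15 = 60).
#'
#' @param ico An [build_icosahedron()] object.
#' @return A list of 60 orthogonal 3 x 3 rotation matrices.
#' @export
icosahedral_rotations <- function(ico) {
  ax <- symmetry_axes(ico)
  rots <- list(diag(3L))
  for (i in seq_len(nrow(ax))) {
    ord <- ax$order[i]
    u <- c(ax$x[i], ax$y[i], ax$z[i])
    for (m in seq_len(ord - 1L)) {
      rots[[length(rots) + 1L]] <- rotation_about(u, 2 * pi * m / ord)
    }
  }
  stopifnot(length(rots) == 60L)
  rots
}
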