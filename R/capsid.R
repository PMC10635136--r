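# Explicit Caspar-Klug capsid lattices.
#
# Each icosahedron face carries a hexagonal net whose pentamer-to-pentamer
# vector is the axial step (h, k).  In the face's lattice frame the triangle
# has corners (0,0), (h,k) and its 60-degree rotation (-k, h+k); a lattice
# point (i, j) has scaled barycentric coordinates
#   pa = i*(h+k) + j*k,   pb = j*h - i*k       (both divided by T)
# which are integers, so face membership (0 <= pa, pb, pa+pb <= T) is exact.
# Boundary sites shared between faces are deduplicated by an exact key: the
# icosahedron vertex index for corners, or (edge, reduced fraction along the
# edge) for edge sites.  No floating-point tolerance enters the construction.

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Build a Caspar-Klug capsid lattice
#'
#' Lays the hexagonal net on each of the 20 flat faces of an icosahedron
#' (faceted embedding; sites are not projected to a sphere), deduplicates
#' sites shared between faces, and assigns each site its type: a pentamer at
#' each of the 12 icosahedron vertices, a hexamer everywhere else. A
#' `T`-capsid has exactly `12` pentamers and `10 (T - 1)` hexamers,
#' `10 T + 2` capsomers in total.
#'
#' @param step Axial step `(h, k)`; canonicalized internally (see
#'   [canonicalize_step()]).
#' @param radius Centroid-to-vertex distance, in arbitrary length units.
#'   The default 300 (read as angstroms in PDB output) corresponds to a
#'   60 nm capsid, the scale of large tailed-phage heads.
#' @param handedness `"laevo"` (default) or `"dextro"`: the two mirror-image
#'   wrappings of a chiral `(h, k)` lattice. `"dextro"` reflects the laevo
#'   lattice through the `x = 0` plane (which maps the icosahedron onto
#'   itself), leaving all counts and symmetry classes unchanged.
#' @return An object of class `capsid_lattice`: list with `step`, `T`,
#'   `radius`, `handedness`, `ico` (the scaffold icosahedron) and `sites`,
#'   a data frame with one row per capsomer: position `x`, `y`, `z`;
#'   `type` (`"pentamer"`/`"hexamer"`); `lattice_class` (exact lattice
#'   symmetry class: `"fivefold_vertex"`, `"global_threefold"`,
#'   `"global_twofold"` or `"general"`); the face index and lattice
#'   coordinates `i`, `j` of one representative copy; and the exact
#'   deduplication `key`.
#' @examples
#' cap <- build_capsid(c(2, 1))            # T = 7
#' table(cap$sites$type)                    # 60 hexamers, 12 pentamers
#' @export
build_capsid <- function(step, radius = 300, handedness = c("laevo", "dextro")) {
  handedness <- match.arg(handedness)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    abort_invalid("radius must be a single positive number")
  }
  step <- canonicalize_step(step)
  h <- step$h; k <- step$k
  T <- t_number(step)

  ico <- build_icosahedron()
  V <- ico$vertices * radius

  # one face's lattice points, in the shared per-face frame
  gg <- expand.grid(i = (-k):h, j = 0:(h + k))
  pa <- gg$i * (h + k) + gg$j * k
  pb <- gg$j * h - gg$i * k
  keep <- pa >= 0L & pb >= 0L & (pa + pb) <= T
  gi <- gg$i[keep]; gj <- gg$j[keep]
  pa <- pa[keep]; pb <- pb[keep]
  m <- length(pa)

  edge_key <- function(v1, v2, num) {
    # canonical orientation: from the lower vertex index
    if (v1 > v2) { tmp <- v1; v1 <- v2; v2 <- tmp; num <- T - num }
    g <- gcd_int(num, T)
    sprintf("E%d_%d_%d/%d", v1, v2, num %/% g, T %/% g)
  }

  chunks <- vector("list", 20L)
  for (f in seq_len(20L)) {
    va <- ico$faces[f, 1L]; vb <- ico$faces[f, 2L]; vc <- ico$faces[f, 3L]
    A <- V[va, ]; B <- V[vb, ]; C <- V[vc, ]
    al <- pa / T; be <- pb / T
    pos <- cbind(A[1] + al * (B[1] - A[1]) + be * (C[1] - A[1]),
                 A[2] + al * (B[2] - A[2]) + be * (C[2] - A[2]),
                 A[3] + al * (B[3] - A[3]) + be * (C[3] - A[3]))

    key <- character(m)
    lclass <- character(m)
    for (s in seq_len(m)) {
      a_ <- pa[s]; b_ <- pb[s]
      if (a_ == 0L && b_ == 0L)      { key[s] <- sprintf("V%d", va); lclass[s] <- "fivefold_vertex" }
      else if (a_ == T && b_ == 0L)  { key[s] <- sprintf("V%d", vb); lclass[s] <- "fivefold_vertex" }
      else if (a_ == 0L && b_ == T)  { key[s] <- sprintf("V%d", vc); lclass[s] <- "fivefold_vertex" }
      else if (b_ == 0L)             { key[s] <- edge_key(va, vb, a_); lclass[s] <- if (2L * a_ == T) "global_twofold" else "general" }
      else if (a_ == 0L)             { key[s] <- edge_key(va, vc, b_); lclass[s] <- if (2L * b_ == T) "global_twofold" else "general" }
      else if (a_ + b_ == T)         { key[s] <- edge_key(vb, vc, b_); lclass[s] <- if (2L * b_ == T) "global_twofold" else "general" }
      else if (a_ == b_ && 3L * a_ == T) { key[s] <- sprintf("F%d_%d_%d", f, gi[s], gj[s]); lclass[s] <- "global_threefold" }
      else                           { key[s] <- sprintf("F%d_%d_%d", f, gi[s], gj[s]); lclass[s] <- "general" }
    }
    chunks[[f]] <- data.frame(face = f, i = gi, j = gj, pa = pa, pb = pb,
                              x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                              key = key, lattice_class = lclass,
                              stringsAsFactors = FALSE)
  }
  all_pts <- do.call(rbind, chunks)

  first <- !duplicated(all_pts$key)
  sites <- all_pts[first, , drop = FALSE]
  site_id <- match(all_pts$key, sites$key)
  rownames(sites) <- NULL
  sites$id <- seq_len(nrow(sites))
  sites$type <- ifelse(startsWith(sites$key, "V"), "pentamer", "hexamer")

  if (handedness == "dextro") sites$x <- -sites$x

  n_pent <- sum(sites$type == "pentamer")
  n_hex <- sum(sites$type == "hexamer")
  stopifnot(n_pent == 12L, n_hex == 10L * (T - 1L), nrow(sites) == 10L * T + 2L)

  structure(
    list(step = step, T = T, radius = radius, handedness = handedness,
         ico = ico,
         sites = sites[, c("id", "key", "x", "y", "z", "type",
                           "lattice_class", "face", "i", "j", "pa", "pb")],
         face_points = data.frame(face = all_pts$face, pa = all_pts$pa,
                                  pb = all_pts$pb, site_id = site_id)),
    class = "capsid_lattice"
  )
}

#' @export
print.capsid_lattice <- function(x, ...) {
  cat(sprintf(
    "<capsid_lattice> T = %d (h = %d, k = %d), %s, radius %g\n  %d capsomers: 12 pentamers + %d hexamers\n",
    x$T, x$step$h, x$step$k, x$handedness, x$radius,
    nrow(x$sites), sum(x$sites$type == "hexamer")))
  invisible(x)
}

# --- facet mesh -------------------------------------------------------------

# Conforming triangulation of one face's lattice points in the exact integer
# (pa, pb) frame, by incremental insertion with integer orientation tests.
# Triangles are kept counter-clockwise; a point falling on an existing edge
# splits both incident triangles.  Quality is irrelevant here: the mesh is a
# topological carrier whose vertex set is the capsomer set.
triangulate_face <- function(px, py, T) {
  orient <- function(i, j, p) {
    (px[j] - px[i]) * (py[p] - py[i]) - (py[j] - py[i]) * (px[p] - px[i])
  }
  corner_of <- function(a_, b_) which(px == a_ & py == b_)[1L]
  c0 <- corner_of(0L, 0L); c1 <- corner_of(T, 0L); c2 <- corner_of(0L, T)
  stopifnot(!is.na(c0), !is.na(c1), !is.na(c2))

  tris <- list(c(c0, c1, c2))
  rest <- setdiff(order(px + py, px), c(c0, c1, c2))

  for (p in rest) {
    placed <- FALSE
    for (t in seq_along(tris)) {
      tri <- tris[[t]]
      s1 <- orient(tri[1L], tri[2L], p)
      s2 <- orient(tri[2L], tri[3L], p)
      s3 <- orient(tri[3L], tri[1L], p)
      if (s1 < 0 || s2 < 0 || s3 < 0) next
      nz <- c(s1, s2, s3) == 0
      if (sum(nz) >= 2L) stop("duplicate lattice point in face triangulation")
      if (!any(nz)) {
        tris[[t]] <- c(tri[1L], tri[2L], p)
        tris[[length(tris) + 1L]] <- c(tri[2L], tri[3L], p)
        tris[[length(tris) + 1L]] <- c(tri[3L], tri[1L], p)
      } else {
        e <- which(nz)                      # edge tri[e] -> tri[e %% 3 + 1]
        a <- tri[e]; b <- tri[e %% 3L + 1L]; c_ <- tri[(e + 1L) %% 3L + 1L]
        tris[[t]] <- c(a, p, c_)
        tris[[length(tris) + 1L]] <- c(p, b, c_)
        # neighbor across (a, b), traversing b -> a
        for (t2 in seq_along(tris)) {
          tri2 <- tris[[t2]]
          if (t2 == t || !(a %in% tri2) || !(b %in% tri2) || p %in% tri2) next
          rot <- which(tri2 == b)
          tri2 <- tri2[((rot - 1L + 0:2) %% 3L) + 1L]   # now (b, a, d)
          stopifnot(tri2[2L] == a)
          d <- tri2[3L]
          tris[[t2]] <- c(b, p, d)
          tris[[length(tris) + 1L]] <- c(p, a, d)
          break
        }
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("lattice point not located in any triangle")
  }
  do.call(rbind, tris)
}

#' Triangulated surface mesh of a faceted capsid
#'
#' Builds a closed, outward-wound triangle mesh of the faceted capsid whose
#' vertices are exactly the capsomer sites. Each face is triangulated over
#' its lattice points with exact integer predicates; shared boundary vertices
#' carry the same global index on both sides, so the glued mesh is a closed
#' 2-manifold (Euler characteristic 2).
#'
#' @param capsid A [build_capsid()] object.
#' @return A list of class `facet_mesh` with `vertices` (`n x 3` matrix,
#'   row order matching `capsid$sites`) and `faces` (`m x 3` matrix of
#'   1-based vertex indices, counter-clockwise seen from outside).
#' @examples
#' mesh <- facet_mesh(build_capsid(c(1, 1), radius = 100))
#' nrow(mesh$vertices)  # 32 capsomers for T = 3
#' @export
facet_mesh <- function(capsid) {
  if (!inherits(capsid, "capsid_lattice")) abort_invalid("capsid must be a capsid_lattice")
  fp <- capsid$face_points
  tris <- vector("list", 20L)
  for (f in seq_len(20L)) {
    sel <- fp$face == f
    local <- triangulate_face(fp$pa[sel], fp$pb[sel], capsid$T)
    ids <- fp$site_id[sel]
    tris[[f]] <- matrix(ids[local], ncol = 3L)
  }
  faces <- do.call(rbind, tris)
  if (capsid$handedness == "dextro") faces <- faces[, c(1L, 3L, 2L)]
  structure(list(vertices = as.matrix(capsid$sites[, c("x", "y", "z")]),
                 faces = faces),
            class = "facet_mesh")
}
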