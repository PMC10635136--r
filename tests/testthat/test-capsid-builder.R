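test_that("the icosahedron scaffold is regular and correctly oriented", {
  ico <- build_icosahedron()
  expect_identical(dim(ico$vertices), c(12L, 3L))
  expect_identical(nrow(ico$faces), 20L)
  expect_identical(nrow(ico$edges), 30L)
  expect_identical(12L - 30L + 20L, 2L)   # Euler characteristic

  expect_equal(rowSums(ico$vertices^2), rep(1, 12), tolerance = 1e-12)

  lens <- apply(ico$edges, 1L, function(e) {
    sqrt(sum((ico$vertices[e[1], ] - ico$vertices[e[2], ])^2))
  })
  expect_lt(diff(range(lens)) / mean(lens), 1e-9)

  # outward winding of every face
  for (f in seq_len(20L)) {
    v <- ico$vertices[ico$faces[f, ], ]
    n <- c(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nrm <- c(n[2] * n[6] - n[3] * n[5], n[3] * n[4] - n[1] * n[6],
             n[1] * n[5] - n[2] * n[4])
    expect_gt(sum(nrm * colMeans(v)), 0)
  }

  # orientation convention: 180-degree rotations about coordinate axes are
  # symmetries of the vertex set
  for (ax in 1:3) {
    R <- diag(c(-1, -1, -1)); R[ax, ax] <- 1
    expect_lt(set_distance(ico$vertices %*% R, ico$vertices), 1e-9)
  }
})

test_that("symmetry_axes yields 6 five-fold, 10 three-fold, 15 two-fold axes", {
  ico <- build_icosahedron()
  ax <- symmetry_axes(ico)
  expect_identical(unname(c(table(ax$order))), c(15L, 10L, 6L))
  expect_equal(rowSums(as.matrix(ax[, c("x", "y", "z")])^2), rep(1, 31),
               tolerance = 1e-9)

  # each 3-fold axis is parallel to a face centroid
  three <- as.matrix(ax[ax$order == 3L, c("x", "y", "z")])
  cents <- t(apply(ico$faces, 1L, function(f) colMeans(ico$vertices[f, ])))
  cents <- cents / sqrt(rowSums(cents^2))
  cosines <- abs(three %*% t(cents))
  expect_true(all(apply(cosines, 1L, max) > 1 - 1e-9))

  # a 2*pi/5 turn about any 5-fold axis maps the vertex set to itself
  five <- as.matrix(ax[ax$order == 5L, c("x", "y", "z")])
  for (i in seq_len(nrow(five))) {
    R <- capsidlattice:::rotation_about(five[i, ], 2 * pi / 5)
    expect_lt(set_distance(ico$vertices %*% t(R), ico$vertices), 1e-9)
  }
})

test_that("built capsids have 12 pentamers and 10(T-1) hexamers for all T <= 52", {
  for (rec in enumerate_t_numbers(52)) {
    cap <- build_capsid(rec$representations[[1]], radius = 300)
    expect_identical(cap$T, rec$T)
    expect_identical(sum(cap$sites$type == "pentamer"), 12L)
    expect_identical(sum(cap$sites$type == "hexamer"), 10L * (rec$T - 1L))
    expect_identical(nrow(cap$sites), 10L * rec$T + 2L)
  }
  expect_error(build_capsid(c(0, 0)), class = "capsid_invalid_input")
  expect_error(build_capsid(c(2, 1), radius = -1), class = "capsid_invalid_input")
})

test_that("pentamers sit exactly at icosahedron vertices", {
  cap <- build_capsid(c(2, 1), radius = 150)
  pent <- as.matrix(cap$sites[cap$sites$type == "pentamer", c("x", "y", "z")])
  expect_identical(nrow(pent), 12L)
  expect_lt(set_distance(pent, cap$ico$vertices * cap$radius), 1e-9 * cap$radius)
})

test_that("the site set is invariant under all 60 icosahedral rotations", {
  for (step in list(c(2, 1), c(2, 2))) {
    cap <- build_capsid(step, radius = 300)
    P <- as.matrix(cap$sites[, c("x", "y", "z")])
    for (R in icosahedral_rotations(cap$ico)) {
      expect_lt(set_distance(P %*% t(R), P), 1e-6 * cap$radius)
    }
  }
})

test_that("handedness swap mirrors the site set and preserves all counts", {
  laevo <- build_capsid(c(2, 1), radius = 300, handedness = "laevo")
  dextro <- build_capsid(c(2, 1), radius = 300, handedness = "dextro")
  PL <- as.matrix(laevo$sites[, c("x", "y", "z")])
  PD <- as.matrix(dextro$sites[, c("x", "y", "z")])
  mirror <- PL %*% diag(c(-1, 1, 1))
  expect_lt(set_distance(mirror, PD), 1e-9 * laevo$radius)
  expect_identical(table(laevo$sites$type), table(dextro$sites$type))
  expect_identical(table(laevo$sites$lattice_class),
                   table(dextro$sites$lattice_class))
  # a chiral lattice is NOT superimposable on its mirror image
  expect_gt(set_distance(PL, PD), 0.01 * laevo$radius)
})

test_that("minimum site spacing is positive and scales as radius/sqrt(T)", {
  for (step in list(c(1, 0), c(2, 1), c(2, 2), c(4, 3), c(7, 0))) {
    cap <- build_capsid(step, radius = 300)
    mind <- min(stats::dist(as.matrix(cap$sites[, c("x", "y", "z")])))
    scaled <- mind * sqrt(cap$T) / cap$radius
    expect_gt(scaled, 0.9)
    expect_lt(scaled, 1.1)
  }
})

test_that("facet_mesh is a closed outward mesh over the capsomer set", {
  for (step in list(c(1, 0), c(2, 1), c(2, 2))) {
    cap <- build_capsid(step, radius = 200)
    mesh <- facet_mesh(cap)
    expect_identical(nrow(mesh$vertices), nrow(cap$sites))
    expect_identical(nrow(mesh$faces), 20L * cap$T)
    expect_identical(euler_characteristic(mesh), 2L)

    # outward winding: every triangle normal points away from the centroid
    for (r in seq_len(nrow(mesh$faces))) {
      v <- mesh$vertices[mesh$faces[r, ], ]
      n <- c((v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
             (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
             (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
      expect_gt(sum(n * colMeans(v)), 0)
    }

    # closed manifold: every edge borders exactly two triangles
    ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
    ed <- apply(ed, 1L, function(e) paste(sort(e), collapse = "-"))
    expect_true(all(table(ed) == 2L))
  }
})
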