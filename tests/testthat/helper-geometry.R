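# Independent geometric helpers used as oracles. They deliberately avoid the
# package's own lattice arithmetic: steps are converted to 2D cartesian
# coordinates and transformed with explicit rotation/reflection matrices.

# hexagonal basis vectors, 60 degrees apart
hex_to_cart <- function(h, k) {
  c(h + k / 2, k * sqrt(3) / 2)
}

cart_to_hex <- function(p) {
  k <- p[2] * 2 / sqrt(3)
  h <- p[1] - k / 2
  round(c(h, k))
}

# The 12 point-group images of a step: rotate the step and its mirror image
# (reflection across the first basis vector) by multiples of 60 degrees,
# all in explicit 2D cartesian arithmetic.
independent_images <- function(h, k) {
  seeds <- list(hex_to_cart(h, k), hex_to_cart(h, k) * c(1, -1))
  out <- matrix(NA_integer_, 0L, 2L)
  for (p in seeds) {
    for (m in 0:5) {
      th <- m * pi / 3
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, byrow = TRUE)
      out <- rbind(out, cart_to_hex(R %*% p))
    }
  }
  unique(out)
}

euler_characteristic <- function(mesh) {
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  ed <- unique(t(apply(ed, 1L, sort)))
  nrow(mesh$vertices) - nrow(ed) + nrow(mesh$faces)
}

# Largest nearest-neighbor gap between two point sets (both directions).
# The fast squared-distance matrix only nominates the nearest neighbor; the
# reported distance is recomputed from the coordinate difference, which stays
# accurate when the quadratic form cancels.
set_distance <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  nnP <- apply(d2, 1L, which.min)
  nnQ <- apply(d2, 2L, which.min)
  max(sqrt(rowSums((P - Q[nnP, , drop = FALSE])^2)),
      sqrt(rowSums((Q - P[nnQ, , drop = FALSE])^2)))
}

# all canonical steps (h >= k >= 0, not both zero) with T <= t_max
canonical_steps_upto <- function(t_max) {
  out <- list()
  for (h in 0:ceiling(sqrt(t_max))) {
    for (k in 0:h) {
      if (h == 0 && k == 0) next
      if (h^2 + h * k + k^2 <= t_max) out[[length(out) + 1L]] <- c(h, k)
    }
  }
  out
}
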