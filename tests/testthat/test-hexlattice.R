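test_that("t_number evaluates the Diophantine equation and rejects the zero step", {
  expect_identical(t_number(c(2, 2)), 12L)
  expect_identical(t_number(c(1, 0)), 1L)
  expect_identical(t_number(c(2, 1)), 7L)
  expect_identical(t_number(axial_step(-1, 2)), 3L)
  expect_error(t_number(c(0, 0)), class = "capsid_invalid_input")
  expect_error(axial_step(1.5, 0), class = "capsid_invalid_input")
})

test_that("t_number is invariant under the 12 hexagonal point-group images", {
  for (s in canonical_steps_upto(300)) {
    imgs <- independent_images(s[1], s[2])
    expect_true(nrow(imgs) %in% c(1L, 2L, 3L, 6L, 12L))
    for (r in seq_len(nrow(imgs))) {
      expect_identical(t_number(imgs[r, ]), t_number(s))
    }
  }
})

test_that("canonicalize_step picks the unique h >= k >= 0 representative", {
  expect_identical(unclass(canonicalize_step(c(2, -1))), list(h = 1L, k = 1L))
  expect_identical(unclass(canonicalize_step(c(1, 1))), list(h = 1L, k = 1L))
  expect_identical(unclass(canonicalize_step(c(0, 3))), list(h = 3L, k = 0L))
  expect_error(canonicalize_step(c(0, 0)), class = "capsid_invalid_input")

  # every point-group image of a step canonicalizes to the same representative
  for (s in canonical_steps_upto(100)) {
    imgs <- independent_images(s[1], s[2])
    for (r in seq_len(nrow(imgs))) {
      can <- canonicalize_step(imgs[r, ])
      expect_identical(c(can$h, can$k), c(s[1], s[2]))
    }
  }
})

test_that("enumerate_t_numbers agrees with an independent brute-force sieve", {
  # oracle: an integer t is a T-number iff some (h, k) pair realizes it
  sieve <- function(t_max) {
    hit <- logical(t_max)
    for (h in 0:ceiling(sqrt(t_max))) {
      for (k in 0:ceiling(sqrt(t_max))) {
        t <- h^2 + h * k + k^2
        if (t >= 1 && t <= t_max) hit[t] <- TRUE
      }
    }
    which(hit)
  }
  recs <- enumerate_t_numbers(300)
  expect_identical(vapply(recs, `[[`, integer(1), "T"), sieve(300))

  recs52 <- enumerate_t_numbers(52)
  expect_length(recs52, 21L)
  expect_identical(vapply(recs52, `[[`, integer(1), "T"),
                   c(1L, 3L, 4L, 7L, 9L, 12L, 13L, 16L, 19L, 21L, 25L, 27L,
                     28L, 31L, 36L, 37L, 39L, 43L, 48L, 49L, 52L))

  expect_length(enumerate_t_numbers(1), 1L)
  expect_error(enumerate_t_numbers(0), class = "capsid_invalid_input")
})

test_that("T = 49 carries two inequivalent lattice representations in one record", {
  rec49 <- Filter(function(r) r$T == 49L, enumerate_t_numbers(52))[[1]]
  reps <- vapply(rec49$representations, function(s) sprintf("%d,%d", s$h, s$k), "")
  expect_identical(reps, c("5,3", "7,0"))
})

test_that("predict_centered_hexamer is T %% 3 and rejects non-T-numbers", {
  for (T in c(3, 9, 12, 21, 27, 36, 39, 48)) expect_true(predict_centered_hexamer(T))
  for (T in c(4, 7, 13, 16, 19, 25, 28, 31, 37, 43, 49, 52)) {
    expect_false(predict_centered_hexamer(T))
  }
  for (bad in c(2, 5, 6, 10)) {
    expect_error(predict_centered_hexamer(bad), class = "capsid_not_t_number")
  }
})

test_that("centroid_steps finds the face-centroid sublattice point", {
  cs <- centroid_steps(c(2, 2))
  expect_identical(c(cs$hH, cs$kH), c(0L, 2L))
  cs <- centroid_steps(c(3, 0))
  expect_identical(c(cs$hH, cs$kH), c(1L, 1L))
  expect_error(centroid_steps(c(2, 1)), class = "capsid_no_centered_hexamer")

  # geometric oracle: (hH, kH) must land exactly on the centroid of the
  # triangle spanned by (h, k) and its 60-degree rotation, in 2D cartesian
  for (s in canonical_steps_upto(300)) {
    if (t_number(s) %% 3L != 0L) next
    cs <- centroid_steps(s)
    p1 <- hex_to_cart(s[1], s[2])
    R60 <- matrix(c(cos(pi / 3), -sin(pi / 3), sin(pi / 3), cos(pi / 3)), 2L, byrow = TRUE)
    centroid <- (p1 + as.numeric(R60 %*% p1)) / 3
    expect_equal(hex_to_cart(cs$hH, cs$kH), centroid, tolerance = 1e-12)
    expect_identical(3L * t_number(c(cs$hH, cs$kH)), t_number(s))
  }
})

test_that("centroid steps exist exactly when h == k (mod 3), i.e. 3 | T", {
  for (s in canonical_steps_upto(300)) {
    mod_ok <- (s[1] - s[2]) %% 3L == 0L
    expect_identical(mod_ok, t_number(s) %% 3L == 0L)
    if (mod_ok) {
      expect_s3_class(centroid_steps(s), "centroid_steps")
    } else {
      expect_error(centroid_steps(s), class = "capsid_no_centered_hexamer")
    }
  }
})

test_that("expand_by_three triples T and round-trips with centroid_steps", {
  e <- expand_by_three(c(1, 0))
  expect_identical(c(e$h, e$k), c(1L, 1L))
  e <- expand_by_three(c(1, 1))
  expect_identical(c(e$h, e$k), c(3L, 0L))
  expect_identical(t_number(expand_by_three(c(2, 0))), 12L)
  expect_error(expand_by_three(c(0, 0)), class = "capsid_invalid_input")

  for (s in canonical_steps_upto(300)) {
    up <- expand_by_three(s)
    expect_identical(t_number(up), 3L * t_number(s))
    # down again: centroid steps of the expanded capsid recover the step
    cs <- centroid_steps(up)
    back <- canonicalize_step(c(cs$hH, cs$kH))
    expect_identical(c(back$h, back$k), c(s[1], s[2]))
  }
})
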