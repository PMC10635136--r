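# Exact integer arithmetic on the hexagonal lattice underlying the
# Caspar-Klug construction.  An axial step (h, k) counts lattice steps along
# two hexagonal basis directions 60 degrees apart; the triangulation number
# T = h^2 + h*k + k^2 gives the capsid size class.

#' Axial lattice step
#'
#' Create an axial step `(h, k)` on the hexagonal lattice: the integer number
#' of steps along the two hexagonal basis directions (60 degrees apart) needed
#' to walk from one pentamer to a nearby pentamer of the capsid lattice.
#'
#' @param h,k Integer lattice steps. May be negative (the twelve hexagonal
#'   point-group images of a step all describe the same capsid), but
#'   `(0, 0)` is rejected wherever a step defines a capsid.
#' @return An object of class `axial_step` with fields `h` and `k`.
#' @examples
#' axial_step(2, 1)   # the T = 7 step
#' @seealso [t_number()], [canonicalize_step()]
#' @export
axial_step <- function(h, k) {
  if (length(h) != 1L || length(k) != 1L || is.na(h) || is.na(k) ||
      h != round(h) || k != round(k)) {
    abort_invalid("h and k must be single integers")
  }
  structure(list(h = as.integer(h), k = as.integer(k)), class = "axial_step")
}

#' @export
print.axial_step <- function(x, ...) {
  cat(sprintf("<axial_step> (h = %d, k = %d), T = %d\n", x$h, x$k,
              x$h^2 + x$h * x$k + x$k^2))
  invisible(x)
}

as_axial_step <- function(step) {
  if (inherits(step, "axial_step")) return(step)
  if (is.numeric(step) && length(step) == 2L) return(axial_step(step[1L], step[2L]))
  abort_invalid("step must be an axial_step or a numeric vector c(h, k)")
}

check_nonzero <- function(step) {
  if (step$h == 0L && step$k == 0L) {
    abort_invalid("the zero step (0, 0) does not define a capsid")
  }
  step
}

# The 12 point-group images of a step: six 60-degree rotations
# (h, k) -> (-k, h + k) and their reflections (h, k) -> (k, h).
# All preserve T.
hex_images <- function(step) {
  step <- as_axial_step(step)
  imgs <- matrix(NA_integer_, nrow = 12L, ncol = 2L)
  p <- c(step$h, step$k)
  q <- c(step$k, step$h)
  for (n in 1:6) {
    imgs[n, ] <- p
    imgs[n + 6L, ] <- q
    p <- c(-p[2L], p[1L] + p[2L])
    q <- c(-q[2L], q[1L] + q[2L])
  }
  unique(imgs)
}

#' Triangulation number of a step
#'
#' Evaluates `T(h, k) = h^2 + h*k + k^2`, the Diophantine equation classifying
#' icosahedral capsid lattices. A `T`-capsid is built from `60 T` major capsid
#' proteins arranged in 12 pentamers and `10 (T - 1)` hexamers.
#'
#' @param step An [axial_step()] or numeric `c(h, k)`; must not be `(0, 0)`.
#' @return A positive integer, invariant under the twelve hexagonal
#'   point-group images of `step`.
#' @examples
#' t_number(c(2, 2))  # 12
#' t_number(c(2, 1))  # 7
#' @export
t_number <- function(step) {
  step <- check_nonzero(as_axial_step(step))
  as.integer(step$h^2 + step$h * step$k + step$k^2)
}

#' Canonical form of an axial step
#'
#' Among the twelve hexagonal point-group images of a step (six rotations by
#' 60 degrees and their mirror images), exactly one satisfies `h >= k >= 0`;
#' that representative is returned. Canonicalization identifies the two
#' enantiomers `(h, k)` and `(k, h)`: a chiral capsid and its mirror image
#' share one canonical step (handedness is carried separately, see
#' [build_capsid()]).
#'
#' @inheritParams t_number
#' @return An [axial_step()] with `h >= k >= 0` and the same triangulation
#'   number.
#' @examples
#' canonicalize_step(c(2, -1))  # (1, 1), T = 3
#' canonicalize_step(c(0, 3))   # (3, 0)
#' @export
canonicalize_step <- function(step) {
  step <- check_nonzero(as_axial_step(step))
  imgs <- hex_images(step)
  ok <- imgs[, 1L] >= imgs[, 2L] & imgs[, 2L] >= 0L
  hit <- imgs[ok, , drop = FALSE]
  hit <- unique(hit)
  stopifnot(nrow(hit) == 1L)  # uniqueness of the canonical representative
  axial_step(hit[1L, 1L], hit[1L, 2L])
}

is_canonical <- function(step) {
  step <- as_axial_step(step)
  step$h >= step$k && step$k >= 0L
}

#' Test whether an integer is a triangulation number
#'
#' Exhaustive search over `0 <= k <= h <= ceiling(sqrt(T))`; no
#' number-theoretic shortcut is used.
#'
#' @param T A single positive integer.
#' @return `TRUE` if some step `(h, k)` satisfies `h^2 + h*k + k^2 == T`.
#' @examples
#' is_t_number(7)  # TRUE
#' is_t_number(6)  # FALSE
#' @export
is_t_number <- function(T) {
  if (length(T) != 1L || is.na(T) || T != round(T) || T < 1) {
    abort_invalid("T must be a single positive integer")
  }
  length(representations_of(as.integer(T))) > 0L
}

# All canonical steps with the given T, sorted by (h, k).
representations_of <- function(T) {
  hmax <- as.integer(ceiling(sqrt(T)))
  reps <- list()
  for (h in 0:hmax) {
    for (k in 0:h) {
      if (h == 0L && k == 0L) next
      if (h * h + h * k + k * k == T) reps[[length(reps) + 1L]] <- axial_step(h, k)
    }
  }
  if (length(reps) > 1L) {
    ord <- order(vapply(reps, `[[`, integer(1), "h"),
                 vapply(reps, `[[`, integer(1), "k"))
    reps <- reps[ord]
  }
  reps
}

#' Enumerate all triangulation numbers up to a bound
#'
#' Scans all canonical steps with `T(h, k) <= t_max` and returns one record
#' per distinct triangulation number. A `T` with several inequivalent lattice
#' representations (the first is `T = 49`, realized by both `(7, 0)` and
#' `(5, 3)`) yields a single record listing all of them.
#'
#' @param t_max Upper bound on `T` (at least 1).
#' @return A list of records of class `t_number_record`, sorted by `T`. Each
#'   record has fields `T`, `representations` (a list of canonical
#'   [axial_step()]s) and `centered_hexamer_predicted`
#'   (`TRUE` iff `T %% 3 == 0`; see [predict_centered_hexamer()]).
#' @examples
#' length(enumerate_t_numbers(52))  # 21 distinct T-numbers
#' @export
enumerate_t_numbers <- function(t_max) {
  if (length(t_max) != 1L || is.na(t_max) || t_max < 1 || t_max != round(t_max)) {
    abort_invalid("t_max must be a single integer >= 1")
  }
  t_max <- as.integer(t_max)
  hmax <- as.integer(ceiling(sqrt(t_max)))
  found <- new.env(parent = emptyenv())
  for (h in 0:hmax) {
    for (k in 0:h) {
      if (h == 0L && k == 0L) next
      T <- h * h + h * k + k * k
      if (T > t_max) next
      key <- as.character(T)
      cur <- if (is.null(found[[key]])) list() else found[[key]]
      found[[key]] <- c(cur, list(axial_step(h, k)))
    }
  }
  ts <- sort(as.integer(ls(found)))
  lapply(ts, function(T) {
    reps <- found[[as.character(T)]]
    ord <- order(vapply(reps, `[[`, integer(1), "h"),
                 vapply(reps, `[[`, integer(1), "k"))
    structure(
      list(T = T, representations = reps[ord],
           centered_hexamer_predicted = (T %% 3L == 0L)),
      class = "t_number_record"
    )
  })
}

#' @export
print.t_number_record <- function(x, ...) {
  reps <- vapply(x$representations, function(s) sprintf("(%d,%d)", s$h, s$k), "")
  cat(sprintf("<t_number_record> T = %d [%s] centered hexamer: %s\n",
              x$T, paste(reps, collapse = ", "),
              if (x$centered_hexamer_predicted) "yes" else "no"))
  invisible(x)
}

#' Arithmetic prediction of a centered hexamer
#'
#' An icosahedral capsid has a hexamer whose center lies on a global 3-fold
#' axis (a face centroid of the icosahedron) if and only if its triangulation
#' number is a multiple of three. This is the lattice-arithmetic route; the
#' independent geometric route is [has_centered_hexamer()].
#'
#' @param T A triangulation number (an error is raised for integers such as
#'   2, 5 or 6 that no step realizes).
#' @return `TRUE` iff `T %% 3 == 0`.
#' @examples
#' predict_centered_hexamer(9)   # TRUE
#' predict_centered_hexamer(7)   # FALSE
#' @export
predict_centered_hexamer <- function(T) {
  if (!is_t_number(T)) abort_not_t_number(T)
  as.integer(T) %% 3L == 0L
}

#' Steps from a pentamer to the centered hexamer
#'
#' For a capsid whose `T` is divisible by three, the hexamer sitting on a
#' global 3-fold axis occupies the centroid of the triangle spanned by three
#' neighboring pentamers. This returns the lattice steps `(hH, kH)` joining a
#' pentamer to that centroid: `((h - k)/3, (h + 2k)/3)`, which are integers
#' exactly when `h == k (mod 3)`, a condition equivalent to `3 | T`. The
#' result satisfies `3 * t_number(c(hH, kH)) == t_number(step)`.
#'
#' @param step A canonical [axial_step()] (non-canonical input is
#'   canonicalized first) whose triangulation number is divisible by 3.
#' @return An object of class `centroid_steps` with fields `hH`, `kH`, and
#'   `T` (the parent triangulation number).
#' @examples
#' centroid_steps(c(2, 2))  # (0, 2): 3 * T(0,2) = 12
#' centroid_steps(c(3, 0))  # (1, 1): 3 * T(1,1) = 9
#' @seealso [expand_by_three()] for the inverse transformation.
#' @export
centroid_steps <- function(step) {
  step <- canonicalize_step(step)
  T <- t_number(step)
  if (T %% 3L != 0L) abort_no_centered_hexamer(T)
  stopifnot((step$h - step$k) %% 3L == 0L)  # h == k (mod 3) <=> 3 | T
  hH <- (step$h - step$k) %/% 3L
  kH <- (step$h + 2L * step$k) %/% 3L
  stopifnot(3L * (hH^2 + hH * kH + kH^2) == T)
  structure(list(hH = hH, kH = kH, T = T), class = "centroid_steps")
}

#' @export
print.centroid_steps <- function(x, ...) {
  cat(sprintf("<centroid_steps> (hH = %d, kH = %d) for T = %d = 3 x %d\n",
              x$hH, x$kH, x$T, x$T %/% 3L))
  invisible(x)
}

#' Expand a step to triple its triangulation number
#'
#' Maps a step `(h, k)` to a canonical step realizing `3 * T(h, k)`: tripling
#' any triangulation number yields another triangulation number, namely one
#' whose capsid carries hexamers centered on the global 3-fold axes
#' (T = 1 leads to T = 3, T = 3 to T = 9, T = 4 to T = 12, ...). The
#' transformation applied is `(h, k) -> (2h + k, k - h)` followed by
#' canonicalization; it is the inverse of [centroid_steps()] up to
#' canonical form.
#'
#' @inheritParams t_number
#' @return A canonical [axial_step()] with `t_number` equal to
#'   `3 * t_number(step)`.
#' @examples
#' expand_by_three(c(1, 0))  # (1, 1), T = 3
#' expand_by_three(c(1, 1))  # (3, 0), T = 9
#' @export
expand_by_three <- function(step) {
  step <- check_nonzero(as_axial_step(step))
  out <- canonicalize_step(c(2L * step$h + step$k, step$k - step$h))
  stopifnot(t_number(out) == 3L * t_number(step))
  out
}
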