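# Classification of capsomer sites against the 31 global icosahedral
# symmetry axes, by two deliberately independent routes:
#
#   * geometric: 3D point-to-axis distance, knowing nothing about (h, k);
#   * exact lattice: integer predicates recorded at construction time
#     (vertex corner; face centroid, which exists iff h == k mod 3;
#     edge midpoint, which exists iff h and k are both even).
#
# Their site-by-site agreement is the brute-force check of the theorem that
# a hexamer sits on a true 3-fold axis iff 3 | T.

#' Classify capsomer sites against the global symmetry axes
#'
#' Assigns each site the highest-order global icosahedral axis (5 > 3 > 2)
#' whose line passes within `tol * radius` of the site center, purely from
#' 3D geometry. The exact lattice classification stored by [build_capsid()]
#' is returned alongside for cross-checking; the two must agree site by site
#' (any disagreement indicates a construction bug and is treated as a test
#' failure, not a warning).
#'
#' @param capsid A [build_capsid()] object.
#' @param tol Relative tolerance (fraction of the radius) for the
#'   point-on-axis decision. The default `1e-6` cleanly separates floating
#'   rounding (below `1e-12` of the radius in the faceted construction) from
#'   genuine off-axis offsets (above `1e-2` of the radius for any `T` up to
#'   a few hundred).
#' @return A data frame with one row per site: `id`, `type`,
#'   `on_axis_order` (geometric; 0, 2, 3 or 5),
#'   `lattice_order` (from the exact lattice predicates),
#'   `distance_to_nearest_axis` (absolute length), and `agree`.
#' @examples
#' cls <- classify_sites(build_capsid(c(2, 2)))   # T = 12
#' sum(cls$on_axis_order == 3)                     # 20 centered hexamers
#' @export
classify_sites <- function(capsid, tol = 1e-6) {
  if (!inherits(capsid, "capsid_lattice")) abort_invalid("capsid must be a capsid_lattice")
  if (length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    abort_invalid("tol must be a single positive number")
  }
  ax <- symmetry_axes(capsid$ico)
  U <- as.matrix(ax[, c("x", "y", "z")])
  P <- as.matrix(capsid$sites[, c("x", "y", "z")])

  # n_sites x 31 point-to-axis distances, via the explicit perpendicular
  # component (numerically stable where |p| and the axial projection cancel)
  d <- matrix(0, nrow(P), nrow(U))
  for (a in seq_len(nrow(U))) {
    u <- U[a, ]
    w <- P - (P %*% u) %*% t(u)
    d[, a] <- sqrt(rowSums(w^2))
  }

  hit <- d < tol * capsid$radius
  on5 <- rowSums(hit[, ax$order == 5L, drop = FALSE]) > 0L
  on3 <- rowSums(hit[, ax$order == 3L, drop = FALSE]) > 0L
  on2 <- rowSums(hit[, ax$order == 2L, drop = FALSE]) > 0L
  geo <- ifelse(on5, 5L, ifelse(on3, 3L, ifelse(on2, 2L, 0L)))

  lat <- c(fivefold_vertex = 5L, global_threefold = 3L,
           global_twofold = 2L, general = 0L)[capsid$sites$lattice_class]

  data.frame(id = capsid$sites$id,
             type = capsid$sites$type,
             on_axis_order = geo,
             lattice_order = unname(lat),
             distance_to_nearest_axis = apply(d, 1L, min),
             agree = geo == unname(lat))
}

#' Geometric test for a centered hexamer
#'
#' `TRUE` iff at least one hexamer center lies on a global 3-fold axis. This
#' is the purely geometric route: it classifies the built 3D lattice and
#' never consults `T %% 3`, so it can serve as the independent oracle for
#' [predict_centered_hexamer()].
#'
#' @inheritParams classify_sites
#' @return Logical scalar.
#' @examples
#' has_centered_hexamer(build_capsid(c(2, 2)))  # TRUE  (T = 12)
#' has_centered_hexamer(build_capsid(c(2, 1)))  # FALSE (T = 7)
#' @export
has_centered_hexamer <- function(capsid, tol = 1e-6) {
  cls <- classify_sites(capsid, tol)
  any(cls$type == "hexamer" & cls$on_axis_order == 3L)
}

#' Can the capsid be built from all split/skew hexamers?
#'
#' Split and skew hexamers retain only 2-fold symmetry, which is compatible
#' with a global 2-fold axis but clashes with a global 3-fold axis. A capsid
#' can therefore be formed entirely from split/skew hexamers iff it has at
#' least one hexamer and none of them is centered on a global 3-fold axis
#' (equivalently, iff `T > 1` and `T` is not a multiple of three).
#'
#' @inheritParams classify_sites
#' @return Logical scalar; `FALSE` (vacuously) for the hexamer-free `T = 1`.
#' @examples
#' all_skew_compatible(build_capsid(c(2, 1)))  # TRUE, T = 7
#' all_skew_compatible(build_capsid(c(1, 1)))  # FALSE, T = 3
#' @export
all_skew_compatible <- function(capsid, tol = 1e-6) {
  has_hex <- any(capsid$sites$type == "hexamer")
  has_hex && !has_centered_hexamer(capsid, tol)
}

#' Survey capsid architectures up to a T-number bound
#'
#' Builds every distinct `T <= t_max` capsid (one per triangulation number;
#' inequivalent representations share a row), classifies all sites, and
#' tabulates which architectures carry a hexamer centered on a 3-fold axis
#' and which can be formed from all split/skew hexamers. The hexamer-free
#' `T = 1` appears as a row but is excluded from both summary counts.
#'
#' @param t_max Upper bound on `T` (at least 1).
#' @param radius,tol Passed to [build_capsid()] and [classify_sites()].
#' @return A data frame of class `survey_report`, one row per distinct `T`,
#'   with columns `T`, `h`, `k` (first canonical representation),
#'   `representations` (all of them, semicolon-separated), `has_hexamers`,
#'   `centered_hexamer_geometric`, `centered_hexamer_predicted`,
#'   `n_pentamers`, `n_hexamers`, `n_hex_on_3fold`, `n_hex_on_2fold`,
#'   `all_skew_compatible`. The summary counts are stored in
#'   `attr(x, "summary")`: `n_centered`, `n_all_skew`, `centered_t`,
#'   `all_skew_t`.
#' @examples
#' rep52 <- survey(52)
#' attr(rep52, "summary")$n_centered   # 8
#' attr(rep52, "summary")$n_all_skew   # 12
#' @export
survey <- function(t_max, radius = 300, tol = 1e-6) {
  recs <- enumerate_t_numbers(t_max)
  rows <- lapply(recs, function(rec) {
    cap <- build_capsid(rec$representations[[1L]], radius = radius)
    cls <- classify_sites(cap, tol)
    hex <- cls$type == "hexamer"
    data.frame(
      T = rec$T,
      h = rec$representations[[1L]]$h,
      k = rec$representations[[1L]]$k,
      representations = paste(vapply(rec$representations,
                                     function(s) sprintf("(%d,%d)", s$h, s$k), ""),
                              collapse = ";"),
      has_hexamers = any(hex),
      centered_hexamer_geometric = any(hex & cls$on_axis_order == 3L),
      centered_hexamer_predicted = rec$centered_hexamer_predicted,
      n_pentamers = sum(cls$type == "pentamer"),
      n_hexamers = sum(hex),
      n_hex_on_3fold = sum(hex & cls$on_axis_order == 3L),
      n_hex_on_2fold = sum(hex & cls$on_axis_order == 2L),
      all_skew_compatible = any(hex) && !any(hex & cls$on_axis_order == 3L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    t_max = as.integer(t_max),
    n_capsids_with_hexamers = sum(out$has_hexamers),
    n_centered = sum(out$has_hexamers & out$centered_hexamer_geometric),
    n_all_skew = sum(out$all_skew_compatible),
    centered_t = out$T[out$has_hexamers & out$centered_hexamer_geometric],
    all_skew_t = out$T[out$all_skew_compatible]
  )
  class(out) <- c("survey_report", "data.frame")
  out
}

#' @export
print.survey_report <- function(x, ...) {
  s <- attr(x, "summary")
  NextMethod()
  cat(sprintf(
    "\nSurvey T <= %d: %d hexamer-bearing architectures; %d with a centered hexamer {%s}; %d all-skew compatible {%s}\n",
    s$t_max, s$n_capsids_with_hexamers,
    s$n_centered, paste(s$centered_t, collapse = ","),
    s$n_all_skew, paste(s$all_skew_t, collapse = ",")))
  invisible(x)
}

#' Verify the centered-hexamer theorem by brute force
#'
#' For every distinct triangulation number up to `t_max`, builds the capsid,
#' runs the geometric centered-hexamer oracle, and compares it with the
#' arithmetic prediction `T %% 3 == 0`.
#'
#' @inheritParams survey
#' @return A data frame with columns `T`, `centered_geometric`,
#'   `centered_predicted`, `agree`; `attr(x, "all_agree")` is the overall
#'   verdict.
#' @examples
#' v <- verify_theorem(52)
#' attr(v, "all_agree")  # TRUE
#' @export
verify_theorem <- function(t_max, radius = 300, tol = 1e-6) {
  rep <- survey(t_max, radius = radius, tol = tol)
  out <- data.frame(T = rep$T,
                    centered_geometric = rep$centered_hexamer_geometric,
                    centered_predicted = rep$centered_hexamer_predicted)
  out$agree <- out$centered_geometric == out$centered_predicted
  attr(out, "all_agree") <- all(out$agree)
  out
}
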