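# File writers: survey CSV/JSON, pseudo-atom PDB, OBJ mesh, ChimeraX-style
# marker scripts.  All outputs are deterministic (no timestamps): identical
# inputs give byte-identical files.

#' Reference survey classification for T <= 52
#'
#' The frozen reference partition of the `T <= 52` survey, used as a
#' regression fixture: the eight architectures with a hexamer centered on a
#' global 3-fold axis, the twelve compatible with all split/skew hexamers,
#' and the survey bound. Together with the hexamer-free `T = 1` these cover
#' all 21 triangulation numbers up to 52.
#'
#' @return A list with `centered`, `all_skew` and `survey_bound`.
#' @examples
#' reference_fixtures()$centered   # 3 9 12 21 27 36 39 48
#' @export
reference_fixtures <- function() {
  list(centered = c(3L, 9L, 12L, 21L, 27L, 36L, 39L, 48L),
       all_skew = c(4L, 7L, 13L, 16L, 19L, 25L, 28L, 31L, 37L, 43L, 49L, 52L),
       survey_bound = 52L)
}

survey_csv_columns <- c("T", "h", "k", "centered_hexamer", "n_pentamers",
                        "n_hexamers", "n_hex_on_3fold", "n_hex_on_2fold",
                        "all_skew_compatible")

open_for_write <- function(path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort_io(sprintf("cannot write to '%s': %s",
                                                       path, conditionMessage(e))),
                  warning = function(w) abort_io(sprintf("cannot write to '%s': %s",
                                                         path, conditionMessage(w))))
  con
}

#' Write a survey report as CSV
#'
#' Comma-separated, header row, UTF-8, LF line endings, one row per distinct
#' `T` in ascending order. Columns: `T,h,k,centered_hexamer,n_pentamers,`
#' `n_hexamers,n_hex_on_3fold,n_hex_on_2fold,all_skew_compatible`; logicals
#' are written as `TRUE`/`FALSE`.
#'
#' @param report A [survey()] report.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(report, path) {
  df <- data.frame(T = report$T, h = report$h, k = report$k,
                   centered_hexamer = report$centered_hexamer_geometric,
                   n_pentamers = report$n_pentamers,
                   n_hexamers = report$n_hexamers,
                   n_hex_on_3fold = report$n_hex_on_3fold,
                   n_hex_on_2fold = report$n_hex_on_2fold,
                   all_skew_compatible = report$all_skew_compatible)
  con <- open_for_write(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read back a survey CSV
#'
#' @param path A file written by [write_survey_csv()].
#' @return A data frame with the CSV columns and their natural types.
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path, colClasses = c(T = "integer", h = "integer", k = "integer",
                                       centered_hexamer = "logical",
                                       n_pentamers = "integer", n_hexamers = "integer",
                                       n_hex_on_3fold = "integer", n_hex_on_2fold = "integer",
                                       all_skew_compatible = "logical"))
}

#' Write a survey report as JSON
#'
#' JSON mirror of the CSV rows plus the summary counts.
#'
#' @inheritParams write_survey_csv
#' @return `path`, invisibly.
#' @export
write_survey_json <- function(report, path) {
  s <- attr(report, "summary")
  obj <- list(
    t_max = s$t_max,
    rows = report[, c("T", "h", "k", "representations", "has_hexamers",
                      "centered_hexamer_geometric", "centered_hexamer_predicted",
                      "n_pentamers", "n_hexamers", "n_hex_on_3fold",
                      "n_hex_on_2fold", "all_skew_compatible")],
    summary = list(n_capsids_with_hexamers = s$n_capsids_with_hexamers,
                   centered = s$n_centered, all_skew = s$n_all_skew,
                   centered_t = s$centered_t, all_skew_t = s$all_skew_t)
  )
  tryCatch(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = TRUE),
           error = function(e) abort_io(sprintf("cannot write to '%s': %s",
                                                path, conditionMessage(e))))
  invisible(path)
}

#' Write a capsid as a pseudo-atom PDB file
#'
#' One `HETATM` pseudo-atom per capsomer center (a common coarse-model
#' convention; the file opens in any molecular viewer). Chain `A`, residue
#' `CAP`, element `C`, residue number = 1-based site index, occupancy 1.00.
#' The B-factor column encodes the symmetry class: `0.00` pentamer, `1.00`
#' general-position hexamer, `2.00` hexamer on a global 2-fold axis, `3.00`
#' hexamer on a global 3-fold axis. `REMARK 300` records document the
#' encoding. Coordinates are in the capsid's radius units, read as
#' angstroms.
#'
#' @param capsid A [build_capsid()] object.
#' @param path Output file path.
#' @param tol Axis-classification tolerance, see [classify_sites()].
#' @return `path`, invisibly.
#' @export
write_capsid_pdb <- function(capsid, path, tol = 1e-6) {
  cls <- classify_sites(capsid, tol)
  b <- ifelse(cls$on_axis_order == 5L, 0,
       ifelse(cls$on_axis_order == 3L, 3,
       ifelse(cls$on_axis_order == 2L, 2, 1)))
  n <- nrow(capsid$sites)

  remarks <- c(
    "REMARK 300 COARSE CAPSID LATTICE: ONE PSEUDO-ATOM PER CAPSOMER CENTER",
    sprintf("REMARK 300 T = %d (H = %d, K = %d), HANDEDNESS = %s, RADIUS = %g",
            capsid$T, capsid$step$h, capsid$step$k,
            toupper(capsid$handedness), capsid$radius),
    "REMARK 300 B-FACTOR CLASS: 0 PENTAMER, 1 HEXAMER GENERAL POSITION,",
    "REMARK 300   2 HEXAMER ON GLOBAL 2-FOLD AXIS, 3 HEXAMER ON GLOBAL 3-FOLD AXIS"
  )

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(capsid$sites[, c("x", "y", "z")]))),
                   type = rep("HETATM", n),
                   resno = seq_len(n), resid = rep("CAP", n),
                   eleno = seq_len(n), elety = rep("C", n),
                   chain = rep("A", n), o = rep(1, n), b = b,
                   elesy = rep("C", n))
  con <- open_for_write(path)
  on.exit(close(con), add = TRUE, after = FALSE)
  writeLines(c(remarks, readLines(tmp)), con)
  invisible(path)
}

#' Write the faceted capsid mesh as Wavefront OBJ
#'
#' Plain `v`/`f` records, 1-based indices, outward winding; vertices are the
#' capsomer centers (see [facet_mesh()]).
#'
#' @inheritParams write_capsid_pdb
#' @return `path`, invisibly.
#' @export
write_capsid_obj <- function(capsid, path) {
  mesh <- facet_mesh(capsid)
  con <- open_for_write(path)
  on.exit(close(con))
  writeLines(c(
    sprintf("# faceted capsid mesh, T = %d (h = %d, k = %d), %s",
            capsid$T, capsid$step$h, capsid$step$k, capsid$handedness),
    sprintf("v %.6f %.6f %.6f",
            mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]),
    sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L])
  ), con)
  invisible(path)
}

#' Write a ChimeraX-style marker command script
#'
#' One `marker` command per capsomer, colored by symmetry class (pentamers
#' orange; hexamers steel blue in general position, sea green on 2-fold
#' axes, firebrick on 3-fold axes).
#'
#' @inheritParams write_capsid_pdb
#' @return `path`, invisibly.
#' @export
write_chimerax_markers <- function(capsid, path, tol = 1e-6) {
  cls <- classify_sites(capsid, tol)
  col <- ifelse(cls$on_axis_order == 5L, "orange",
         ifelse(cls$on_axis_order == 3L, "firebrick",
         ifelse(cls$on_axis_order == 2L, "sea green", "steel blue")))
  mr <- capsid$radius / (4 * sqrt(capsid$T))   # marker radius ~ capsomer size
  con <- open_for_write(path)
  on.exit(close(con))
  writeLines(c(
    sprintf("# capsid markers, T = %d (h = %d, k = %d)",
            capsid$T, capsid$step$h, capsid$step$k),
    sprintf("marker #1 position %.4f,%.4f,%.4f radius %.4f color %s",
            capsid$sites$x, capsid$sites$y, capsid$sites$z, mr, col)
  ), con)
  invisible(path)
}
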