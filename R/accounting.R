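# Protein stoichiometry and genome packing density arithmetic.

#' Protein census of a capsid
#'
#' Copy-number accounting for a `T`-capsid: `60 T` major capsid proteins
#' (MCPs) in 12 pentamers and `10 (T - 1)` hexamers. In tailed phages one
#' pentameric vertex is replaced by the dodecameric portal complex, removing
#' the five MCPs of that vertex (`60 T - 5`, 11 pentamers); the portal
#' itself is counted as one portal unit, not as MCPs. Accessory
#' (decoration/cement) proteins are counted per hexamer: the default
#' stoichiometry of interest is 2 per hexamer, a dimer bridging the split
#' hexamer's 2-fold chasm, but any non-negative count may be given.
#'
#' @param T A triangulation number (validated with [is_t_number()]).
#' @param portal Logical; does the portal complex replace one vertex?
#' @param accessory_per_hexamer Non-negative integer copies per hexamer.
#' @return An object of class `protein_census`: list with `T`,
#'   `portal_present`, `mcp_count`, `pentamer_count`, `hexamer_count`,
#'   `accessory_per_hexamer`, `accessory_total`.
#' @examples
#' protein_census(7, portal = TRUE)$mcp_count   # 415
#' protein_census(12)$hexamer_count             # 110
#' @export
protein_census <- function(T, portal = FALSE, accessory_per_hexamer = 0L) {
  if (!is_t_number(T)) abort_not_t_number(T)
  if (length(accessory_per_hexamer) != 1L || is.na(accessory_per_hexamer) ||
      accessory_per_hexamer < 0 || accessory_per_hexamer != round(accessory_per_hexamer)) {
    abort_invalid("accessory_per_hexamer must be a single non-negative integer")
  }
  T <- as.integer(T)
  acc <- as.integer(accessory_per_hexamer)
  hexamers <- 10L * (T - 1L)
  structure(
    list(T = T,
         portal_present = isTRUE(portal),
         mcp_count = 60L * T - if (isTRUE(portal)) 5L else 0L,
         pentamer_count = if (isTRUE(portal)) 11L else 12L,
         hexamer_count = hexamers,
         accessory_per_hexamer = acc,
         accessory_total = acc * hexamers),
    class = "protein_census"
  )
}

#' @export
print.protein_census <- function(x, ...) {
  cat(sprintf(
    "<protein_census> T = %d%s: %d MCPs in %d pentamers + %d hexamers; %d accessory proteins (%d per hexamer)\n",
    x$T, if (x$portal_present) " (portal at one vertex)" else "",
    x$mcp_count, x$pentamer_count, x$hexamer_count,
    x$accessory_total, x$accessory_per_hexamer))
  invisible(x)
}

#' Genome payload of a capsid
#'
#' @param genome_length_kb Genome length in kilobase pairs.
#' @param internal_diameter_nm Internal capsid diameter in nm; the internal
#'   volume is modeled as a sphere of this diameter.
#' @return An object of class `capsid_payload` with the inputs and the
#'   packing `density` in bp per cubic nm.
#' @examples
#' capsid_payload(70.5, 63)$density   # ~0.539 bp/nm^3
#' @export
capsid_payload <- function(genome_length_kb, internal_diameter_nm) {
  structure(
    list(genome_length_kb = genome_length_kb,
         internal_diameter_nm = internal_diameter_nm,
         density = genome_density(genome_length_kb, internal_diameter_nm)),
    class = "capsid_payload"
  )
}

#' Genome packing density
#'
#' Base pairs per cubic nanometer assuming a spherical interior:
#' `1000 * kb / ((4/3) * pi * (d/2)^3)`.
#'
#' @inheritParams capsid_payload
#' @return Density in bp/nm^3.
#' @examples
#' genome_density(70.5, 63)   # 0.5386...
#' genome_density(64.5, 63)   # 0.4928...
#' @export
genome_density <- function(genome_length_kb, internal_diameter_nm) {
  if (length(genome_length_kb) != 1L || !is.finite(genome_length_kb) || genome_length_kb <= 0 ||
      length(internal_diameter_nm) != 1L || !is.finite(internal_diameter_nm) || internal_diameter_nm <= 0) {
    abort_invalid("genome length and internal diameter must be single positive numbers")
  }
  (genome_length_kb * 1000) / ((4 / 3) * pi * (internal_diameter_nm / 2)^3)
}

#' Percent change in genome packing density
#'
#' `100 * (density(a) / density(b) - 1)`. With equal internal diameters this
#' reduces to the genome-length ratio.
#'
#' @param a,b [capsid_payload()] objects.
#' @return Percent change of `a` relative to `b`.
#' @examples
#' density_ratio(capsid_payload(70.5, 63), capsid_payload(64.5, 63))  # +9.30
#' @export
density_ratio <- function(a, b) {
  if (!inherits(a, "capsid_payload") || !inherits(b, "capsid_payload")) {
    abort_invalid("a and b must be capsid_payload objects")
  }
  100 * (a$density / b$density - 1)
}
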