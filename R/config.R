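# Shared constant tables: amino-acid codes, atomic masses, van der Waals
# radii, and the physical constants used by the quasi-harmonic entropy
# estimator.  Everything tunable at run time lives in geometry_config().

#' Three-letter to one-letter amino-acid translation table
#'
#' Standard 20 amino acids only; anything else maps to `"X"` and is
#' excluded from IMGT anchoring.
#'
#' @keywords internal
.aa321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.aa123 <- stats::setNames(names(.aa321), unname(.aa321))

aa_three_to_one <- function(resid) {
  out <- unname(.aa321[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(aa) {
  out <- unname(.aa123[toupper(aa)])
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(aa[is.na(out)], collapse = ", "))
  out
}

# Atomic masses in amu (standard atomic weights).
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

element_mass <- function(element) {
  m <- unname(.atomic_mass[toupper(element)])
  if (anyNA(m)) stop("no mass tabulated for element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  m
}

# Physical constants (SI), used only inside the entropy estimator.
.phys <- list(
  kB   = 1.380649e-23,       # J/K
  hbar = 1.054571817e-34,    # J s
  amu  = 1.66053906660e-27,  # kg
  R_cal = 1.987204258640832  # gas constant, cal mol^-1 K^-1
)

#' Geometry configuration
#'
#' Bundles every threshold that affects a geometric verdict: hydrogen-bond
#' distance window and angle cutoff, Bondi van der Waals radii, clash
#' tolerance and cavity probe radius.  All downstream functions take a
#' `config` argument so each cutoff can be overridden without touching
#' code.
#'
#' @param hb_min,hb_max heavy-atom donor--acceptor distance window for a
#'   hydrogen bond, in Angstrom.
#' @param hb_angle_min minimum antecedent--donor--acceptor angle in
#'   degrees; pairs whose antecedent cannot be resolved pass this check.
#' @param vdw_radii named vector of van der Waals radii (Angstrom) per
#'   element.
#' @param clash_tolerance overlap forgiven before a contact counts as a
#'   steric clash, in Angstrom.
#' @param probe_radius radius of the spherical cavity probe (Angstrom);
#'   the default is water-sized.
#' @return A list of class `"geometry_config"`.
#' @examples
#' cfg <- geometry_config(hb_max = 3.2)
#' cfg$hb_max
#' @export
geometry_config <- function(hb_min = 2.4, hb_max = 3.5, hb_angle_min = 90,
                            vdw_radii = c(C = 1.70, N = 1.55,
                                          O = 1.52, S = 1.80),
                            clash_tolerance = 0.4, probe_radius = 1.4) {
  stopifnot(hb_min > 0, hb_max >= hb_min, all(vdw_radii > 0),
            clash_tolerance >= 0, probe_radius > 0)
  structure(list(hb_min = hb_min, hb_max = hb_max,
                 hb_angle_min = hb_angle_min, vdw_radii = vdw_radii,
                 clash_tolerance = clash_tolerance,
                 probe_radius = probe_radius),
            class = "geometry_config")
}

vdw_radius <- function(element, config) {
  r <- unname(config$vdw_radii[toupper(element)])
  if (anyNA(r)) stop("no van der Waals radius configured for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  r
}

# Ideal serine internal coordinates used by the mutator (bond lengths in
# Angstrom, angles in degrees).
.ideal_ser <- list(b_ca_cb = 1.53, b_cb_og = 1.42, ang = 110.5)
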