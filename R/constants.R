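# Physical constants and residue-level composition tables.
#
# All tables live in this one file so the numerical inputs of the mass,
# volume and hydrodynamic bookkeeping are auditable in a single place.
# Volumes are consensus crystallographic residue volumes (nm^3), masses are
# average residue masses (Da, i.e. monomer minus water), and partial
# specific volumes are the classical consensus values (mL/g).

# unit conversions
.NM_PER_ANGSTROM <- 0.1

# water at 20 degrees C
.WATER_VISCOSITY_20C <- 1.002e-3   # Pa s
.WATER_DENSITY_20C <- 0.99823     # g/mL
.AVOGADRO <- 6.02214076e23

# hydration of glycoproteins: grams of bound water per gram of protein
.HYDRATION_G_PER_G <- 0.3

# default bead radius representing hydrated atomic elements (nm)
.HYDRO_BEAD_RADIUS <- 0.284

# amino-acid residue tables, keyed by three-letter code
.AA_TABLE <- data.frame(
  resname = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL"),
  code1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V"),
  mass = c(71.079, 156.188, 114.104, 115.089, 103.143, 128.131, 129.116,
           57.052, 137.141, 113.160, 113.160, 128.174, 131.196, 147.177,
           97.117, 87.078, 101.105, 186.213, 163.176, 99.133),
  volume_nm3 = c(0.0886, 0.1734, 0.1141, 0.1111, 0.1085, 0.1438, 0.1384,
                 0.0601, 0.1532, 0.1667, 0.1667, 0.1686, 0.1629, 0.1899,
                 0.1127, 0.0890, 0.1161, 0.2278, 0.1936, 0.1400),
  vbar = c(0.74, 0.70, 0.62, 0.60, 0.63, 0.67, 0.66, 0.64, 0.67, 0.90, 0.90,
           0.82, 0.75, 0.77, 0.76, 0.63, 0.70, 0.74, 0.71, 0.86),
  stringsAsFactors = FALSE
)

# generic sugar unit used for simplified extended N-glycan stubs:
# an anhydro-hexose unit.  HexNAc values provided for completeness.
.SUGAR_TABLE <- data.frame(
  sugar = c("HEX", "HEXNAC"),
  mass = c(162.141, 203.195),
  volume_nm3 = c(0.1710, 0.2220),
  vbar = c(0.607, 0.666),
  stringsAsFactors = FALSE
)

# van der Waals radii by element (nm), used by the rolling-probe SASA
.VDW_RADII <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120,
                P = 0.180, CA = 0.231, SE = 0.190)
.VDW_DEFAULT <- 0.170

# mean heavy-atom volume of protein interiors (nm^3), used when a dry
# volume must be estimated for a model without standard residue names
.HEAVY_ATOM_VOLUME <- 0.0116

#' Composition tables used by the package
#'
#' Returns the residue-level tables (amino-acid masses, volumes and partial
#' specific volumes; sugar-unit values; van der Waals radii) that drive the
#' mass, volume and hydration bookkeeping, so their provenance can be
#' audited or overridden upstream.
#'
#' @return A named list of tibbles/named vectors: `amino_acids`, `sugars`,
#'   `vdw_radii_nm`, plus scalar constants `hydration_g_per_g`,
#'   `water_viscosity_Pa_s`, `water_density_g_per_mL`.
#' @export
#' @examples
#' composition_tables()$amino_acids
composition_tables <- function() {
  list(
    amino_acids = tibble::as_tibble(.AA_TABLE),
    sugars = tibble::as_tibble(.SUGAR_TABLE),
    vdw_radii_nm = .VDW_RADII,
    hydration_g_per_g = .HYDRATION_G_PER_G,
    water_viscosity_Pa_s = .WATER_VISCOSITY_20C,
    water_density_g_per_mL = .WATER_DENSITY_20C
  )
}
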