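#' Convert a western-blot band to an intracellular concentration
#'
#' Reproduces the route from a quantified immunoblot to the total molar
#' GTPase concentration used by the model. The sample band intensity relative
#' to a control band of known loaded mass gives the protein mass in the
#' loaded lysate fraction; dividing by the fraction loaded and the number of
#' cells in the lysate gives mass per cell; the molecular weight and the
#' Avogadro constant give molecules per cell; and an idealized spherical cell
#' volume converts this to uM.
#'
#' @param band_ratio sample-band / control-band intensity ratio
#'   (dimensionless, >= 0).
#' @param control_mass_pg mass of control protein loaded on the gel, pg.
#' @param lysate_fraction_loaded fraction of the total lysate loaded in the
#'   sample lane (0 < fraction <= 1).
#' @param cells_in_lysate number of cells the total lysate represents
#'   (default 1.5e6, a confluent filter culture).
#' @param molecular_weight_kDa protein molecular weight (default 21 kDa, a
#'   small GTPase).
#' @param cell_diameter_um diameter of the idealized spherical cell
#'   (default 10 um).
#' @return Total intracellular concentration in uM. Vectorized over
#'   `band_ratio` and `control_mass_pg`.
#' @examples
#' # a band ratio that corresponds to ~1.387e6 molecules per 10-um cell
#' blot_to_concentration(1, 4.838e4 * 1e-6, 1e-6)
#' @export
blot_to_concentration <- function(band_ratio, control_mass_pg,
                                  lysate_fraction_loaded,
                                  cells_in_lysate = 1.5e6,
                                  molecular_weight_kDa = 21,
                                  cell_diameter_um = 10) {
  if (any(band_ratio < 0)) abort("band_ratio must be non-negative")
  for (v in list(control_mass_pg, lysate_fraction_loaded, cells_in_lysate,
                 molecular_weight_kDa, cell_diameter_um)) {
    if (any(v <= 0)) abort("masses, fractions, counts and geometry must be positive")
  }
  avogadro <- 6.02214076e23
  mass_per_cell_pg <- band_ratio * control_mass_pg /
    lysate_fraction_loaded / cells_in_lysate
  # pg -> g -> mol -> molecules
  molecules_per_cell <- mass_per_cell_pg * 1e-12 /
    (molecular_weight_kDa * 1e3) * avogadro
  volume_L <- (pi / 6) * cell_diameter_um^3 * 1e-15
  # molecules / (N_A * V) in mol/L, then to uM
  molecules_per_cell / (avogadro * volume_L) * 1e6
}

#' Blot quantification over a table of bands
#'
#' Applies [blot_to_concentration()] row-wise to a data frame of band
#' measurements, e.g. read from CSV with one row per protein band.
#'
#' @param bands data frame with columns `protein`, `band_ratio`,
#'   `control_mass_pg`, `lysate_fraction_loaded` and optionally
#'   `cells_in_lysate`, `molecular_weight_kDa`, `cell_diameter_um` (missing
#'   optional columns fall back to the defaults of
#'   [blot_to_concentration()]).
#' @return The input as a tibble with an added `concentration_uM` column.
#' @export
quantify_blots <- function(bands) {
  required <- c("protein", "band_ratio", "control_mass_pg",
                "lysate_fraction_loaded")
  missing_cols <- setdiff(required, names(bands))
  if (length(missing_cols)) {
    abort(paste0("bands is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bands <- tibble::as_tibble(bands)
  opt <- function(col, default) {
    if (col %in% names(bands)) bands[[col]] else default
  }
  dplyr::mutate(bands, concentration_uM = blot_to_concentration(
    .data$band_ratio, .data$control_mass_pg, .data$lysate_fraction_loaded,
    cells_in_lysate = opt("cells_in_lysate", 1.5e6),
    molecular_weight_kDa = opt("molecular_weight_kDa", 21),
    cell_diameter_um = opt("cell_diameter_um", 10)
  ))
}
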