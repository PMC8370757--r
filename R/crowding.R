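# Hard-sphere excluded-volume arithmetic for macromolecular crowding: from a
# crowder's mass concentration and Stokes radius to molecule count, occupied
# volume, the effective concentration of the phase-separating species, and
# the between-crowder exclusion ratio. All intermediates are kept at full
# precision; rounding is applied only when reporting (3 significant figures
# for counts, nearest microlitre for volumes, one decimal for concentrations
# and ratios), which reproduces printed chains without compounding rounding
# error.

AVOGADRO <- 6.022e23  # mol^-1

#' Crowder specification
#'
#' @param name crowder label (e.g. "dextran70").
#' @param mass_da molecular mass in daltons.
#' @param stokes_radius_a Stokes radius in angstroms.
#' @param conc_percent_wv mass concentration in % w/v, i.e. grams per 100 ml
#'   (6% = 60 g/l — the only reading consistent with crowder molecule
#'   counts as conventionally printed).
#' @param surface_active metadata flag (Ficoll is surface active, dextran is
#'   not); carried, not used in the arithmetic.
#' @return a `crowder_spec`.
#' @export
crowder_spec <- function(name, mass_da, stokes_radius_a, conc_percent_wv,
                         surface_active = FALSE) {
  check_number(mass_da, "mass_da", positive = TRUE)
  check_number(stokes_radius_a, "stokes_radius_a", positive = TRUE)
  check_number(conc_percent_wv, "conc_percent_wv", nonneg = TRUE)
  structure(list(name = name, mass_da = mass_da,
                 stokes_radius_a = stokes_radius_a,
                 conc_percent_wv = conc_percent_wv,
                 surface_active = isTRUE(surface_active)),
            class = "crowder_spec")
}

#' Number of crowder molecules in a reaction volume
#'
#' `count = (c[g/l] * V[l] / MW[g/mol]) * N_A`, with % w/v converting as
#' 6% -> 60 g/l.
#'
#' @param spec a [crowder_spec()].
#' @param reaction_volume_ul reaction volume in microlitres.
#' @return molecule count (dimensionless, full precision).
#' @export
molecule_count <- function(spec, reaction_volume_ul) {
  stopifnot(inherits(spec, "crowder_spec"))
  check_number(reaction_volume_ul, "reaction_volume_ul", positive = TRUE)
  g_per_l <- spec$conc_percent_wv * 10
  (g_per_l * reaction_volume_ul * 1e-6 / spec$mass_da) * AVOGADRO
}

#' Volume occupied by hard spheres of the Stokes radius
#'
#' `V_occ = count * (4 pi / 3) * r^3` with r in nm; 1 nm^3 = 1e-24 l.
#'
#' @param count number of molecules (>= 0).
#' @param stokes_radius_a sphere radius in angstroms (> 0).
#' @return occupied volume in microlitres (full precision).
#' @export
occupied_volume <- function(count, stokes_radius_a) {
  check_number(count, "count", nonneg = TRUE)
  check_number(stokes_radius_a, "stokes_radius_a", positive = TRUE)
  r_nm <- stokes_radius_a / 10
  count * (4 * pi / 3) * r_nm^3 * 1e-18   # nm^3 -> ul
}

#' Effective concentration after volume exclusion
#'
#' `c_eff = nominal * V / (V - V_occ)`; the occupied volume must be smaller
#' than the reaction volume.
#'
#' @param nominal_um nominal concentration, uM.
#' @param reaction_volume_ul reaction volume, ul.
#' @param occupied_ul excluded (occupied) volume, ul.
#' @return effective concentration in uM (full precision).
#' @export
effective_concentration <- function(nominal_um, reaction_volume_ul,
                                    occupied_ul) {
  check_number(nominal_um, "nominal_um", positive = TRUE)
  check_number(reaction_volume_ul, "reaction_volume_ul", positive = TRUE)
  check_number(occupied_ul, "occupied_ul", nonneg = TRUE)
  if (occupied_ul >= reaction_volume_ul)
    stop("occupied volume reaches the reaction volume (fully excluded)",
         call. = FALSE)
  nominal_um * reaction_volume_ul / (reaction_volume_ul - occupied_ul)
}

#' Ratio of occupied volumes between two crowders
#'
#' @param occupied_a_ul,occupied_b_ul occupied volumes (> 0), ul.
#' @return list `raw` and `ratio` (one decimal, half-up).
#' @export
exclusion_ratio <- function(occupied_a_ul, occupied_b_ul) {
  check_number(occupied_a_ul, "occupied_a_ul", positive = TRUE)
  check_number(occupied_b_ul, "occupied_b_ul", positive = TRUE)
  raw <- occupied_a_ul / occupied_b_ul
  list(raw = raw, ratio = round_half_up(raw, 1))
}

#' Full crowding chain for a set of crowders
#'
#' Runs count -> occupied volume -> effective concentration for each crowder
#' at full precision and reports at conventional precision alongside.
#'
#' @param specs list of [crowder_spec()]s.
#' @param reaction_volume_ul reaction volume, ul.
#' @param nominal_um nominal concentration of the phase-separating species,
#'   uM.
#' @return a `crowding_result` data.frame: `name`, `molecule_count`,
#'   `molecule_count_3sf`, `occupied_ul`, `occupied_ul_rounded`,
#'   `available_ul`, `effective_um`, `effective_um_1dp`.
#' @export
crowding_analysis <- function(specs, reaction_volume_ul = 345,
                              nominal_um = 4) {
  if (inherits(specs, "crowder_spec")) specs <- list(specs)
  rows <- lapply(specs, function(s) {
    n <- molecule_count(s, reaction_volume_ul)
    # the printed chain applies the sphere volume to the count as reported
    # (3 s.f.); the fully unrounded volume is kept alongside
    occ <- occupied_volume(signif(n, 3), s$stokes_radius_a)
    occ_full <- occupied_volume(n, s$stokes_radius_a)
    eff <- effective_concentration(nominal_um, reaction_volume_ul, occ)
    data.frame(name = s$name,
               molecule_count = n,
               molecule_count_3sf = signif(n, 3),
               occupied_ul = occ,
               occupied_ul_full = occ_full,
               occupied_ul_rounded = round_half_up(occ, 0),
               available_ul = reaction_volume_ul - occ,
               effective_um = eff,
               effective_um_1dp = round_half_up(eff, 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "reaction_volume_ul") <- reaction_volume_ul
  attr(out, "nominal_um") <- nominal_um
  class(out) <- c("crowding_result", "data.frame")
  out
}
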