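## User-facing energy/force evaluation on a single conformation.

#' Bonded energy terms
#'
#' Quadratic bond (U12) and angle (U13) deformation energies plus the periodic
#' torsion term (U14; identically zero for the siloxane series, which carry no
#' dihedral list).
#'
#' @param conf a `conformation` (see [embed_3d()]).
#' @param ff a `forcefield`.
#' @return named list `U12`, `U13`, `U14` in kcal/mol.
#' @export
bonded_energy <- function(conf, ff = default_forcefield()) {
  res <- energy_forces_cpp(conf$coords, ff_system(conf$topology, ff),
                           numeric(0))
  as.list(res$energy[c("U12", "U13", "U14")])
}

#' Non-bonded energy terms
#'
#' Pairwise Lennard-Jones (Uvw) and screened-Coulomb (Uqq) energies with
#' 1-2/1-3 exclusions, scaled 1-4 pairs and the configured cutoff.
#'
#' @inheritParams bonded_energy
#' @return named list `Uvw`, `Uqq` in kcal/mol.
#' @export
nonbonded_energy <- function(conf, ff = default_forcefield()) {
  res <- energy_forces_cpp(conf$coords, ff_system(conf$topology, ff),
                           numeric(0))
  as.list(res$energy[c("Uvw", "Uqq")])
}

#' Total forces and energy breakdown
#'
#' Sums all force-field terms (and the wall term when `wall` is given) and
#' returns analytic forces together with the per-term energy breakdown.
#'
#' @inheritParams bonded_energy
#' @param wall optional [wall_params()]; when supplied, `U_ads` sums the 9-3
#'   wall potential over all atoms and its z-forces are included.
#' @return list with `forces` (N x 3, kcal/mol/Angstrom), `energy` (named
#'   vector U12, U13, U14, Uvw, Uqq, U_ads) and `total`.
#' @export
total_forces <- function(conf, ff = default_forcefield(), wall = NULL) {
  res <- energy_forces_cpp(conf$coords, ff_system(conf$topology, ff),
                           wall_vec(wall))
  list(forces = res$forces, energy = res$energy,
       total = sum(res$energy))
}
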