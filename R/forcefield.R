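## Force-field parameter container and the analytic 9-3 wall potential.
##
## Functional forms:
##   U12 = sum k_b (b - b0)^2                       bond stretching
##   U13 = sum k_th (theta - theta0)^2              angle bending
##   U14 = sum A (1 + cos(n phi - delta))           torsions, carbosilane only
##   Uvw = sum 4 eps_ij ((s/r)^12 - (s/r)^6)        LJ, Lorentz-Berthelot mixing
##   Uqq = sum C q_i q_j / (kappa r^2)              screened Coulomb with a
##                                                  distance-dependent dielectric
##   Uads(z) = 0.5 eps ((Rmin/z)^9 - 3 (Rmin/z)^3)  9-3 wall, identical for all
##                                                  atoms regardless of type

#' Nominal united-atom force field
#'
#' Representative literature-style united-atom parameters for carbosilane and
#' siloxane dendrimers (quadratic bonds/angles, a 3-fold torsion for the
#' carbosilane backbone, united-atom LJ sites, screened Coulomb for the
#' siloxane partial charges).  All values are configuration, serializable with
#' [write_forcefield()].
#'
#' @return object of class `forcefield`.
#' @export
default_forcefield <- function() {
  structure(list(
    bonds = list(
      `C-C`  = list(b0 = 1.53, k = 310),
      `C-Si` = list(b0 = 1.89, k = 190),
      `O-Si` = list(b0 = 1.64, k = 350)),
    angles = list( # theta0 in degrees, k in kcal/mol/rad^2
      `C-Si-C` = list(theta0 = 109.47, k = 60),
      `C-C-Si` = list(theta0 = 112.0,  k = 60),
      `C-C-C`  = list(theta0 = 112.0,  k = 63),
      `O-Si-O` = list(theta0 = 109.47, k = 60),
      `C-Si-O` = list(theta0 = 109.47, k = 60),
      `Si-O-Si` = list(theta0 = 150.0, k = 15)), # wide, soft siloxane hinge
    dihedrals = list(
      generic = list(amplitude = 0.3, multiplicity = 3, phase = 0)),
    lj = list( # well depth kcal/mol, size (sigma) Angstrom
      Si  = list(eps = 0.10,  sigma = 3.80),
      O   = list(eps = 0.17,  sigma = 3.00),
      CH2 = list(eps = 0.118, sigma = 3.905),
      CH3 = list(eps = 0.175, sigma = 3.905)),
    coulomb = list(coupling = 332.0637, dielectric_slope = 1.0),
    nonbonded_cutoff = 10.5,
    scale14 = list(lj = 0.5, qq = 0.5)),
    class = "forcefield")
}

#' Wall (adsorption potential) parameters
#'
#' The adsorbing plane sits at z = 0; every united atom feels the same 9-3
#' potential with minimum -epsilon at z = R_min.
#'
#' @param epsilon well depth in kcal/mol (>= 0).
#' @param r_min position of the minimum in Angstrom (default 3).
#' @param cutoff distance beyond which the potential is exactly zero
#'   (default 130 Angstrom, large enough to span an entire dendrimer).
#' @return object of class `wall_params`.
#' @export
wall_params <- function(epsilon, r_min = 3, cutoff = 130) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (r_min <= 0) stop("r_min must be > 0")
  if (cutoff <= r_min) stop("cutoff must exceed r_min")
  structure(list(epsilon = epsilon, r_min = r_min, cutoff = cutoff),
            class = "wall_params")
}

#' 9-3 wall potential energy
#'
#' `U(z) = 0.5 epsilon ((R_min/z)^9 - 3 (R_min/z)^3)` for `0 < z <= cutoff`,
#' exactly 0 beyond the cutoff.  The minimum is `-epsilon` at `z = R_min`; the
#' root is at `z = R_min * 3^(-1/6)`.
#'
#' @param z height(s) above the plane, Angstrom; must be positive (the plane is
#'   impenetrable).
#' @param wall a [wall_params()].
#' @return energy in kcal/mol, vectorized over `z`.
#' @export
wall_energy <- function(z, wall) {
  if (any(z <= 0)) stop("z <= 0: atom penetrated the impenetrable plane")
  a <- wall$r_min / z
  u <- 0.5 * wall$epsilon * (a^9 - 3 * a^3)
  u[z > wall$cutoff] <- 0
  u
}

#' 9-3 wall force
#'
#' Analytic `-dU/dz`; zero beyond the cutoff and at `z = R_min`.
#'
#' @inheritParams wall_energy
#' @return z-force in kcal/mol/Angstrom, vectorized over `z`.
#' @export
wall_force <- function(z, wall) {
  if (any(z <= 0)) stop("z <= 0: atom penetrated the impenetrable plane")
  a <- wall$r_min / z
  f <- 4.5 * wall$epsilon / z * (a^9 - a^3)
  f[z > wall$cutoff] <- 0
  f
}

#' Write force-field (and optional wall) parameters to YAML
#'
#' @param ff a `forcefield`.
#' @param path output file.
#' @param wall optional [wall_params()] stored under a `wall` section.
#' @export
write_forcefield <- function(ff, path, wall = NULL) {
  obj <- unclass(ff)
  if (!is.null(wall)) obj$wall <- unclass(wall)
  writeLines(yaml::as.yaml(obj, precision = 12L), path)
  invisible(path)
}

#' Read force-field parameters from YAML
#'
#' Inverse of [write_forcefield()]; values written with the shipped defaults
#' round-trip exactly.
#'
#' @param path YAML file.
#' @return list with `forcefield` and (if present) `wall`.
#' @export
read_forcefield <- function(path) {
  obj <- yaml::read_yaml(path)
  wall <- NULL
  if (!is.null(obj$wall)) {
    wall <- do.call(wall_params, obj$wall)
    obj$wall <- NULL
  }
  ff <- structure(obj, class = "forcefield")
  required <- c("bonds", "angles", "dihedrals", "lj", "coulomb",
                "nonbonded_cutoff", "scale14")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("force-field file lacks sections: ", paste(missing, collapse = ", "))
  }
  list(forcefield = ff, wall = wall)
}
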