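## Flattening of topology + force field into the numeric arrays consumed by
## the compiled energy/force kernels.

#' Build 1-2/1-3 exclusion and scaled 1-4 pair lists
#'
#' Directly bonded (1-2) and angle-end (1-3) pairs are excluded from the
#' non-bonded terms; 1-4 (dihedral-end) pairs are kept with configurable
#' scaling.  The molecule is a tree, so the three sets are disjoint.
#' @noRd
nonbonded_pairlists <- function(topology) {
  b <- as.matrix(topology$bonds[, c("i", "j")])
  a <- as.matrix(topology$angles[, c("i", "k")])
  excl <- rbind(b, a)
  if (nrow(topology$dihedrals)) {
    p14 <- unique(t(apply(as.matrix(topology$dihedrals[, c("i", "l")]), 1L,
                          sort)))
  } else {
    p14 <- matrix(integer(0), ncol = 2L)
  }
  list(excl = excl, pairs14 = p14)
}

lookup_or_stop <- function(tab, keys, what) {
  miss <- setdiff(unique(keys), names(tab))
  if (length(miss)) {
    stop(sprintf("missing %s parameters for type(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
  tab[keys]
}

#' Assemble the flat numeric system passed to the compiled kernels
#' @noRd
ff_system <- function(topology, ff) {
  at <- topology$atoms
  bt <- lookup_or_stop(ff$bonds, topology$bonds$type, "bond")
  ang <- lookup_or_stop(ff$angles, topology$angles$type, "angle")
  lj <- lookup_or_stop(ff$lj, at$type, "LJ")
  pl <- nonbonded_pairlists(topology)

  sys <- list(
    n = topology$N,
    mass = at$mass,
    charge = at$charge,
    lj_eps = vapply(lj, `[[`, numeric(1), "eps"),
    lj_sigma = vapply(lj, `[[`, numeric(1), "sigma"),
    bonds = as.matrix(topology$bonds[, c("i", "j")]) - 1L,
    b0 = vapply(bt, `[[`, numeric(1), "b0"),
    kb = vapply(bt, `[[`, numeric(1), "k"),
    angles = as.matrix(topology$angles[, c("i", "j", "k")]) - 1L,
    theta0 = vapply(ang, `[[`, numeric(1), "theta0") * pi / 180,
    ktheta = vapply(ang, `[[`, numeric(1), "k"),
    dihedrals = matrix(integer(0), ncol = 4L),
    d_amp = numeric(0), d_mult = integer(0), d_phase = numeric(0),
    excl = pl$excl - 1L,
    pairs14 = pl$pairs14 - 1L,
    scale14_lj = ff$scale14$lj,
    scale14_qq = ff$scale14$qq,
    cutoff = ff$nonbonded_cutoff,
    qq_coupling = ff$coulomb$coupling,
    qq_slope = ff$coulomb$dielectric_slope)

  if (nrow(topology$dihedrals)) {
    dt <- lookup_or_stop(ff$dihedrals, topology$dihedrals$type, "dihedral")
    sys$dihedrals <- as.matrix(topology$dihedrals[, c("i", "j", "k", "l")]) - 1L
    sys$d_amp <- vapply(dt, `[[`, numeric(1), "amplitude")
    sys$d_mult <- as.integer(vapply(dt, `[[`, numeric(1), "multiplicity"))
    sys$d_phase <- vapply(dt, `[[`, numeric(1), "phase")
  }
  sys
}

wall_vec <- function(wall) {
  if (is.null(wall)) numeric(0)
  else c(wall$epsilon, wall$r_min, wall$cutoff)
}
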