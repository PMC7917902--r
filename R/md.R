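## MD driver layer: simulation parameters, reference velocity-Verlet stepper,
## collisional thermostat, relaxation and adsorption protocols.

#' Simulation parameters
#'
#' @param timestep_fs integration timestep in femtoseconds (default 1).
#' @param temperature thermostat temperature in K (default 350).
#' @param thermostat_mass virtual-particle mass m0 in Da (default 1).
#' @param collision_rate per-atom collision frequency lambda in 1/ps
#'   (default 55); `collision_rate * dt` must be well below 1.
#' @param duration_ns trajectory length in ns.
#' @param snapshot_ps interval between stored frames in ps (default 1).
#' @param seed integer RNG seed for initial velocities, orientations and
#'   thermostat collisions.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(timestep_fs = 1, temperature = 350,
                              thermostat_mass = 1, collision_rate = 55,
                              duration_ns = 0.1, snapshot_ps = 1, seed = 1L) {
  if (timestep_fs <= 0) stop("timestep must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (duration_ns <= 0) stop("duration must be > 0")
  if (collision_rate * timestep_fs * 1e-3 >= 0.5) {
    stop("collision_rate * timestep too large for per-step collision sampling")
  }
  structure(list(timestep_fs = timestep_fs, temperature = temperature,
                 thermostat_mass = thermostat_mass,
                 collision_rate = collision_rate, duration_ns = duration_ns,
                 snapshot_ps = snapshot_ps, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses atomic masses in Da.
#' @param temperature temperature in K.
#' @param seed RNG seed.
#' @return N x 3 velocity matrix in Angstrom/ps.
#' @export
maxwell_velocities <- function(masses, temperature, seed = 1L) {
  n <- length(masses)
  sdv <- sqrt(.KB * temperature * .ECONV / masses)
  with_seed(seed, matrix(rnorm(3 * n, 0, rep(sdv, 3L)), n, 3L))
}

#' Reference velocity-Verlet integrator
#'
#' A plain R implementation of the velocity-Verlet update used as an
#' executable specification of the compiled engine: forces come from an
#' arbitrary callback, so closed-form test cases (constant force, harmonic
#' dimer) can be integrated directly.
#'
#' @param coords N x 3 positions (Angstrom).
#' @param vels N x 3 velocities (Angstrom/ps).
#' @param masses masses (Da).
#' @param force_fn function(coords) returning an N x 3 force matrix in
#'   kcal/mol/Angstrom.
#' @param dt_fs timestep in fs.
#' @param nsteps number of steps.
#' @return list with final `coords`, `vels` and the position `history`
#'   (N x 3 x (nsteps+1)).
#' @export
velocity_verlet <- function(coords, vels, masses, force_fn, dt_fs, nsteps) {
  dt <- dt_fs * 1e-3
  inv_m <- .ECONV / masses
  hist <- array(NA_real_, c(nrow(coords), 3L, nsteps + 1L))
  hist[, , 1L] <- coords
  f <- force_fn(coords)
  for (s in seq_len(nsteps)) {
    vels <- vels + 0.5 * dt * f * inv_m
    coords <- coords + dt * vels
    f <- force_fn(coords)
    vels <- vels + 0.5 * dt * f * inv_m
    hist[, , s + 1L] <- coords
  }
  list(coords = coords, vels = vels, history = hist)
}

#' One collisional-thermostat sweep
#'
#' Each atom independently collides, with probability `collision_rate * dt`,
#' with a virtual particle of mass m0 whose velocity is Maxwell-distributed at
#' the target temperature; the elastic collision
#' `v' = v + 2 m0/(m + m0) (u - v)` conserves the momentum of the pair.
#'
#' @param vels N x 3 velocity matrix (Angstrom/ps).
#' @param masses atomic masses (Da).
#' @param sim a [simulation_params()].
#' @param seed RNG seed for this sweep.
#' @return updated velocity matrix.
#' @export
thermostat_collide <- function(vels, masses, sim, seed = 1L) {
  p <- sim$collision_rate * sim$timestep_fs * 1e-3
  if (p <= 0) return(vels)
  m0 <- sim$thermostat_mass
  sdv <- sqrt(.KB * sim$temperature * .ECONV / m0)
  with_seed(seed, {
    hit <- stats::runif(nrow(vels)) < p
    if (any(hit)) {
      u <- matrix(rnorm(3 * sum(hit), 0, sdv), sum(hit), 3L)
      fac <- 2 * m0 / (masses[hit] + m0)
      vels[hit, ] <- vels[hit, ] + fac * (u - vels[hit, , drop = FALSE])
    }
    vels
  })
}

make_trajectory <- function(res, topology, sim, wall, phase,
                            record_velocities) {
  nsnap <- length(res$times)
  traj <- structure(list(
    topology = topology,
    times = as.numeric(res$times),
    coords = array(res$coords, c(topology$N, 3L, nsnap)),
    energies = `colnames<-`(res$energies,
                            c("U12", "U13", "U14", "Uvw", "Uqq", "U_ads",
                              "KE", "temperature")),
    final_coords = res$final_coords,
    final_velocities = res$final_velocities,
    provenance = list(spec = topology$spec, sim = sim, wall = wall,
                      phase = phase)),
    class = "trajectory")
  if (record_velocities) {
    traj$velocities <- array(res$velocities, c(topology$N, 3L, nsnap))
  }
  traj
}

#' Number of stored frames
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame
#'
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return list with `time` (ps), `coords`, optional `velocities`, `energy`
#'   (named vector) and `temperature` (K).
#' @export
get_frame <- function(traj, i) {
  out <- list(time = traj$times[i], coords = traj$coords[, , i],
              energy = traj$energies[i, 1:6],
              temperature = traj$energies[i, "temperature"])
  if (!is.null(traj$velocities)) out$velocities <- traj$velocities[, , i]
  out
}

#' Indices of the production window
#'
#' The trailing `fraction` of the trajectory (by time) used for averaging.
#'
#' @param traj a `trajectory`.
#' @param fraction trailing fraction in (0, 1].
#' @return integer frame indices.
#' @export
production_frames <- function(traj, fraction = 2 / 3) {
  tmax <- max(traj$times)
  which(traj$times > tmax - fraction * (tmax - min(traj$times)) - 1e-9)
}

run_engine <- function(conf, ff, sim, wall, vels, phase,
                       thermostat = TRUE, record_velocities = FALSE) {
  dt <- sim$timestep_fs * 1e-3
  nsteps <- max(1L, round(sim$duration_ns * 1000 / dt))
  snap_every <- max(1L, round(sim$snapshot_ps / dt))
  res <- md_run_cpp(conf$coords, vels, ff_system(conf$topology, ff),
                    wall_vec(wall), dt, nsteps, snap_every,
                    thermostat, sim$temperature, sim$thermostat_mass,
                    sim$collision_rate, sim$seed, record_velocities)
  make_trajectory(res, conf$topology, sim, wall, phase, record_velocities)
}

#' Relax a dendrimer in free space
#'
#' Thermostatted trajectory with no wall; the final frame is the equilibrated
#' structure handed to [adsorb()].
#'
#' @param conf an embedded `conformation`.
#' @param ff a `forcefield`.
#' @param sim a [simulation_params()].
#' @param record_velocities store per-frame velocities (memory-heavy).
#' @return a `trajectory`.
#' @export
relax <- function(conf, ff = default_forcefield(),
                  sim = simulation_params(), record_velocities = FALSE) {
  vels <- maxwell_velocities(conf$topology$atoms$mass, sim$temperature,
                             sim$seed)
  run_engine(conf, ff, sim, wall = NULL, vels = vels, phase = "relax",
             record_velocities = record_velocities)
}

#' Final frame of a trajectory as a conformation
#'
#' @param traj a `trajectory`.
#' @return a `conformation`.
#' @export
final_conformation <- function(traj) {
  structure(list(topology = traj$topology, coords = traj$final_coords),
            class = "conformation")
}

#' Simulate adsorption onto the wall
#'
#' The equilibrated molecule is rotated by a uniformly random orientation,
#' translated so its lowest atom sits `initial_gap` above the plane at z = 0,
#' and integrated with the 9-3 wall potential acting identically on every
#' atom.
#'
#' @param conf an equilibrated `conformation`.
#' @param ff a `forcefield`.
#' @param wall a [wall_params()].
#' @param sim a [simulation_params()].
#' @param initial_gap starting height of the lowest atom (Angstrom).
#' @param record_velocities store per-frame velocities.
#' @return a `trajectory`.
#' @export
adsorb <- function(conf, ff = default_forcefield(), wall = wall_params(1),
                   sim = simulation_params(), initial_gap = 5,
                   record_velocities = FALSE) {
  x <- conf$coords
  com <- colMeans(x)
  rot <- with_seed(sim$seed, random_rotation())
  x <- sweep(x, 2L, com) %*% t(rot)
  x[, 3L] <- x[, 3L] - min(x[, 3L]) + initial_gap
  start <- structure(list(topology = conf$topology, coords = x),
                     class = "conformation")
  vels <- maxwell_velocities(conf$topology$atoms$mass, sim$temperature,
                             sim$seed + 1L)
  run_engine(start, ff, sim, wall = wall, vels = vels, phase = "adsorb",
             record_velocities = record_velocities)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %s G%d, %d atoms, %d frames over %.1f ps, <T> = %.1f K\n",
              x$provenance$phase, x$topology$spec$series,
              x$topology$spec$generation, x$topology$N, n_frames(x),
              max(x$times), mean(x$energies[, "temperature"])))
  invisible(x)
}
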