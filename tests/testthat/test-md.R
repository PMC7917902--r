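# ECONV converts kcal/mol to Da A^2/ps^2; KB is Boltzmann's constant
ECONV <- 418.4
KB <- 0.0019872041

test_that("velocity Verlet reproduces closed-form uniformly accelerated motion", {
  m <- 10
  f <- c(2, -1, 0.5) # constant force, kcal/mol/A
  v0 <- c(1, 0, -2)  # A/ps
  res <- velocity_verlet(matrix(0, 1, 3), matrix(v0, 1, 3), m,
                         function(x) matrix(f, 1, 3), dt_fs = 1, nsteps = 500)
  t <- 0.5 # ps
  a <- f * ECONV / m
  # Verlet is exact for constant forces
  expect_equal(as.numeric(res$coords), v0 * t + 0.5 * a * t^2, tolerance = 1e-10)
  expect_equal(as.numeric(res$vels), v0 + a * t, tolerance = 1e-10)
  # zero force, zero velocity -> state unchanged
  still <- velocity_verlet(matrix(1, 1, 3), matrix(0, 1, 3), m,
                           function(x) matrix(0, 1, 3), 1, 100)
  expect_equal(as.numeric(still$coords), rep(1, 3))
})

test_that("a harmonic dimer oscillates at its analytic period", {
  k <- 100     # kcal/mol/A^2 in U = k (b - b0)^2
  b0 <- 1.5
  m <- 12
  mu <- m / 2  # reduced mass
  omega <- sqrt(2 * k * ECONV / mu) # 1/ps, from U = k db^2
  period_fs <- 2 * pi / omega * 1e3
  force_fn <- function(x) {
    d <- x[2, ] - x[1, ]
    r <- sqrt(sum(d^2))
    f <- 2 * k * (r - b0) * d / r
    rbind(f, -f)
  }
  dt <- period_fs / 100
  nst <- 400
  x0 <- rbind(c(0, 0, 0), c(b0 + 0.1, 0, 0))
  res <- velocity_verlet(x0, matrix(0, 2, 3), c(m, m), force_fn, dt, nst)
  sep <- res$history[2, 1, ] - res$history[1, 1, ]
  # measured period from successive maxima of the separation
  peaks <- which(diff(sign(diff(sep))) == -2) + 1
  measured <- mean(diff(peaks)) * dt
  expect_equal(measured, period_fs, tolerance = 0.01)
  # bounded energy oscillation
  amp <- max(sep) - b0
  expect_lt(abs(amp - 0.1) / 0.1, 0.02)
})

test_that("the compiled engine matches the R reference integrator step for step", {
  ff <- default_forcefield()
  conf <- cached_conformation("S", 1)
  topo <- conf$topology
  v0 <- maxwell_velocities(topo$atoms$mass, 350, seed = 3)
  nst <- 50
  # compiled path, thermostat quiescent
  sim <- simulation_params(collision_rate = 0, duration_ns = nst * 1e-6,
                           snapshot_ps = nst * 1e-3, seed = 3)
  tr <- dendrisorb:::run_engine(conf, ff, sim, wall = NULL, vels = v0,
                                phase = "test", thermostat = FALSE)
  # R reference using the same force routine
  ref <- velocity_verlet(conf$coords, v0, topo$atoms$mass,
                         function(x) total_forces(as_conformation(topo, x), ff)$forces,
                         dt_fs = 1, nsteps = nst)
  expect_equal(tr$final_coords, unname(ref$coords), tolerance = 1e-10)
  expect_equal(tr$final_velocities, unname(ref$vels), tolerance = 1e-10)
})

test_that("trajectories are deterministic in the seed", {
  conf <- cached_conformation("S", 1)
  sim <- simulation_params(duration_ns = 0.005, seed = 11)
  t1 <- relax(conf, sim = sim)
  t2 <- relax(conf, sim = sim)
  expect_identical(t1$coords, t2$coords)
  t3 <- relax(conf, sim = simulation_params(duration_ns = 0.005, seed = 12))
  expect_false(identical(t1$final_coords, t3$final_coords))
})

test_that("collisional thermostat sweep conserves pair momentum and is inert at rate 0", {
  sim0 <- simulation_params(collision_rate = 0)
  v <- matrix(rnorm(30), 10, 3)
  m <- rep(14, 10)
  expect_identical(thermostat_collide(v, m, sim0, seed = 1), v)
  # v' - v = 2 m0/(m+m0) (u - v): recover the virtual-particle velocity u and
  # check the implied pair momentum change balances
  sim <- simulation_params(collision_rate = 400)
  set.seed(99)
  v2 <- thermostat_collide(v, m, sim, seed = 7)
  hit <- rowSums(v2 != v) > 0
  expect_gt(sum(hit), 0)
  m0 <- sim$thermostat_mass
  u <- v[hit, , drop = FALSE] +
    (v2[hit, , drop = FALSE] - v[hit, , drop = FALSE]) * (m[hit] + m0) / (2 * m0)
  dp_atom <- m[hit] * (v2[hit, , drop = FALSE] - v[hit, , drop = FALSE])
  u_after <- u - dp_atom / m0 # virtual particle recoil
  expect_equal(m[hit] * v[hit, , drop = FALSE] + m0 * u,
               m[hit] * v2[hit, , drop = FALSE] + m0 * u_after,
               tolerance = 1e-9)
})

test_that("thermostatted dynamics hold the target temperature and Maxwell statistics", {
  conf <- cached_conformation("S", 1)
  tr <- relax(conf, sim = simulation_params(duration_ns = 0.25, seed = 9,
                                            snapshot_ps = 1))
  Tt <- tr$energies[-(1:50), "temperature"]
  se <- sd(Tt) / sqrt(length(Tt))
  expect_lt(abs(mean(Tt) - 350), 3 * se + 1e-9)
  # velocity components scaled by sqrt(m) are N(0, sqrt(kB T)) in energy units
  tr2 <- relax(conf, sim = simulation_params(duration_ns = 0.1, seed = 10,
                                             snapshot_ps = 0.5),
               record_velocities = TRUE)
  keep <- seq(41, n_frames(tr2))
  x <- sweep(tr2$velocities[, , keep], 1, sqrt(conf$topology$atoms$mass), "*")
  x <- as.vector(x) / sqrt(KB * 350 * ECONV)
  expect_equal(sd(x), 1, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(x, "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("free dynamics conserve energy without a thermostat", {
  ff <- default_forcefield()
  conf <- cached_conformation("C4", 1)
  eq <- final_conformation(relax(conf, ff, simulation_params(duration_ns = 0.005,
                                                             seed = 2)))
  sim <- simulation_params(collision_rate = 0, duration_ns = 0.01,
                           snapshot_ps = 0.1, seed = 3)
  tr <- dendrisorb:::run_engine(eq, ff, sim, wall = NULL,
                                vels = maxwell_velocities(conf$topology$atoms$mass,
                                                          350, 3),
                                phase = "nve", thermostat = FALSE)
  E <- rowSums(tr$energies[, 1:7])
  drift <- abs(mean(tail(E, 10)) - mean(head(E, 10)))
  expect_lt(drift, 1e-3 * tr$energies[1, "KE"])
})

test_that("relaxation reaches a gyration plateau", {
  conf <- cached_conformation("C4", 2)
  tr <- relax(conf, sim = simulation_params(duration_ns = 0.06, seed = 21))
  rg <- vapply(seq_len(n_frames(tr)), function(i) {
    radius_of_gyration(tr$coords[, , i], conf$topology$atoms$mass)
  }, numeric(1))
  last3 <- tail(rg, ceiling(length(rg) / 3))
  # no monotone drift over the last third: trend small vs fluctuation
  fit <- coef(lm(last3 ~ seq_along(last3)))[2]
  expect_lt(abs(fit * length(last3)), 4 * sd(last3))
})

test_that("adsorption runs start at the configured gap with a seeded orientation", {
  conf <- cached_conformation("C4", 2, seed = 2)
  eq <- final_conformation(relax(conf, sim = simulation_params(duration_ns = 0.01,
                                                               seed = 4)))
  w <- wall_params(3)
  sim <- simulation_params(duration_ns = 0.002, seed = 5)
  t1 <- adsorb(eq, wall = w, sim = sim)
  t2 <- adsorb(eq, wall = w, sim = sim)
  expect_identical(t1$coords, t2$coords)           # same seed, same orientation
  expect_equal(min(t1$coords[, 3, 1]), 5)          # initial gap
  t3 <- adsorb(eq, wall = w, sim = sim, initial_gap = 8)
  expect_equal(min(t3$coords[, 3, 1]), 8)
  t4 <- adsorb(eq, wall = w, sim = simulation_params(duration_ns = 0.002, seed = 6))
  expect_false(identical(t1$coords[, , 1], t4$coords[, , 1]))
})

test_that("a zero-strength wall exerts no force on the trajectory", {
  conf <- cached_conformation("S", 2)
  eq <- final_conformation(relax(conf, sim = simulation_params(duration_ns = 0.01,
                                                               seed = 7)))
  tr <- adsorb(eq, wall = wall_params(0), sim = simulation_params(duration_ns = 0.01,
                                                                  seed = 8))
  expect_true(all(tr$energies[, "U_ads"] == 0))
  # identical to the same run with no wall at all
  conf0 <- final_conformation(tr) # reuse topology
  x0 <- tr$coords[, , 1]
  v0 <- maxwell_velocities(conf$topology$atoms$mass, 350, 8 + 1L)
  start <- as_conformation(conf$topology, x0)
  free <- dendrisorb:::run_engine(start, default_forcefield(),
                                  simulation_params(duration_ns = 0.01, seed = 8),
                                  wall = NULL, vels = v0, phase = "free")
  expect_equal(free$final_coords, tr$final_coords, tolerance = 1e-12)
})

test_that("strong adsorption keeps the lowest atom inside the adsorption layer", {
  conf <- cached_conformation("C4", 2, seed = 3)
  eq <- final_conformation(relax(conf, sim = simulation_params(duration_ns = 0.02,
                                                               seed = 14)))
  tr <- adsorb(eq, wall = wall_params(3), sim = simulation_params(duration_ns = 0.08,
                                                                  seed = 15))
  minz <- vapply(production_frames(tr, 0.5), function(i) min(tr$coords[, 3, i]),
                 numeric(1))
  expect_true(all(minz > 0))
  expect_true(all(minz <= 5))
})
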