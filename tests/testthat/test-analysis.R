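make_layered_topo <- function() build_topology(dendrimer_spec("S", 2))

test_that("adsorbed atoms are counted with an inclusive 5 A boundary", {
  topo <- make_layered_topo()
  z <- rep(10, topo$N)
  z[1:3] <- c(3, 6, 10)
  coords <- cbind(0, 0, z)
  cr <- count_adsorbed(coords, topo)
  expect_identical(cr$M, 1L)
  # an atom exactly at z = 5.0 counts as adsorbed
  z[2] <- 5.0
  expect_identical(count_adsorbed(cbind(0, 0, z), topo)$M, 2L)
  # everything inside the layer
  all_in <- count_adsorbed(cbind(0, 0, rep(4, topo$N)), topo)
  expect_identical(all_in$M, topo$N)
  expect_equal(all_in$fraction, 1)
})

test_that("per-layer contact counts partition M", {
  topo <- make_layered_topo()
  set.seed(5)
  for (rep in 1:5) {
    coords <- cbind(rnorm(topo$N), rnorm(topo$N), runif(topo$N, 0, 12))
    cr <- count_adsorbed(coords, topo)
    expect_identical(sum(cr$per_layer$count), cr$M)
    expect_true(all(cr$per_layer$fraction >= 0 & cr$per_layer$fraction <= 1))
    expect_identical(sum(cr$per_layer$n_atoms), cr$N)
  }
})

test_that("layer contact fractions average over frames and stay in [0, 1]", {
  topo <- make_layered_topo()
  flat <- cbind(seq_len(topo$N), 0, rep(2, topo$N))
  high <- cbind(seq_len(topo$N), 0, rep(20, topo$N))
  tr <- fake_trajectory(topo, list(flat, high))
  lf <- layer_contact_fractions(tr)
  expect_equal(lf$fraction, rep(0.5, nrow(lf)))
  lf1 <- layer_contact_fractions(tr, frames = 1L)
  expect_equal(lf1$fraction, rep(1, nrow(lf1)))
})

test_that("the perpendicular profile integrates to the molecular mass", {
  topo <- make_layered_topo()
  mtot <- sum(topo$atoms$mass)
  set.seed(8)
  frames <- replicate(3, cbind(rnorm(topo$N), rnorm(topo$N),
                               runif(topo$N, 0.2, 18)), simplify = FALSE)
  tr <- fake_trajectory(topo, frames)
  for (dH in c(0.2, 0.1)) {
    prof <- density_perp(tr, dH = dH)
    expect_equal(sum(prof$rho) * dH, mtot, tolerance = 1e-9)
  }
  # one atom of mass m alone in a bin contributes m/dH
  single <- cbind(0, 0, c(0.1, rep(30, topo$N - 1L)))
  p1 <- density_perp(fake_trajectory(topo, list(single)), dH = 0.2)
  expect_equal(p1$rho[1], topo$atoms$mass[1] / 0.2)
  expect_equal(sum(p1$rho > 0), 2L)
})

test_that("the parallel profile integrates to the molecular mass and is flat for a disk", {
  topo <- make_layered_topo()
  mtot <- sum(topo$atoms$mass)
  set.seed(9)
  frames <- replicate(2, cbind(rnorm(topo$N, 0, 6), rnorm(topo$N, 0, 6),
                               runif(topo$N, 0, 5)), simplify = FALSE)
  tr <- fake_trajectory(topo, frames)
  prof <- density_parallel(tr, dR = 1)
  expect_equal(sum(prof$rho * prof$S), mtot, tolerance = 1e-9)

  # synthetic uniform disk of equal test masses -> flat profile
  topo_u <- make_layered_topo()
  topo_u$atoms$mass <- rep(1, topo_u$N)
  n <- 40000
  topo_big <- topo_u
  topo_big$N <- n
  topo_big$atoms <- topo_u$atoms[rep(1L, n), ]
  set.seed(10)
  r <- 10 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  disk <- cbind(r * cos(th), r * sin(th), 1)
  prof_d <- density_parallel(fake_trajectory(topo_big, list(disk)), dR = 1)
  inner <- prof_d$rho[prof_d$R_mid < 8]
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.15)

  # a single atom sits in the first annulus around the center of mass
  lone <- topo_u
  lone$N <- 1L
  lone$atoms <- lone$atoms[1L, ]
  p1 <- density_parallel(fake_trajectory(lone, list(matrix(c(3, 4, 1), 1))), dR = 1)
  expect_equal(p1$rho[1] * p1$S[1], 1)
})

test_that("shape metrics recover closed-form limits", {
  m <- rep(1, 4000)
  # all atoms coincident
  z0 <- shape_metrics(matrix(1.5, 4000, 3), m)
  expect_equal(z0$rg, 0)
  expect_equal(z0$asphericity, 0)
  expect_equal(z0$height, 0)
  # flat uniform disk: smallest eigenvalue 0, asphericity 1/4
  set.seed(11)
  r <- sqrt(runif(4000)); th <- runif(4000, 0, 2 * pi)
  disk <- cbind(10 * r * cos(th), 10 * r * sin(th), 0)
  sd_ <- shape_metrics(disk, m)
  expect_equal(sd_$eigenvalues[3], 0)
  expect_equal(sd_$asphericity, 0.25, tolerance = 0.02)
  expect_equal(sd_$height, 0)
  # isotropic cloud: three equal eigenvalues, asphericity ~ 0
  cloud <- matrix(rnorm(3 * 4000), ncol = 3)
  sc <- shape_metrics(cloud, m)
  expect_lt(diff(range(sc$eigenvalues)) / mean(sc$eigenvalues), 0.1)
  expect_lt(sc$asphericity, 0.01)
})

test_that("frontal projections select exactly the adsorption layer", {
  topo <- make_layered_topo()
  set.seed(12)
  coords <- cbind(rnorm(topo$N), rnorm(topo$N), runif(topo$N, 0, 15))
  tr <- fake_trajectory(topo, list(coords))
  pr <- frontal_projection(tr, frame = 1)
  cr <- count_adsorbed(coords, topo)
  expect_identical(nrow(pr), cr$M)
  expect_true(all(pr$z <= 5))
  # projected points are a subset of the frame coordinates
  expect_equal(as.matrix(pr[, c("x", "y", "z")]),
               unname(coords[pr$atom, ]), ignore_attr = TRUE)
  # empty adsorption layer -> empty projection
  none <- fake_trajectory(topo, list(cbind(0, 0, rep(30, topo$N))))
  expect_identical(nrow(frontal_projection(none, frame = 1)), 0L)
})

test_that("the energy audit reports per-atom means and percent changes", {
  topo <- make_layered_topo()
  mk <- function(vals) {
    tr <- fake_trajectory(topo, list(cbind(0, 0, rep(1, topo$N)),
                                     cbind(0, 0, rep(1, topo$N))))
    tr$energies[, names(vals)] <- matrix(vals, 2, length(vals), byrow = TRUE)
    tr
  }
  base <- c(U12 = 10, U13 = 20, U14 = 0, Uvw = -40, Uqq = 2, U_ads = 0)
  up <- base; up["U13"] <- 25; up["U_ads"] <- -60
  aud <- energy_audit(list(`0` = mk(base), `3` = mk(up)))
  expect_equal(aud$pct_change[aud$eps == 0 & aud$term == "U13"], 0)
  # (25 - 20)/|20| * 100
  expect_equal(aud$pct_change[aud$eps == 3 & aud$term == "U13"], 25)
  # negative reference: percent change uses |U_ref|
  expect_equal(aud$pct_change[aud$eps == 3 & aud$term == "Uvw"], 0)
  expect_true(is.na(aud$pct_change[aud$eps == 3 & aud$term == "U_ads"]))
  expect_equal(aud$per_atom[aud$eps == 3 & aud$term == "U13"], 25 / topo$N)
  # identical trajectories -> zero percent change everywhere (wall aside)
  aud0 <- energy_audit(list(`1` = mk(base), `2` = mk(base)))
  expect_true(all(aud0$pct_change[!is.na(aud0$pct_change)] == 0))
  expect_error(energy_audit(list(`1` = mk(base))), "at least two")
})

test_that("replica aggregation matches closed-form mean and SEM", {
  st <- replica_stats(c(4, 6))
  expect_equal(st$mean, 5)
  expect_equal(st$sem, sd(c(4, 6)) / sqrt(2)) # n-1 normalization
  expect_true(is.na(replica_stats(7)$sem))

  df <- data.frame(series = rep(c("S", "L"), each = 3),
                   eps = 3, replica = rep(1:3, 2),
                   M = c(10, 12, 14, 20, 22, 24))
  agg <- aggregate_replicas(df, c("series", "eps"), "M")
  expect_equal(agg$mean[agg$series == "S"], 12)
  expect_equal(agg$mean[agg$series == "L"], 22)
  expect_equal(agg$n, c(3L, 3L))
  # invariant to replica order
  agg2 <- aggregate_replicas(df[sample(nrow(df)), ], c("series", "eps"), "M")
  expect_equal(agg, agg2)
})
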