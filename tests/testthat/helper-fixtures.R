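# Shared fixtures and independent oracles used across test files.

# hand-built minimal topologies (independent of build_topology) -------------

# two bonded CH3 united atoms ("ethane")
dimer_topology <- function() {
  structure(list(
    spec = dendrimer_spec("C4", 1),
    atoms = data.frame(id = 1:2, type = "CH3", element = "C",
                       mass = 15.035, charge = 0, layer = 0L,
                       role = c("core", "terminal"), depth = 0L,
                       parent = c(NA, 1L)),
    bonds = data.frame(i = 1L, j = 2L, type = "C-C"),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        type = character(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), type = character(0)),
    N = 2L), class = "molecular_topology")
}

# three-atom CH3-CH2-CH3 chain ("propane")
trimer_topology <- function() {
  structure(list(
    spec = dendrimer_spec("C4", 1),
    atoms = data.frame(id = 1:3, type = c("CH3", "CH2", "CH3"),
                       element = "C", mass = c(15.035, 14.027, 15.035),
                       charge = 0, layer = 0L,
                       role = c("core", "spacer", "terminal"), depth = 0L,
                       parent = c(NA, 1L, 2L)),
    bonds = data.frame(i = 1:2, j = 2:3, type = "C-C"),
    angles = data.frame(i = 1L, j = 2L, k = 3L, type = "C-C-C"),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), type = character(0)),
    N = 3L), class = "molecular_topology")
}

as_conformation <- function(topology, coords) {
  structure(list(topology = topology, coords = coords),
            class = "conformation")
}

# synthetic trajectory wrapping explicit frames (for analysis tests)
fake_trajectory <- function(topology, frames, times = seq_along(frames)) {
  coords <- array(NA_real_, c(topology$N, 3L, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]
  structure(list(topology = topology, times = as.numeric(times),
                 coords = coords,
                 energies = matrix(0, length(frames), 8L,
                                   dimnames = list(NULL,
                                     c("U12", "U13", "U14", "Uvw", "Uqq",
                                       "U_ads", "KE", "temperature"))),
                 provenance = list(phase = "synthetic")),
            class = "trajectory")
}

# brute-force oracle: count branch points / terminal groups by explicitly
# growing the branching tree, independently of the builder's bookkeeping
tree_census <- function(fc, G) {
  # each node is a branching point at depth k; grow recursively
  n_branch_at <- integer(G)
  n_terminal <- 0L
  grow <- function(depth) {
    n_branch_at[depth] <<- n_branch_at[depth] + 1L
    if (depth < G) {
      grow(depth + 1L); grow(depth + 1L)
    } else {
      n_terminal <<- n_terminal + 2L
    }
  }
  for (d in seq_len(fc)) grow(1L)
  list(branch_at = n_branch_at, terminals = n_terminal)
}

# brute-force O(N^2) non-bonded energy in plain R (truncated-and-shifted LJ
# and screened Coulomb, 1-2/1-3 excluded, 1-4 scaled), independent of the
# compiled kernels
nonbonded_oracle <- function(topology, coords, ff) {
  at <- topology$atoms
  lj <- ff$lj[at$type]
  epsv <- vapply(lj, `[[`, numeric(1), "eps")
  sigv <- vapply(lj, `[[`, numeric(1), "sigma")
  b <- topology$bonds; a <- topology$angles; d <- topology$dihedrals
  keyf <- function(i, j) paste(pmin(i, j), pmax(i, j))
  excl <- c(keyf(b$i, b$j), keyf(a$i, a$k))
  p14 <- if (nrow(d)) unique(keyf(d$i, d$l)) else character(0)
  p14 <- setdiff(p14, excl)
  rc <- ff$nonbonded_cutoff
  Uvw <- 0; Uqq <- 0
  for (i in seq_len(topology$N - 1L)) {
    for (j in (i + 1L):topology$N) {
      k <- keyf(i, j)
      if (k %in% excl) next
      slj <- 1; sqq <- 1
      if (k %in% p14) { slj <- ff$scale14$lj; sqq <- ff$scale14$qq }
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r > rc) next
      e <- sqrt(unname(epsv[i] * epsv[j])) * slj
      s <- 0.5 * unname(sigv[i] + sigv[j])
      Uvw <- Uvw + 4 * e * ((s / r)^12 - (s / r)^6) -
        4 * e * ((s / rc)^12 - (s / rc)^6)
      qi <- at$charge[i]; qj <- at$charge[j]
      if (qi != 0 && qj != 0) {
        Uqq <- Uqq + ff$coulomb$coupling * qi * qj * sqq /
          ff$coulomb$dielectric_slope * (1 / r^2 - 1 / rc^2)
      }
    }
  }
  list(Uvw = Uvw, Uqq = Uqq)
}

# quick embedded conformations, cached across test files
.fixture_cache <- new.env(parent = emptyenv())
cached_conformation <- function(series, generation, seed = 1L) {
  key <- sprintf("%s_%d_%d", series, generation, seed)
  if (is.null(.fixture_cache[[key]])) {
    topo <- build_topology(dendrimer_spec(series, generation))
    .fixture_cache[[key]] <- embed_3d(topo, seed = seed)
  }
  .fixture_cache[[key]]
}
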