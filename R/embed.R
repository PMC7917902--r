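## Initial 3D embedding: recursive geometric placement at equilibrium bond
## lengths and angles with randomized torsions, followed by steepest-descent
## relaxation until the conformation is clash-free.

angle_key_of <- function(e1, ec, e2) {
  s <- sort(c(e1, e2))
  paste(s[1], ec, s[2], sep = "-")
}

ff_bond_length <- function(ff, e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  p <- ff$bonds[[key]]
  if (is.null(p)) stop("no bond parameters for ", key)
  p$b0
}

ff_angle_theta <- function(ff, e1, ec, e2) {
  p <- ff$angles[[angle_key_of(e1, ec, e2)]]
  if (is.null(p)) 109.47 * pi / 180 else p$theta0 * pi / 180
}

## place atom bonded to C with bond length r, angle d-c-b = theta and
## torsion d-c-b-a = phi (natural-extension reference frame)
nerf_place <- function(a, b, cc, r, theta, phi) {
  bc <- cc - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) { # collinear reference; pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- cross3(ref, bc); nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  cc + d[1] * bc + d[2] * m + d[3] * n
}

place_initial <- function(topology, ff) {
  at <- topology$atoms
  N <- topology$N
  el <- at$element
  children <- split(which(!is.na(at$parent)), at$parent[!is.na(at$parent)])
  coords <- matrix(NA_real_, N, 3)
  coords[1L, ] <- 0

  ## random rigid frame for the core dendron directions (tetrahedral spread)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rot <- random_rotation()
  dirs <- tet %*% t(rot)

  core_children <- children[["1"]]
  for (idx in seq_along(core_children)) {
    ch <- core_children[idx]
    r <- ff_bond_length(ff, el[1L], el[ch])
    coords[ch, ] <- coords[1L, ] + r * dirs[idx, ]
  }

  ## breadth-first placement; siblings take torsions offset by 2*pi/3
  ord <- order(at$id)
  for (p in ord) {
    kids <- children[[as.character(p)]]
    if (is.null(kids) || p == 1L) next
    gp <- at$parent[p]
    ggp <- if (is.na(at$parent[gp])) NULL else at$parent[gp]
    a <- if (is.null(ggp)) coords[gp, ] + rot %*% c(0.77, 0.62, -0.15) else coords[ggp, ]
    base <- stats::runif(1, 0, 2 * pi)
    for (idx in seq_along(kids)) {
      ch <- kids[idx]
      r <- ff_bond_length(ff, el[p], el[ch])
      theta <- ff_angle_theta(ff, el[gp], el[p], el[ch])
      phi <- base + (idx - 1L) * 2 * pi / 3 + stats::runif(1, -0.3, 0.3)
      coords[ch, ] <- nerf_place(as.numeric(a), coords[gp, ], coords[p, ],
                                 r, theta, phi)
    }
  }
  coords
}

random_rotation <- function() {
  ## uniform random rotation from a random unit quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Check conformation invariants
#'
#' Bonded distances must lie within `bond_tol` of their equilibrium lengths
#' and no non-bonded pair (beyond the 1-2/1-3/1-4 neighbourhood) may be closer
#' than `clash_factor` times its LJ contact distance.
#'
#' @param conf a `conformation`.
#' @param ff a `forcefield`.
#' @param bond_tol relative bond-length tolerance (default 0.10).
#' @param clash_factor fraction of the LJ sigma below which a pair counts as a
#'   clash (default 0.8).
#' @return list with logicals `bonds_ok`, `clash_free`, `ok` and diagnostics
#'   `max_bond_dev`, `min_contact_ratio`.
#' @export
check_conformation <- function(conf, ff = default_forcefield(),
                               bond_tol = 0.10, clash_factor = 0.8) {
  topo <- conf$topology
  x <- conf$coords
  bt <- lookup_or_stop(ff$bonds, topo$bonds$type, "bond")
  b0 <- vapply(bt, `[[`, numeric(1), "b0")
  d <- sqrt(rowSums((x[topo$bonds$i, , drop = FALSE] -
                     x[topo$bonds$j, , drop = FALSE])^2))
  max_dev <- max(abs(d - b0) / b0)

  pl <- nonbonded_pairlists(topo)
  near <- rbind(pl$excl, pl$pairs14)
  skip <- rep(FALSE, topo$N * (topo$N - 1) / 2)
  pr <- which(upper.tri(matrix(0, topo$N, topo$N)), arr.ind = TRUE)
  key <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (lo - 1) * topo$N + hi
  }
  skipkeys <- key(near[, 1L], near[, 2L])
  allkeys <- key(pr[, 1L], pr[, 2L])
  use <- !(allkeys %in% skipkeys)
  i <- pr[use, 1L]; j <- pr[use, 2L]
  sig <- vapply(ff$lj[topo$atoms$type], `[[`, numeric(1), "sigma")
  sij <- 0.5 * (sig[i] + sig[j])
  rij <- sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
  min_ratio <- min(rij / sij)

  list(bonds_ok = max_dev <= bond_tol,
       clash_free = min_ratio >= clash_factor,
       ok = max_dev <= bond_tol && min_ratio >= clash_factor,
       max_bond_dev = max_dev, min_contact_ratio = min_ratio)
}

#' Embed a topology in 3D
#'
#' Places atoms recursively at equilibrium bond lengths and angles with
#' randomized torsions (siblings spread by 120 degrees), then relaxes by
#' steepest descent until the conformation satisfies the bond-length and
#' clash invariants (see [check_conformation()]).  Deterministic for a fixed
#' seed; retries with fresh torsions up to `max_attempts` times.
#'
#' @param topology a `molecular_topology`.
#' @param seed integer RNG seed.
#' @param ff force field used for relaxation geometry.
#' @param max_attempts placement retries before giving up.
#' @return object of class `conformation`: list(`topology`, `coords` N x 3).
#' @export
embed_3d <- function(topology, seed = 1L, ff = default_forcefield(),
                     max_attempts = 8L) {
  sys <- ff_system(topology, ff)
  last <- NULL
  for (attempt in seq_len(max_attempts)) {
    coords <- with_seed(seed + 7919L * (attempt - 1L),
                        place_initial(topology, ff))
    res <- minimize_cpp(coords, sys, maxit = 1500L, ftol = 4.0, step0 = 0.05)
    conf <- structure(list(topology = topology, coords = res$coords),
                      class = "conformation")
    chk <- check_conformation(conf, ff)
    if (chk$ok) return(conf)
    last <- chk
  }
  stop(sprintf(paste0("embedding failed after %d attempts ",
                      "(max bond deviation %.3f, min contact ratio %.3f)"),
               max_attempts, last$max_bond_dev, last$min_contact_ratio))
}

#' Mass-weighted radius of gyration
#'
#' @param coords N x 3 coordinate matrix.
#' @param masses atomic masses (Da).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2L, com)^2)) / sum(masses))
}

#' @export
print.conformation <- function(x, ...) {
  rg <- radius_of_gyration(x$coords, x$topology$atoms$mass)
  cat(sprintf("conformation of %s G%d (%d atoms), Rg = %.2f A\n",
              x$topology$spec$series, x$topology$spec$generation,
              x$topology$N, rg))
  invisible(x)
}
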