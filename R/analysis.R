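## Adsorption observables: contact counts, layer-resolved contact fractions,
## density profiles, energy audit, shape metrics, projections, aggregation.

frame_indices <- function(traj, frames) {
  if (is.null(frames)) seq_len(n_frames(traj)) else frames
}

#' Count adsorbed atoms in one frame
#'
#' An atom is adsorbed when its height satisfies `z <= z_cut` (boundary
#' inclusive).  Counts are also partitioned by structural layer.
#'
#' @param coords N x 3 coordinate matrix (or a frame from [get_frame()]).
#' @param topology the matching `molecular_topology`.
#' @param z_cut adsorption-layer thickness in Angstrom (default 5).
#' @return object of class `contact_result`: `M`, `N`, `fraction` and a
#'   `per_layer` data frame (`layer`, `n_atoms`, `count`, `fraction`).
#' @export
count_adsorbed <- function(coords, topology, z_cut = 5) {
  if (is.list(coords)) coords <- coords$coords
  z <- coords[, 3L]
  adsorbed <- z <= z_cut
  layer <- topology$atoms$layer
  lev <- sort(unique(layer))
  n_at <- vapply(lev, function(k) sum(layer == k), integer(1))
  cnt <- vapply(lev, function(k) sum(adsorbed & layer == k), integer(1))
  structure(list(M = sum(adsorbed), N = topology$N,
                 fraction = sum(adsorbed) / topology$N, z_cut = z_cut,
                 per_layer = data.frame(layer = lev, n_atoms = n_at,
                                        count = cnt,
                                        fraction = cnt / n_at)),
            class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("contacts: M = %d of N = %d (M/N = %.3f) within z <= %g A\n",
              x$M, x$N, x$fraction, x$z_cut))
  invisible(x)
}

#' Time-averaged contact statistics
#'
#' @param traj an adsorption `trajectory`.
#' @param z_cut adsorption-layer thickness (Angstrom).
#' @param frames frame indices to average over (default: all; typically
#'   [production_frames()]).
#' @return list with `M` (mean adsorbed count), `fraction` (mean M/N), `N`
#'   and the per-frame counts `M_t`.
#' @export
contact_series <- function(traj, z_cut = 5, frames = NULL) {
  idx <- frame_indices(traj, frames)
  M_t <- vapply(idx, function(i) sum(traj$coords[, 3L, i] <= z_cut),
                integer(1))
  list(M = mean(M_t), fraction = mean(M_t) / traj$topology$N,
       N = traj$topology$N, M_t = M_t)
}

#' Layer-resolved contact fractions
#'
#' For each structural layer k, the time average of (adsorbed atoms in k) /
#' (atoms in k).
#'
#' @inheritParams contact_series
#' @return data frame with `layer`, `n_atoms`, `fraction`.
#' @export
layer_contact_fractions <- function(traj, z_cut = 5, frames = NULL) {
  idx <- frame_indices(traj, frames)
  layer <- traj$topology$atoms$layer
  lev <- sort(unique(layer))
  n_at <- vapply(lev, function(k) sum(layer == k), integer(1))
  acc <- numeric(length(lev))
  for (i in idx) {
    adsorbed <- traj$coords[, 3L, i] <= z_cut
    acc <- acc + vapply(seq_along(lev),
                        function(u) sum(adsorbed & layer == lev[u]),
                        integer(1))
  }
  data.frame(layer = lev, n_atoms = n_at,
             fraction = acc / (n_at * length(idx)))
}

#' Perpendicular density profile
#'
#' Mass-weighted linear density versus height above the plane:
#' `rho_perp(H) = sum_i n_i(H) m_i / dH`, averaged over frames.  The profile
#' integrates exactly to the molecular mass: `sum(rho) * dH = M_mol`.
#'
#' @param traj a `trajectory`.
#' @param dH slab width in Angstrom (default 0.2).
#' @param frames frame indices to average over.
#' @return data frame with bin centers `H` (Angstrom) and `rho` (Da/Angstrom);
#'   attribute `dH`.
#' @export
density_perp <- function(traj, dH = 0.2, frames = NULL) {
  if (dH <= 0) stop("dH must be > 0")
  idx <- frame_indices(traj, frames)
  mass <- traj$topology$atoms$mass
  zmax <- max(traj$coords[, 3L, idx])
  nbin <- max(1L, ceiling(zmax / dH + 1e-9))
  acc <- numeric(nbin)
  for (i in idx) {
    bin <- pmin(nbin, floor(traj$coords[, 3L, i] / dH) + 1L)
    acc <- acc + vapply(split(mass, factor(bin, levels = seq_len(nbin))),
                        sum, numeric(1))
  }
  out <- data.frame(H = (seq_len(nbin) - 0.5) * dH,
                    rho = acc / (dH * length(idx)))
  attr(out, "dH") <- dH
  out
}

#' Parallel (radial) density profile
#'
#' Mass-weighted areal density versus lateral distance R from the molecular
#' center of mass: `rho_par(R) = sum_i n_i(R) m_i / S_i` with annulus area
#' `S_i = pi ((R + dR)^2 - R^2)`.  The center of mass is recomputed for every
#' frame so lateral diffusion does not smear the profile.  The profile obeys
#' `sum(rho * S) = M_mol`.
#'
#' @param traj a `trajectory`.
#' @param dR annulus width in Angstrom (default 1).
#' @param frames frame indices to average over.
#' @return data frame with inner radius `R`, bin center `R_mid`, annulus area
#'   `S` and `rho` (Da/Angstrom^2); attribute `dR`.
#' @export
density_parallel <- function(traj, dR = 1, frames = NULL) {
  if (dR <= 0) stop("dR must be > 0")
  idx <- frame_indices(traj, frames)
  mass <- traj$topology$atoms$mass
  mtot <- sum(mass)
  ## lateral distances from the instantaneous center of mass
  rmax <- 0
  rlist <- vector("list", length(idx))
  for (u in seq_along(idx)) {
    xy <- matrix(traj$coords[, 1:2, idx[u]], ncol = 2L)
    com <- colSums(xy * mass) / mtot
    r <- sqrt((xy[, 1L] - com[1L])^2 + (xy[, 2L] - com[2L])^2)
    rlist[[u]] <- r
    rmax <- max(rmax, max(r))
  }
  nbin <- max(1L, ceiling(rmax / dR + 1e-9))
  acc <- numeric(nbin)
  for (r in rlist) {
    bin <- pmin(nbin, floor(r / dR) + 1L)
    acc <- acc + vapply(split(mass, factor(bin, levels = seq_len(nbin))),
                        sum, numeric(1))
  }
  Rin <- (seq_len(nbin) - 1L) * dR
  S <- pi * ((Rin + dR)^2 - Rin^2)
  out <- data.frame(R = Rin, R_mid = Rin + dR / 2, S = S,
                    rho = acc / (S * length(idx)))
  attr(out, "dR") <- dR
  out
}

#' Per-atom energy audit across adsorption strengths
#'
#' Averages each potential-energy term per atom over the chosen frames for a
#' set of trajectories keyed by the wall energy parameter epsilon, and
#' reports the percent change of each force-field term relative to a
#' reference epsilon: `(U_eps - U_ref) / |U_ref| * 100`.  The wall term is
#' listed but excluded from the percent comparison.
#'
#' @param trajs named list of trajectories; names are epsilon values
#'   (kcal/mol).
#' @param reference reference epsilon (default: the smallest present,
#'   typically an unadsorbed run).
#' @param frames frame indices averaged in every trajectory (default: all).
#' @return data frame with `eps`, `term`, `per_atom` (kcal/mol/atom) and
#'   `pct_change` (NA for the wall term).
#' @export
energy_audit <- function(trajs, reference = NULL, frames = NULL) {
  if (length(trajs) < 2L) stop("need at least two epsilon values")
  eps <- as.numeric(names(trajs))
  if (anyNA(eps)) stop("trajectory list must be named by epsilon values")
  if (is.null(reference)) reference <- min(eps)
  if (!any(abs(eps - reference) < 1e-12)) stop("missing reference epsilon")
  terms <- c("U12", "U13", "U14", "Uvw", "Uqq", "U_ads")
  per_atom <- t(vapply(trajs, function(tr) {
    idx <- frame_indices(tr, frames)
    colMeans(tr$energies[idx, terms, drop = FALSE]) / tr$topology$N
  }, numeric(length(terms))))
  iref <- which.min(abs(eps - reference))
  out <- do.call(rbind, lapply(seq_along(eps), function(u) {
    ref <- per_atom[iref, ]
    pct <- ifelse(terms == "U_ads" | abs(ref) < 1e-12, NA_real_,
                  (per_atom[u, ] - ref) / abs(ref) * 100)
    data.frame(eps = eps[u], term = terms, per_atom = per_atom[u, ],
               pct_change = pct, row.names = NULL)
  }))
  out[order(out$eps, out$term), ]
}

#' Gyration-based shape metrics
#'
#' Mass-weighted gyration tensor eigenvalues, radius of gyration,
#' perpendicular extent, lateral radius and relative asphericity
#' (0 for a sphere, 1/4 for a flat disk, 1 for a rod).
#'
#' @param coords N x 3 coordinate matrix or a frame from [get_frame()].
#' @param masses atomic masses (Da).
#' @return list with `eigenvalues` (descending, Angstrom^2), `rg`, `height`
#'   (max z - min z), `lateral_radius` (sqrt of the in-plane tensor trace) and
#'   `asphericity`.
#' @export
shape_metrics <- function(coords, masses) {
  if (is.list(coords)) coords <- coords$coords
  mtot <- sum(masses)
  com <- colSums(coords * masses) / mtot
  d <- sweep(coords, 2L, com)
  gyr <- crossprod(d * masses, d) / mtot
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tr <- sum(ev)
  asph <- if (tr > 0) {
    ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2) / (2 * tr^2)
  } else 0
  list(eigenvalues = ev,
       rg = sqrt(tr),
       height = max(coords[, 3L]) - min(coords[, 3L]),
       lateral_radius = sqrt(gyr[1L, 1L] + gyr[2L, 2L]),
       asphericity = asph)
}

#' Frontal projection of the adsorption layer
#'
#' In-plane coordinates of the adsorbed atoms (z <= z_cut) tagged by
#' structural layer, for top-view renderings of which layers touch the
#' surface.
#'
#' @param traj a `trajectory`.
#' @param frame frame index (default: last).
#' @param z_cut adsorption-layer thickness (Angstrom).
#' @return data frame with `x`, `y`, `z`, `layer`, `atom`.
#' @export
frontal_projection <- function(traj, frame = n_frames(traj), z_cut = 5) {
  x <- traj$coords[, , frame]
  sel <- which(x[, 3L] <= z_cut)
  data.frame(x = x[sel, 1L], y = x[sel, 2L], z = x[sel, 3L],
             layer = traj$topology$atoms$layer[sel], atom = sel)
}

#' Mean and standard error over replicas
#'
#' @param values numeric vector of per-replica values.
#' @return list with `mean`, `sem` (n-1 normalization; NA for a single
#'   replica) and `n`.
#' @export
replica_stats <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Aggregate per-replica observations
#'
#' Collapses a long table of per-replica values to means and standard errors
#' within groups; the result is invariant to replica order.
#'
#' @param df data frame of per-replica rows.
#' @param by character vector of grouping columns.
#' @param value name of the value column.
#' @return data frame with the grouping columns plus `mean`, `sem`, `n`.
#' @export
aggregate_replicas <- function(df, by, value) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  parts <- split(df, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    st <- replica_stats(p[[value]])
    cbind(p[1L, by, drop = FALSE],
          data.frame(mean = st$mean, sem = st$sem, n = st$n))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
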