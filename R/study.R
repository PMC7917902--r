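## Study orchestration: build -> relax -> epsilon-sweep adsorption runs x
## replicas -> per-run observables, from a single configuration.

#' Epsilon schedule used throughout the study
#'
#' 0 to 1 kcal/mol in steps of 0.2, then 1 to 3 kcal/mol in steps of 0.5
#' (deduplicated, sorted).
#' @return numeric vector of epsilon values.
#' @export
epsilon_schedule <- function() {
  sort(unique(c(seq(0, 1, by = 0.2), seq(1, 3, by = 0.5))))
}

#' Study configuration
#'
#' Defaults describe the desk-scale protocol (low generations, 3 replicas,
#' 0.25 ns adsorption runs with the trailing 0.2 ns as production window); the
#' full-scale protocol (G4-G7, 8 replicas, 20 ns trajectories averaged over
#' the last 5 ns) is reached by overriding the corresponding fields.
#'
#' @param series dendrimer series to run.
#' @param generations generations to run.
#' @param eps epsilon schedule in kcal/mol (non-negative; sorted and
#'   deduplicated).
#' @param replicas independent realizations per condition (>= 1).
#' @param relax_ns free-relaxation length (ns).
#' @param adsorb_ns adsorption-run length (ns).
#' @param production_fraction trailing fraction of the adsorption run used
#'   for averaging.
#' @param timestep_fs,temperature,thermostat_mass,collision_rate,snapshot_ps
#'   see [simulation_params()].
#' @param z_cut adsorption-layer thickness (Angstrom).
#' @param dH,dR density-profile bin widths (Angstrom).
#' @param wall_r_min,wall_cutoff wall-potential geometry (Angstrom).
#' @param master_seed master seed; per-run seeds are derived from it with
#'   [seed_for_run()].
#' @param output_dir directory for result tables, or `NULL` to keep results
#'   in memory only.
#' @return object of class `study_config`.
#' @export
study_config <- function(series = DENDRIMER_SERIES,
                         generations = 2:3,
                         eps = c(0.4, 1.5, 3.0),
                         replicas = 3L,
                         relax_ns = 0.02,
                         adsorb_ns = 0.25,
                         production_fraction = 0.8,
                         timestep_fs = 1,
                         temperature = 350,
                         thermostat_mass = 1,
                         collision_rate = 55,
                         snapshot_ps = 1,
                         z_cut = 5,
                         dH = 0.2,
                         dR = 1,
                         wall_r_min = 3,
                         wall_cutoff = 130,
                         master_seed = 1L,
                         output_dir = NULL) {
  problems <- character(0)
  if (!all(series %in% DENDRIMER_SERIES)) {
    problems <- c(problems, paste("unknown series:",
                                  paste(setdiff(series, DENDRIMER_SERIES),
                                        collapse = ", ")))
  }
  if (any(eps < 0)) problems <- c(problems, "epsilon values must be >= 0")
  if (replicas < 1) problems <- c(problems, "replicas must be >= 1")
  if (any(generations < 1)) problems <- c(problems, "generations must be >= 1")
  if (production_fraction <= 0 || production_fraction > 1) {
    problems <- c(problems, "production_fraction must be in (0, 1]")
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  structure(list(
    series = series, generations = sort(unique(as.integer(generations))),
    eps = sort(unique(eps)), replicas = as.integer(replicas),
    relax_ns = relax_ns, adsorb_ns = adsorb_ns,
    production_fraction = production_fraction,
    timestep_fs = timestep_fs, temperature = temperature,
    thermostat_mass = thermostat_mass, collision_rate = collision_rate,
    snapshot_ps = snapshot_ps, z_cut = z_cut, dH = dH, dR = dR,
    wall_r_min = wall_r_min, wall_cutoff = wall_cutoff,
    master_seed = as.integer(master_seed), output_dir = output_dir),
    class = "study_config")
}

#' Load and validate a study configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are a hard error, and all
#' schema violations are reported together.
#'
#' @param path YAML file (an empty file yields the full default study with
#'   the canonical epsilon schedule).
#' @return a `study_config`.
#' @export
validate_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(obj$eps)) obj$eps <- epsilon_schedule()
  if (is.null(obj$generations)) obj$generations <- 4:7
  if (is.null(obj$replicas)) obj$replicas <- 8L
  do.call(study_config, obj)
}

#' Derive a reproducible per-run seed
#'
#' Mixes the master seed with the run coordinates (series, generation,
#' epsilon, replica) through a polynomial rolling hash so replicas and
#' conditions get independent, reproducible streams.  Always below 2^31.
#'
#' @param master master seed.
#' @param series series code.
#' @param generation generation.
#' @param eps epsilon (kcal/mol); use `NA` for the shared relaxation stage.
#' @param replica replica index.
#' @return integer seed.
#' @export
seed_for_run <- function(master, series, generation, eps, replica) {
  tag <- sprintf("%s|G%d|eps%.3f|rep%d", series, generation,
                 ifelse(is.na(eps), -1, eps), replica)
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 2147483647
  as.integer(max(1, h))
}

#' Run the full adsorption study
#'
#' For every series x generation x replica: build the topology, embed and
#' relax once, then run one adsorption trajectory per epsilon from the shared
#' equilibrated conformation.  Per-run observables (production-window means)
#' are returned as tidy tables and, when `output_dir` is set, written as CSV;
#' completed per-condition tables found on disk are reused, making the study
#' resumable.
#'
#' @param config a [study_config()].
#' @param ff force field (default [default_forcefield()]).
#' @param verbose print progress lines.
#' @return list of data frames: `contacts` (one row per run: `series`,
#'   `generation`, `eps`, `replica`, `seed`, `N`, `M`, `fraction`), `layers`
#'   (per-run per-layer contact fractions) and `energies` (per-run per-term
#'   per-atom means).
#' @export
run_study <- function(config, ff = default_forcefield(), verbose = FALSE) {
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  contacts <- list(); layers <- list(); energies <- list()
  for (series in config$series) {
    for (gen in config$generations) {
      cond_tag <- sprintf("%s_G%d", series, gen)
      cache <- if (!is.null(out_dir)) {
        file.path(out_dir, paste0(cond_tag, c("_contacts.csv", "_layers.csv",
                                              "_energies.csv")))
      }
      if (!is.null(out_dir) && all(file.exists(cache))) {
        if (verbose) message("reusing completed condition ", cond_tag)
        contacts[[cond_tag]] <- utils::read.csv(cache[1])
        layers[[cond_tag]] <- utils::read.csv(cache[2])
        energies[[cond_tag]] <- utils::read.csv(cache[3])
        next
      }
      spec <- dendrimer_spec(series, gen)
      topo <- build_topology(spec)
      cc <- list(); ll <- list(); ee <- list()
      for (repl in seq_len(config$replicas)) {
        seed0 <- seed_for_run(config$master_seed, series, gen, NA, repl)
        conf <- embed_3d(topo, seed = seed0, ff = ff)
        relax_tr <- relax(conf, ff,
                          simulation_params(config$timestep_fs,
                                            config$temperature,
                                            config$thermostat_mass,
                                            config$collision_rate,
                                            duration_ns = config$relax_ns,
                                            snapshot_ps = config$snapshot_ps,
                                            seed = seed0))
        eq <- final_conformation(relax_tr)
        for (eps in config$eps) {
          seed <- seed_for_run(config$master_seed, series, gen, eps, repl)
          wall <- wall_params(eps, config$wall_r_min, config$wall_cutoff)
          tr <- adsorb(eq, ff, wall,
                       simulation_params(config$timestep_fs,
                                         config$temperature,
                                         config$thermostat_mass,
                                         config$collision_rate,
                                         duration_ns = config$adsorb_ns,
                                         snapshot_ps = config$snapshot_ps,
                                         seed = seed))
          idx <- production_frames(tr, config$production_fraction)
          cs <- contact_series(tr, config$z_cut, idx)
          lf <- layer_contact_fractions(tr, config$z_cut, idx)
          epa <- colMeans(tr$energies[idx, 1:6, drop = FALSE]) / topo$N
          meta <- data.frame(series = series, generation = gen, eps = eps,
                             replica = repl, seed = seed)
          cc[[length(cc) + 1L]] <- cbind(meta, data.frame(
            N = topo$N, M = cs$M, fraction = cs$fraction))
          ll[[length(ll) + 1L]] <- merge(meta, lf)
          ee[[length(ee) + 1L]] <- cbind(
            meta[rep(1L, 6L), ],
            data.frame(term = names(epa), per_atom = as.numeric(epa)))
          if (verbose) {
            message(sprintf("%s rep %d eps %.1f: M = %.1f (M/N = %.3f)",
                            cond_tag, repl, eps, cs$M, cs$fraction))
          }
        }
      }
      contacts[[cond_tag]] <- do.call(rbind, cc)
      layers[[cond_tag]] <- do.call(rbind, ll)
      energies[[cond_tag]] <- do.call(rbind, ee)
      if (!is.null(out_dir)) {
        utils::write.csv(contacts[[cond_tag]], cache[1], row.names = FALSE)
        utils::write.csv(layers[[cond_tag]], cache[2], row.names = FALSE)
        utils::write.csv(energies[[cond_tag]], cache[3], row.names = FALSE)
      }
    }
  }
  res <- list(contacts = do.call(rbind, unname(contacts)),
              layers = do.call(rbind, unname(layers)),
              energies = do.call(rbind, unname(energies)))
  rownames(res$contacts) <- rownames(res$layers) <- rownames(res$energies) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(res$contacts, file.path(out_dir, "contacts.csv"),
                     row.names = FALSE)
    utils::write.csv(res$layers, file.path(out_dir, "layers.csv"),
                     row.names = FALSE)
    utils::write.csv(res$energies, file.path(out_dir, "energies.csv"),
                     row.names = FALSE)
  }
  res
}
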