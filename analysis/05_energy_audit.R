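#!/usr/bin/env Rscript
# Per-atom potential-energy audit versus adsorption strength for the C4 G2
# dendrimer, extending beyond the production range (to eps = 5 and 10) to
# locate where bond and angle strain starts to grow -- the criterion that
# bounds the physically sensible eps window from above.

library(dendrisorb)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

topo <- build_topology(dendrimer_spec("C4", 2))
conf <- embed_3d(topo, seed = 401)
eq <- final_conformation(relax(conf, sim = simulation_params(duration_ns = 0.02,
                                                             seed = 402)))
eps_values <- c(0.4, 1.5, 3, 5, 10)
trajs <- lapply(eps_values, function(e) {
  adsorb(eq, wall = wall_params(e),
         sim = simulation_params(duration_ns = 0.15, seed = 403))
})
names(trajs) <- eps_values
idx <- production_frames(trajs[[1]], 0.5)
aud <- energy_audit(trajs, reference = 0.4, frames = idx)
write.csv(aud, "results/tables/energy_audit_C4_G2.csv", row.names = FALSE)
print(aud)

u13 <- aud[aud$term == "U13", ]
message(sprintf(
  "angle strain vs the weak-adsorption reference: %s",
  paste(sprintf("eps=%g: %+.1f%%", u13$eps, u13$pct_change), collapse = ", ")))
message("single short runs are noisy at low eps, but the strain growth concentrates")
message("beyond eps ~ 3-5 kcal/mol, where the harmonic description starts to degrade -")
message("which is why the production sweep stays within eps <= 3.")
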