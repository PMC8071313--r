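#!/usr/bin/env Rscript
# Stage 2: design the twelve seed mixtures from the simulated species pool.
# For each community type (mesic, wet) and each ordered pair of distinct
# traits, abundances maximize Rao's Q on the diversified trait while the
# community-weighted mean of the constrained trait is pinned to the invader's
# value. Reads the stage-1 artifacts; rewrites the mixture tables under
# results/design so this stage can be re-run in isolation.
#
# Usage: Rscript analysis/02_design_mixtures.R

suppressPackageStartupMessages(library(traitmix))

in_dir <- "results/simulation"
out_dir <- "results/design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

species <- load_species_table(file.path(in_dir, "species.csv"))
invader <- load_invader_record(file.path(in_dir, "invader.csv"))
mesic <- species[species$community == "mesic" & species$in_design_pool, ]
wet <- species[species$community == "wet" & species$in_design_pool, ]

designs <- build_all_mixtures(mesic, wet, invader)
smry <- design_summary(designs)
write.csv(design_abundances(designs), file.path(out_dir, "mixtures.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(smry, file.path(out_dir, "design_summary.csv"),
          row.names = FALSE, quote = FALSE)

cat(sprintf("designed %d mixtures (%d feasible):\n", nrow(smry),
            sum(smry$solver_status != "infeasible")))
print(smry, row.names = FALSE)
cat(sprintf("\nachieved Rao's Q: %.3f (min) .. %.3f (max); worst residual %.1e\n",
            min(smry$rao_q), max(smry$rao_q), max(smry$constraint_residual)))

# sowing plan for the first mixture, at the study densities
d1 <- designs[[1]]
sm <- species$seed_mass_mg[match(d1$species_ids, species$species_id)]
plan <- sowing_plan(d1, sm)
cat(sprintf("\nsowing plan for %s (3 g/m2 native, 1 g/m2 invader, %.4f m2 tray):\n",
            d1$mixture_code, attr(plan, "tray_area_m2")))
print(plan, row.names = FALSE, digits = 3)
write.csv(plan, file.path(out_dir, "sowing_plan_example.csv"),
          row.names = FALSE, quote = FALSE)
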