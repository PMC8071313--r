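test_that("generated pools match the study layout and are deterministic", {
  cfg <- generator_config()
  pool <- generate_pool(cfg, seed = 100)
  expect_equal(nrow(pool$species), 36)
  expect_equal(length(unique(pool$species$family)), 15)
  expect_true(validate_species_table(pool$species) |> is.data.frame())
  # both design pools carry 3 grasses + 5 forbs
  for (comm in c("mesic", "wet")) {
    dp <- pool$species[pool$species$community == comm & pool$species$in_design_pool, ]
    expect_equal(sum(dp$growth_form == "grass"), 3)
    expect_equal(sum(dp$growth_form == "forb"), 5)
  }
  pool2 <- generate_pool(cfg, seed = 100)
  expect_identical(pool, pool2)
  expect_false(identical(pool, generate_pool(cfg, seed = 101)))
})

test_that("invader traits sit inside both design pools' ranges", {
  cfg <- generator_config()
  for (seed in seq(1, 200, by = 10)) {
    pool <- generate_pool(cfg, seed = seed)
    pools <- split(pool$species[pool$species$in_design_pool, ],
                   pool$species$community[pool$species$in_design_pool])
    for (col in c("height_m", "leaf_area_mm2", "seed_mass_mg")) {
      for (pl in pools) {
        expect_gt(pool$invader[[col]], min(pl[[col]]))
        expect_lt(pool$invader[[col]], max(pl[[col]]))
      }
    }
  }
})

test_that("random phylogenies preserve labels and cluster families", {
  cfg <- generator_config()
  pool <- generate_pool(cfg, seed = 7)
  tree <- generate_tree(pool$species, seed = 8)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, pool$species$species_id)
  expect_true(all(tree$edge.length > 0))
  expect_true(ape::is.rooted(tree))
  expect_identical(ape::write.tree(generate_tree(pool$species, seed = 8)),
                   ape::write.tree(tree))

  dm <- ape::cophenetic.phylo(tree)
  fam <- pool$species$family[match(rownames(dm), pool$species$species_id)]
  same <- outer(fam, fam, "==") & upper.tri(dm)
  diff <- outer(fam, fam, "!=") & upper.tri(dm)
  expect_lt(mean(dm[same]), mean(dm[diff]))
})

test_that("a full experiment has the study dimensions and fixed-seed identity", {
  cfg <- generator_config()
  ex <- generate_experiment(cfg, seed = 42)
  expect_equal(nrow(ex$observations), 252)  # 14 mixtures x 6 trays x 3 periods
  expect_equal(length(ex$designs), 14)
  expect_equal(nrow(ex$summaries), 39)      # 13 native communities x 3 periods
  expect_equal(sort(unique(ex$observations$community_type)),
               sort(c("mesic", "wet", "reference_LfL", "monoculture")))
  smry <- design_summary(ex$designs[!names(ex$designs) %in% c("LfL", "Mono")])
  expect_true(all(smry$solver_status == "optimal"))
  expect_true(all(smry$constraint_residual <= 1e-6))

  ex2 <- generate_experiment(cfg, seed = 42)
  expect_identical(ex$observations, ex2$observations)
  expect_identical(ape::write.tree(ex$tree), ape::write.tree(ex2$tree))
})

test_that("monoculture invader biomass is the largest in every period", {
  ex <- generate_experiment(generator_config(), seed = 9)
  obs <- standardize_per_week(ex$observations)
  means <- aggregate(invader_pw ~ mixture_code + period, data = obs, FUN = mean)
  for (k in 1:3) {
    mk <- means[means$period == k, ]
    expect_identical(mk$mixture_code[which.max(mk$invader_pw)], "Mono")
  }
  # commercial reference has the highest native biomass
  nat <- aggregate(native_pw ~ mixture_code, data = obs, FUN = mean)
  expect_identical(nat$mixture_code[which.max(nat$native_pw)], "LfL")
})

test_that("stronger native suppression lowers mean invader biomass", {
  grid <- c(-0.1, -0.4, -0.8)
  means <- vapply(grid, function(b) {
    cfg <- generator_config(beta = c(native = b, seed_mass = 0.25,
                                     leaf_area = -0.15, height = 0, pd = 0.2))
    ex <- generate_experiment(cfg, seed = 333)
    obs <- ex$observations
    designed <- obs$community_type %in% c("mesic", "wet")
    mean(obs$invader_biomass_g[designed] / obs$weeks[designed])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("experiment artifacts round-trip through plain-text files", {
  ex <- generate_experiment(generator_config(replicates = 2), seed = 3)
  dir <- withr::local_tempdir()
  files <- write_experiment(ex, dir)
  expect_true(all(file.exists(files)))
  back_species <- load_species_table(file.path(dir, "species.csv"))
  expect_equal(back_species$species_id, ex$species$species_id)
  back_tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(back_tree$tip.label, ex$tree$tip.label)
  back_obs <- read.csv(file.path(dir, "observations.csv"))
  expect_equal(nrow(back_obs), nrow(ex$observations))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$beta$native, ex$ground_truth$beta$native)
})

test_that("generator configuration rejects invalid study conditions", {
  expect_error(generator_config(n_species = 10), class = "traitmix_validation_error")
  expect_error(generator_config(n_species = 17), class = "traitmix_validation_error")
  expect_error(generator_config(sigma = 0), class = "traitmix_validation_error")
  expect_error(generator_config(beta = c(native = -1)), class = "traitmix_validation_error")
  expect_error(generator_config(cutting_weights = rep(1, 5)),
               class = "traitmix_validation_error")
})
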