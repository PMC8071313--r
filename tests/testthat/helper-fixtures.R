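# Fixtures built in code: tiny species pools, toy trees, and small
# observation tables used across the suite.

toy_species <- function(n = 8, seed = 101, growth_form = NULL) {
  set.seed(seed)
  if (is.null(growth_form))
    growth_form <- rep(c("grass", "forb"), length.out = n)
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    family = sprintf("f%02d", rep(seq_len(max(2, n %/% 2)), length.out = n)),
    growth_form = growth_form,
    height_m = exp(rnorm(n, log(0.5), 0.5)),
    leaf_area_mm2 = exp(rnorm(n, log(600), 1)),
    seed_mass_mg = exp(rnorm(n, log(1), 1)),
    germination_rate = runif(n, 0.3, 0.9),
    cutting_tolerance = sample(1:9, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

toy_invader <- function(species) {
  data.frame(
    species_id = "invader",
    height_m = exp(mean(log(species$height_m))),
    leaf_area_mm2 = exp(mean(log(species$leaf_area_mm2))),
    seed_mass_mg = exp(mean(log(species$seed_mass_mg))),
    stringsAsFactors = FALSE
  )
}

balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# small observation table: k mixtures x reps trays x 3 periods
toy_observations <- function(k = 3, reps = 4, means = rep(1, k), sd = 0.2,
                             seed = 11) {
  set.seed(seed)
  weeks <- c(10, 15, 22)
  codes <- sprintf("MX%02d", seq_len(k))
  rows <- expand.grid(rep = seq_len(reps), mixture_code = codes,
                      period = 1:3, stringsAsFactors = FALSE)
  rows$tray_id <- sprintf("%s-r%d", rows$mixture_code, rows$rep)
  rows$weeks <- weeks[rows$period]
  mu <- means[match(rows$mixture_code, codes)]
  rows$native_biomass_g <- pmax(0, rnorm(nrow(rows), 1.3, 0.3)) * rows$weeks
  rows$invader_biomass_g <- pmax(0, rnorm(nrow(rows), mu, sd)) * rows$weeks
  rows$community_type <- "mesic"
  rows[, c("tray_id", "mixture_code", "community_type", "period", "weeks",
           "native_biomass_g", "invader_biomass_g")]
}

# brute-force double-loop Rao Q, independent of the package implementation
rao_q_loop <- function(p, d) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) q <- q + p[i] * p[j] * d[i, j]
  q
}
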