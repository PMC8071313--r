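# Synthetic-experiment generator. The greenhouse data behind the study are
# not deposited in a machine-readable archive, so this module emulates the
# study conditions end to end: a 36-species pool in 15 families split between
# a mesic and a wet community, a family-clustered random phylogeny, the twelve
# designed mixtures plus the two reference communities (a grass-dominated
# commercial mixture and an invader monoculture), and tray-level biomass whose
# effect-sign structure matches the reported results (native biomass -, CWM
# seed mass +, CWM leaf area -, PD + in period 1 only, CWM height 0).

#' Generator configuration
#'
#' Defaults reproduce the study layout (36 species, 15 families, 6 replicates,
#' periods of 10/15/22 weeks, 3 grasses + 5 forbs per designed mixture) and
#' the reported effect signs; effect magnitudes and noise levels are generator
#' choices on the g/week scale, documented in the methods vignette.
#'
#' @param n_species pool size (>= 16, even; split equally between mesic and
#'   wet).
#' @param n_families number of plant families in the pool.
#' @param replicates trays per mixture.
#' @param period_weeks weeks per harvest period.
#' @param n_grass,n_forb designed-mixture composition (3 grasses + 5 forbs).
#' @param beta named effect sizes on unit-SD predictors (g/week per SD):
#'   `native`, `seed_mass`, `leaf_area`, `height`, `pd`. The native predictor
#'   is scaled to unit SD but anchored at zero biomass (no centering), so the
#'   intercept is the invader's competition-free biomass; the CWM and PD
#'   predictors are centered and scaled.
#' @param intercept competition-free invader biomass (g/week): the
#'   monoculture baseline from which native biomass suppresses the invader.
#' @param sigma residual SD (g/week).
#' @param sd_tray,sd_period random-intercept SDs.
#' @param native_mean_designed,native_mean_lfl,native_sd,mixture_sd native
#'   per-week biomass means (designed mixtures and commercial reference), the
#'   tray-level SD, and the between-mixture SD of the designed-mixture means.
#' @param trait_meanlog,trait_sdlog log-normal trait parameters (height m,
#'   leaf area mm^2, seed mass mg).
#' @param germination_mean,germination_sd beta-distributed germination rates.
#' @param cutting_weights sampling weights over tolerance scores 1..9.
#' @param pd_period1_only if `TRUE` (default) the PD effect acts only in
#'   period 1, mirroring the early-only PD signal; `FALSE` gives a constant
#'   PD effect (useful for null calibration).
#' @param response_dist `"gaussian"` (truncated at zero, default) or
#'   `"lognormal"`.
#' @param invader_id tip label used for the invader.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_species = 36L,
                             n_families = 15L,
                             replicates = 6L,
                             period_weeks = c(10L, 15L, 22L),
                             n_grass = 3L,
                             n_forb = 5L,
                             beta = c(native = -0.4, seed_mass = 0.25,
                                      leaf_area = -0.15, height = 0, pd = 0.2),
                             intercept = 1.6,
                             sigma = 0.25,
                             sd_tray = 0.10,
                             sd_period = 0.08,
                             native_mean_designed = 1.33,
                             native_mean_lfl = 2.25,
                             native_sd = 0.35,
                             mixture_sd = 0.15,
                             trait_meanlog = c(height = log(0.5),
                                               leaf_area = log(600),
                                               seed_mass = log(1)),
                             trait_sdlog = c(height = 0.5, leaf_area = 1.0,
                                             seed_mass = 1.0),
                             germination_mean = 0.65,
                             germination_sd = 0.218,
                             cutting_weights = c(1, 2, 3, 5, 6, 5, 3, 2, 1),
                             pd_period1_only = TRUE,
                             response_dist = c("gaussian", "lognormal"),
                             invader_id = "Jaq_aquatica") {
  response_dist <- match.arg(response_dist)
  if (n_species < 16) tm_validation_error("n_species must be at least 16 (two 8-species pools)")
  if (n_species %% 2 != 0) tm_validation_error("n_species must be even (two equal communities)")
  if (n_families < 1 || n_families > n_species)
    tm_validation_error("n_families must lie in 1..n_species")
  needed_beta <- c("native", "seed_mass", "leaf_area", "height", "pd")
  if (!all(needed_beta %in% names(beta)))
    tm_validation_error(sprintf("beta must name: %s", paste(needed_beta, collapse = ", ")))
  if (sigma <= 0 || sd_tray < 0 || sd_period < 0 || native_sd <= 0)
    tm_validation_error("noise scales must be positive")
  if (any(trait_sdlog <= 0)) tm_validation_error("trait_sdlog must be positive")
  if (length(cutting_weights) != 9 || any(cutting_weights < 0))
    tm_validation_error("cutting_weights must be 9 nonnegative weights")
  structure(list(
    n_species = as.integer(n_species), n_families = as.integer(n_families),
    replicates = as.integer(replicates), period_weeks = as.integer(period_weeks),
    n_grass = as.integer(n_grass), n_forb = as.integer(n_forb),
    beta = beta[needed_beta], intercept = intercept, sigma = sigma,
    sd_tray = sd_tray, sd_period = sd_period,
    native_mean_designed = native_mean_designed,
    native_mean_lfl = native_mean_lfl,
    native_sd = native_sd, mixture_sd = mixture_sd,
    trait_meanlog = trait_meanlog, trait_sdlog = trait_sdlog,
    germination_mean = germination_mean, germination_sd = germination_sd,
    cutting_weights = cutting_weights,
    pd_period1_only = isTRUE(pd_period1_only),
    response_dist = response_dist,
    invader_id = invader_id
  ), class = "generator_config")
}

# growth-form counts for one community half
half_growth_forms <- function(half, n_grass, n_forb) {
  grasses <- max(n_grass, min(7L, half - n_forb - 1L))
  legumes <- max(0L, min(2L, half - grasses - n_forb - 1L))
  forbs <- half - grasses - legumes
  c(grass = grasses, forb = forbs, legume = legumes)
}

#' Generate a species pool and a feasible invader record
#'
#' Traits are drawn log-normal; germination rates beta-distributed around 65%
#' (SD about 22%); cutting tolerances sampled on 1..9. Each community half
#' carries enough grasses and forbs to supply a designed mixture, and the
#' species chosen for the two design pools are marked (`in_design_pool`).
#' The invader's traits are drawn from the interior of the intersection of
#' the two design pools' trait ranges, so every constrained/diversified trait
#' combination is feasible; if a drawn pool leaves no interior (100 attempts),
#' an error advises widening the pool.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `species` (table with extra `community` and
#'   `in_design_pool` columns) and `invader` (one-row record).
#' @export
generate_pool <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_species
  half <- n %/% 2L
  forms_half <- half_growth_forms(half, config$n_grass, config$n_forb)
  # beta shapes from mean/sd
  m <- config$germination_mean
  v <- min(config$germination_sd^2, m * (1 - m) * 0.95)
  ab <- m * (1 - m) / v - 1
  shape1 <- m * ab
  shape2 <- (1 - m) * ab

  with_local_seed(seed, {
    for (attempt in seq_len(100L)) {
      families <- c(sprintf("f%02d", seq_len(config$n_families)),
                    sample(sprintf("f%02d", seq_len(config$n_families)),
                           n - config$n_families, replace = TRUE))
      families <- sample(families)
      growth_form <- c(sample(rep(names(forms_half), times = forms_half)),
                       sample(rep(names(forms_half), times = forms_half)))
      species <- data.frame(
        species_id = sprintf("sp%02d", seq_len(n)),
        family = families,
        growth_form = growth_form,
        height_m = stats::rlnorm(n, config$trait_meanlog[["height"]],
                                 config$trait_sdlog[["height"]]),
        leaf_area_mm2 = stats::rlnorm(n, config$trait_meanlog[["leaf_area"]],
                                      config$trait_sdlog[["leaf_area"]]),
        seed_mass_mg = stats::rlnorm(n, config$trait_meanlog[["seed_mass"]],
                                     config$trait_sdlog[["seed_mass"]]),
        germination_rate = stats::rbeta(n, shape1, shape2),
        cutting_tolerance = sample(1:9, n, replace = TRUE,
                                   prob = config$cutting_weights),
        community = rep(c("mesic", "wet"), each = half),
        stringsAsFactors = FALSE
      )
      # choose the two design pools (n_grass grasses + n_forb forbs per half)
      species$in_design_pool <- FALSE
      for (comm in c("mesic", "wet")) {
        idx_g <- which(species$community == comm & species$growth_form == "grass")
        idx_f <- which(species$community == comm & species$growth_form == "forb")
        pick <- c(sample(idx_g, config$n_grass), sample(idx_f, config$n_forb))
        species$in_design_pool[pick] <- TRUE
      }
      pools <- split(species[species$in_design_pool, ],
                     species$community[species$in_design_pool])
      inv <- list(species_id = config$invader_id)
      ok <- TRUE
      for (trait in names(TRAIT_COLUMNS)) {
        col <- TRAIT_COLUMNS[[trait]]
        lo <- max(vapply(pools, function(pl) min(pl[[col]]), numeric(1)))
        hi <- min(vapply(pools, function(pl) max(pl[[col]]), numeric(1)))
        width <- hi - lo
        if (width <= 0) { ok <- FALSE; break }
        inv[[col]] <- stats::runif(1, lo + 0.2 * width, hi - 0.2 * width)
      }
      if (ok) {
        invader <- as.data.frame(inv, stringsAsFactors = FALSE)
        validate_species_table(species)
        validate_invader_record(invader)
        return(list(species = species, invader = invader))
      }
    }
    tm_validation_error(paste(
      "could not draw invader traits inside both design pools' trait ranges",
      "after 100 attempts; widen the pool (more species or larger trait_sdlog)"))
  })
}

#' Generate a family-clustered random phylogeny
#'
#' A random coalescent backbone over the families, with each multi-species
#' family replaced by its own shallow coalescent subtree (depth 15% of the
#' backbone depth), so confamilial species sit closer to each other than to
#' the rest of the pool. Branch lengths are positive; the tree is rooted and
#' not necessarily ultrametric after grafting.
#'
#' @param species species table (uses `species_id` and `family`).
#' @param seed integer seed.
#' @return a rooted `phylo` whose tip labels are the pool's `species_id`s.
#' @export
generate_tree <- function(species, seed) {
  if (nrow(species) < 2) tm_validation_error("need at least two species for a tree")
  fams <- split(species$species_id, species$family)
  with_local_seed(seed, {
    if (length(fams) == 1) {
      tree <- ape::rcoal(length(fams[[1]]), tip.label = fams[[1]])
      return(tree)
    }
    backbone <- ape::rcoal(length(fams), tip.label = names(fams))
    depth <- max(ape::node.depth.edgelength(backbone))
    tree <- backbone
    for (fam in names(fams)) {
      ids <- fams[[fam]]
      if (length(ids) == 1) {
        tree$tip.label[tree$tip.label == fam] <- ids
      } else {
        sub <- ape::rcoal(length(ids), tip.label = sample(ids))
        sub_depth <- max(ape::node.depth.edgelength(sub))
        sub$edge.length <- sub$edge.length / sub_depth * (0.15 * depth)
        tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == fam))
      }
    }
    tree
  })
}

#' Reference designs: commercial mixture and invader monoculture
#'
#' The commercial reference (`LfL`) is a grass-dominated mixture of six
#' grasses and two forbs drawn from the mesic half of the pool (grasses share
#' 85% of the abundance); the `Mono` reference is an invader monoculture with
#' no native community.
#'
#' @param species species table.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return named list with `LfL` and `Mono` design-like objects.
#' @export
make_reference_designs <- function(species, config, seed) {
  with_local_seed(seed, {
    mesic <- species[species$community == "mesic", ]
    grasses <- mesic$species_id[mesic$growth_form == "grass"]
    forbs <- mesic$species_id[mesic$growth_form == "forb"]
    n_g <- min(6L, length(grasses))
    ids <- c(sample(grasses, n_g), sample(forbs, 2L))
    p <- c(rep(0.85 / n_g, n_g), rep(0.15 / 2, 2L))
    lfl <- structure(list(
      mixture_code = "LfL", species_ids = ids, abundances = p / sum(p),
      rao_q = NA_real_, constraint_residual = NA_real_,
      solver_status = "reference", spec = NULL,
      target_standardized = NA_real_, message = "commercial reference mixture"
    ), class = "mixture_design")
    mono <- structure(list(
      mixture_code = "Mono", species_ids = config$invader_id, abundances = 1,
      rao_q = 0, constraint_residual = NA_real_,
      solver_status = "reference", spec = NULL,
      target_standardized = NA_real_, message = "invader monoculture"
    ), class = "mixture_design")
    list(LfL = lfl, Mono = mono)
  })
}

community_type_of <- function(codes) {
  out <- rep(NA_character_, length(codes))
  out[startsWith(codes, "M-")] <- "mesic"
  out[startsWith(codes, "W-")] <- "wet"
  out[codes == "LfL"] <- "reference_LfL"
  out[codes == "Mono"] <- "monoculture"
  out
}

#' Generate tray-level observations
#'
#' Native per-week biomass is drawn around a mixture-specific mean (the
#' commercial reference highest, the monoculture zero). Invader per-week
#' biomass follows the linear predictor
#' `intercept + beta_native * z(native) + beta_sm * z(CWM seed mass) +
#' beta_la * z(CWM leaf area) + beta_ph * z(CWM height) + beta_pd * z(PD) *
#' [period == 1] + tray and period random intercepts + noise`, floored at
#' zero (or log-normal), then converted back to g/tray by multiplying with
#' the period length. Predictors are standardized internally so the effect
#' sizes are per-SD; the native predictor keeps its natural zero, so the
#' monoculture (no native community, zero trait/PD contributions) sits at the
#' competition-free baseline and has the largest invader biomass, while the
#' grass-dominated commercial reference has the smallest — the
#' competition-release pattern of the study.
#'
#' @param designs named list of `mixture_design` objects (12 designed + the
#'   two references).
#' @param summaries community summaries for the native communities (from
#'   [summarize_communities()]).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `observations` (tray x period table) and `ground_truth`.
#' @export
generate_observations <- function(designs, summaries, config, seed) {
  stopifnot(inherits(config, "generator_config"))
  codes <- vapply(designs, function(d) d$mixture_code, character(1))
  designed <- codes[!codes %in% c("LfL", "Mono")]
  periods <- seq_along(config$period_weeks)

  with_local_seed(seed, {
    mix_native_mu <- stats::setNames(rep(NA_real_, length(codes)), codes)
    mix_native_mu[designed] <- config$native_mean_designed +
      stats::rnorm(length(designed), 0, config$mixture_sd)
    mix_native_mu["LfL"] <- config$native_mean_lfl
    mix_native_mu["Mono"] <- 0

    n_trays <- length(codes) * config$replicates
    trays <- data.frame(
      tray_id = sprintf("T%03d", seq_len(n_trays)),
      mixture_code = rep(codes, each = config$replicates),
      stringsAsFactors = FALSE
    )
    obs <- merge(
      trays,
      data.frame(period = periods, weeks = config$period_weeks),
      by = NULL
    )
    obs <- obs[order(obs$tray_id, obs$period), ]
    rownames(obs) <- NULL
    obs$community_type <- community_type_of(obs$mixture_code)

    mu <- mix_native_mu[obs$mixture_code]
    obs$native_pw <- ifelse(obs$mixture_code == "Mono", 0,
                            pmax(0, stats::rnorm(nrow(obs), mu, config$native_sd)))

    # standardized predictors: CWMs/PD at the mixture x period level
    pred_cols <- c("cwm_seed_mass", "cwm_leaf_area", "cwm_height", "pd_faith")
    smr <- summaries[, c("mixture_code", "period", pred_cols)]
    for (col in pred_cols) {
      s <- stats::sd(smr[[col]])
      smr[[paste0("z_", col)]] <-
        if (s > 1e-12) (smr[[col]] - mean(smr[[col]])) / s else 0
    }
    obs <- merge(obs, smr[, c("mixture_code", "period", paste0("z_", pred_cols))],
                 by = c("mixture_code", "period"), all.x = TRUE, sort = FALSE)
    obs <- obs[order(obs$tray_id, obs$period), ]
    rownames(obs) <- NULL
    for (col in paste0("z_", pred_cols)) obs[[col]][is.na(obs[[col]])] <- 0

    # the native term is scaled to unit SD but anchored at zero biomass, so
    # the intercept is the competition-free (monoculture) invader biomass and
    # stronger suppression coefficients strictly lower mixture biomass
    has_native <- obs$mixture_code != "Mono"
    z_native <- obs$native_pw / stats::sd(obs$native_pw[has_native])
    pd_gate <- if (config$pd_period1_only) as.numeric(obs$period == 1) else 1
    lp <- config$intercept +
      config$beta[["native"]] * z_native +
      config$beta[["seed_mass"]] * obs$z_cwm_seed_mass +
      config$beta[["leaf_area"]] * obs$z_cwm_leaf_area +
      config$beta[["height"]] * obs$z_cwm_height +
      config$beta[["pd"]] * obs$z_pd_faith * pd_gate

    b_tray <- stats::setNames(stats::rnorm(n_trays, 0, config$sd_tray), trays$tray_id)
    b_period <- stats::setNames(stats::rnorm(length(periods), 0, config$sd_period),
                                as.character(periods))
    eta <- lp + b_tray[obs$tray_id] + b_period[as.character(obs$period)]
    obs$invader_pw <- if (config$response_dist == "gaussian") {
      pmax(0, eta + stats::rnorm(nrow(obs), 0, config$sigma))
    } else {
      stats::rlnorm(nrow(obs), log(pmax(eta, 0.02)), config$sigma)
    }

    observations <- data.frame(
      tray_id = obs$tray_id,
      mixture_code = obs$mixture_code,
      community_type = obs$community_type,
      period = obs$period,
      weeks = obs$weeks,
      native_biomass_g = obs$native_pw * obs$weeks,
      invader_biomass_g = obs$invader_pw * obs$weeks,
      stringsAsFactors = FALSE
    )
    ground_truth <- list(
      beta = as.list(config$beta),
      intercept = config$intercept,
      sigma = config$sigma,
      sd_tray = config$sd_tray,
      sd_period = config$sd_period,
      pd_period1_only = config$pd_period1_only,
      seed = seed
    )
    list(observations = observations, ground_truth = ground_truth)
  })
}

#' Generate a complete synthetic experiment
#'
#' Pool and invader, phylogeny, the twelve designed mixtures plus references,
#' community summaries, and tray observations, all driven by one seed fanned
#' out to per-stage seeds with [derive_seed()]. Two calls with the same seed
#' and configuration return identical objects.
#'
#' @param config a [generator_config()].
#' @param seed integer run seed.
#' @return object of class `synthetic_experiment`: `config`, `seed`,
#'   `species`, `invader`, `tree`, `designs` (named list of 14),
#'   `summaries`, `observations`, `ground_truth`.
#' @export
generate_experiment <- function(config = generator_config(), seed = 1L) {
  pool <- generate_pool(config, derive_seed(seed, 1))
  species <- pool$species
  tree <- generate_tree(species, derive_seed(seed, 2))
  mesic_pool <- species[species$community == "mesic" & species$in_design_pool, ]
  wet_pool <- species[species$community == "wet" & species$in_design_pool, ]
  designs <- build_all_mixtures(mesic_pool, wet_pool, pool$invader)
  refs <- make_reference_designs(species, config, derive_seed(seed, 3))
  native_designs <- c(designs, refs["LfL"])
  summaries <- summarize_communities(native_designs, species, tree)
  gen <- generate_observations(c(designs, refs), summaries, config,
                               derive_seed(seed, 4))
  structure(list(
    config = config, seed = as.integer(seed),
    species = species, invader = pool$invader, tree = tree,
    designs = c(designs, refs), summaries = summaries,
    observations = gen$observations, ground_truth = gen$ground_truth
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment seed=%d> %d species / %d families; %d mixtures; %d observations\n",
    x$seed, nrow(x$species), length(unique(x$species$family)),
    length(x$designs), nrow(x$observations)))
  invisible(x)
}

#' Write a synthetic experiment to plain-text artifacts
#'
#' Species CSV, invader CSV, Newick tree, mixture abundances CSV, design
#' summary CSV, community summaries CSV, observations CSV, ground-truth JSON.
#'
#' @param experiment a `synthetic_experiment`.
#' @param dir output directory (created if absent).
#' @return character vector of the files written (invisibly).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    species = file.path(dir, "species.csv"),
    invader = file.path(dir, "invader.csv"),
    tree = file.path(dir, "tree.nwk"),
    mixtures = file.path(dir, "mixtures.csv"),
    design_summary = file.path(dir, "design_summary.csv"),
    summaries = file.path(dir, "community_summaries.csv"),
    observations = file.path(dir, "observations.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(experiment$species, paths["species"], row.names = FALSE, quote = FALSE)
  utils::write.csv(experiment$invader, paths["invader"], row.names = FALSE, quote = FALSE)
  ape::write.tree(experiment$tree, paths["tree"])
  native <- experiment$designs[
    vapply(experiment$designs, function(d) d$mixture_code != "Mono", logical(1))]
  utils::write.csv(design_abundances(native), paths["mixtures"], row.names = FALSE, quote = FALSE)
  utils::write.csv(design_summary(native), paths["design_summary"], row.names = FALSE, quote = FALSE)
  utils::write.csv(experiment$summaries, paths["summaries"], row.names = FALSE, quote = FALSE)
  utils::write.csv(experiment$observations, paths["observations"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(experiment$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(unname(paths))
}
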