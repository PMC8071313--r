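test_that("per-week standardization divides by period length", {
  obs <- data.frame(weeks = c(10, 15), native_biomass_g = c(10, 0),
                    invader_biomass_g = c(5, 3))
  out <- standardize_per_week(obs)
  expect_equal(out$native_pw, c(1, 0))
  expect_equal(out$invader_pw, c(0.5, 0.2))
  # ratio invariance
  obs2 <- transform(obs, weeks = weeks * 2, native_biomass_g = native_biomass_g * 2,
                    invader_biomass_g = invader_biomass_g * 2)
  expect_equal(standardize_per_week(obs2)$native_pw, out$native_pw)
  expect_error(standardize_per_week(transform(obs, weeks = 0)),
               class = "traitmix_validation_error")
})

test_that("grubbs statistic matches hand arithmetic and is affine-invariant", {
  g <- grubbs_statistic(c(-1, 0, 1))
  expect_equal(g$g, 1.0, tolerance = 1e-12)
  x <- c(1, 2, 3, 10)
  g <- grubbs_statistic(x)
  expect_equal(g$g, (10 - 4) / sqrt(50 / 3), tolerance = 1e-12)  # ~1.470
  expect_equal(g$index, 4L)
  g2 <- grubbs_statistic(-2.5 * x + 7)
  expect_equal(g2$g, g$g, tolerance = 1e-12)
  expect_error(grubbs_statistic(c(1, 2)), class = "traitmix_validation_error")
  expect_error(grubbs_statistic(rep(1, 5)), class = "traitmix_degenerate_error")
})

test_that("the closed-form critical value follows the t-distribution formula", {
  for (n in c(4, 6, 10, 25)) {
    tcrit <- qt(1 - 0.05 / (2 * n), n - 2)
    expect_equal(grubbs_critical(n, 0.05),
                 (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2)),
                 tolerance = 1e-12)
  }
})

test_that("outlier replacement flags the worked example and logs it", {
  obs <- data.frame(
    mixture_code = "MX", period = 1,
    tray = 1:6,
    invader_pw = c(1.0, 1.1, 0.9, 1.0, 1.05, 5.0),
    native_pw = rep(1, 6)  # constant -> skipped with a log entry
  )
  out <- replace_outliers(obs, alpha = 0.05)
  repl <- out$log[out$log$action == "replaced", ]
  expect_equal(nrow(repl), 1)
  expect_equal(repl$original, 5.0)
  expect_equal(repl$replacement, 1.01, tolerance = 1e-12)
  expect_equal(out$observations$invader_pw[6], 1.01, tolerance = 1e-12)
  expect_true(any(grepl("constant", out$log$action)))
  # group size unchanged; replacement inside the retained range
  expect_equal(nrow(out$observations), nrow(obs))
  expect_gte(repl$replacement, 0.9)
  expect_lte(repl$replacement, 1.1)
  # a clean group is untouched
  clean <- data.frame(mixture_code = "MX", period = 1, tray = 1:6,
                      invader_pw = c(1.0, 1.1, 0.9, 1.0, 1.05, 1.08),
                      native_pw = c(1.2, 1.1, 1.3, 1.25, 1.15, 1.22))
  out2 <- replace_outliers(clean)
  expect_identical(out2$observations, clean)
  expect_equal(sum(out2$log$action == "replaced"), 0)
  # "all" mode keeps the outlier in its own replacement mean
  out3 <- replace_outliers(obs, mode = "all")
  expect_equal(out3$observations$invader_pw[6], mean(obs$invader_pw),
               tolerance = 1e-12)
})

test_that("scale_columns rescales to unit sample SD and logs the transform", {
  tab <- data.frame(a = c(2, 4), b = c(10, 20))
  out <- scale_columns(tab, "a")
  expect_equal(out$a, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  log <- attr(out, "scale_log")
  expect_equal(log$center, 3)
  expect_equal(log$scale, sd(c(2, 4)))
  set.seed(6)
  tab <- data.frame(x = rnorm(20, 100, 7), y = rexp(20))
  out <- scale_columns(tab, c("x", "y"))
  expect_equal(sd(out$x), 1, tolerance = 1e-12)
  expect_equal(sd(out$y), 1, tolerance = 1e-12)
  expect_error(scale_columns(data.frame(x = rep(1, 4)), "x"),
               class = "traitmix_degenerate_error")
  # centering can be disabled
  out2 <- scale_columns(tab, "x", center = FALSE)
  expect_equal(out2$x, tab$x / sd(tab$x), tolerance = 1e-12)
})

test_that("predictor rescaling leaves slope Wald statistics unchanged", {
  set.seed(44)
  n <- 60
  dat <- data.frame(tray_id = rep(sprintf("t%02d", 1:20), each = 3),
                    period = rep(1:3, 20))
  dat$native_pw <- rnorm(n, 1.3, 0.3)
  dat$cwm_seed_mass <- rnorm(n, 2, 0.8)[match(dat$tray_id, unique(dat$tray_id))]
  dat$invader_pw <- 1 - 0.3 * dat$native_pw + 0.2 * dat$cwm_seed_mass + rnorm(n, 0, 0.2)
  m1 <- fit_invader_model(dat, predictors = c("native_pw", "cwm_seed_mass"),
                          rescale = TRUE)
  m2 <- fit_invader_model(dat, predictors = c("native_pw", "cwm_seed_mass"),
                          rescale = FALSE)
  expect_equal(m1$terms$chisq, m2$terms$chisq, tolerance = 1e-6)
})

test_that("mixture comparison reports levels-1 df and separates extreme mixtures", {
  obs <- standardize_per_week(toy_observations(k = 5, reps = 4))
  cmp <- compare_mixtures(obs)
  expect_equal(cmp$df, 4)
  expect_true(all(sort(cmp$letters$mixture_code) == sort(unique(obs$mixture_code))))

  # all-zero invader vs large invader -> distinct letters
  obs2 <- standardize_per_week(toy_observations(k = 2, reps = 6,
                                                means = c(0, 3), sd = 0.1))
  obs2$invader_biomass_g[obs2$mixture_code == "MX01"] <- 0
  obs2 <- standardize_per_week(obs2)
  cmp2 <- compare_mixtures(obs2)
  expect_false(cmp2$letters$group[1] == cmp2$letters$group[2])
  expect_lt(cmp2$p_value, 1e-6)

  expect_error(compare_mixtures(obs2[obs2$mixture_code == "MX01", ]),
               class = "traitmix_validation_error")
})

test_that("Tukey separation of identical mixtures is rare under the null", {
  set.seed(55)
  false_sep <- replicate(300, {
    obs <- data.frame(
      mixture_code = rep(c("A", "B"), each = 12),
      period = rep(1:3, 8),
      invader_pw = rnorm(24, 1, 0.3)
    )
    cmp <- compare_mixtures(obs, tukey_seed = 1)
    cmp$letters$group[1] != cmp$letters$group[2]
  })
  rate <- mean(false_sep)
  # nominal 0.05; 300 replicates give MC SE ~ 0.013
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("duplicating every observation keeps estimates and shrinks SEs", {
  set.seed(66)
  ex <- generate_experiment(generator_config(replicates = 3), seed = 606)
  obs <- standardize_per_week(ex$observations)
  merged <- merge(obs, ex$summaries, by = c("mixture_code", "period"),
                  all.x = TRUE, sort = FALSE)
  m1 <- fit_invader_model(merged)
  doubled <- merged
  doubled$tray_id <- paste0(doubled$tray_id, "b")
  m2 <- fit_invader_model(rbind(merged, doubled))
  expect_equal(m2$terms$estimate, m1$terms$estimate, tolerance = 0.05)
  expect_true(all(m2$terms$se < m1$terms$se))
})

test_that("treatment-structure model tests the factorial design", {
  ex <- generate_experiment(generator_config(replicates = 3), seed = 77)
  obs <- standardize_per_week(ex$observations)
  designed <- obs[obs$community_type %in% c("mesic", "wet"), ]
  m <- fit_treatment_model(designed)
  expect_setequal(m$terms$term,
                  c("community_type", "diversified", "constrained",
                    "community_type:diversified"))
  # diversified and constrained traits have 3 levels -> 2 df
  expect_equal(m$terms$df[m$terms$term == "diversified"], 2)
  expect_equal(m$terms$df[m$terms$term == "community_type"], 1)
  expect_true(all(m$terms$p >= 0 & m$terms$p <= 1))
})

test_that("design enumeration reproduces the experiment layout", {
  d <- enumerate_design()
  expect_equal(d$treatments_per_type, 6)
  expect_equal(d$designed_mixtures, 12)
  expect_equal(d$n_trays, 84)
  expect_equal(d$n_observations, 252)
  expect_equal(d$omnibus_df, 11)
  expect_equal(nrow(d$trays), 84)
  # scaling behaviour
  d2 <- enumerate_design(n_traits = 4, community_types = 1, references = 0,
                         replicates = 2)
  expect_equal(d2$treatments_per_type, 12)
  expect_equal(d2$n_trays, 24)
})
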