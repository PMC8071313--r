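test_that("distance matrix is elementwise |x_i - x_j|", {
  d <- trait_distance_matrix(c(0, 1, 3))
  expect_equal(unname(d), rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))
  expect_equal(unname(trait_distance_matrix(rep(2, 4))), matrix(0, 4, 4))
  set.seed(3)
  x <- rnorm(6)
  d <- trait_distance_matrix(x)
  for (i in 1:6) for (j in 1:6) expect_equal(d[i, j], abs(x[i] - x[j]))
  expect_error(trait_distance_matrix(c(1, NA)), class = "traitmix_validation_error")
})

test_that("rao_q equals the double-loop sum and vanishes without pairs", {
  expect_equal(rao_q(1, matrix(0, 1, 1)), 0)
  expect_equal(rao_q(c(0.5, 0.5), rbind(c(0, 1), c(1, 0))), 0.5)
  set.seed(4)
  for (i in 1:5) {
    p <- runif(5); p <- p / sum(p)
    d <- trait_distance_matrix(rnorm(5))
    expect_equal(rao_q(p, d), rao_q_loop(p, d), tolerance = 1e-12)
  }
  expect_error(rao_q(c(0.5, 0.5), matrix(0, 3, 3)), class = "traitmix_validation_error")
})

test_that("a single equality constraint on two species pins the solution", {
  sp <- toy_species(2)
  sp$height_m <- c(10, 30)   # raw values; target 20 -> p = (0.5, 0.5)
  inv <- toy_invader(sp)
  inv$height_m <- 20
  # height must not be log-transformed for the raw midpoint to be the target
  des <- design_mixture(sp, trait_spec("height", "seed_mass"), inv,
                        options = list(log_transform = character(0)))
  expect_equal(des$abundances, c(0.5, 0.5), tolerance = 1e-8)
  expect_lte(des$constraint_residual, 1e-6)
  # same regardless of which trait is diversified
  des2 <- design_mixture(sp, trait_spec("height", "leaf_area"), inv,
                         options = list(log_transform = character(0)))
  expect_equal(des2$abundances, des$abundances, tolerance = 1e-8)
})

test_that("solver matches the exhaustive feasible-grid oracle on small pools", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(2:4, 1)
    x <- rnorm(n)
    t <- rnorm(n)
    d <- trait_distance_matrix(x)
    target <- runif(1, min(t), max(t))
    sol <- solve_constrained_raoq(d, t, target)
    ora <- rao_constrained_oracle(d, t, target, step = 0.001)
    expect_lte(abs(sol$q - ora$q), 1e-4)
    expect_lte(sol$residual, 1e-6)
  }
})

test_that("targets outside the attainable range are infeasible, not errors", {
  sp <- toy_species(4)
  inv <- toy_invader(sp)
  inv$height_m <- min(sp$height_m) / 10
  des <- design_mixture(sp, trait_spec("height", "seed_mass"), inv)
  expect_identical(des$solver_status, "infeasible")
  expect_true(all(is.na(des$abundances)))
})

test_that("a target at the pool extreme collapses to the extreme species", {
  set.seed(8)
  t <- c(-1.3, 0.2, 0.9)
  d <- trait_distance_matrix(rnorm(3))
  sol <- solve_constrained_raoq(d, t, min(t))
  expect_identical(sol$status, "boundary")
  expect_equal(sol$p, c(1, 0, 0), tolerance = 1e-8)
  expect_equal(sol$q, 0, tolerance = 1e-12)
})

test_that("optimal Q scales with the distances and the solution does not", {
  set.seed(13)
  t <- rnorm(4)
  d <- trait_distance_matrix(rnorm(4))
  target <- mean(range(t))
  a <- solve_constrained_raoq(d, t, target)
  b <- solve_constrained_raoq(3.7 * d, t, target)
  expect_equal(b$q, 3.7 * a$q, tolerance = 1e-7)
  expect_equal(b$p, a$p, tolerance = 1e-6)
})

test_that("permuting the pool permutes the abundances identically", {
  set.seed(17)
  t <- rnorm(4); x <- rnorm(4)
  target <- mean(range(t))
  perm <- c(3, 1, 4, 2)
  a <- solve_constrained_raoq(trait_distance_matrix(x), t, target)
  b <- solve_constrained_raoq(trait_distance_matrix(x[perm]), t[perm], target)
  expect_equal(b$p, a$p[perm], tolerance = 1e-7)
  expect_equal(b$q, a$q, tolerance = 1e-9)
})

test_that("all twelve mixtures are built with the community/trait code scheme", {
  sp <- toy_species(16)
  mesic <- sp[1:8, ]
  wet <- sp[9:16, ]
  inv <- toy_invader(sp)
  designs <- build_all_mixtures(mesic, wet, inv)
  expect_length(designs, 12)
  codes <- vapply(designs, function(d) d$mixture_code, character(1))
  expect_true("M-Ph*Sm*" %in% codes)
  expect_equal(sum(startsWith(codes, "M-")), 6)
  expect_equal(sum(startsWith(codes, "W-")), 6)
  expect_equal(anyDuplicated(codes), 0)
  # constrained != diversified in every code
  parsed <- parse_mixture_code(codes)
  expect_false(any(parsed$constrained == parsed$diversified))
  smry <- design_summary(designs)
  expect_true(all(smry$solver_status %in% c("optimal", "boundary", "infeasible")))
  ab <- design_abundances(designs)
  sums <- tapply(ab$abundance, ab$mixture_code, sum)
  feasible <- smry$mixture_code[smry$solver_status != "infeasible"]
  expect_equal(as.numeric(sums[feasible]), rep(1, length(feasible)), tolerance = 1e-8)
})

test_that("sowing plan masses sum to density x area and counts follow seed mass", {
  sp <- toy_species(2)
  inv <- toy_invader(sp)
  sp$height_m <- c(10, 30); inv$height_m <- 20
  des <- design_mixture(sp, trait_spec("height", "seed_mass"), inv,
                        options = list(log_transform = character(0)))
  plan <- sowing_plan(des, seed_masses = c(1, 10))
  # equal abundances, seed masses 1 and 10 mg -> counts in ratio 10:1
  expect_equal(plan$seed_count[1] / plan$seed_count[2], 10, tolerance = 1e-9)
  expect_equal(sum(plan$sown_mass_g_tray), 3 * 0.1584, tolerance = 1e-9)

  mono <- des; mono$abundances <- c(1, 0)
  plan1 <- sowing_plan(mono, seed_masses = c(1, 10), native_density = 3,
                       tray_area = 0.1584)
  expect_equal(plan1$sown_mass_g_tray[1], 0.4752, tolerance = 1e-9)

  set.seed(31)
  sp8 <- toy_species(8)
  des8 <- design_mixture(sp8, trait_spec("seed_mass", "height"), toy_invader(sp8))
  plan8 <- sowing_plan(des8, seed_masses = sp8$seed_mass_mg)
  expect_equal(sum(plan8$sown_mass_g_tray), 3 * 0.1584, tolerance = 1e-9)
  expect_error(sowing_plan(des8, seed_masses = rep(0, 8)),
               class = "traitmix_validation_error")
})
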