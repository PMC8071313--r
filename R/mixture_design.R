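# Seed-mixture design: assign relative abundances to a candidate species set
# by maximizing Rao's quadratic entropy Q = sum_ij p_i p_j d_ij on the
# diversified trait, subject to sum(p) = 1, p >= 0, and a community-weighted
# mean equality constraint pinning the constrained trait to the invader's
# value (limiting similarity). All trait arithmetic happens on the
# standardized scale of the candidate pool.
#
# For one standardized trait, d_ij = |x_i - x_j| is a distance of negative
# type, so p' D p is concave on the affine set {sum(p) = 1}: the program is a
# concave QP over a polytope and a primal active-set method finds the global
# optimum in finitely many steps, deterministically.

TRAIT_ABBREV <- c(height = "Ph", leaf_area = "La", seed_mass = "Sm")

#' Pairwise trait distance matrix
#'
#' Absolute differences of a single (standardized) trait column: Euclidean
#' distance in one dimension. Only one trait is diversified per mixture, so no
#' multi-trait machinery is involved.
#'
#' @param values numeric vector of trait values (>= 2).
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return a symmetric nonnegative matrix with zero diagonal.
#' @export
trait_distance_matrix <- function(values, metric = c("euclidean")) {
  metric <- match.arg(metric)
  if (length(values) < 2) tm_validation_error("need at least two species for a distance matrix")
  if (any(!is.finite(values))) tm_validation_error("non-finite trait value in distance computation")
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(names(values), names(values))
  d
}

#' Rao's quadratic entropy
#'
#' `Q = sum_i sum_j p_i p_j d_ij`: the expected trait distance between two
#' individuals drawn with replacement from the community.
#'
#' @param p abundance vector on the simplex (within 1e-6 tolerance).
#' @param d symmetric distance matrix with zero diagonal.
#' @return nonnegative scalar Q.
#' @export
rao_q <- function(p, d) {
  if (length(p) != nrow(d) || nrow(d) != ncol(d))
    tm_validation_error("dimension mismatch between abundances and distance matrix")
  if (abs(sum(p) - 1) > 1e-6 || min(p) < -1e-8)
    tm_validation_error("abundances must lie on the simplex")
  if (max(abs(d - t(d))) > 1e-8 || max(abs(diag(d))) > 1e-12)
    tm_validation_error("distance matrix must be symmetric with zero diagonal")
  max(0, drop(crossprod(p, d %*% p)))
}

#' Constrained/diversified trait pair
#'
#' @param constrained trait whose community-weighted mean is pinned to the
#'   invader's value.
#' @param diversified trait whose Rao's Q is maximized.
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(constrained, diversified) {
  traits <- names(TRAIT_ABBREV)
  constrained <- match.arg(constrained, traits)
  diversified <- match.arg(diversified, traits)
  if (constrained == diversified)
    tm_validation_error("constrained and diversified trait must differ")
  structure(list(constrained = constrained, diversified = diversified),
            class = "trait_spec")
}

#' Mixture code following the community/trait labelling scheme
#'
#' Community letter (M mesic, W wet), constrained trait abbreviation, then the
#' diversified trait abbreviation marked with asterisks, e.g. `"M-Ph*Sm*"` for
#' a mesic mixture constraining plant height and diversifying seed mass.
#'
#' @param community `"mesic"` or `"wet"`.
#' @param spec a [trait_spec()].
#' @return character code.
#' @export
mixture_code <- function(community, spec) {
  letter <- c(mesic = "M", wet = "W")[[match.arg(community, c("mesic", "wet"))]]
  sprintf("%s-%s*%s*", letter, TRAIT_ABBREV[[spec$constrained]], TRAIT_ABBREV[[spec$diversified]])
}

# ---- active-set QP -----------------------------------------------------------

# maximize p' D p  s.t.  A p = b, p >= 0, from a feasible start p0.
# D must be (conditionally) negative semidefinite on the nullspace of A's
# first row (the simplex constraint), which holds for 1-D distance matrices.
qp_active_set_max <- function(D, A, b, p0, tol = 1e-10, max_iter = 500L) {
  n <- length(p0)
  m <- nrow(A)
  p <- p0
  active <- which(p <= tol)
  for (iter in seq_len(max_iter)) {
    free <- setdiff(seq_len(n), active)
    k <- length(free)
    AF <- A[, free, drop = FALSE]
    KKT <- rbind(
      cbind(2 * D[free, free, drop = FALSE], -t(AF)),
      cbind(AF, matrix(0, m, m))
    )
    rhs <- c(rep(0, k), b)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)))
      sol <- as.numeric(MASS::ginv(KKT) %*% rhs)
    pF <- sol[seq_len(k)]
    lam <- sol[k + seq_len(m)]
    if (all(pF >= -1e-9)) {
      p[] <- 0
      p[free] <- pmax(pF, 0)
      if (length(active) == 0) return(list(p = p, iterations = iter))
      g <- drop(2 * D %*% p)
      mu <- drop(crossprod(A[, active, drop = FALSE], lam)) - g[active]
      if (all(mu >= -1e-7)) return(list(p = p, iterations = iter))
      release <- active[which.min(mu)]
      active <- setdiff(active, release)
    } else {
      # partial step toward the subproblem optimum until a bound blocks
      pcur <- p[free]
      dir <- pF - pcur
      blocking <- which(dir < -tol & pF < -tol)
      if (length(blocking) == 0) blocking <- which(dir < -tol)
      alphas <- -pcur[blocking] / dir[blocking]
      a <- max(min(alphas), 0)
      pnew <- pcur + a * dir
      hit <- free[blocking[which.min(alphas)]]
      p[] <- 0
      p[free] <- pmax(pnew, 0)
      p[hit] <- 0
      active <- sort(unique(c(active, hit)))
    }
  }
  list(p = p, iterations = max_iter)
}

# feasible vertex: mix the two constrained-trait extremes to hit the target
feasible_start <- function(t, target) {
  n <- length(t)
  i_min <- which.min(t)
  i_max <- which.max(t)
  p <- numeric(n)
  spread <- t[i_max] - t[i_min]
  if (spread < 1e-12) {
    p[i_min] <- 1
  } else {
    lam <- min(max((target - t[i_min]) / spread, 0), 1)
    p[i_min] <- 1 - lam
    p[i_max] <- lam
  }
  p
}

#' Solve the constrained Rao's Q maximization
#'
#' Low-level solver on the standardized scale: maximize `p' d p` subject to
#' `sum(p) = 1`, `p >= 0`, and `sum(p * t) = target`.
#'
#' @param d distance matrix on the diversified trait.
#' @param t constrained-trait values (standardized).
#' @param target constrained-trait target (standardized invader value).
#' @param feasibility_tol slack allowed on the attainable range check.
#' @return list with `status` (`"optimal"`, `"boundary"`, `"infeasible"`),
#'   `p`, `q`, `residual`, `message`.
#' @export
solve_constrained_raoq <- function(d, t, target, feasibility_tol = 1e-8) {
  n <- length(t)
  if (n < 2) tm_validation_error("pool must contain at least two species")
  if (nrow(d) != n) tm_validation_error("distance matrix and trait vector dimensions differ")
  rng <- range(t)
  if (target < rng[1] - feasibility_tol || target > rng[2] + feasibility_tol) {
    return(list(
      status = "infeasible", p = rep(NA_real_, n), q = NA_real_, residual = NA_real_,
      message = sprintf(
        "target %.6g outside the attainable community-weighted mean range [%.6g, %.6g]",
        target, rng[1], rng[2])
    ))
  }
  at_boundary <- target <= rng[1] + feasibility_tol || target >= rng[2] - feasibility_tol

  if (diff(rng) < 1e-12) {
    # constrained trait constant: CWM constraint is vacuous once feasible
    A <- matrix(1, 1, n); b <- 1
  } else {
    A <- rbind(rep(1, n), t); b <- c(1, target)
  }
  p0 <- feasible_start(t, target)
  fit <- qp_active_set_max(d, A, b, p0)
  p <- fit$p
  # clip solver dust and renormalize
  p[p < 1e-8] <- 0
  p <- p / sum(p)
  list(
    status = if (at_boundary) "boundary" else "optimal",
    p = p,
    q = max(0, drop(crossprod(p, d %*% p))),
    residual = abs(sum(p * t) - target),
    message = "ok"
  )
}

#' Design one seed mixture
#'
#' Standardizes the candidate pool's traits, places the invader's
#' constrained-trait value on the same scale, and solves the constrained
#' Rao's Q maximization. Deterministic: fixed feasible start, no randomness.
#'
#' @param pool species table for the candidate set (for the designed mixtures,
#'   3 grasses + 5 forbs chosen by the caller; composition is not optimized).
#' @param spec a [trait_spec()].
#' @param invader one-row invader record (see [load_invader_record()]).
#' @param options list; recognized entries: `log_transform` (passed to
#'   [standardize_traits()]), `code` (mixture code label), `constraint_tol`
#'   (maximum accepted residual on the standardized scale, default `1e-6`).
#' @return an object of class `mixture_design`: `mixture_code`, `species_ids`,
#'   `abundances`, `rao_q`, `constraint_residual`, `solver_status`, plus the
#'   `trait_spec` and standardized target.
#' @export
design_mixture <- function(pool, spec, invader, options = list()) {
  stopifnot(inherits(spec, "trait_spec"))
  validate_invader_record(invader)
  if (nrow(pool) < 2) tm_validation_error("pool must contain at least two species")
  log_transform <- options$log_transform %||% c("leaf_area", "seed_mass")
  constraint_tol <- options$constraint_tol %||% 1e-6

  tm <- standardize_traits(pool, log_transform = log_transform)
  t_con <- tm$standardized[, spec$constrained]
  x_div <- tm$standardized[, spec$diversified]
  target <- standardize_value(tm, spec$constrained,
                              invader[[TRAIT_COLUMNS[[spec$constrained]]]])
  d <- trait_distance_matrix(x_div)
  sol <- solve_constrained_raoq(d, t_con, target)

  if (sol$status != "infeasible" && sol$residual > constraint_tol)
    sol$status <- "infeasible"

  structure(list(
    mixture_code = options$code %||%
      sprintf("%s%s*", TRAIT_ABBREV[[spec$constrained]], TRAIT_ABBREV[[spec$diversified]]),
    species_ids = pool$species_id,
    abundances = unname(sol$p),
    rao_q = sol$q,
    constraint_residual = sol$residual,
    solver_status = sol$status,
    spec = spec,
    target_standardized = target,
    message = sol$message
  ), class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design %s> %s; RaoQ = %.4f; residual = %.2e; status = %s\n",
              x$mixture_code,
              sprintf("constrain %s / diversify %s", x$spec$constrained, x$spec$diversified),
              x$rao_q, x$constraint_residual, x$solver_status))
  sup <- which(x$abundances > 0)
  cat(paste(sprintf("  %s: %.4f", x$species_ids[sup], x$abundances[sup]), collapse = "\n"), "\n")
  invisible(x)
}

#' Build the full set of designed mixtures
#'
#' All six ordered pairs of distinct constrained/diversified traits for each
#' of the two community types: twelve designed mixtures. Infeasible designs
#' are flagged in `solver_status`, never dropped.
#'
#' @param mesic_pool,wet_pool species tables (3 grasses + 5 forbs each).
#' @param invader invader record.
#' @param options passed to [design_mixture()].
#' @return named list of 12 `mixture_design` objects.
#' @export
build_all_mixtures <- function(mesic_pool, wet_pool, invader, options = list()) {
  traits <- names(TRAIT_ABBREV)
  pairs <- expand.grid(diversified = traits, constrained = traits,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$constrained != pairs$diversified, c("constrained", "diversified")]
  pools <- list(mesic = mesic_pool, wet = wet_pool)
  out <- list()
  for (community in names(pools)) {
    for (i in seq_len(nrow(pairs))) {
      spec <- trait_spec(pairs$constrained[i], pairs$diversified[i])
      opts <- options
      opts$code <- mixture_code(community, spec)
      out[[opts$code]] <- design_mixture(pools[[community]], spec, invader, opts)
    }
  }
  out
}

#' Summarize a list of mixture designs
#'
#' @param designs list of `mixture_design` objects.
#' @return data.frame `mixture_code, rao_q, constraint_residual, solver_status`.
#' @export
design_summary <- function(designs) {
  do.call(rbind, lapply(designs, function(d) data.frame(
    mixture_code = d$mixture_code,
    rao_q = d$rao_q,
    constraint_residual = d$constraint_residual,
    solver_status = d$solver_status,
    stringsAsFactors = FALSE
  )))
}

#' Long-format abundance table for a list of designs
#'
#' @param designs list of `mixture_design` objects.
#' @return data.frame `mixture_code, species_id, abundance`.
#' @export
design_abundances <- function(designs) {
  do.call(rbind, lapply(designs, function(d) data.frame(
    mixture_code = d$mixture_code,
    species_id = d$species_ids,
    abundance = d$abundances,
    stringsAsFactors = FALSE
  )))
}

# ---- brute-force oracle ------------------------------------------------------

#' Brute-force grid reference for the constrained Rao's Q optimum
#'
#' Independent check of [solve_constrained_raoq()] for small pools (n <= 4):
#' enumerates every support subset of the pool and, within each support, grids
#' the feasible polytope `{sum(p) = 1, sum(p * t) = target, p >= 0}` at the
#' given abundance step, solving two pivot coordinates exactly so every
#' evaluated point satisfies the equality constraints to machine precision
#' (faces and vertices of the polytope included). Exhaustive up to the grid
#' resolution; exponentially slower than the solver and used only for
#' verification.
#'
#' @param d distance matrix on the diversified trait.
#' @param t constrained-trait values.
#' @param target constrained-trait target.
#' @param step grid step on the abundance scale (default 0.001).
#' @return list with `q` (best objective found), `p`, `residual`,
#'   `n_evaluated`; `q = -Inf` if no support is feasible.
#' @export
rao_constrained_oracle <- function(d, t, target, step = 0.001) {
  n <- length(t)
  if (n < 2 || n > 4)
    tm_validation_error("the grid oracle handles pools of 2 to 4 species")
  best <- list(q = -Inf, p = NULL, residual = NA_real_, n_evaluated = 0L)

  consider <- function(P, S) {
    # P: matrix of candidate abundance vectors on support S (columns = S)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    keep <- rowSums(P < -1e-12) == 0
    P <- P[keep, , drop = FALSE]
    if (nrow(P) == 0) return()
    P[P < 0] <- 0
    DS <- d[S, S, drop = FALSE]
    q <- rowSums((P %*% DS) * P)
    best$n_evaluated <<- best$n_evaluated + nrow(P)
    i <- which.max(q)
    if (q[i] > best$q) {
      p_full <- numeric(n)
      p_full[S] <- P[i, ]
      best$q <<- q[i]
      best$p <<- p_full
      best$residual <<- abs(sum(p_full * t) - target)
    }
  }

  supports <- unlist(lapply(seq_len(n), function(k) {
    utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)

  for (S in supports) {
    tS <- t[S]
    s <- length(S)
    if (target < min(tS) - 1e-9 || target > max(tS) + 1e-9) next
    if (diff(range(tS)) < 1e-12) {
      # constraint vacuous on this support: grid the whole (s-1)-simplex
      if (abs(tS[1] - target) > 1e-9) next
      if (s == 1) consider(matrix(1, 1, 1), S)
      else if (s == 2) {
        a <- seq(0, 1, by = step)
        consider(cbind(a, 1 - a), S)
      } else {
        grid <- simplex_grid(s, step)
        consider(grid, S)
      }
      next
    }
    # pivot pair: the two most-separated trait values in the support
    iu <- which.min(tS); iv <- which.max(tS)
    others <- setdiff(seq_len(s), c(iu, iv))
    if (length(others) == 0) {
      # unique feasible point on a 2-species support
      lam <- (target - tS[iu]) / (tS[iv] - tS[iu])
      if (lam >= -1e-12 && lam <= 1 + 1e-12) {
        P <- matrix(0, 1, s); P[1, iu] <- 1 - lam; P[1, iv] <- lam
        consider(P, S)
      }
    } else if (length(others) == 1) {
      a <- seq(0, 1, by = step)
      rest <- 1 - a
      tgt <- target - a * tS[others]
      lam <- (tgt - rest * tS[iu]) / (tS[iv] - tS[iu])
      P <- matrix(0, length(a), s)
      P[, others] <- a
      P[, iu] <- rest - lam
      P[, iv] <- lam
      consider(P, S)
    } else {
      a <- seq(0, 1, by = step)
      grid <- expand.grid(a = a, b = a)
      grid <- grid[grid$a + grid$b <= 1 + 1e-12, ]
      rest <- 1 - grid$a - grid$b
      tgt <- target - grid$a * tS[others[1]] - grid$b * tS[others[2]]
      lam <- (tgt - rest * tS[iu]) / (tS[iv] - tS[iu])
      P <- matrix(0, nrow(grid), s)
      P[, others[1]] <- grid$a
      P[, others[2]] <- grid$b
      P[, iu] <- rest - lam
      P[, iv] <- lam
      consider(P, S)
    }
  }
  best
}

# all grid points of the (k-1)-simplex at the given step
simplex_grid <- function(k, step) {
  m <- round(1 / step)
  if (k == 1) return(matrix(1, 1, 1))
  if (k == 2) {
    a <- seq(0, m) / m
    return(cbind(a, 1 - a))
  }
  grid <- expand.grid(i = 0:m, j = 0:m)
  grid <- grid[grid$i + grid$j <= m, ]
  if (k == 3) return(cbind(grid$i, grid$j, m - grid$i - grid$j) / m)
  tm_validation_error("simplex_grid supports up to 3 free dimensions")
}

# ---- sowing plan -------------------------------------------------------------

#' Translate a mixture design into a sowing plan
#'
#' Per-species sown seed mass and approximate seed counts for a tray, given a
#' native sowing density. Small-seeded species end up sown at higher counts
#' than large-seeded ones at equal abundance, as seed counts are mass divided
#' by per-seed mass.
#'
#' @param design a `mixture_design`.
#' @param seed_masses per-species seed mass in mg, aligned with
#'   `design$species_ids`.
#' @param native_density native seed density in g/m^2 (default 3).
#' @param invader_density invader seed density in g/m^2 (default 1).
#' @param tray_area tray area in m^2 (default 0.1584, a 48 cm x 33 cm tray).
#' @return data.frame of per-species sown mass (g/m^2 and g/tray) and seed
#'   count, with the tray totals as attributes.
#' @export
sowing_plan <- function(design, seed_masses, native_density = 3,
                        invader_density = 1, tray_area = 0.1584) {
  if (native_density <= 0 || invader_density <= 0 || tray_area <= 0)
    tm_validation_error("densities and tray area must be positive")
  if (length(seed_masses) != length(design$species_ids))
    tm_validation_error("seed_masses must align with the design's species")
  if (any(!is.finite(seed_masses) | seed_masses <= 0))
    tm_validation_error("seed masses must be strictly positive")
  p <- design$abundances
  mass_m2 <- p * native_density
  mass_tray <- mass_m2 * tray_area
  count_tray <- mass_tray / (seed_masses / 1000)  # mg -> g per seed
  out <- data.frame(
    species_id = design$species_ids,
    abundance = p,
    sown_mass_g_m2 = mass_m2,
    sown_mass_g_tray = mass_tray,
    seed_count = count_tray,
    stringsAsFactors = FALSE
  )
  attr(out, "native_total_g_tray") <- native_density * tray_area
  attr(out, "invader_total_g_tray") <- invader_density * tray_area
  attr(out, "tray_area_m2") <- tray_area
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
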