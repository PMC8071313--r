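# Inference stage: per-week biomass standardization, Grubbs outlier screening
# with group-mean replacement, predictor rescaling, mixture comparison with
# Tukey grouping, and linear mixed-effects models with type III Wald
# chi-square tests.

#' Standardize biomass per week
#'
#' Harvest periods differ in length (10, 15 and 22 weeks by default), so
#' biomass is divided by the period length before any comparison across
#' periods. Adds `native_pw` and `invader_pw` columns (g/week).
#'
#' @param obs tray observation table with columns `weeks`,
#'   `native_biomass_g`, `invader_biomass_g`.
#' @return `obs` with the two per-week columns appended.
#' @export
standardize_per_week <- function(obs) {
  needed <- c("weeks", "native_biomass_g", "invader_biomass_g")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (any(!is.finite(obs$weeks) | obs$weeks <= 0))
    tm_validation_error("weeks must be positive")
  obs$native_pw <- obs$native_biomass_g / obs$weeks
  obs$invader_pw <- obs$invader_biomass_g / obs$weeks
  obs
}

#' Grubbs statistic and critical value
#'
#' `grubbs_statistic` returns the maximum studentized deviation from the
#' sample mean, `G = max_i |x_i - mean(x)| / sd(x)` (sample SD), and the index
#' of the extreme point. `grubbs_critical` gives the two-sided critical value
#' at level `alpha` from the closed form
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with
#' `t = qt(alpha/(2n), n-2)` (upper tail).
#'
#' @param x numeric sample, `n >= 3`, non-constant.
#' @return list with `g` and `index`.
#' @export
grubbs_statistic <- function(x) {
  n <- length(x)
  if (n < 3) tm_validation_error("Grubbs test needs at least 3 observations")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    tm_degenerate_error("Grubbs test is not applicable to a constant sample")
  dev <- abs(x - mean(x)) / s
  i <- which.max(dev)
  list(g = dev[i], index = i)
}

#' @rdname grubbs_statistic
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) tm_validation_error("Grubbs critical value needs n >= 3")
  tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Replace outliers by group means
#'
#' Within each mixture x period group, each screened column is tested with an
#' iterative two-sided Grubbs test at level `alpha` (at most `max_iter`
#' removals per group). Flagged values are replaced by the group mean; by
#' default the mean is computed over the retained (non-flagged) members, since
#' including the outlier in its own replacement would leave its influence in
#' place (`mode = "all"` gives that alternative reading). Group size never
#' changes and replacements always lie inside the retained members' observed
#' range. Groups that are too small or constant are skipped and logged.
#'
#' @param obs observation table.
#' @param columns columns to screen (default the two per-week biomasses).
#' @param group_cols grouping columns (default mixture x period).
#' @param alpha Grubbs level (default 0.05).
#' @param max_iter maximum outliers removed per group and column (default 2).
#' @param mode `"retained"` (default) or `"all"`: which members enter the
#'   replacement mean.
#' @return list with `observations` (cleaned table, same dimensions) and `log`
#'   (one row per replacement or skipped group).
#' @export
replace_outliers <- function(obs, columns = c("native_pw", "invader_pw"),
                             group_cols = c("mixture_code", "period"),
                             alpha = 0.05, max_iter = 2L,
                             mode = c("retained", "all")) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(c(columns, group_cols), names(obs))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  key <- interaction(obs[group_cols], drop = TRUE, sep = " | ")
  log_rows <- list()
  note <- function(group, column, row, action, original, replacement) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      group = group, column = column, row = row, action = action,
      original = original, replacement = replacement, stringsAsFactors = FALSE)
  }
  for (g in levels(key)) {
    rows <- which(key == g)
    for (col in columns) {
      x <- obs[[col]][rows]
      if (length(x) < 3) {
        note(g, col, NA_integer_, "skipped: group smaller than 3", NA_real_, NA_real_)
        next
      }
      if (stats::sd(x) < 1e-12) {
        note(g, col, NA_integer_, "skipped: constant group", NA_real_, NA_real_)
        next
      }
      flagged <- integer(0)
      retained <- seq_along(x)
      for (iter in seq_len(max_iter)) {
        if (length(retained) < 3 || stats::sd(x[retained]) < 1e-12) break
        gs <- grubbs_statistic(x[retained])
        if (gs$g <= grubbs_critical(length(retained), alpha)) break
        flagged <- c(flagged, retained[gs$index])
        retained <- retained[-gs$index]
      }
      if (length(flagged) > 0) {
        members <- if (mode == "retained") retained else seq_along(x)
        repl <- mean(x[members])
        for (f in flagged) {
          note(g, col, rows[f], "replaced", x[f], repl)
          obs[[col]][rows[f]] <- repl
        }
      }
    }
  }
  log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(group = character(0), column = character(0), row = integer(0),
               action = character(0), original = numeric(0), replacement = numeric(0),
               stringsAsFactors = FALSE)
  list(observations = obs, log = log)
}

#' Rescale table columns to unit sample standard deviation
#'
#' Mirrors the conventional centre-and-scale rescaling applied to continuous
#' model inputs whose units span orders of magnitude (mm^2 to mg): each
#' selected column is centered (optional, default on) and divided by its
#' sample SD. The per-column location and scale are stored in the
#' `"scale_log"` attribute.
#'
#' @param table data.frame.
#' @param columns numeric columns to rescale.
#' @param center logical, subtract the mean first (default `TRUE`).
#' @return the table with rescaled columns and a `"scale_log"` attribute.
#' @export
scale_columns <- function(table, columns, center = TRUE) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  log <- data.frame(column = columns, center = NA_real_, scale = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    x <- table[[columns[i]]]
    if (!is.numeric(x)) tm_validation_error(sprintf("column %s is not numeric", columns[i]))
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12)
      tm_degenerate_error(sprintf("column %s is constant; cannot rescale", columns[i]))
    ctr <- if (center) mean(x, na.rm = TRUE) else 0
    table[[columns[i]]] <- (x - ctr) / s
    log$center[i] <- ctr
    log$scale[i] <- s
  }
  attr(table, "scale_log") <- log
  table
}

#' Compare mixtures with a linear model and Tukey grouping
#'
#' Fits `response ~ mixture + period` (period as a covariate), reports the
#' omnibus Wald chi-square over the mixture factor (df = levels - 1), and
#' groups mixtures with pairwise Tukey contrasts at family-wise `alpha`:
#' mixtures sharing a letter are not significantly different. The
#' multivariate-t adjustment behind the letters consumes random numbers, so it
#' runs under a locally fixed seed (`tukey_seed`) and restores the caller's
#' RNG state, keeping results reproducible.
#'
#' @param obs observation table with `mixture_code`, `period` and the response
#'   column; at least two mixtures with at least two replicates each.
#' @param response response column (default `"invader_pw"`).
#' @param alpha family-wise level for the letter display (default 0.05).
#' @param tukey_seed seed for the multivariate-t quadrature (default 1).
#' @return object of class `mixture_comparison`: `chisq`, `df`, `p_value`,
#'   `letters` (data.frame `mixture_code, group`), and the underlying `lm`
#'   fit.
#' @export
compare_mixtures <- function(obs, response = "invader_pw", alpha = 0.05,
                             tukey_seed = 1L) {
  missing_cols <- setdiff(c("mixture_code", "period", response), names(obs))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  obs$mixture_code <- factor(obs$mixture_code)
  if (nlevels(obs$mixture_code) < 2)
    tm_validation_error("need at least two mixtures to compare")
  if (min(table(obs$mixture_code)) < 2)
    tm_validation_error("each mixture needs at least two replicates")

  fml <- stats::as.formula(paste(response, "~ mixture_code + period"))
  fit <- stats::lm(fml, data = obs)
  coefs <- names(stats::coef(fit))
  mix_coefs <- coefs[startsWith(coefs, "mixture_code")]
  lh <- car::linearHypothesis(fit, mix_coefs, test = "Chisq")
  chisq <- lh$Chisq[2]
  df <- as.integer(lh$Df[2])
  p <- lh$`Pr(>Chisq)`[2]

  letters_df <- with_local_seed(tukey_seed, {
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(mixture_code = "Tukey"))
    # the quadrature reports when it misses its accuracy target on many-level
    # factors; letter grouping is unaffected at that scale
    cld_fit <- suppressWarnings(multcomp::cld(glht_fit, level = alpha))
    lt <- cld_fit$mcletters$Letters
    data.frame(mixture_code = names(lt), group = unname(lt), stringsAsFactors = FALSE)
  })

  structure(list(chisq = chisq, df = df, p_value = p,
                 alpha = alpha, letters = letters_df, fit = fit),
            class = "mixture_comparison")
}

#' @export
print.mixture_comparison <- function(x, ...) {
  cat(sprintf("Mixture omnibus Wald test: chisq = %.2f, df = %d, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  cat("Tukey letter groups (alpha =", x$alpha, "):\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}

#' Mixed-effects model for invader biomass
#'
#' Fits the predictor model for per-week invader biomass: native per-week
#' biomass, CWM seed mass, CWM leaf area, CWM plant height and Faith's PD
#' (all rescaled to unit SD by default), with random intercepts for tray and
#' for period. Each fixed effect is tested with a type III Wald chi-square
#' `(estimate/SE)^2` on 1 df. With only three period levels the period
#' variance component is often estimated at the boundary; a singular fit
#' triggers the documented fallback with period as a fixed factor (recorded
#' in the result).
#'
#' @param data merged observation/summary table; rows with missing predictors
#'   (e.g. the invader monoculture, which has no native community) are
#'   dropped.
#' @param response response column (default `"invader_pw"`).
#' @param predictors fixed-effect columns.
#' @param rescale rescale predictors to unit SD first (default `TRUE`).
#' @return object of class `invader_model`: `terms` (data.frame with
#'   `term, estimate, se, chisq, df, p`), `random` (descriptor),
#'   `singular_fallback`, `n`, and the `lme4` fit.
#' @export
fit_invader_model <- function(data, response = "invader_pw",
                              predictors = c("native_pw", "cwm_seed_mass",
                                             "cwm_leaf_area", "cwm_height",
                                             "pd_faith"),
                              rescale = TRUE) {
  needed <- c(response, predictors, "tray_id", "period")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  keep <- stats::complete.cases(data[, needed])
  data <- data[keep, ]
  if (rescale) data <- scale_columns(data, predictors)
  data$period_f <- factor(data$period)

  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "),
    "+ (1 | tray_id) + (1 | period_f)"))
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))
  singular_fallback <- lme4::isSingular(fit, tol = 1e-5)
  random <- "(1 | tray_id) + (1 | period)"
  if (singular_fallback) {
    fml2 <- stats::as.formula(paste(
      response, "~", paste(predictors, collapse = " + "),
      "+ period_f + (1 | tray_id)"))
    fit <- suppressMessages(lme4::lmer(fml2, data = data, REML = TRUE))
    random <- "(1 | tray_id); period as fixed factor (singular-fit fallback)"
  }

  sm <- summary(fit)$coefficients
  est <- sm[predictors, "Estimate"]
  se <- sm[predictors, "Std. Error"]
  chisq <- (est / se)^2
  terms <- data.frame(
    term = predictors,
    estimate = unname(est),
    se = unname(se),
    chisq = unname(chisq),
    df = 1L,
    p = unname(stats::pchisq(chisq, df = 1, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms, random = random,
                 singular_fallback = singular_fallback,
                 n = nrow(data), fit = fit),
            class = "invader_model")
}

#' @export
print.invader_model <- function(x, ...) {
  cat(sprintf("Invader-biomass mixed model (n = %d); random: %s\n", x$n, x$random))
  out <- x$terms
  out$chisq <- round(out$chisq, 2)
  out$p <- signif(out$p, 3)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Treatment-structure model: community type, constrained and diversified trait
#'
#' Companion mixed model on the designed mixtures only, testing the factorial
#' treatment structure (community type, constrained trait, diversified trait,
#' and the diversified x community-type interaction) with type III Wald
#' chi-square tests under sum-to-zero contrasts.
#'
#' @param obs observation table restricted to designed mixtures, with
#'   `mixture_code`, `tray_id`, `period` and the response; treatment factors
#'   are parsed from the mixture codes.
#' @param response response column (default `"invader_pw"`).
#' @return an `invader_model`-like object with one row per tested term
#'   (multi-df terms allowed).
#' @export
fit_treatment_model <- function(obs, response = "invader_pw") {
  parsed <- parse_mixture_code(obs$mixture_code)
  bad <- is.na(parsed$community_type)
  if (any(bad))
    tm_validation_error(sprintf("not a designed-mixture code: %s",
                                paste(unique(obs$mixture_code[bad]), collapse = ", ")))
  obs$community_type <- factor(parsed$community_type)
  obs$constrained <- factor(parsed$constrained)
  obs$diversified <- factor(parsed$diversified)
  obs$period_f <- factor(obs$period)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fml <- stats::as.formula(paste(
    response, "~ community_type * diversified + constrained",
    "+ (1 | tray_id) + (1 | period_f)"))
  fit <- suppressMessages(lme4::lmer(fml, data = obs, REML = TRUE))
  singular_fallback <- lme4::isSingular(fit, tol = 1e-5)
  random <- "(1 | tray_id) + (1 | period)"
  if (singular_fallback) {
    fml2 <- stats::as.formula(paste(
      response, "~ community_type * diversified + constrained + period_f + (1 | tray_id)"))
    fit <- suppressMessages(lme4::lmer(fml2, data = obs, REML = TRUE))
    random <- "(1 | tray_id); period as fixed factor (singular-fit fallback)"
  }
  an <- car::Anova(fit, type = 3)
  keep <- c("community_type", "diversified", "constrained", "community_type:diversified")
  an <- an[rownames(an) %in% keep, ]
  terms <- data.frame(
    term = rownames(an),
    estimate = NA_real_,
    se = NA_real_,
    chisq = an$Chisq,
    df = an$Df,
    p = an$`Pr(>Chisq)`,
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms, random = random,
                 singular_fallback = singular_fallback,
                 n = nrow(obs), fit = fit),
            class = "invader_model")
}

#' Parse mixture codes into treatment factors
#'
#' @param codes character vector of codes like `"M-Ph*Sm*"`.
#' @return data.frame `community_type, constrained, diversified` (NA for
#'   reference codes).
#' @export
parse_mixture_code <- function(codes) {
  m <- regmatches(codes, regexec("^([MW])-(Ph|La|Sm)\\*(Ph|La|Sm)\\*$", codes))
  traits <- stats::setNames(names(TRAIT_ABBREV), TRAIT_ABBREV)
  out <- data.frame(community_type = NA_character_, constrained = NA_character_,
                    diversified = NA_character_, stringsAsFactors = FALSE)[rep(1, length(codes)), ]
  for (i in seq_along(codes)) {
    if (length(m[[i]]) == 4) {
      out$community_type[i] <- c(M = "mesic", W = "wet")[[m[[i]][2]]]
      out$constrained[i] <- traits[[m[[i]][3]]]
      out$diversified[i] <- traits[[m[[i]][4]]]
    }
  }
  rownames(out) <- NULL
  out
}

#' Enumerate the experimental design
#'
#' Ordered pairs of distinct traits give `n_traits * (n_traits - 1)`
#' treatments per community type; designed mixtures multiply by the number of
#' community types; trays add the reference communities and multiply by the
#' replicates. Defaults reproduce the study layout: 6 treatments per
#' community type, 12 designed mixtures, 84 trays.
#'
#' @param n_traits number of manipulated traits (>= 2).
#' @param community_types number of base community types.
#' @param references number of reference communities (commercial mixture and
#'   invader monoculture).
#' @param replicates trays per mixture.
#' @param periods number of harvest periods.
#' @return list with the counts and a `trays` data.frame (one row per tray).
#' @export
enumerate_design <- function(n_traits = 3, community_types = 2, references = 2,
                             replicates = 6, periods = 3) {
  if (n_traits < 2) tm_validation_error("need at least two traits")
  treatments_per_type <- as.integer(n_traits * (n_traits - 1))
  designed_mixtures <- as.integer(treatments_per_type * community_types)
  n_mixtures <- as.integer(designed_mixtures + references)
  n_trays <- as.integer(n_mixtures * replicates)
  trays <- data.frame(
    tray_id = sprintf("T%03d", seq_len(n_trays)),
    mixture_index = rep(seq_len(n_mixtures), each = replicates),
    replicate = rep(seq_len(replicates), times = n_mixtures),
    stringsAsFactors = FALSE
  )
  list(
    treatments_per_type = treatments_per_type,
    designed_mixtures = designed_mixtures,
    n_mixtures = n_mixtures,
    n_trays = n_trays,
    n_observations = as.integer(n_trays * periods),
    omnibus_df = as.integer(designed_mixtures - 1),
    trays = trays
  )
}
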