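# Species-pool ingestion and trait standardization.
#
# The species table carries, per pool member: taxonomy (family), growth form
# (grass/forb/legume), the three functional traits used for mixture design
# (plant height in m, leaf area in mm^2, seed mass in mg), a germination rate,
# and the Briemle-Ellenberg cutting-tolerance score (1-9). Units are taken at
# face value from the file; the loader validates presence and sign, not unit
# correctness.

# canonical trait names -> CSV column names
TRAIT_COLUMNS <- c(
  height    = "height_m",
  leaf_area = "leaf_area_mm2",
  seed_mass = "seed_mass_mg"
)

SPECIES_COLUMNS <- c(
  "species_id", "family", "growth_form",
  unname(TRAIT_COLUMNS),
  "germination_rate", "cutting_tolerance"
)

GROWTH_FORMS <- c("grass", "forb", "legume")

#' Load and validate a species trait table
#'
#' Reads a UTF-8, comma-separated table with header columns
#' `species_id,family,growth_form,height_m,leaf_area_mm2,seed_mass_mg,germination_rate,cutting_tolerance`
#' (extra columns are carried through untouched). Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return a `data.frame`, one row per species.
#' @seealso [load_invader_record()], [standardize_traits()]
#' @export
load_species_table <- function(path) {
  if (!file.exists(path)) tm_validation_error(sprintf("species table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_species_table(df)
  df
}

#' Validate a species table in memory
#'
#' @param df a data.frame shaped like the output of [load_species_table()].
#' @return `df`, invisibly, if valid; otherwise a schema or validation error.
#' @export
validate_species_table <- function(df) {
  missing_cols <- setdiff(SPECIES_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("missing required column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) return(invisible(df))

  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup) > 0)
    tm_validation_error(sprintf("duplicate species_id: %s",
                                paste(unique(dup), collapse = ", ")))
  bad_form <- setdiff(unique(df$growth_form), GROWTH_FORMS)
  if (length(bad_form) > 0)
    tm_validation_error(sprintf("unknown growth_form value(s): %s",
                                paste(bad_form, collapse = ", ")))
  for (trait in names(TRAIT_COLUMNS)) {
    col <- TRAIT_COLUMNS[[trait]]
    x <- df[[col]]
    bad <- !is.finite(x) | x <= 0
    if (any(bad))
      tm_validation_error(sprintf(
        "trait %s must be strictly positive; offending species: %s",
        col, paste(df$species_id[bad], collapse = ", ")))
  }
  g <- df$germination_rate
  bad_g <- !is.finite(g) | g < 0 | g > 1
  if (any(bad_g))
    tm_validation_error(sprintf("germination_rate outside [0, 1] for: %s",
                                paste(df$species_id[bad_g], collapse = ", ")))
  ct <- df$cutting_tolerance
  bad_ct <- !is.finite(ct) | ct != round(ct) | ct < 1 | ct > 9
  if (any(bad_ct))
    tm_validation_error(sprintf("cutting_tolerance must be an integer in 1..9 for: %s",
                                paste(df$species_id[bad_ct], collapse = ", ")))
  invisible(df)
}

#' Write a species table back to CSV
#'
#' Inverse of [load_species_table()] up to numeric formatting; loading, writing
#' and re-loading yields identical records.
#'
#' @param df species table.
#' @param path output path.
#' @export
write_species_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the invader's trait record
#'
#' Same schema as the species table but a single row; `germination_rate` and
#' `cutting_tolerance` are optional for the invader. Trait units must match the
#' pool's.
#'
#' @param path path to a one-row CSV.
#' @return a one-row `data.frame` with at least `species_id` and the three
#'   trait columns.
#' @export
load_invader_record <- function(path) {
  if (!file.exists(path)) tm_validation_error(sprintf("invader record not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_invader_record(df)
  df
}

#' @rdname load_invader_record
#' @param df one-row data.frame to validate in memory.
#' @export
validate_invader_record <- function(df) {
  needed <- c("species_id", unname(TRAIT_COLUMNS))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    tm_schema_error(sprintf("invader record: missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  if (nrow(df) != 1)
    tm_validation_error(sprintf("invader record must have exactly one row, got %d", nrow(df)))
  for (col in unname(TRAIT_COLUMNS)) {
    x <- df[[col]]
    if (!is.finite(x) || x <= 0)
      tm_validation_error(sprintf("invader trait %s must be strictly positive", col))
  }
  invisible(df)
}

#' Standardize the trait matrix
#'
#' Selected traits are optionally log-transformed, then centered and scaled to
#' unit sample (n - 1) standard deviation. Seed mass and leaf area are
#' log-transformed by default because both span orders of magnitude across a
#' typical grassland pool. The transform parameters are stored so the
#' standardization can be inverted exactly, and so external values (the
#' invader's trait) can be placed on the same scale.
#'
#' @param species species table (validated; >= 2 rows).
#' @param log_transform character vector of trait names (any of `"height"`,
#'   `"leaf_area"`, `"seed_mass"`) to log before scaling.
#' @return an object of class `trait_matrix`: list with `species_id`, `raw`
#'   (n x 3), `standardized` (n x 3, unit sample SD columns), and `params`
#'   (per-trait log flag, center, scale).
#' @export
standardize_traits <- function(species, log_transform = c("leaf_area", "seed_mass")) {
  validate_species_table(species)
  if (nrow(species) < 2)
    tm_validation_error("need at least two species to standardize traits")
  unknown <- setdiff(log_transform, names(TRAIT_COLUMNS))
  if (length(unknown) > 0)
    tm_validation_error(sprintf("unknown trait name(s) in log_transform: %s",
                                paste(unknown, collapse = ", ")))

  raw <- as.matrix(species[, unname(TRAIT_COLUMNS)])
  colnames(raw) <- names(TRAIT_COLUMNS)
  rownames(raw) <- species$species_id

  std <- raw
  params <- data.frame(
    trait  = names(TRAIT_COLUMNS),
    log    = names(TRAIT_COLUMNS) %in% log_transform,
    center = NA_real_,
    scale  = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(names(TRAIT_COLUMNS))) {
    x <- raw[, k]
    if (params$log[k]) x <- log(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12)
      tm_degenerate_error(sprintf(
        "trait %s is constant across species; cannot standardize", params$trait[k]))
    params$center[k] <- mean(x)
    params$scale[k] <- s
    std[, k] <- (x - params$center[k]) / s
  }
  structure(
    list(species_id = species$species_id, raw = raw, standardized = std, params = params),
    class = "trait_matrix"
  )
}

#' Invert a standardized trait matrix back to raw units
#'
#' @param tm a `trait_matrix` from [standardize_traits()].
#' @param standardized optional matrix of standardized values to invert
#'   (defaults to `tm$standardized`).
#' @return a matrix of raw trait values.
#' @export
invert_traits <- function(tm, standardized = tm$standardized) {
  stopifnot(inherits(tm, "trait_matrix"))
  out <- standardized
  for (k in seq_len(nrow(tm$params))) {
    x <- standardized[, k] * tm$params$scale[k] + tm$params$center[k]
    if (tm$params$log[k]) x <- exp(x)
    out[, k] <- x
  }
  out
}

#' Place an external raw trait value on a pool's standardized scale
#'
#' Used to standardize the invader's trait value with the pool's own
#' transform parameters before it becomes the equality-constraint target.
#'
#' @param tm a `trait_matrix`.
#' @param trait one of `"height"`, `"leaf_area"`, `"seed_mass"`.
#' @param value raw trait value (same units as the pool's table).
#' @return the standardized (dimensionless) value.
#' @export
standardize_value <- function(tm, trait, value) {
  stopifnot(inherits(tm, "trait_matrix"))
  k <- match(trait, tm$params$trait)
  if (is.na(k)) tm_validation_error(sprintf("unknown trait: %s", trait))
  if (!is.finite(value) || value <= 0)
    tm_validation_error(sprintf("trait value for %s must be strictly positive", trait))
  x <- if (tm$params$log[k]) log(value) else value
  (x - tm$params$center[k]) / tm$params$scale[k]
}

#' Re-weight abundances by germination rate
#'
#' Optional hook, off by default throughout the pipeline: the study reports
#' germination around 65% but does not state whether germination adjusted sown
#' abundances or community-weighted means, so no stage applies this implicitly.
#'
#' @param p simplex abundance vector.
#' @param germination germination rates in \[0, 1\], same length as `p`.
#' @return renormalized abundance vector proportional to `p * germination`.
#' @export
adjust_for_germination <- function(p, germination) {
  if (length(p) != length(germination))
    tm_validation_error("abundances and germination rates differ in length")
  w <- p * germination
  tot <- sum(w)
  if (tot <= 0) tm_degenerate_error("all germination-weighted abundances are zero")
  w / tot
}
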