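# Community descriptors: community-weighted mean traits on raw units,
# cutting-tolerance abundance updates across harvest periods, and Faith's
# phylogenetic diversity on a rooted tree.

#' Community-weighted mean
#'
#' `CWM = sum(p * t)`: abundance-weighted average of a trait, always inside
#' the convex hull of the trait values of supported species.
#'
#' @param p simplex abundance vector.
#' @param t raw trait values, same length.
#' @return scalar CWM in raw trait units.
#' @export
cwm <- function(p, t) {
  if (length(p) != length(t)) tm_validation_error("abundance and trait vectors differ in length")
  if (abs(sum(p) - 1) > 1e-6 || min(p) < -1e-8)
    tm_validation_error("abundances must lie on the simplex")
  sum(p * t)
}

#' Cutting-tolerance abundance update
#'
#' One cutting event re-weights abundances by the Briemle-Ellenberg cutting
#' tolerance (1 = not cutting tolerant ... 9 = promoted by cutting; 5 =
#' unaffected): `p'_i = p_i c_i / sum_j p_j c_j`. A uniform tolerance vector
#' leaves abundances unchanged; applying the update with `c` twice equals one
#' update with `c^2`.
#'
#' @param p simplex abundance vector.
#' @param tolerance cutting tolerances, same length as `p`; the
#'   Briemle-Ellenberg scale is 1..9 (enforced on species tables by the
#'   loader), but any positive weights are accepted so that composed updates
#'   (`tolerance^2`, ...) remain expressible.
#' @param events number of cutting events to apply (>= 0); cumulative
#'   application uses `tolerance^events`.
#' @return updated simplex abundance vector.
#' @export
update_abundances_cutting <- function(p, tolerance, events = 1L) {
  if (length(p) != length(tolerance))
    tm_validation_error("abundance and tolerance vectors differ in length")
  if (any(!is.finite(tolerance) | tolerance <= 0))
    tm_validation_error("cutting tolerance weights must be positive")
  if (events < 0) tm_validation_error("number of cutting events must be >= 0")
  if (events == 0) return(p)
  w <- p * tolerance^events
  tot <- sum(w)
  if (tot <= 0) tm_degenerate_error("all weighted abundances are zero after the cutting update")
  w / tot
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the given taxa.
#' Under the default rooted convention the subtree always includes the path to
#' the root of the supplied tree, so PD is monotone under taxon addition and a
#' single-taxon community has PD equal to its root-to-tip distance. With
#' `include_root = FALSE` the subtree is cut at the taxa's most recent common
#' ancestor instead (a single taxon then has PD 0).
#'
#' @param tree a rooted `phylo` object with branch lengths (>= 0).
#' @param taxa character vector of tip labels; the empty set has PD 0.
#' @param include_root logical; include the stem path to the root
#'   (default `TRUE`).
#' @return nonnegative PD in branch-length units.
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  if (!inherits(tree, "phylo")) tm_validation_error("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) tm_validation_error("tree must have branch lengths")
  if (any(tree$edge.length < 0)) tm_validation_error("branch lengths must be nonnegative")
  taxa <- unique(taxa)
  if (length(taxa) == 0) return(0)
  tips <- match(taxa, tree$tip.label)
  if (anyNA(tips))
    tm_validation_error(sprintf("taxa not found in the tree: %s",
                                paste(taxa[is.na(tips)], collapse = ", ")))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))          # child node -> edge index
  parent_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  edges_used <- logical(nrow(tree$edge))
  for (tip in tips) {
    node <- tip
    while (node != root) {
      e <- parent_of[node]
      if (edges_used[e]) break                  # path above already collected
      edges_used[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  if (!include_root && length(tips) >= 1) {
    # remove the stem edges between the root and the taxa's MRCA
    mrca_node <- if (length(tips) == 1) tips else ape::getMRCA(tree, tips)
    node <- mrca_node
    while (node != root) {
      e <- parent_of[node]
      edges_used[e] <- FALSE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges_used])
}

#' Summarize one community in one experimental period
#'
#' CWMs of the three design traits (raw units) on the period's realized
#' abundances, plus Faith's PD of the species set. Period 1 uses the sown
#' abundances; periods 2 and 3 use the cutting-tolerance update applied
#' cumulatively to the original mixture (one event before period 2, two before
#' period 3). PD depends only on the species set, never on abundances, so it
#' is constant across periods for a fixed mixture. The invader is not part of
#' the native community and never enters these summaries.
#'
#' @param design a `mixture_design` (or any list with `mixture_code`,
#'   `species_ids`, `abundances`).
#' @param species species table supplying raw traits and cutting tolerances.
#' @param tree rooted `phylo` whose tips cover the design's species.
#' @param period integer 1..3.
#' @param cumulative logical; if `FALSE`, periods 2 and 3 both use a single
#'   multiplication of the original abundances (the alternative reading of the
#'   update rule).
#' @param include_root passed to [faith_pd()].
#' @return one-row data.frame `mixture_code, period, cwm_height,
#'   cwm_leaf_area, cwm_seed_mass, pd_faith`.
#' @export
summarize_community <- function(design, species, tree, period,
                                cumulative = TRUE, include_root = TRUE) {
  if (!period %in% 1:3) tm_validation_error("period must be 1, 2 or 3")
  idx <- match(design$species_ids, species$species_id)
  if (anyNA(idx))
    tm_validation_error(sprintf("species missing from the trait table: %s",
                                paste(design$species_ids[is.na(idx)], collapse = ", ")))
  sp <- species[idx, ]
  p <- design$abundances
  events <- if (cumulative) period - 1L else min(period - 1L, 1L)
  p_t <- update_abundances_cutting(p, sp$cutting_tolerance, events = events)
  supported <- design$species_ids[p > 0]
  data.frame(
    mixture_code = design$mixture_code,
    period = as.integer(period),
    cwm_height = cwm(p_t, sp$height_m),
    cwm_leaf_area = cwm(p_t, sp$leaf_area_mm2),
    cwm_seed_mass = cwm(p_t, sp$seed_mass_mg),
    pd_faith = faith_pd(tree, supported, include_root = include_root),
    stringsAsFactors = FALSE
  )
}

#' Community summaries for all designs and periods
#'
#' @param designs list of `mixture_design` objects.
#' @param species species table.
#' @param tree rooted `phylo`.
#' @param periods integer vector (default 1:3).
#' @inheritParams summarize_community
#' @return data.frame, one row per mixture x period.
#' @export
summarize_communities <- function(designs, species, tree, periods = 1:3,
                                  cumulative = TRUE, include_root = TRUE) {
  rows <- list()
  for (d in designs) {
    for (k in periods) {
      rows[[length(rows) + 1L]] <-
        summarize_community(d, species, tree, k,
                            cumulative = cumulative, include_root = include_root)
    }
  }
  do.call(rbind, rows)
}
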