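#' Synthetic-feasibility score configuration
#'
#' The feasibility reward scores each route tree as the product of three
#' factors and scores a molecule as its highest-scoring tree:
#'
#' * stock factor: product over leaf precursors of 1.0 (internal stock),
#'   0.8 (commercial) or 0.1 (unavailable);
#' * reaction factor: product over reaction steps of 1.0 (preferred
#'   reaction) or 0.1 (any other);
#' * step factor: `k^n` with `k` in (0,1) (default 0.9) and `n` the number
#'   of reaction steps, so a stock-available target scores 1.0 and a
#'   three-step route 0.9^3 = 0.729.
#'
#' Preferred reactions may be given at any taxonomy level: an entry `"3.1"`
#' admits every named Suzuki variant because the route's code is truncated
#' to the entry's level before membership is tested.
#'
#' @param internal_score,commercial_score,unavailable_score per-leaf stock
#'   factors, each in (0, 1].
#' @param preferred_reactions character vector of preferred reaction codes
#'   (any level, e.g. `c("3.1", "2.1", "1.3")`).
#' @param preferred_score,other_reaction_score per-reaction factors in
#'   (0, 1].
#' @param k step coefficient, strictly between 0 and 1.
#' @param use_unsolved score unsolved trees as well (default `TRUE`; the
#'   unavailable-leaf factor already penalizes them).
#' @param max_steps optional cap: trees with more reaction steps are
#'   ignored when scoring a molecule (`NULL` = no cap).
#' @return An object of class `sf_config`.
#' @export
sf_config <- function(internal_score = 1.0, commercial_score = 0.8,
                      unavailable_score = 0.1,
                      preferred_reactions = character(),
                      preferred_score = 1.0, other_reaction_score = 0.1,
                      k = 0.9, use_unsolved = TRUE, max_steps = NULL) {
  scores <- c(internal_score, commercial_score, unavailable_score,
              preferred_score, other_reaction_score)
  if (any(scores <= 0) || any(scores > 1))
    stop("all component scores must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1)
    stop("step coefficient `k` must lie strictly between 0 and 1", call. = FALSE)
  preferred <- lapply(as.character(preferred_reactions), parse_code)
  structure(
    list(internal_score = internal_score, commercial_score = commercial_score,
         unavailable_score = unavailable_score, preferred = preferred,
         preferred_score = preferred_score,
         other_reaction_score = other_reaction_score, k = k,
         use_unsolved = isTRUE(use_unsolved),
         max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps)),
    class = "sf_config"
  )
}

#' Stock-availability factor of a route
#'
#' Product over the leaf precursors of the per-status score. Availability is
#' looked up in `catalog` at score time (so swapping catalogs re-scores
#' correctly); with `catalog = NULL` the stock annotations recorded on the
#' tree are used.
#'
#' @param tree a `route_tree`.
#' @param catalog a [stock_catalog()] or `NULL`.
#' @param cfg an [sf_config()].
#' @return Number in (0, 1].
#' @export
stock_score <- function(tree, catalog = NULL, cfg = sf_config()) {
  leaves <- route_leaves(tree)
  if (length(leaves) == 0L) return(1)
  status <- if (is.null(catalog)) {
    vapply(leaves, function(l) l$stock, character(1))
  } else {
    stock_status(catalog, vapply(leaves, function(l) l$id, character(1)))
  }
  factors <- c(internal = cfg$internal_score, commercial = cfg$commercial_score,
               unavailable = cfg$unavailable_score)
  prod(factors[status])
}

#' Reaction-preference factor of a route
#'
#' Product over reaction steps of `preferred_score` when the step's code
#' matches a preferred entry (after truncation to the entry's level) and
#' `other_reaction_score` otherwise. A zero-step route scores 1 (empty
#' product); unrecognized reactions are never preferred.
#'
#' @inheritParams stock_score
#' @return Number in (0, 1].
#' @export
reaction_score <- function(tree, cfg = sf_config()) {
  codes <- route_reactions(tree)
  if (length(codes) == 0L) return(1)
  is_pref <- vapply(codes, function(cd) {
    if (is_unrecognized(cd)) return(FALSE)
    own <- match(code_level(cd), .code_levels)
    any(vapply(cfg$preferred, function(p) {
      want <- match(code_level(p), .code_levels)
      want <= own && truncate_code(cd, code_level(p)) == p
    }, logical(1)))
  }, logical(1))
  prod(ifelse(is_pref, cfg$preferred_score, cfg$other_reaction_score))
}

#' Step-count factor
#'
#' Exponential decay `k^n` penalizing synthetic length: 1.0 at zero steps,
#' 0.9^3 = 0.729 for a three-step route at the default `k`.
#'
#' @param n non-negative integer step count.
#' @param k coefficient strictly between 0 and 1.
#' @return Number in (0, 1].
#' @export
step_score <- function(n, k = 0.9) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1)
    stop("step coefficient `k` must lie strictly between 0 and 1", call. = FALSE)
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  k^n
}

#' Feasibility score of a single route tree
#'
#' The product stock factor x reaction factor x step factor.
#'
#' @inheritParams stock_score
#' @return Number in (0, 1].
#' @export
sfscore_tree <- function(tree, catalog = NULL, cfg = sf_config()) {
  stock_score(tree, catalog, cfg) * reaction_score(tree, cfg) *
    step_score(count_steps(tree), cfg$k)
}

#' Feasibility score of a molecule
#'
#' A molecule is scored as its highest-scoring route tree. Unsolved trees
#' are included unless `cfg$use_unsolved` is `FALSE`, and trees longer than
#' `cfg$max_steps` (when set) are ignored. A molecule with no eligible
#' trees scores 0.
#'
#' @param trees list of `route_tree` objects for one molecule.
#' @inheritParams stock_score
#' @return Number in \[0, 1\].
#' @export
sfscore_molecule <- function(trees, catalog = NULL, cfg = sf_config()) {
  if (length(trees) == 0L) return(0)
  keep <- vapply(trees, function(t) {
    (cfg$use_unsolved || t$solved) &&
      (is.null(cfg$max_steps) || count_steps(t) <= cfg$max_steps)
  }, logical(1))
  trees <- trees[keep]
  if (length(trees) == 0L) return(0)
  max(vapply(trees, sfscore_tree, numeric(1), catalog = catalog, cfg = cfg))
}

# ---- reference-route similarity -------------------------------------------

#' Reference-route similarity configuration
#'
#' The reference-route reward measures, for each solved route of a
#' molecule, the tree edit distance between its canonical reaction tree and
#' a fixed reference tree, maps the distance to a similarity in \[0, 1\],
#' and scores the molecule as the maximum similarity over its solved
#' routes. The similarity transform maps distance 0 to 1 and decreases
#' strictly toward 0:
#'
#' * `"reciprocal"` (default): `1 / (1 + d / scale)`;
#' * `"exponential"`: `exp(-d / scale)`.
#'
#' @param reference_route a `reaction_tree` (e.g. from [reaction_chain()]
#'   or [canonical_reaction_tree()]); must be non-empty.
#' @param scheme a [ted_cost_scheme()].
#' @param transform `"reciprocal"` or `"exponential"`.
#' @param scale positive scale parameter of the transform.
#' @return An object of class `rr_config`.
#' @export
rr_config <- function(reference_route, scheme = ted_cost_scheme(),
                      transform = c("reciprocal", "exponential"), scale = 1) {
  transform <- match.arg(transform)
  if (is.null(reference_route) || tree_size(reference_route) == 0L)
    stop("the reference route must be a non-empty reaction tree", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0)
    stop("`scale` must be positive", call. = FALSE)
  structure(
    list(reference_route = reference_route, scheme = scheme,
         transform = transform, scale = scale),
    class = "rr_config"
  )
}

#' Map a tree edit distance to a similarity
#' @param d non-negative distance(s).
#' @param cfg an [rr_config()] (only its transform fields are used).
#' @return Similarity in (0, 1], equal to 1 iff `d == 0`.
#' @export
ted_similarity <- function(d, cfg) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  switch(cfg$transform,
         reciprocal = 1 / (1 + d / cfg$scale),
         exponential = exp(-d / cfg$scale))
}

#' Reference-route similarity of a molecule
#'
#' Maximum similarity over the molecule's solved routes; a molecule with no
#' solved routes scores 0, and a molecule with a solved route identical to
#' the reference scores exactly 1.
#'
#' @param solved_trees list of solved `route_tree` objects (unsolved trees,
#'   if present, are skipped).
#' @param cfg an [rr_config()].
#' @return Number in \[0, 1\].
#' @export
rrscore_molecule <- function(solved_trees, cfg) {
  stopifnot(inherits(cfg, "rr_config"))
  solved_trees <- Filter(function(t) isTRUE(t$solved), solved_trees)
  if (length(solved_trees) == 0L) return(0)
  d <- vapply(solved_trees, function(t)
    tree_edit_distance(canonical_reaction_tree(t), cfg$reference_route,
                       cfg$scheme), numeric(1))
  max(ted_similarity(d, cfg))
}
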