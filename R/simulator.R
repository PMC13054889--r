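#' Synthetic-world specification
#'
#' The desk-scale simulator replaces the full retrosynthesis stack with a
#' seeded synthetic world: a reaction taxonomy, a stock catalog, and a set
#' of route archetypes. An archetype is a family of routes drawing its
#' reaction steps from a small pool of named-level codes (so its class-level
#' signatures are subsets of a few classes), with a step-count
#' distribution, a solvability probability, and surrogate property-score
#' parameters standing in for external property oracles. Each archetype
#' owns a finite pocket of candidate molecules, so a policy that
#' over-exploits one archetype starts regenerating duplicate molecules —
#' the behaviour the batch-level rewards are designed to expose.
#'
#' The first archetype (`ref`) emits the fixed two-step reference route
#' (2.1.10 carboxylic ester + amine, then 3.1.2 chloro Suzuki coupling),
#' with occasional named-level variants, and is the convergence target of
#' the reference-route reward.
#'
#' @param n_superclasses,classes_per_superclass,named_per_class taxonomy
#'   dimensions (display bookkeeping; codes are drawn from archetype
#'   pools).
#' @param stock_size number of building blocks in the generated catalog.
#' @param internal_fraction fraction of the stock flagged as internal.
#' @param archetypes list of archetype definitions; see
#'   [default_archetypes()].
#' @param pocket_size candidate molecules per archetype.
#' @param unrecognized_prob probability that a reaction step loses its
#'   classification (yielding an invalid signature).
#' @param trees_per_molecule probabilities of a molecule having 1, 2 or 3
#'   route trees.
#' @return An object of class `world_spec`.
#' @export
world_spec <- function(n_superclasses = 12, classes_per_superclass = 8,
                       named_per_class = 10,
                       stock_size = 600, internal_fraction = 0.5,
                       archetypes = default_archetypes(),
                       pocket_size = 3000, unrecognized_prob = 0.04,
                       trees_per_molecule = c(0.45, 0.35, 0.2)) {
  probs <- c(internal_fraction, unrecognized_prob, trees_per_molecule,
             vapply(archetypes, function(a) a$solvability, numeric(1)),
             vapply(archetypes, function(a) a$hit_prob, numeric(1)))
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (length(archetypes) < 2L)
    stop("a world needs at least two route archetypes", call. = FALSE)
  if (abs(sum(trees_per_molecule) - 1) > 1e-8)
    stop("`trees_per_molecule` must sum to 1", call. = FALSE)
  nm <- vapply(archetypes, function(a) a$name, character(1))
  if (anyDuplicated(nm)) stop("archetype names must be unique", call. = FALSE)
  structure(
    list(n_superclasses = n_superclasses,
         classes_per_superclass = classes_per_superclass,
         named_per_class = named_per_class,
         stock_size = as.integer(stock_size),
         internal_fraction = internal_fraction,
         archetypes = archetypes, pocket_size = as.integer(pocket_size),
         unrecognized_prob = unrecognized_prob,
         trees_per_molecule = trees_per_molecule),
    class = "world_spec"
  )
}

.archetype <- function(name, pool, steps_probs = c(0.35, 0.45, 0.2),
                       solvability = 0.85, hit_prob = 0.1, prop_mean = 0.55,
                       chain = NULL) {
  list(name = name, pool = pool, steps_probs = steps_probs,
       solvability = solvability, hit_prob = hit_prob, prop_mean = prop_mean,
       chain = chain)
}

#' Default route archetypes
#'
#' Eight archetypes spanning distinct regions of the reaction taxonomy.
#' Each generic archetype draws 1-3 steps from a six-code pool covering
#' three reaction classes, so its class-level signatures are the non-empty
#' subsets of those classes (up to seven plates per archetype). The `ref`
#' archetype emits the fixed reference chain. Property-score means are
#' deliberately uneven — `sub_s` is the most rewarding pocket for the
#' surrogate property oracle — so that a property-only (control) policy
#' drifts into a single pocket, the behaviour the plate-filling reward is
#' meant to counteract.
#'
#' @return List of archetype definitions for [world_spec()].
#' @export
default_archetypes <- function() {
  list(
    .archetype("ref", pool = c("2.1.10", "3.1.2"),
               chain = c("2.1.10", "3.1.2"),
               solvability = 0.9, hit_prob = 0.12, prop_mean = 0.55),
    .archetype("sub_s", pool = c("1.8.1", "1.8.5", "1.7.2", "1.7.9", "1.2.1", "1.2.4"),
               solvability = 0.85, hit_prob = 0.14, prop_mean = 0.74),
    .archetype("n_aryl", pool = c("1.3.1", "1.3.6", "1.4.2", "1.4.5", "1.5.1", "1.5.3"),
               solvability = 0.85, hit_prob = 0.12, prop_mean = 0.58),
    .archetype("alkylation", pool = c("1.6.2", "1.6.4", "1.9.1", "1.9.6", "1.1.2", "1.1.5"),
               solvability = 0.8, hit_prob = 0.1, prop_mean = 0.56),
    .archetype("amide", pool = c("2.1.1", "2.1.2", "2.2.3", "2.2.5", "2.3.1", "2.3.4"),
               solvability = 0.9, hit_prob = 0.12, prop_mean = 0.6),
    .archetype("suzuki", pool = c("3.1.1", "3.1.5", "3.2.1", "3.2.3", "3.3.2", "3.3.4"),
               solvability = 0.85, hit_prob = 0.12, prop_mean = 0.57),
    .archetype("heterocycle", pool = c("4.1.1", "4.1.3", "4.2.2", "4.2.6", "4.3.1", "4.3.5"),
               solvability = 0.8, hit_prob = 0.1, prop_mean = 0.54),
    .archetype("reduction", pool = c("5.1.1", "5.1.4", "5.2.2", "5.2.5", "5.3.1", "5.3.3"),
               solvability = 0.85, hit_prob = 0.1, prop_mean = 0.55)
  )
}

#' Build a deterministic synthetic world
#'
#' @param spec a [world_spec()].
#' @param seed integer seed; the same (spec, seed) pair always yields an
#'   identical world.
#' @return An object of class `sim_world` holding the stock catalog and
#'   archetype definitions.
#' @export
build_world <- function(spec = world_spec(), seed = 1) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(as.integer(seed))
  ids <- sprintf("BB%05d", seq_len(spec$stock_size))
  n_int <- round(spec$stock_size * spec$internal_fraction)
  sources <- c(rep("internal", n_int),
               rep("commercial", spec$stock_size - n_int))
  structure(
    list(spec = spec, seed = as.integer(seed),
         catalog = stock_catalog(ids, sources),
         stock_ids = ids,
         archetype_names = vapply(spec$archetypes, function(a) a$name,
                                  character(1))),
    class = "sim_world"
  )
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world> seed ", x$seed, ": ", length(x$stock_ids),
      " building blocks, archetypes ",
      paste(x$archetype_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one route tree drawn from an archetype (uses current RNG state)
.sample_route <- function(world, arch, mol_id) {
  spec <- world$spec
  if (!is.null(arch$chain)) {
    codes <- arch$chain
    # occasional named-level variant keeps the reference pocket non-trivial
    if (stats::runif(1) < 0.3) {
      slot <- sample.int(length(codes), 1L)
      codes[slot] <- if (slot == 1L) "2.1.3" else "3.1.1"
    }
  } else {
    n <- sample.int(3L, 1L, prob = arch$steps_probs)
    codes <- sample(arch$pool, min(n, length(arch$pool)))
  }
  lost <- stats::runif(length(codes)) < spec$unrecognized_prob
  cls <- ifelse(lost, NA_character_, codes)
  solved <- stats::runif(1) < arch$solvability
  leaf <- function(ok) {
    if (ok) {
      id <- sample(world$stock_ids, 1L)
      .mol_node(id, unname(world$catalog$entries[[id]]))
    } else {
      .mol_node(sprintf("UNK%06d", sample.int(999999L, 1L)), "unavailable")
    }
  }
  # build from the deepest reaction up; one leaf of the deepest step is
  # knocked out of stock when the route is unsolved
  node <- NULL
  for (i in rev(seq_along(codes))) {
    deepest <- i == length(codes)
    kids <- list(leaf(solved || !deepest))
    if (!is.null(node)) {
      inter <- .mol_node(sprintf("INT_%s_%d", mol_id, i), "unavailable",
                         list(node))
      kids <- c(kids, list(inter))
    } else {
      kids <- c(kids, list(leaf(TRUE)))
    }
    cd <- if (is.na(cls[i])) code_unrecognized() else parse_code(cls[i])
    node <- .reaction_node(cd, if (is.na(cls[i])) NULL else cls[i], kids)
  }
  root <- .mol_node(mol_id, "unavailable", list(node))
  new_route_tree(root, "simulator")
}

#' Sample a batch of molecules from the world
#'
#' Each molecule is drawn from the archetype selected by the policy, given
#' an identifier from that archetype's finite pocket (unique within the
#' batch; pockets are shared across batches, so duplicates recur between
#' epochs under a concentrated policy), 1-3 route trees, a surrogate
#' property score in \[0, 1\] and a surrogate hit flag.
#'
#' @param world a [build_world()] result.
#' @param policy a [new_policy()].
#' @param n batch size.
#' @param seed integer seed for this batch.
#' @param epoch epoch index recorded on the batch.
#' @return A [batch_context()]; each molecule record carries `mol_id`,
#'   `trees`, `archetype`, `property` and `hit`.
#' @export
sample_batch <- function(world, policy, n = 128, seed = 1, epoch = NA_integer_) {
  stopifnot(inherits(world, "sim_world"), inherits(policy, "sim_policy"), n >= 1)
  set.seed(as.integer(seed))
  spec <- world$spec
  archs <- spec$archetypes
  pick <- sample.int(length(archs), n, replace = TRUE, prob = policy$weights)
  used <- character(0)
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- archs[[pick[i]]]
    repeat {
      idx <- sample.int(spec$pocket_size, 1L)
      id <- sprintf("%s_m%05d", arch$name, idx)
      if (!id %in% used) break
    }
    used <- c(used, id)
    n_trees <- sample.int(3L, 1L, prob = spec$trees_per_molecule)
    trees <- lapply(seq_len(n_trees), function(j) .sample_route(world, arch, id))
    conc <- 10
    prop <- stats::rbeta(1, arch$prop_mean * conc, (1 - arch$prop_mean) * conc)
    solved_any <- any(vapply(trees, function(t) t$solved, logical(1)))
    hit <- solved_any && stats::runif(1) < arch$hit_prob
    mols[[i]] <- list(mol_id = id, trees = trees, archetype = arch$name,
                      property = prop, hit = hit)
  }
  batch_context(mols, epoch = epoch)
}

#' Archetype-selection policy
#'
#' A multiplicative-weights bandit over route archetypes — the smallest
#' policy that can respond to a reward signal. It stands in for the
#' sequence-model agent of a full generative-RL stack and makes no claim
#' about it.
#'
#' @param archetypes character vector of archetype names.
#' @param lr learning rate of the multiplicative update.
#' @param weights initial weights (uniform by default); normalized to sum
#'   to 1.
#' @return An object of class `sim_policy`.
#' @export
new_policy <- function(archetypes, lr = 2, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(archetypes))
  if (length(weights) != length(archetypes) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  w <- weights / sum(weights)
  names(w) <- archetypes
  structure(list(weights = w, lr = lr), class = "sim_policy")
}

#' @export
print.sim_policy <- function(x, ...) {
  cat("<sim_policy> lr ", x$lr, "; weights: ",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Multiplicative-weights policy update
#'
#' Each archetype's weight is multiplied by `exp(lr * r_a)` where `r_a` is
#' the mean reward of its molecules in the batch (0 for archetypes absent
#' from the batch), then the weights are renormalized. With all archetypes
#' present and equal rewards the policy is unchanged; `lr = 0` is the
#' identity.
#'
#' @param policy a [new_policy()].
#' @param rewards named numeric vector of per-molecule rewards in \[0, 1\]
#'   (names are molecule ids).
#' @param batch the [batch_context()] the rewards were computed on (its
#'   molecule records carry the archetype assignment).
#' @return The updated `sim_policy`.
#' @export
policy_update <- function(policy, rewards, batch) {
  stopifnot(inherits(policy, "sim_policy"), inherits(batch, "batch_context"))
  if (any(rewards < 0 - 1e-12) || any(rewards > 1 + 1e-12))
    stop("rewards must lie in [0, 1]", call. = FALSE)
  arch <- vapply(batch$molecules, function(m) m$archetype, character(1))
  ids <- vapply(batch$molecules, function(m) m$mol_id, character(1))
  r <- rewards[ids]
  mean_r <- vapply(names(policy$weights), function(a) {
    sel <- arch == a
    if (any(sel)) mean(r[sel]) else 0
  }, numeric(1))
  w <- policy$weights * exp(policy$lr * mean_r)
  policy$weights <- w / sum(w)
  policy
}

#' Simulation run configuration
#'
#' Defaults echo the full-scale experimental setting where desk scale
#' permits: batch size 128, geometric-mean MPO over the synthesis-aware
#' component and the surrogate property score with equal weight (weight 0
#' on the synthesis component in control runs), class-level signatures,
#' preferred reaction classes 3.1 / 2.1 / 1.3, and the two-step
#' 2.1.10 -> 3.1.2 reference route. Epochs default to 200 and plate
#' capacity to 50 at desk scale (1000 epochs and capacity 1000 reproduce
#' the full-scale loop shape).
#'
#' @param reward one of `"sfscore"`, `"rrscore"`, `"popularity"`,
#'   `"fill_a_plate"`, `"control"`. A control run evaluates and logs the
#'   plate-filling component but gives it weight 0 in the MPO, so policy
#'   drift is driven by the surrogate property score alone.
#' @param epochs,batch_size loop dimensions.
#' @param capacity plate capacity for the ledger.
#' @param seed master seed; all batch seeds derive from it.
#' @param lr policy learning rate.
#' @param exclude_molecules plate-filling exclusion flag.
#' @param spec a [world_spec()].
#' @param sf an [sf_config()].
#' @param rr an [rr_config()].
#' @param level signature taxonomy level.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(reward = c("sfscore", "rrscore", "popularity",
                                         "fill_a_plate", "control"),
                              epochs = 200, batch_size = 128, capacity = 50,
                              seed = 1, lr = 2, exclude_molecules = TRUE,
                              spec = world_spec(),
                              sf = sf_config(preferred_reactions =
                                               c("3.1", "2.1", "1.3"),
                                             max_steps = 3),
                              rr = rr_config(reaction_chain(c("2.1.10", "3.1.2"))),
                              level = "class") {
  reward <- match.arg(reward)
  structure(
    list(reward = reward, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), capacity = as.integer(capacity),
         seed = as.integer(seed), lr = lr,
         exclude_molecules = isTRUE(exclude_molecules),
         spec = spec, sf = sf, rr = rr, level = level),
    class = "sim_config"
  )
}

.batch_seed <- function(seed, epoch) {
  as.integer((as.numeric(seed) * 7919 + epoch) %% 2147483587)
}

# min TED to the reference over solved trees, memoised by canonical key
.min_ref_distance <- function(trees, rr, cache) {
  trees <- Filter(function(t) isTRUE(t$solved), trees)
  if (length(trees) == 0L) return(NA_real_)
  d <- vapply(trees, function(t) {
    ct <- canonical_reaction_tree(t)
    key <- .tree_key(ct)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tree_edit_distance(ct, rr$reference_route, rr$scheme)
    assign(key, val, envir = cache)
    val
  }, numeric(1))
  min(d)
}

#' Run a desk-scale generation experiment
#'
#' Runs the toy generation loop: sample a batch from the policy, compute
#' the active reward for every molecule, combine it with the surrogate
#' property score by weighted geometric mean (weight 0 on the active
#' component in control runs), update the policy, and log per-epoch
#' metrics. The plate ledger and the batch-level popularity metrics are
#' computed for every run regardless of the active reward, so control runs
#' log the same synthetic metrics they do not optimize.
#'
#' @param config a [simulation_config()].
#' @return A list of class `sim_result`: `metrics` (a data.frame with one
#'   row per epoch: `epoch`, `mean_active`, `mean_combined`,
#'   `dominant_signature`, `dominant_fraction`, `cum_unique_molecules`,
#'   `cum_hits`, `filled_plates`, `mean_ted`), the final `ledger`, the
#'   final `policy` and the `config`. `mean_ted` is the batch-mean minimum
#'   distance to the reference route (reference-route runs only, `NA`
#'   otherwise).
#' @export
run_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  world <- build_world(config$spec, config$seed)
  policy <- new_policy(world$archetype_names, lr = config$lr)
  ledger <- plate_ledger(config$capacity)
  ted_cache <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  hits <- new.env(parent = emptyenv())
  active_weight <- if (config$reward == "control") 0 else 1
  rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    batch <- sample_batch(world, policy, config$batch_size,
                          seed = .batch_seed(config$seed, epoch),
                          epoch = epoch)
    ids <- vapply(batch$molecules, function(m) m$mol_id, character(1))
    pop <- popularity_scores(batch, level = config$level)
    fap <- fill_a_plate_update(batch, ledger,
                               exclude_molecules = config$exclude_molecules,
                               level = config$level)
    ledger <- fap$ledger
    active <- switch(
      config$reward,
      sfscore = vapply(batch$molecules, function(m)
        sfscore_molecule(m$trees, world$catalog, config$sf), numeric(1)),
      rrscore = vapply(batch$molecules, function(m) {
        d <- .min_ref_distance(m$trees, config$rr, ted_cache)
        if (is.na(d)) 0 else ted_similarity(d, config$rr)
      }, numeric(1)),
      popularity = unname(pop),
      fill_a_plate = unname(fap$scores),
      control = unname(fap$scores)
    )
    names(active) <- ids
    prop <- vapply(batch$molecules, function(m) m$property, numeric(1))
    combined <- vapply(seq_along(active), function(i)
      combine_scores(c(active[i], prop[i]), c(active_weight, 1)), numeric(1))
    names(combined) <- ids
    mean_ted <- NA_real_
    if (config$reward == "rrscore") {
      d <- vapply(batch$molecules, function(m)
        .min_ref_distance(m$trees, config$rr, ted_cache), numeric(1))
      mean_ted <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }
    for (id in ids) assign(id, TRUE, envir = seen)
    for (i in seq_along(ids))
      if (isTRUE(batch$molecules[[i]]$hit)) assign(ids[i], TRUE, envir = hits)
    fr <- attr(pop, "signature_fractions")
    rows[[epoch]] <- data.frame(
      epoch = epoch,
      mean_active = mean(active),
      mean_combined = mean(combined),
      dominant_signature = if (length(fr)) names(fr)[1L] else NA_character_,
      dominant_fraction = if (length(fr)) unname(fr[1L]) else 0,
      cum_unique_molecules = length(ls(seen)),
      cum_hits = length(ls(hits)),
      filled_plates = filled_plate_count(ledger),
      mean_ted = mean_ted,
      stringsAsFactors = FALSE
    )
    policy <- policy_update(policy, combined, batch)
  }
  structure(list(metrics = do.call(rbind, rows), ledger = ledger,
                 policy = policy, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat("<sim_result> reward=", x$config$reward, ", ", nrow(x$metrics),
      " epochs x ", x$config$batch_size, " molecules (seed ",
      x$config$seed, ")\n", sep = "")
  cat("  final epoch: mean reward ", signif(last$mean_active, 3),
      ", dominant signature {", last$dominant_signature, "} at ",
      signif(last$dominant_fraction, 3), ", ", last$filled_plates,
      " filled plates\n", sep = "")
  invisible(x)
}
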