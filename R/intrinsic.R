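#' Batch of generated molecules
#'
#' The intrinsic rewards operate on a batch: an ordered list of molecules,
#' each carrying the route trees found for it. Molecule ids must be unique
#' within a batch.
#'
#' @param molecules list of records, each a list with at least `mol_id`
#'   (non-empty string) and `trees` (list of `route_tree`); extra fields
#'   (archetype, surrogate property scores, ...) are carried through.
#' @param epoch optional epoch index for bookkeeping.
#' @return An object of class `batch_context`.
#' @export
batch_context <- function(molecules, epoch = NA_integer_) {
  if (!is.list(molecules) || length(molecules) == 0L)
    stop("a batch must contain at least one molecule", call. = FALSE)
  ids <- vapply(molecules, function(m) as.character(m$mol_id %||% ""), character(1))
  if (any(!nzchar(ids)))
    stop("every batch molecule needs a non-empty `mol_id`", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate mol_id within batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(molecules = molecules, n = length(molecules), epoch = epoch),
            class = "batch_context")
}

#' @export
print.batch_context <- function(x, ...) {
  cat("<batch_context> ", x$n, " molecules",
      if (!is.na(x$epoch)) paste0(" (epoch ", x$epoch, ")"), "\n", sep = "")
  invisible(x)
}

# unique valid signature keys of a molecule's trees
.molecule_signatures <- function(mol, level, solved_only) {
  trees <- mol$trees
  if (solved_only) trees <- Filter(function(t) isTRUE(t$solved), trees)
  sigs <- lapply(trees, route_signature, level = level)
  keys <- vapply(sigs, function(s) if (s$valid) s$key else NA_character_,
                 character(1))
  unique(keys[!is.na(keys)])
}

#' Batch-level route popularity
#'
#' Encodes each solved route of each molecule as a class-level route
#' signature and measures, per signature `S`, the fraction `|M_S| / N` of
#' batch molecules possessing a solved route with that signature. Each
#' molecule scores the maximum popularity over its own solved-route
#' signatures, so a score of 1 means the molecule shares a route signature
#' with every other molecule in the batch. Molecules with no solved tree,
#' or whose routes all carry invalid signatures (e.g. unrecognized
#' reactions), score 0.
#'
#' @param batch a [batch_context()].
#' @param level signature taxonomy level (class by default).
#' @return Named numeric vector of scores in \[0, 1\] (names are molecule
#'   ids, in batch order), with an attribute `signature_fractions`: the
#'   named popularity of every signature seen in the batch, decreasing.
#' @export
popularity_scores <- function(batch, level = c("class", "superclass", "named")) {
  stopifnot(inherits(batch, "batch_context"))
  level <- match.arg(level)
  per_mol <- lapply(batch$molecules, .molecule_signatures,
                    level = level, solved_only = TRUE)
  counts <- table(unlist(per_mol))
  pop <- as.numeric(counts) / batch$n
  names(pop) <- names(counts)
  scores <- vapply(per_mol, function(keys)
    if (length(keys)) max(pop[keys]) else 0, numeric(1))
  names(scores) <- vapply(batch$molecules, function(m) m$mol_id, character(1))
  attr(scores, "signature_fractions") <-
    if (length(pop)) sort(pop, decreasing = TRUE) else pop
  scores
}

# ---- plate ledger ----------------------------------------------------------

#' Cross-batch plate ledger
#'
#' The plate-filling reward tracks, across batches, how many distinct
#' molecules have been assigned to each route signature ("plate"). Each
#' plate holds at most `capacity` molecules; once full it is saturated and
#' never scores again, and (optionally) the molecules that filled it are
#' excluded from all future plates.
#'
#' @param capacity positive integer plate capacity (1000 in the full-scale
#'   setting; desk-scale runs typically use less).
#' @return An object of class `plate_ledger` with fields `capacity`,
#'   `counts` (named, per signature key), `saturated`, `consumed`,
#'   `assignments` (mol_id -> signature key) and `filled_epoch`.
#' @export
plate_ledger <- function(capacity = 1000) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity <= 0L)
    stop("plate capacity must be a positive integer", call. = FALSE)
  structure(
    list(capacity = capacity,
         counts = structure(numeric(0), names = character(0)),
         saturated = character(0),
         consumed = character(0),
         assignments = structure(character(0), names = character(0)),
         filled_epoch = structure(integer(0), names = character(0))),
    class = "plate_ledger"
  )
}

#' @export
print.plate_ledger <- function(x, ...) {
  cat("<plate_ledger> capacity ", x$capacity, ": ", length(x$counts),
      " signature(s), ", length(x$saturated), " saturated, ",
      length(x$assignments), " molecules assigned\n", sep = "")
  invisible(x)
}

#' Number of filled plates
#' @param ledger a [plate_ledger()].
#' @return Non-negative integer, the number of saturated signatures.
#' @export
filled_plate_count <- function(ledger) {
  stopifnot(inherits(ledger, "plate_ledger"))
  length(ledger$saturated)
}

#' Plate-filling reward for a batch
#'
#' Processes the batch in order. For each molecule, among the valid,
#' unsaturated signatures of all its routes (solved and unsolved), the one
#' with the highest cumulative count is chosen — the plate closest to
#' capacity — with ties broken by the lexicographically smallest signature
#' key. If the molecule is new to that plate its count is incremented, and
#' the reward is the filling ratio `count / capacity` after assignment
#' (0.7 for a plate 70% full). When a plate reaches capacity its signature
#' is saturated and scores 0 from then on; with `exclude_molecules = TRUE`
#' the molecules that filled it are additionally consumed and score 0 in
#' all future batches. Molecules whose ids were seen before never
#' re-increment a count: without exclusion they receive the current ratio
#' of their assigned plate, with exclusion they receive 0. Molecules with
#' no valid unsaturated signature score 0.
#'
#' @param batch a [batch_context()] (trees include solved and unsolved
#'   routes).
#' @param ledger a [plate_ledger()].
#' @param exclude_molecules exclude molecules of a filled plate from future
#'   plates.
#' @param level signature taxonomy level (class by default).
#' @return A list with `scores` (named numeric, batch order) and the
#'   updated `ledger`.
#' @export
fill_a_plate_update <- function(batch, ledger, exclude_molecules = FALSE,
                                level = c("class", "superclass", "named")) {
  stopifnot(inherits(batch, "batch_context"), inherits(ledger, "plate_ledger"))
  level <- match.arg(level)
  C <- ledger$capacity
  scores <- numeric(batch$n)
  names(scores) <- vapply(batch$molecules, function(m) m$mol_id, character(1))
  for (i in seq_len(batch$n)) {
    m <- batch$molecules[[i]]
    id <- m$mol_id
    if (exclude_molecules &&
        (id %in% ledger$consumed || id %in% names(ledger$assignments))) {
      scores[i] <- 0
      next
    }
    if (id %in% names(ledger$assignments)) {
      sig <- ledger$assignments[[id]]
      scores[i] <- if (sig %in% ledger$saturated) 0 else ledger$counts[[sig]] / C
      next
    }
    keys <- .molecule_signatures(m, level = level, solved_only = FALSE)
    keys <- setdiff(keys, ledger$saturated)
    if (length(keys) == 0L) {
      scores[i] <- 0
      next
    }
    cnt <- ledger$counts[keys]
    cnt[is.na(cnt)] <- 0
    names(cnt) <- keys
    best <- keys[cnt == max(cnt)]
    sig <- sort(best)[1L]
    new_count <- unname(cnt[[sig]]) + 1
    ledger$counts[[sig]] <- new_count
    ledger$assignments[[id]] <- sig
    scores[i] <- new_count / C
    if (new_count >= C) {
      ledger$saturated <- c(ledger$saturated, sig)
      ledger$filled_epoch[[sig]] <-
        if (is.na(batch$epoch)) NA_integer_ else as.integer(batch$epoch)
      if (exclude_molecules) {
        members <- names(ledger$assignments)[ledger$assignments == sig]
        ledger$consumed <- union(ledger$consumed, members)
      }
    }
  }
  list(scores = scores, ledger = ledger)
}

#' Persist and restore plate ledgers
#'
#' The ledger serializes to a small JSON document (schema
#' `synthreward-ledger/1`) including the saturated and consumed sets, so a
#' run can be resumed across processes with identical state.
#'
#' @param ledger a [plate_ledger()].
#' @param path file path.
#' @return `ledger_load()` returns the restored [plate_ledger()];
#'   `ledger_save()` returns `path` invisibly.
#' @export
ledger_save <- function(ledger, path) {
  stopifnot(inherits(ledger, "plate_ledger"))
  rec <- list(
    schema = "synthreward-ledger/1",
    capacity = ledger$capacity,
    counts = as.list(ledger$counts),
    saturated = ledger$saturated,
    consumed = ledger$consumed,
    assignments = as.list(ledger$assignments),
    filled_epoch = as.list(ledger$filled_epoch)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname ledger_save
#' @export
ledger_load <- function(path) {
  if (!file.exists(path)) stop("no such ledger file: ", path, call. = FALSE)
  rec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt ledger file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(rec$schema, "synthreward-ledger/1"))
    stop("corrupt ledger file ", path, ": missing or unknown `schema` field",
         call. = FALSE)
  if (is.null(rec$capacity))
    stop("corrupt ledger file ", path, ": missing `capacity`", call. = FALSE)
  led <- plate_ledger(rec$capacity)
  led$counts <- vapply(rec$counts, as.numeric, numeric(1))
  if (length(led$counts) == 0L)
    led$counts <- structure(numeric(0), names = character(0))
  led$saturated <- as.character(unlist(rec$saturated))
  led$consumed <- as.character(unlist(rec$consumed))
  led$assignments <- vapply(rec$assignments, as.character, character(1))
  if (length(led$assignments) == 0L)
    led$assignments <- structure(character(0), names = character(0))
  led$filled_epoch <- vapply(rec$filled_epoch,
                             function(x) if (is.null(x)) NA_integer_ else as.integer(x),
                             integer(1))
  if (length(led$filled_epoch) == 0L)
    led$filled_epoch <- structure(integer(0), names = character(0))
  if (any(led$counts > led$capacity))
    stop("corrupt ledger file ", path, ": count exceeds capacity", call. = FALSE)
  led
}

#' Per-plate report
#' @param ledger a [plate_ledger()].
#' @return A data.frame with one row per signature: `signature`, `count`,
#'   `saturated`, `filled_epoch`, sorted by decreasing count.
#' @export
plates_report <- function(ledger) {
  stopifnot(inherits(ledger, "plate_ledger"))
  sigs <- names(ledger$counts)
  df <- data.frame(
    signature = sigs,
    count = as.numeric(ledger$counts),
    saturated = sigs %in% ledger$saturated,
    filled_epoch = vapply(sigs, function(s)
      if (s %in% names(ledger$filled_epoch)) ledger$filled_epoch[[s]]
      else NA_integer_, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df[order(-df$count, df$signature), , drop = FALSE]
}
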