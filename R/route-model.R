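#' Stock catalogs of starting materials
#'
#' A stock catalog maps molecule identifiers to their availability:
#' `"internal"` (in-house stock), `"commercial"` (purchasable building
#' blocks) or `"unavailable"`. Looking up an identifier absent from the
#' catalog yields `"unavailable"`. Identifiers are compared after a single
#' normalization step (whitespace trimming), applied identically to catalog
#' entries and route documents.
#'
#' @param ids character vector of molecule identifiers (opaque ids or
#'   SMILES strings).
#' @param sources availability of each id, `"internal"` or `"commercial"`;
#'   recycled if scalar.
#' @return An object of class `stock_catalog`.
#' @examples
#' cat <- stock_catalog(c("CCO", "c1ccccc1"), c("internal", "commercial"))
#' stock_status(cat, "CCO")        # "internal"
#' stock_status(cat, "missing")    # "unavailable"
#' @export
stock_catalog <- function(ids = character(), sources = "internal") {
  ids <- canonical_id(ids)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("catalog ids must be non-empty strings", call. = FALSE)
  sources <- rep_len(as.character(sources), length(ids))
  bad <- setdiff(unique(sources), c("internal", "commercial"))
  if (length(bad))
    stop("unknown stock source(s): ", paste(bad, collapse = ", "), call. = FALSE)
  entries <- sources
  names(entries) <- ids
  # last entry wins on duplicate ids
  entries <- entries[!duplicated(names(entries), fromLast = TRUE)]
  structure(list(entries = entries), class = "stock_catalog")
}

#' @export
print.stock_catalog <- function(x, ...) {
  tab <- table(factor(x$entries, levels = c("internal", "commercial")))
  cat("<stock_catalog> ", length(x$entries), " ids (",
      tab[["internal"]], " internal, ", tab[["commercial"]], " commercial)\n",
      sep = "")
  invisible(x)
}

#' Canonicalize molecule identifiers
#'
#' The single normalization applied to every identifier before comparison:
#' leading/trailing whitespace is trimmed. Applied identically to stock
#' catalogs and route documents.
#' @param id character vector.
#' @return Character vector of the same length.
#' @export
canonical_id <- function(id) trimws(as.character(id))

#' Look up stock status
#' @param catalog a [stock_catalog()] or `NULL` (everything unavailable).
#' @param id character vector of molecule identifiers.
#' @return Character vector: `"internal"`, `"commercial"` or `"unavailable"`.
#' @export
stock_status <- function(catalog, id) {
  id <- canonical_id(id)
  if (is.null(catalog)) return(rep("unavailable", length(id)))
  stopifnot(inherits(catalog, "stock_catalog"))
  status <- unname(catalog$entries[id])
  status[is.na(status)] <- "unavailable"
  status
}

#' Read a stock catalog from disk
#'
#' Two formats are supported: CSV with a header `id,source` where source is
#' `internal` or `commercial`, and plain text with one identifier per line
#' (all entries treated as internal stock).
#'
#' @param path file path.
#' @param format `"auto"` (CSV when the first line is an `id,source`
#'   header), `"csv"` or `"plain"`.
#' @return A [stock_catalog()].
#' @export
read_stock_catalog <- function(path, format = c("auto", "csv", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such stock file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*id\\s*,\\s*source\\s*$", first)) "csv" else "plain"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "source") %in% names(df)))
      stop("stock CSV must have columns `id` and `source`", call. = FALSE)
    stock_catalog(df$id, df$source)
  } else {
    ids <- readLines(path, warn = FALSE)
    ids <- ids[nzchar(trimws(ids))]
    stock_catalog(ids, "internal")
  }
}

# ---- route trees -----------------------------------------------------------

.mol_node <- function(id, stock = "unavailable", children = list()) {
  list(type = "mol", id = id, stock = stock, children = children)
}

.reaction_node <- function(code, classification = NULL, children = list()) {
  list(type = "reaction", code = code, classification = classification,
       children = children)
}

new_route_tree <- function(root, provenance = NULL) {
  structure(
    list(root = root, solved = .all_leaves_stocked(root), provenance = provenance),
    class = "route_tree"
  )
}

.all_leaves_stocked <- function(node) {
  if (node$type == "mol" && length(node$children) == 0L)
    return(node$stock != "unavailable")
  all(vapply(node$children, .all_leaves_stocked, logical(1)))
}

#' Build a route tree in code
#'
#' Programmatic constructor mirroring the JSON schema: a molecule node is
#' `mol(id, stock, reaction)` and a reaction node is
#' `rxn(classification, mol, mol, ...)`. The solved flag is computed from
#' the leaf stock annotations (or from `catalog` when supplied, which takes
#' precedence over per-node annotations).
#'
#' @param root a molecule node built with [mol()].
#' @param catalog optional [stock_catalog()] used to (re)annotate leaves.
#' @param provenance free-text source tag.
#' @return A validated `route_tree`.
#' @examples
#' t <- route_tree(mol("TARGET", reaction = rxn("2.1.10",
#'   mol("A", "internal"), mol("B", "commercial"))))
#' count_steps(t)   # 1
#' t$solved         # TRUE
#' @export
route_tree <- function(root, catalog = NULL, provenance = NULL) {
  root <- .validate_node(root, expect = "mol", path = "root", catalog = catalog)
  new_route_tree(root, provenance)
}

#' @rdname route_tree
#' @param id molecule identifier.
#' @param stock `"internal"`, `"commercial"` or `"unavailable"`.
#' @param reaction optional child [rxn()] node (a route is a single
#'   decomposition, so a molecule has at most one reaction child).
#' @export
mol <- function(id, stock = "unavailable", reaction = NULL) {
  .mol_node(id, stock, if (is.null(reaction)) list() else list(reaction))
}

#' @rdname route_tree
#' @param classification reaction classification string (e.g. `"2.1.10"`),
#'   or `NULL` for an unclassified reaction.
#' @param ... child molecule nodes (at least one precursor).
#' @export
rxn <- function(classification, ...) {
  .reaction_node(code_from_annotation(classification), classification, list(...))
}

.validate_node <- function(node, expect, path, catalog) {
  if (!is.list(node) || is.null(node$type))
    stop("schema error at ", path, ": node is not a typed object", call. = FALSE)
  if (node$type != expect)
    stop("schema error at ", path, ": expected a ", expect, " node, found ",
         node$type, call. = FALSE)
  if (node$type == "mol") {
    id <- canonical_id(node$id %||% "")
    if (!nzchar(id))
      stop("schema error at ", path, ": molecule node lacks an id", call. = FALSE)
    if (length(node$children) > 1L)
      stop("schema error at ", path,
           ": a molecule node may have at most one reaction child", call. = FALSE)
    stock <- node$stock %||% "unavailable"
    if (!is.null(catalog)) {
      looked <- stock_status(catalog, id)
      if (looked != "unavailable") stock <- looked
      else if (is.null(node$stock)) stock <- "unavailable"
    }
    if (!stock %in% c("internal", "commercial", "unavailable"))
      stop("schema error at ", path, ": unknown stock status ", sQuote(stock),
           call. = FALSE)
    kids <- lapply(seq_along(node$children), function(i)
      .validate_node(node$children[[i]], "reaction",
                     paste0(path, "/children[", i, "]"), catalog))
    .mol_node(id, stock, kids)
  } else {
    if (length(node$children) < 1L)
      stop("schema error at ", path,
           ": reaction node needs at least one precursor", call. = FALSE)
    code <- node$code %||% code_from_annotation(node$classification)
    kids <- lapply(seq_along(node$children), function(i)
      .validate_node(node$children[[i]], "mol",
                     paste0(path, "/children[", i, "]"), catalog))
    .reaction_node(code, node$classification, kids)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a route document
#'
#' Reads a retrosynthetic route tree from JSON. Two dialects are supported:
#'
#' * `"native"`: `{"schema": "synthreward-route/1", "provenance": ...,
#'   "root": <node>}` where molecule nodes are `{"type": "mol", "id": ...,
#'   "stock": ..., "children": [...]}` and reaction nodes are
#'   `{"type": "reaction", "classification": "2.1.10 ...",
#'   "children": [...]}`.
#' * `"aizynthfinder"`: the nested output of AiZynthFinder route export —
#'   molecule nodes carry `"smiles"` and `"in_stock"`, reaction nodes carry
#'   the classification under `"metadata"`; unknown metadata is ignored.
#'   `in_stock: true` maps to `"commercial"` and `false` to
#'   `"unavailable"` unless the catalog says otherwise.
#'
#' Leaf availability is taken from `catalog` when one is supplied (falling
#' back to the document's own annotation for ids the catalog does not list),
#' and the solved flag is recomputed from the leaves: a route is solved iff
#' every leaf precursor has stock status other than `"unavailable"`.
#' Reactions with missing or unparseable classification strings are coded as
#' unrecognized (`0.0`); this invalidates the route's signature but is not a
#' parse error.
#'
#' @param document a file path, a JSON string, or an already-decoded list.
#' @param dialect `"native"` or `"aizynthfinder"`.
#' @param catalog optional [stock_catalog()].
#' @return A `route_tree`.
#' @export
parse_route <- function(document, dialect = c("native", "aizynthfinder"),
                        catalog = NULL) {
  dialect <- match.arg(dialect)
  doc <- .decode_document(document)
  if (dialect == "native") {
    if (is.null(doc$root))
      stop("schema error at root: native route document lacks a `root` node",
           call. = FALSE)
    root <- .validate_node(doc$root, "mol", "root", catalog)
    new_route_tree(root, doc$provenance %||% NULL)
  } else {
    root <- .from_aizynth(doc, "root")
    root <- .validate_node(root, "mol", "root", catalog)
    new_route_tree(root, "aizynthfinder")
  }
}

.decode_document <- function(document) {
  if (is.character(document) && length(document) == 1L) {
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  } else if (is.list(document)) {
    document
  } else {
    stop("`document` must be a file path, JSON string or list", call. = FALSE)
  }
}

.from_aizynth <- function(node, path) {
  if (!is.list(node) || is.null(node$type))
    stop("schema error at ", path, ": node is not a typed object", call. = FALSE)
  kids <- lapply(seq_along(node$children %||% list()), function(i)
    .from_aizynth(node$children[[i]], paste0(path, "/children[", i, "]")))
  if (node$type == "mol") {
    stock <- if (isTRUE(node$in_stock)) "commercial" else "unavailable"
    .mol_node(node$smiles %||% node$id %||% "", stock, kids)
  } else if (node$type == "reaction") {
    cls <- node$metadata$classification %||% node$classification %||% NULL
    .reaction_node(code_from_annotation(cls), cls, kids)
  } else {
    stop("schema error at ", path, ": unknown node type ", sQuote(node$type),
         call. = FALSE)
  }
}

#' Serialize a route tree
#'
#' Writes the native JSON schema. `parse_route(write_route(t))` reproduces
#' `t` exactly (stock annotations are embedded, so no catalog is needed to
#' re-parse), and serialization is byte-stable for a given tree.
#'
#' @param tree a `route_tree`.
#' @param path optional file path; when given, pretty-printed JSON is
#'   written there.
#' @return The structured record (a list), invisibly when `path` is given.
#' @export
write_route <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "route_tree"))
  rec <- list(schema = "synthreward-route/1")
  if (!is.null(tree$provenance)) rec$provenance <- tree$provenance
  rec$root <- .node_record(tree$root)
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
    return(invisible(rec))
  }
  rec
}

.node_record <- function(node) {
  if (node$type == "mol") {
    rec <- list(type = "mol", id = node$id, stock = node$stock)
  } else {
    rec <- list(type = "reaction")
    if (!is.null(node$classification)) rec$classification <- node$classification
  }
  if (length(node$children))
    rec$children <- lapply(node$children, .node_record)
  rec
}

#' @export
print.route_tree <- function(x, ...) {
  cat("<route_tree> target ", x$root$id, ": ", count_steps(x), " step(s), ",
      if (x$solved) "solved" else "unsolved",
      if (!is.null(x$provenance)) paste0(" [", x$provenance, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Number of reaction steps in a route
#'
#' Counts reaction nodes (not tree depth): a convergent route with a
#' two-branch root reaction and one further reaction per branch has three
#' steps. A stock-available target with no reactions has zero.
#'
#' @param tree a `route_tree`.
#' @return Non-negative integer.
#' @export
count_steps <- function(tree) {
  stopifnot(inherits(tree, "route_tree"))
  n_rxn <- function(node) {
    sum(vapply(node$children, n_rxn, integer(1)), (node$type == "reaction"))
  }
  n_rxn(tree$root)
}

#' Leaf precursors of a route
#' @param tree a `route_tree`.
#' @return List of leaf molecule nodes (for a zero-step route, the target
#'   itself).
#' @export
route_leaves <- function(tree) {
  stopifnot(inherits(tree, "route_tree"))
  out <- list()
  walk <- function(node) {
    if (node$type == "mol" && length(node$children) == 0L)
      out[[length(out) + 1L]] <<- node
    lapply(node$children, walk)
  }
  walk(tree$root)
  out
}

#' Reaction codes of a route
#' @param tree a `route_tree`.
#' @return List of `reaction_code` objects, one per reaction node, in
#'   depth-first document order.
#' @export
route_reactions <- function(tree) {
  stopifnot(inherits(tree, "route_tree"))
  out <- list()
  walk <- function(node) {
    if (node$type == "reaction") out[[length(out) + 1L]] <<- node$code
    lapply(node$children, walk)
  }
  walk(tree$root)
  out
}

# deterministic ordering key for a set of codes
.code_order <- function(codes) {
  key <- vapply(codes, function(cd)
    sprintf("%05d.%05d.%05d", cd$superclass,
            ifelse(is.na(cd$class_id), -1L, cd$class_id),
            ifelse(is.na(cd$named_id), -1L, cd$named_id)),
    character(1))
  order(key)
}

#' Route signature at a taxonomy level
#'
#' The signature of a route is the set of its reaction codes truncated to
#' the requested level (duplicates collapse). Each code is truncated to the
#' requested level or its own depth, whichever is shallower. The signature
#' is valid only when the route has at least one reaction and none of its
#' reactions is unrecognized: zero-step routes yield the (invalid) empty
#' signature, and the `0.0` sentinel invalidates the signature it appears
#' in.
#'
#' @param tree a `route_tree`.
#' @param level `"superclass"`, `"class"` (the default used by the
#'   batch-level rewards) or `"named"`.
#' @return An object of class `route_signature` with fields `level`,
#'   `codes` (sorted list of `reaction_code`), `valid` and `key` (a
#'   canonical string such as `"2.1+3.1"`, used as the ledger identity).
#' @export
route_signature <- function(tree, level = c("class", "superclass", "named")) {
  level <- match.arg(level)
  codes <- route_reactions(tree)
  valid <- length(codes) > 0L && !any(vapply(codes, is_unrecognized, logical(1)))
  trunc <- lapply(codes, function(cd) {
    own <- code_level(cd)
    lv <- .code_levels[min(match(level, .code_levels), match(own, .code_levels))]
    truncate_code(cd, lv)
  })
  trunc <- trunc[!duplicated(vapply(trunc, format, character(1)))]
  trunc <- trunc[.code_order(trunc)]
  structure(
    list(level = level, codes = trunc, valid = valid,
         key = paste(vapply(trunc, format, character(1)), collapse = "+")),
    class = "route_signature"
  )
}

#' @export
print.route_signature <- function(x, ...) {
  cat("<route_signature> {", x$key, "} at ", x$level, " level, ",
      if (x$valid) "valid" else "invalid", "\n", sep = "")
  invisible(x)
}

#' @export
format.route_signature <- function(x, ...) x$key

# ---- canonical reaction trees ---------------------------------------------

#' Labeled ordered reaction trees
#'
#' The tree-edit-distance machinery compares routes as ordered trees of
#' reaction nodes only; molecule nodes are elided. `reaction_tree()` builds
#' a node, `reaction_chain()` a linear route (first argument at the root),
#' and `empty_reaction_tree()` the empty tree of a zero-step route.
#'
#' @param label a `reaction_code` or classification string.
#' @param children list of child `reaction_tree` nodes.
#' @return A `reaction_tree` (or `NULL` for the empty tree).
#' @examples
#' ref <- reaction_chain(c("2.1.10", "3.1.2"))
#' tree_size(ref)   # 2
#' @export
reaction_tree <- function(label, children = list()) {
  if (is.character(label)) label <- parse_code(label)
  stopifnot(inherits(label, "reaction_code"))
  structure(list(label = label, children = children), class = "reaction_tree")
}

#' @rdname reaction_tree
#' @param codes character vector or list of codes, root first.
#' @export
reaction_chain <- function(codes) {
  if (length(codes) == 0L) return(empty_reaction_tree())
  node <- NULL
  for (cd in rev(as.list(codes)))
    node <- reaction_tree(cd, if (is.null(node)) list() else list(node))
  node
}

#' @rdname reaction_tree
#' @export
empty_reaction_tree <- function() NULL

#' @rdname reaction_tree
#' @param tree a `reaction_tree` or `NULL`.
#' @export
tree_size <- function(tree) {
  if (is.null(tree)) return(0L)
  1L + sum(vapply(tree$children, tree_size, integer(1)))
}

# recursive key: label followed by the sorted child keys
.tree_key <- function(node) {
  if (is.null(node)) return("")
  kid_keys <- sort(vapply(node$children, .tree_key, character(1)))
  paste0(format(node$label), "(", paste(kid_keys, collapse = ","), ")")
}

.sort_tree <- function(node) {
  if (is.null(node)) return(NULL)
  kids <- lapply(node$children, .sort_tree)
  if (length(kids))
    kids <- kids[order(vapply(kids, .tree_key, character(1)))]
  reaction_tree(node$label, kids)
}

#' Canonical reaction tree of a route
#'
#' Extracts the tree of reaction nodes (molecule nodes elided: a reaction's
#' children are the reactions decomposing its precursors) and sorts all
#' children by a deterministic recursive key, so that chemically identical
#' routes written with different child orders map to the same ordered tree.
#'
#' @param tree a `route_tree`.
#' @return A `reaction_tree`, or `NULL` for a zero-step route.
#' @export
canonical_reaction_tree <- function(tree) {
  stopifnot(inherits(tree, "route_tree"))
  from_mol <- function(mnode) {
    if (length(mnode$children) == 0L) return(NULL)
    rnode <- mnode$children[[1L]]
    kids <- Filter(Negate(is.null), lapply(rnode$children, from_mol))
    reaction_tree(rnode$code, kids)
  }
  .sort_tree(from_mol(tree$root))
}

#' @export
print.reaction_tree <- function(x, ...) {
  show <- function(node, indent) {
    cat(strrep("  ", indent), format(node$label), "\n", sep = "")
    for (k in node$children) show(k, indent + 1L)
  }
  cat("<reaction_tree> ", tree_size(x), " node(s)\n", sep = "")
  show(x, 1L)
  invisible(x)
}
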