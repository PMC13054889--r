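#' Hierarchical reaction-taxonomy codes
#'
#' Reaction steps are labelled with hierarchical classification codes of the
#' form `X`, `X.Y` or `X.Y.Z`: `X` is the superclass (e.g. 3 = C-C bond
#' formation), `X.Y` the class (3.1 = Suzuki coupling) and `X.Y.Z` the named
#' reaction (3.1.2 = Chloro Suzuki coupling). Routes whose reactions cannot be
#' classified carry the sentinel code `0.0`, which invalidates route
#' signatures but never aborts parsing.
#'
#' @param superclass positive integer (0 reserved for the unrecognized
#'   sentinel).
#' @param class_id non-negative integer or `NA` when absent.
#' @param named_id non-negative integer or `NA`; requires `class_id`.
#' @param name optional free-text display name (e.g. the named-reaction
#'   label), kept verbatim and ignored by all scoring.
#' @return An object of class `reaction_code`.
#' @examples
#' reaction_code(3, 1, 2, "Chloro Suzuki coupling")
#' parse_code("2.1.10 Carboxylic ester + amine reaction")
#' @export
reaction_code <- function(superclass, class_id = NA, named_id = NA, name = NULL) {
  superclass <- as.integer(superclass)
  class_id <- suppressWarnings(as.integer(class_id))
  named_id <- suppressWarnings(as.integer(named_id))
  if (length(superclass) != 1L || is.na(superclass) || superclass < 0L)
    stop("`superclass` must be a single non-negative integer", call. = FALSE)
  if (!is.na(named_id) && is.na(class_id))
    stop("a named-reaction id requires a class id", call. = FALSE)
  if ((!is.na(class_id) && class_id < 0L) || (!is.na(named_id) && named_id < 0L))
    stop("code components must be non-negative", call. = FALSE)
  structure(
    list(superclass = superclass, class_id = class_id, named_id = named_id,
         name = if (is.null(name) || is.na(name) || !nzchar(name)) NULL else as.character(name)),
    class = "reaction_code"
  )
}

#' Sentinel code for unrecognized reactions
#'
#' Renders as `"0.0"`. It differs from every real code at the superclass
#' level and from itself at cost 0, and it invalidates any route signature
#' containing it.
#' @return A `reaction_code`.
#' @export
code_unrecognized <- function() reaction_code(0L, 0L)

#' @export
format.reaction_code <- function(x, ...) {
  parts <- c(x$superclass,
             if (!is.na(x$class_id)) x$class_id,
             if (!is.na(x$named_id)) x$named_id)
  paste(parts, collapse = ".")
}

#' @export
print.reaction_code <- function(x, ...) {
  cat("<reaction_code> ", format(x),
      if (!is.null(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.reaction_code <- function(x, ...) format(x)

#' @export
`==.reaction_code` <- function(e1, e2) {
  same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  inherits(e2, "reaction_code") &&
    e1$superclass == e2$superclass &&
    same(e1$class_id, e2$class_id) &&
    same(e1$named_id, e2$named_id)
}

#' Parse a reaction classification string
#'
#' Accepts `"X"`, `"X.Y"` or `"X.Y.Z"`, optionally followed by whitespace and
#' a display name, e.g. `"3.1.2 Chloro Suzuki coupling"`.
#'
#' @param text a single character string.
#' @return A `reaction_code`.
#' @seealso [code_from_annotation()] for the lenient variant used during
#'   route parsing, which maps unparseable annotations to the `0.0` sentinel.
#' @export
parse_code <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single string", call. = FALSE)
  m <- regexec("^\\s*([0-9]+)(?:\\.([0-9]+))?(?:\\.([0-9]+))?(?:\\s+(\\S.*?))?\\s*$", text)
  g <- regmatches(text, m)[[1L]]
  if (length(g) == 0L)
    stop("cannot parse reaction code: ", sQuote(text), call. = FALSE)
  reaction_code(
    g[2L],
    if (nzchar(g[3L])) g[3L] else NA,
    if (nzchar(g[4L])) g[4L] else NA,
    if (length(g) >= 5L && nzchar(g[5L])) g[5L] else NULL
  )
}

#' Lenient classification-to-code conversion
#'
#' Used while parsing route documents: a missing, empty or unparseable
#' classification annotation becomes the unrecognized sentinel `0.0` rather
#' than an error.
#' @param text classification annotation (or `NULL`).
#' @return A `reaction_code`.
#' @export
code_from_annotation <- function(text) {
  if (is.null(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    return(code_unrecognized())
  tryCatch(parse_code(text), error = function(e) code_unrecognized())
}

#' Is a code the unrecognized sentinel?
#' @param code a `reaction_code`.
#' @return Logical scalar.
#' @export
is_unrecognized <- function(code) {
  code$superclass == 0L
}

.code_levels <- c("superclass", "class", "named")

#' Depth of a reaction code
#' @param code a `reaction_code`.
#' @return `"superclass"`, `"class"` or `"named"`.
#' @export
code_level <- function(code) {
  if (!is.na(code$named_id)) "named" else if (!is.na(code$class_id)) "class" else "superclass"
}

#' Truncate a reaction code to a taxonomy level
#'
#' @param code a `reaction_code`.
#' @param level `"superclass"`, `"class"` or `"named"`. Must be no deeper
#'   than the code's own level.
#' @return A `reaction_code` with deeper components dropped (the display
#'   name is dropped along with them).
#' @examples
#' truncate_code(parse_code("2.1.10"), "class")  # 2.1
#' @export
truncate_code <- function(code, level = c("class", "superclass", "named")) {
  level <- match.arg(level)
  have <- match(code_level(code), .code_levels)
  want <- match(level, .code_levels)
  if (want > have)
    stop("cannot truncate ", format(code), " to the deeper ", level, " level",
         call. = FALSE)
  if (want == have) return(code)
  reaction_code(code$superclass,
                if (want >= 2L) code$class_id else NA,
                NA)
}

#' Tree-edit cost scheme for reaction trees
#'
#' Node deletion and insertion cost 4.0 by default; renames are scaled by the
#' taxonomic depth of the first disagreement: superclass differences (1.x vs
#' 2.x) cost 3.0, class-level differences (2.1 vs 2.2) cost 2.0, and
#' named-reaction differences (2.1.1 vs 2.1.10) cost 1.0. Identical labels
#' cost 0.
#'
#' @param delete_cost,insert_cost node deletion/insertion costs.
#' @param rename_superclass,rename_class,rename_named rename costs by depth
#'   of first disagreement; must strictly decrease with depth and never
#'   exceed `delete_cost + insert_cost`.
#' @return An object of class `ted_cost_scheme`.
#' @export
ted_cost_scheme <- function(delete_cost = 4, insert_cost = 4,
                            rename_superclass = 3, rename_class = 2,
                            rename_named = 1) {
  costs <- c(delete_cost, insert_cost, rename_superclass, rename_class, rename_named)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("all costs must be finite and non-negative", call. = FALSE)
  if (!(rename_superclass > rename_class && rename_class > rename_named))
    stop("rename costs must strictly decrease with taxonomic depth", call. = FALSE)
  if (rename_superclass > delete_cost + insert_cost)
    stop("rename cost may not exceed delete + insert", call. = FALSE)
  structure(
    list(delete_cost = delete_cost, insert_cost = insert_cost,
         rename_superclass = rename_superclass, rename_class = rename_class,
         rename_named = rename_named),
    class = "ted_cost_scheme"
  )
}

#' @export
print.ted_cost_scheme <- function(x, ...) {
  cat("<ted_cost_scheme> delete/insert ", x$delete_cost, "/", x$insert_cost,
      "; rename ", x$rename_superclass, "/", x$rename_class, "/",
      x$rename_named, " by disagreement depth\n", sep = "")
  invisible(x)
}

#' Hierarchical rename cost between two reaction codes
#'
#' The cost is determined by the shallowest taxonomy level at which the two
#' codes disagree. Components absent from both codes compare equal; a
#' component absent from exactly one side counts as a disagreement at that
#' depth, so partially specified codes compare deterministically.
#'
#' @param a,b `reaction_code` objects.
#' @param scheme a [ted_cost_scheme()].
#' @return 0, `rename_named`, `rename_class` or `rename_superclass`.
#' @examples
#' s <- ted_cost_scheme()
#' rename_cost(parse_code("1.7.9"), parse_code("2.1.1"), s)   # 3
#' rename_cost(parse_code("2.1.10"), parse_code("2.2.3"), s)  # 2
#' rename_cost(parse_code("2.1.1"), parse_code("2.1.10"), s)  # 1
#' @export
rename_cost <- function(a, b, scheme = ted_cost_scheme()) {
  same <- function(x, y) (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && x == y)
  if (a$superclass != b$superclass) return(scheme$rename_superclass)
  if (!same(a$class_id, b$class_id)) return(scheme$rename_class)
  if (!same(a$named_id, b$named_id)) return(scheme$rename_named)
  0
}
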