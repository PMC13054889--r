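#' Tree edit distance between reaction trees
#'
#' Exact minimum-cost edit distance between two labeled ordered trees under
#' a [ted_cost_scheme()]: the cheapest sequence of node deletions,
#' insertions and renames transforming one tree into the other. Renames use
#' the hierarchical costs of the scheme (3/2/1 by the taxonomy depth of the
#' first disagreement); deletions and insertions cost 4 by default.
#' Computed with the Zhang–Shasha dynamic program over postorder keyroots,
#' so the result is the true optimum, and symmetric whenever
#' `delete_cost == insert_cost`.
#'
#' Inputs are expected to be canonical reaction trees
#' ([canonical_reaction_tree()]), whose deterministic child order makes the
#' ordered-tree distance independent of how the route document listed its
#' branches.
#'
#' @param t1,t2 `reaction_tree` objects (or `NULL` for the empty tree).
#' @param scheme a [ted_cost_scheme()].
#' @return Non-negative number.
#' @examples
#' s <- ted_cost_scheme()
#' tree_edit_distance(reaction_tree("1.7.9"), reaction_tree("2.1.1"), s)  # 3
#' tree_edit_distance(reaction_chain(c("2.1.10", "3.1.2")),
#'                    reaction_tree("2.1.10"), s)                         # 4
#' @export
tree_edit_distance <- function(t1, t2, scheme = ted_cost_scheme()) {
  a <- .flatten_tree(t1)
  b <- .flatten_tree(t2)
  if (a$n == 0L && b$n == 0L) return(0)
  if (a$n == 0L) return(b$n * scheme$insert_cost)
  if (b$n == 0L) return(a$n * scheme$delete_cost)
  del <- scheme$delete_cost
  ins <- scheme$insert_cost
  td <- matrix(0, a$n, b$n)
  for (i in a$keyroots) {
    li <- a$l[i]
    for (j in b$keyroots) {
      lj <- b$l[j]
      ni <- i - li + 1L
      nj <- j - lj + 1L
      fd <- matrix(0, ni + 1L, nj + 1L)
      fd[, 1L] <- (0:ni) * del
      fd[1L, ] <- (0:nj) * ins
      for (di in seq_len(ni)) {
        ai <- li + di - 1L
        for (dj in seq_len(nj)) {
          bj <- lj + dj - 1L
          if (a$l[ai] == li && b$l[bj] == lj) {
            fd[di + 1L, dj + 1L] <- min(
              fd[di, dj + 1L] + del,
              fd[di + 1L, dj] + ins,
              fd[di, dj] + rename_cost(a$labels[[ai]], b$labels[[bj]], scheme))
            td[ai, bj] <- fd[di + 1L, dj + 1L]
          } else {
            fd[di + 1L, dj + 1L] <- min(
              fd[di, dj + 1L] + del,
              fd[di + 1L, dj] + ins,
              fd[a$l[ai] - li + 1L, b$l[bj] - lj + 1L] + td[ai, bj])
          }
        }
      }
    }
  }
  td[a$n, b$n]
}

# postorder flattening: labels, leftmost-leaf indices, keyroots
.flatten_tree <- function(tree) {
  labels <- list()
  l <- integer()
  walk <- function(node) {
    first_leaf <- NA_integer_
    for (k in node$children) {
      fl <- walk(k)
      if (is.na(first_leaf)) first_leaf <- fl
    }
    me <- length(labels) + 1L
    labels[[me]] <<- node$label
    l[me] <<- if (is.na(first_leaf)) me else first_leaf
    l[me]
  }
  if (!is.null(tree)) walk(tree)
  n <- length(labels)
  keyroots <- if (n) sort(unname(vapply(split(seq_len(n), l), max, integer(1))))
              else integer()
  list(n = n, labels = labels, l = l, keyroots = keyroots)
}

#' Exhaustive small-tree edit-distance oracle
#'
#' Enumerates every valid edit mapping between the two trees — the partial
#' node matchings that preserve postorder and ancestor relations — and
#' returns the minimum total cost of renames plus deletions and insertions
#' of unmatched nodes. Exponential in tree size; refuses trees larger than
#' `max_nodes`. Intended purely as an independent cross-check of
#' [tree_edit_distance()].
#'
#' @inheritParams tree_edit_distance
#' @param max_nodes size guard per tree (default 6).
#' @return Non-negative number.
#' @export
brute_force_ted <- function(t1, t2, scheme = ted_cost_scheme(), max_nodes = 6L) {
  a <- .flatten_tree(t1)
  b <- .flatten_tree(t2)
  if (a$n > max_nodes || b$n > max_nodes)
    stop("brute_force_ted is an oracle for trees of at most ", max_nodes,
         " nodes", call. = FALSE)
  del <- scheme$delete_cost
  ins <- scheme$insert_cost
  best <- a$n * del + b$n * ins
  m1 <- integer(0)  # matched postorder indices in t1
  m2 <- integer(0)
  recurse <- function(i, jmin, rename_sum) {
    if (i > a$n) {
      k <- length(m1)
      cost <- rename_sum + (a$n - k) * del + (b$n - k) * ins
      if (cost < best) best <<- cost
      return(invisible())
    }
    # leave node i unmatched
    recurse(i + 1L, jmin, rename_sum)
    if (jmin > b$n) return(invisible())
    for (j in jmin:b$n) {
      # ancestor consistency with all earlier pairs: for p < i, p is a
      # descendant of i iff its partner is a descendant of j
      ok <- TRUE
      for (t in seq_along(m1)) {
        if ((m1[t] >= a$l[i]) != (m2[t] >= b$l[j])) { ok <- FALSE; break }
      }
      if (!ok) next
      m1[length(m1) + 1L] <<- i
      m2[length(m2) + 1L] <<- j
      recurse(i + 1L, j + 1L,
              rename_sum + rename_cost(a$labels[[i]], b$labels[[j]], scheme))
      m1 <<- m1[-length(m1)]
      m2 <<- m2[-length(m2)]
    }
    invisible()
  }
  recurse(1L, 1L, 0)
  best
}

#' Random labeled reaction tree
#'
#' Draws an ordered tree with `n` nodes by attaching each node to a
#' uniformly chosen earlier node, labelling nodes uniformly from `codes`.
#' Used for property testing of the edit-distance routines; uses the
#' current RNG state.
#'
#' @param n number of nodes (0 gives the empty tree).
#' @param codes character vector of classification strings to label from.
#' @return A `reaction_tree` or `NULL`.
#' @export
random_reaction_tree <- function(n, codes = c("1.7.9", "2.1.1", "2.1.10",
                                              "2.2.3", "3.1.2", "0.0")) {
  n <- as.integer(n)
  if (n <= 0L) return(empty_reaction_tree())
  parent <- c(0L, if (n > 1L)
    vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  labs <- sample(codes, n, replace = TRUE)
  build <- function(i) {
    kids <- lapply(which(parent == i), build)
    reaction_tree(labs[i], kids)
  }
  build(1L)
}
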