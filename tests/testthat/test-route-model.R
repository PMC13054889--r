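test_that("native route documents parse with catalog annotation and solved flag", {
  path <- system.file("extdata", "route_ref.json", package = "synthreward")
  t <- parse_route(path)
  expect_s3_class(t, "route_tree")
  expect_identical(count_steps(t), 2L)
  expect_true(t$solved)

  # a catalog that does not stock one leaf makes the route unsolved
  partial <- stock_catalog(c("BB-AMINE-1", "BB-BORONIC-1"),
                           c("internal", "commercial"))
  t2 <- parse_route(path, catalog = partial)
  # BB-ARYLCL-1 keeps its embedded annotation, so supply a stripped document
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  strip <- function(n) {
    n$stock <- NULL
    if (!is.null(n$children)) n$children <- lapply(n$children, strip)
    n
  }
  doc$root <- strip(doc$root)
  t3 <- parse_route(doc, catalog = partial)
  expect_false(t3$solved)
  t4 <- parse_route(doc, catalog = read_stock_catalog(
    system.file("extdata", "stock.csv", package = "synthreward")))
  expect_true(t4$solved)
})

test_that("aizynthfinder documents parse, ignoring unknown metadata", {
  path <- system.file("extdata", "route_aizynth.json", package = "synthreward")
  t <- parse_route(path, dialect = "aizynthfinder")
  expect_identical(count_steps(t), 1L)
  expect_true(t$solved)  # both leaves in_stock
  sig <- route_signature(t, "class")
  expect_true(sig$valid)
  expect_identical(sig$key, "2.1")
  expect_identical(t$root$id, "CCOC(=O)c1ccc(N)cc1")
})

test_that("degenerate and unrecognized routes parse per the schema rules", {
  t0 <- stock_singleton()
  expect_identical(count_steps(t0), 0L)
  expect_true(t0$solved)
  expect_identical(route_signature(t0)$key, "")
  expect_false(route_signature(t0)$valid)  # empty signature is invalid

  t1 <- one_step_route("2.1.10", c("internal", "internal"))
  expect_identical(count_steps(t1), 1L)
  expect_true(t1$solved)

  tun <- one_step_route(NA_character_, "internal")
  expect_identical(count_steps(tun), 1L)
  expect_false(route_signature(tun)$valid)
})

test_that("schema errors name the offending node path", {
  bad <- list(root = list(type = "mol", id = "T", children = list(
    list(type = "mol", id = "wrong-layer"))))
  expect_error(parse_route(bad), "root/children\\[1\\]")
  expect_error(parse_route(list(root = list(type = "reaction",
                                            children = list()))),
               "expected a mol")
  expect_error(parse_route(list(notroot = 1)), "root")
})

test_that("step counting counts reaction nodes, not depth", {
  expect_identical(count_steps(chain_route(c("2.1.1", "2.1.2", "2.1.3"))), 3L)
  # convergent: root reaction, each branch holding one further reaction
  branch <- function(code, i) {
    m <- mol(paste0("B", i), "unavailable")
    m$children <- list(rxn(code, mol(paste0("BL", i), "internal")))
    m
  }
  conv <- route_tree(mol("T", reaction = {
    r <- rxn("2.1.10")
    r$children <- list(branch("3.1.2", 1), branch("1.3.1", 2))
    r
  }))
  expect_identical(count_steps(conv), 3L)
})

test_that("signatures collapse duplicates and truncate consistently", {
  t <- chain_route(c("2.1.10", "3.1.2"))
  expect_identical(route_signature(t, "class")$key, "2.1+3.1")
  expect_identical(route_signature(t, "named")$key, "2.1.10+3.1.2")
  t2 <- chain_route(c("2.1.10", "2.1.3"))
  expect_identical(route_signature(t2, "class")$key, "2.1")

  # idempotence: class level equals truncating the named-level signature
  set.seed(11)
  pool <- c("1.3.1", "1.8.5", "2.1.1", "2.1.10", "3.1.2", "5.2.4")
  for (i in 1:20) {
    codes <- sample(pool, sample(1:3, 1))
    tr <- chain_route(codes)
    named <- route_signature(tr, "named")
    via_trunc <- unique(vapply(named$codes, function(cd)
      format(truncate_code(cd, "class")), character(1)))
    expect_setequal(strsplit(route_signature(tr, "class")$key, "+",
                             fixed = TRUE)[[1]], via_trunc)
  }
})

test_that("canonical reaction trees are invariant under child permutation", {
  mk <- function(order) {
    branches <- list(
      function() { m <- mol("B1"); m$children <- list(rxn("3.1.2", mol("x", "internal"))); m },
      function() { m <- mol("B2"); m$children <- list(rxn("1.3.1", mol("y", "internal"))); m }
    )
    r <- rxn("2.1.10")
    r$children <- lapply(branches[order], function(f) f())
    route_tree(mol("T", reaction = r))
  }
  a <- canonical_reaction_tree(mk(c(1, 2)))
  b <- canonical_reaction_tree(mk(c(2, 1)))
  expect_equal(a, b)
  expect_identical(tree_size(a), 3L)
  expect_null(canonical_reaction_tree(stock_singleton()))
})

test_that("write/parse round-trips routes exactly", {
  fixtures <- list(
    parse_route(system.file("extdata", "route_ref.json", package = "synthreward")),
    chain_route(c("2.1.10", "3.1.2")),
    stock_singleton(),
    one_step_route(NA_character_, c("internal", "unavailable"))
  )
  for (t in fixtures) {
    rec <- write_route(t)
    back <- parse_route(rec)
    expect_identical(back$root, t$root)
    expect_identical(back$solved, t$solved)
  }
  # byte-stable on disk, classification preserved verbatim
  t <- parse_route(system.file("extdata", "route_ref.json",
                               package = "synthreward"))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_route(t, f1); write_route(t, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("2.1.10 Carboxylic ester \\+ amine reaction",
                        readLines(f1))))
})

test_that("stock catalogs read from CSV and plain text with trim canonicalization", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,source", "  AAA ,internal", "BBB,commercial"), csv)
  cat1 <- read_stock_catalog(csv)
  expect_identical(stock_status(cat1, "AAA"), "internal")
  expect_identical(stock_status(cat1, " AAA "), "internal")
  expect_identical(stock_status(cat1, "BBB"), "commercial")
  expect_identical(stock_status(cat1, "absent"), "unavailable")

  txt <- tempfile(fileext = ".txt")
  writeLines(c("CCO", "c1ccccc1", ""), txt)
  cat2 <- read_stock_catalog(txt)
  expect_identical(unname(stock_status(cat2, c("CCO", "c1ccccc1"))),
                   c("internal", "internal"))
  expect_error(read_stock_catalog(tempfile()), "no such")
})

test_that("solved equals all-leaves-stocked on generated routes", {
  set.seed(23)
  for (i in 1:25) {
    stocks <- sample(c("internal", "commercial", "unavailable"),
                     sample(1:4, 1), replace = TRUE)
    t <- one_step_route("2.1.1", stocks)
    expect_identical(t$solved, all(stocks != "unavailable"))
    leaves <- route_leaves(t)
    expect_identical(length(leaves), length(stocks))
  }
})
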