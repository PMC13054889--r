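test_that("batch construction enforces unique non-empty molecule ids", {
  m <- batch_mol("m1", list(stock_singleton()))
  expect_error(batch_context(list()), "at least one")
  expect_error(batch_context(list(m, m)), "duplicate")
  expect_error(batch_context(list(list(mol_id = "", trees = list()))),
               "non-empty")
  b <- batch_context(list(m), epoch = 3L)
  expect_identical(b$n, 1L)
})

test_that("popularity reproduces hand-built batch fractions", {
  mk <- function(id, code, stock = "internal")
    batch_mol(id, list(one_step_route(code, stock, target = id)))
  # 3 of 4 molecules share class signature {2.1}
  b <- batch_context(list(mk("m1", "2.1.1"), mk("m2", "2.1.5"),
                          mk("m3", "2.1.9"), mk("m4", "3.1.2")))
  q <- popularity_scores(b)
  expect_equal(as.numeric(q), c(0.75, 0.75, 0.75, 0.25))
  fr <- attr(q, "signature_fractions")
  expect_equal(unname(fr[["2.1"]]), 0.75)
  expect_equal(max(q), max(fr))

  # every molecule shares one signature -> all score 1
  all_share <- batch_context(lapply(1:6, function(i)
    mk(paste0("s", i), "2.1.1")))
  expect_true(all(popularity_scores(all_share) == 1))

  # unrecognized reaction or unsolved route -> 0
  b2 <- batch_context(list(
    mk("ok", "2.1.1"),
    batch_mol("invalid", list(one_step_route(NA_character_, "internal"))),
    batch_mol("unsolved", list(one_step_route("2.1.1", "unavailable")))
  ))
  q2 <- popularity_scores(b2)
  expect_equal(unname(q2[c("invalid", "unsolved")]), c(0, 0))
  expect_equal(unname(q2[["ok"]]), 1 / 3)
})

test_that("popularity uses solved routes only and each molecule counts once", {
  two_routes <- batch_mol("d1", list(one_step_route("2.1.1", "internal"),
                                     one_step_route("2.1.7", "internal")))
  other <- batch_mol("d2", list(one_step_route("2.1.2", "internal")))
  b <- batch_context(list(two_routes, other))
  # both routes of d1 share signature {2.1}; d1 must not be counted twice
  expect_true(all(popularity_scores(b) == 1))
})

test_that("plate filling rewards the assign-then-score ratio and replays by hand", {
  # hand-replayed 3-molecule batch on a fresh ledger with capacity 1000:
  # counts go 1, 2, 3 and each molecule sees its own contribution
  led <- plate_ledger(1000)
  b <- batch_context(lapply(1:3, function(i)
    batch_mol(paste0("m", i), list(one_step_route("2.1.1", "internal",
                                                  target = paste0("m", i))))))
  upd <- fill_a_plate_update(b, led)
  expect_equal(unname(upd$scores), c(0.001, 0.002, 0.003))
  expect_equal(unname(upd$ledger$counts[["2.1"]]), 3)

  # ties at equal counts break to the lexicographically smallest key
  led2 <- plate_ledger(10)
  both <- batch_mol("tie", list(one_step_route("2.1.1", "internal"),
                                one_step_route("1.3.2", "internal")))
  upd2 <- fill_a_plate_update(batch_context(list(both)), led2)
  expect_identical(unname(upd2$ledger$assignments[["tie"]]), "1.3")
})

test_that("saturation freezes a plate at zero and counts filled plates", {
  led <- plate_ledger(2)
  expect_identical(filled_plate_count(led), 0L)
  mk <- function(id) batch_mol(id, list(one_step_route("2.1.1", "internal",
                                                       target = id)))
  upd <- fill_a_plate_update(batch_context(list(mk("a"), mk("b"))), led)
  expect_equal(unname(upd$scores), c(0.5, 1))
  expect_identical(filled_plate_count(upd$ledger), 1L)
  # the saturated signature never scores again
  upd2 <- fill_a_plate_update(batch_context(list(mk("c"))), upd$ledger)
  expect_equal(unname(upd2$scores), 0)
  expect_identical(filled_plate_count(upd2$ledger), 1L)
  expect_error(plate_ledger(0), "positive")
})

test_that("ledger counts conserve distinct assigned molecules", {
  set.seed(77)
  led <- plate_ledger(25)
  pool <- c("1.3.1", "1.8.5", "2.1.1", "2.1.10", "3.1.2")
  for (epoch in 1:6) {
    mols <- lapply(1:20, function(i) {
      id <- sprintf("e%d_m%02d", epoch, i)
      trees <- lapply(seq_len(sample(1:2, 1)), function(j)
        one_step_route(sample(pool, 1),
                       sample(c("internal", "unavailable"), 1), target = id))
      batch_mol(id, trees)
    })
    led <- fill_a_plate_update(batch_context(mols, epoch = epoch), led)$ledger
    expect_equal(sum(led$counts), length(led$assignments))
    expect_true(all(led$counts <= led$capacity))
    expect_setequal(led$saturated,
                    names(led$counts)[led$counts == led$capacity])
  }
})

test_that("exclusion consumes the molecules of a filled plate", {
  led <- plate_ledger(2)
  mk <- function(id, code) batch_mol(id, list(one_step_route(code, "internal",
                                                             target = id)))
  upd <- fill_a_plate_update(batch_context(list(mk("a", "2.1.1"),
                                                mk("b", "2.1.4"))),
                             led, exclude_molecules = TRUE)
  expect_setequal(upd$ledger$consumed, c("a", "b"))
  # a consumed molecule reappearing with a different available signature
  # still scores 0 and is never assigned to a second plate
  upd2 <- fill_a_plate_update(batch_context(list(mk("a", "3.1.2"))),
                              upd$ledger, exclude_molecules = TRUE)
  expect_equal(unname(upd2$scores), 0)
  expect_identical(unname(upd2$ledger$assignments[["a"]]), "2.1")
  expect_false("3.1" %in% names(upd2$ledger$counts))
})

test_that("reappearing molecules never re-increment a plate", {
  led <- plate_ledger(10)
  mk <- function(id) batch_mol(id, list(one_step_route("2.1.1", "internal",
                                                       target = id)))
  led <- fill_a_plate_update(batch_context(list(mk("dup"))), led)$ledger
  upd <- fill_a_plate_update(batch_context(list(mk("dup"))), led)
  expect_equal(unname(upd$ledger$counts[["2.1"]]), 1)  # unchanged
  expect_equal(unname(upd$scores), 0.1)                # current ratio
})

test_that("ledgers round-trip through JSON and resume identically", {
  set.seed(99)
  led <- plate_ledger(3)
  mk <- function(id, code) batch_mol(id, list(one_step_route(code, "internal",
                                                             target = id)))
  b1 <- batch_context(list(mk("a", "2.1.1"), mk("b", "2.1.2"), mk("c", "3.1.2")))
  b2 <- batch_context(list(mk("d", "2.1.9"), mk("e", "3.1.5")))
  led1 <- fill_a_plate_update(b1, led, exclude_molecules = TRUE)$ledger

  path <- tempfile(fileext = ".json")
  ledger_save(led1, path)
  restored <- ledger_load(path)
  expect_equal(restored, led1)

  # loading then updating equals updating without persistence
  direct <- fill_a_plate_update(b2, led1, exclude_molecules = TRUE)
  resumed <- fill_a_plate_update(b2, restored, exclude_molecules = TRUE)
  expect_equal(resumed$scores, direct$scores)
  expect_equal(resumed$ledger, direct$ledger)

  # fresh ledger serializes to a minimal document
  fresh <- tempfile(fileext = ".json")
  ledger_save(plate_ledger(1000), fresh)
  expect_equal(ledger_load(fresh), plate_ledger(1000))

  # corrupt files are diagnosed
  bad <- tempfile(fileext = ".json")
  writeLines('{"capacity": 5}', bad)
  expect_error(ledger_load(bad), "schema")
  writeLines("not json at all {", bad)
  expect_error(ledger_load(bad), "corrupt")
})

test_that("plate reports tabulate counts, saturation and fill epoch", {
  led <- plate_ledger(2)
  mk <- function(id, code) batch_mol(id, list(one_step_route(code, "internal",
                                                             target = id)))
  b <- batch_context(list(mk("a", "2.1.1"), mk("b", "2.1.3"), mk("c", "3.1.2")),
                     epoch = 7L)
  led <- fill_a_plate_update(b, led)$ledger
  rep <- plates_report(led)
  expect_identical(rep$signature, c("2.1", "3.1"))
  expect_equal(rep$count, c(2, 1))
  expect_identical(rep$saturated, c(TRUE, FALSE))
  expect_identical(rep$filled_epoch, c(7L, NA_integer_))
})
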