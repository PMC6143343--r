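ann1 <- data.table::data.table(ies_id = "i1", scaffold = "s1",
                               start = 101L, end = 160L, length = 60L)

test_that("classify_event implements the boundary taxonomy", {
  expect_equal(classify_event("s1", 101L, 160L, ann1)$klass, "CORRECT")
  pi <- classify_event("s1", 101L, 150L, ann1)
  expect_equal(pi$klass, "PARTIAL_INTERNAL")
  expect_equal(pi$right_offset, -10L)
  expect_equal(pi$left_offset, 0L)
  expect_equal(classify_event("s1", 91L, 170L, ann1)$klass, "EXTERNAL")
  expect_equal(classify_event("s1", 111L, 150L, ann1)$klass, "INTERNAL")
  expect_equal(classify_event("s1", 101L, 170L, ann1)$klass, "PARTIAL_EXTERNAL")
  expect_equal(classify_event("s1", 111L, 170L, ann1)$klass, "OVERLAPPING")
  expect_equal(classify_event("s1", 500L, 520L, ann1)$klass, "UNMATCHED")
})

test_that("overlap ties assign to the leftmost IES and are flagged", {
  ann2 <- data.table::data.table(ies_id = c("i1", "i2"), scaffold = "s1",
                                 start = c(100L, 140L), end = c(120L, 160L),
                                 length = c(21L, 21L))
  ev <- classify_event("s1", 110L, 150L, ann2)
  expect_equal(ev$ies_id, "i1")
  expect_true(ev$multi_ies)
})

test_that("classify_event agrees with the brute-force classifier", {
  set.seed(42)
  g <- generate_genomes(small_cfg(n_ies = 15L, scaffold_len = 6000L))
  ann <- g$ies
  df_ann <- as.data.frame(ann)
  for (rep in seq_len(500L)) {
    i <- sample.int(nrow(ann), 1L)
    a <- ann$start[i] + sample(-30:30, 1L)
    b <- ann$end[i] + sample(-30:30, 1L)
    if (b - a < 1L) next
    got <- classify_event(ann$scaffold[i], a, b, ann)
    expect_equal(got$klass, oracle_classify(ann$scaffold[i], a, b, df_ann))
  }
})

test_that("events collapse to one row per distinct junction", {
  ev <- data.table::data.table(
    read_id = sprintf("r%d", 1:9),
    kind = c(rep("ALT_DELETION", 7L), "IES_MINUS", "NONE"),
    ies_id = NA_character_, scaffold = "s1",
    a = c(rep(111L, 7L), 101L, NA), b = c(rep(150L, 7L), 160L, NA))
  out <- collapse_events(ev, ann1)
  expect_equal(nrow(out), 2L)
  expect_equal(out[a == 111L, read_count], 7L)
  expect_equal(out[a == 111L, klass], "INTERNAL")
  expect_equal(out[a == 101L, klass], "CORRECT")
  expect_equal(nrow(collapse_events(ev[0L], ann1)), 0L)
})

test_that("de novo accounting is a set difference with per-million rate", {
  mk <- function(a_vals) data.table::data.table(
    scaffold = "s1", a = a_vals, b = a_vals + 20L, read_count = 1L,
    ies_id = NA_character_, klass = "INTERNAL",
    left_offset = 5L, right_offset = -5L, multi_ies = FALSE)
  auto <- mk(c(10L, 50L, 90L)); par <- mk(50L)
  dn <- de_novo_errors(auto, par, 1e6)
  expect_equal(dn$count, 2L)
  expect_equal(dn$per_million, 2.0)
  expect_setequal(dn$events$a, c(10L, 90L))
  expect_equal(de_novo_errors(auto, auto, 100)$count, 0L)
  expect_equal(de_novo_errors(auto, mk(integer(0)), 100)$count, 3L)
  expect_error(de_novo_errors(auto, par, 0), "undefined rate")
  # doubling reads changes only the denominator
  expect_equal(de_novo_errors(auto, par, 2e6)$per_million, 1.0)
})

test_that("error read fraction sums read support over error classes", {
  ev <- data.table::data.table(
    scaffold = "s1", a = c(101L, 111L), b = c(160L, 150L),
    read_count = c(97L, 3L), ies_id = "i1",
    klass = c("CORRECT", "INTERNAL"),
    left_offset = c(0L, 10L), right_offset = c(0L, -10L), multi_ies = FALSE)
  expect_equal(error_read_fraction(ev), 0.03)
  expect_equal(error_read_fraction(ev[0L]), 0)
})

test_that("shift spectrum excludes small shifts and finds the mode", {
  mk <- function(shifts) data.table::data.table(
    scaffold = "s1", a = seq_along(shifts), b = seq_along(shifts) + 50L,
    read_count = 1L, ies_id = "i1", klass = "PARTIAL_INTERNAL",
    left_offset = 0L, right_offset = -shifts, multi_ies = FALSE)
  sp <- shift_spectrum(mk(rep(10L, 5L)))
  expect_equal(sp$mode, 10L)
  expect_equal(unname(sp$counts["10"]), 5L)
  expect_equal(shift_spectrum(mk(c(2L, 2L)))$mode, NA_integer_)
  sp2 <- shift_spectrum(mk(c(2L, 10L, 10L, 11L)))
  expect_equal(sum(sp2$counts), 3L)   # the 2 bp shift is filtered out
})

test_that("error-prone fractions stratify by IRS", {
  res <- data.table::data.table(
    ies_id = c("i1", "i2", "i3"), irs = c(0.01, 0.02, 0.9),
    fully_excised = c(TRUE, TRUE, FALSE))
  ev <- data.table::data.table(
    scaffold = "s1", a = 1L, b = 2L, read_count = 1L, ies_id = "i1",
    klass = "PARTIAL_INTERNAL", left_offset = 0L, right_offset = -10L,
    multi_ies = FALSE)
  out <- error_prone_fraction(res, ev)
  expect_equal(out[stratum == "fully_excised", fraction], 0.5)
  expect_equal(out[stratum != "fully_excised", sum(n_with_error)], 0L)
  out0 <- error_prone_fraction(res, ev[0L])
  expect_true(all(out0$fraction == 0))
})
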