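test_that("boundary and retention score arithmetic", {
  expect_equal(boundary_score(10, 30), 0.25)
  expect_equal(boundary_score(0, 17), 0)
  expect_true(is.na(boundary_score(0, 0)))
  expect_error(boundary_score(-1, 3), ">= 0")
  expect_equal(retention_score(0.2, 0.4), 0.3)
  expect_equal(retention_score(0.5, NA), 0.5)
  expect_equal(retention_score(1.0, 1.0), 1.0)
  expect_true(is.na(retention_score(NA, NA)))
})

test_that("boundary tallies follow the counting rules", {
  ev <- data.table::data.table(
    read_id = sprintf("r%d", 1:4),
    kind = c("IES_PLUS_LEFT", "IES_PLUS_LEFT", "IES_PLUS_LEFT", "IES_MINUS"),
    ies_id = "i1", scaffold = "s1", a = NA_integer_, b = NA_integer_)
  tal <- tally_boundaries(ev)
  expect_equal(tal[side == "left", plus_count], 3L)
  expect_equal(tal[side == "left", minus_count], 1L)   # minus counts both sides
  expect_equal(tal[side == "right", plus_count], 0L)
  expect_equal(tal[side == "right", minus_count], 1L)
})

test_that("tallies reject evidence for unknown IESs and handle empty input", {
  ann <- data.table::data.table(ies_id = "i1")
  ev <- data.table::data.table(read_id = "r1", kind = "IES_PLUS_LEFT",
                               ies_id = "i9", scaffold = "s1",
                               a = NA_integer_, b = NA_integer_)
  expect_error(tally_boundaries(ev, ann), "unknown ies_id")
  empty <- tally_boundaries(ev[0L], ann)
  expect_equal(nrow(empty), 2L)
  expect_true(all(empty$plus_count == 0L))
})

test_that("one-sided boundary test matches Fisher's exact test", {
  mk <- function(plus, minus)
    data.table::data.table(ies_id = "i1", side = c("left", "right"),
                           plus_count = plus, minus_count = minus)
  res <- call_significance(mk(c(50L, 0L), c(50L, 100L)),
                           mk(c(0L, 0L), c(100L, 100L)))
  oracle <- fisher.test(matrix(c(50, 50, 0, 100), 2, byrow = TRUE),
                        alternative = "greater")$p.value
  expect_equal(res$p_left, oracle, tolerance = 1e-10)
  expect_equal(res$p_left, 2.22296975121e-19, tolerance = 1e-6)
  expect_true(res$significantly_retained)
  # (0,100) vs (0,100): p = 1, not significant
  expect_equal(res$p_right, 1)
  res2 <- call_significance(mk(c(10L, 10L), c(90L, 90L)),
                            mk(c(10L, 10L), c(90L, 90L)))
  expect_false(any(res2$significantly_retained))
})

test_that("IRS is 0 on pure somatic reads and 1 on pure germline reads", {
  cfg <- small_cfg(n_ies = 12L, old_mac_fraction = 0, error_rate = 0,
                   parental_error_junctions = 0L)
  for (p in c(0, 1)) {
    cfg$retention_prob <- p
    g <- generate_genomes(cfg)
    sim <- simulate_reads(g, cfg)
    idx <- build_index(g$germline, g$somatic, g$ies)
    tal <- tally_boundaries(classify_reads(sim$reads, idx), g$ies)
    sc <- boundary_score(tal$plus_count, tal$minus_count)
    expect_true(all(sc[!is.na(sc)] == p))
  }
})

test_that("old-MAC contamination can only lower IRS", {
  irs_at <- function(frac) {
    cfg <- small_cfg(n_ies = 15L, retention_prob = 0.6, error_rate = 0,
                     old_mac_fraction = frac, coverage = 60)
    g <- generate_genomes(cfg)
    sim <- simulate_reads(g, cfg)
    idx <- build_index(g$germline, g$somatic, g$ies)
    tal <- tally_boundaries(classify_reads(sim$reads, idx), g$ies)
    w <- data.table::dcast(tal, ies_id ~ side,
                           value.var = c("plus_count", "minus_count"))
    mean(retention_score(
      boundary_score(w$plus_count_left, w$minus_count_left),
      boundary_score(w$plus_count_right, w$minus_count_right)), na.rm = TRUE)
  }
  vals <- vapply(c(0, 0.25, 0.5), irs_at, numeric(1))
  expect_true(all(diff(vals) < 0.02))   # non-increasing up to sampling noise
})

test_that("the 'both boundaries' policy is stricter than 'either'", {
  mk <- function(pl, ml) data.table::data.table(
    ies_id = "i1", side = c("left", "right"), plus_count = pl, minus_count = ml)
  s <- mk(c(40L, 1L), c(60L, 99L)); ctl <- mk(c(0L, 0L), c(100L, 100L))
  either <- call_significance(s, ctl, policy = "either")
  both <- call_significance(s, ctl, policy = "both")
  expect_true(either$significantly_retained)
  expect_false(both$significantly_retained)
})
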