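test_that("IRS histogram bins by 0.025 and conserves counts", {
  h <- irs_histogram(c(0, 0, 0))
  expect_equal(h$counts[1], 3L)
  expect_equal(sum(h$counts), 3L)
  h2 <- irs_histogram(c(0.024, 0.026))
  expect_equal(h2$counts[1], 1L)
  expect_equal(h2$counts[2], 1L)
  h3 <- irs_histogram(c(0.5, NA, 1))
  expect_equal(sum(h3$counts), 2L)
  expect_equal(h3$n_undefined, 1L)
  expect_equal(h3$counts[length(h3$counts)], 1L)   # irs = 1 lands in last bin
})

test_that("excised set overlap counts are exact", {
  expect_equal(excised_set_overlap(c("a", "b"), c("a", "b"))$fraction_b_in_a, 1)
  expect_equal(excised_set_overlap(c("a", "b"), c("c"))$fraction_b_in_a, 0)
  ov <- excised_set_overlap(c("a", "b", "c"), c("b", "c"))
  expect_equal(ov$a_only, 1L); expect_equal(ov$shared, 2L)
  expect_equal(ov$b_only, 0L); expect_equal(ov$fraction_b_in_a, 1)
})

test_that("length comparison behaves across scales", {
  same <- compare_lengths(c(30, 40, 50, 60), c(30, 40, 50, 60))
  expect_gt(same$p_value, 0.9)
  set.seed(9)
  a <- sample(26:120, 200, replace = TRUE)
  shifted <- compare_lengths(a + 30, a)
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$median_a, shifted$median_b + 30)
  # smallest possible samples still yield a valid p from the null set
  expect_equal(compare_lengths(5, 9)$p_value, 1)
  expect_error(compare_lengths(numeric(0), 1), "non-empty")
})

test_that("MWW p-values match exact enumeration for small samples", {
  set.seed(3)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    x <- sample(1000L, n1); y <- sample(2000L, n2)  # ties negligible
    while (length(intersect(x, y))) y <- sample(2000L, n2)
    got <- compare_lengths(x, y)$p_value
    expect_equal(got, oracle_mww_p(x, y), tolerance = 1e-9)
  }
})

test_that("size peak fractions honour their windows", {
  out <- size_peak_fractions(rep(27, 10))
  expect_equal(out[label == "26-28", frac_set], 1)
  expect_equal(out[label == "75-77", frac_set], 0)
  out2 <- size_peak_fractions(c(27, 36, 75), reference = c(46, 46))
  expect_equal(out2[label == "36-37", n_set], 1L)
  expect_equal(out2[label == "46-47", frac_ref], 1)
  bad <- data.table::data.table(label = c("x", "y"), min_bp = c(26L, 27L),
                                max_bp = c(30L, 40L))
  expect_error(size_peak_fractions(27, spec = bad), "disjoint")
})

test_that("top_retained picks the highest-IRS IESs", {
  res <- data.table::data.table(ies_id = c("a", "b", "c", "d"),
                                irs = c(0.9, NA, 0.2, 0.5))
  expect_equal(top_retained(res, 2L), c("a", "d"))
})

test_that("PWM columns sum to the number of ends counted", {
  g <- generate_genomes(small_cfg(n_ies = 15L))
  pwm <- end_motif_pwm(g$ies, g$germline)
  expect_true(all(colSums(pwm) == 2L * nrow(g$ies)))
  pwm_l <- end_motif_pwm(g$ies, g$germline, which = "left")
  expect_true(all(colSums(pwm_l) == nrow(g$ies)))
  # both orientations start with the TA anchor
  expect_equal(unname(pwm["T", 1] + pwm["A", 1]), 2L * nrow(g$ies))
})

test_that("internal TA offsets are counted correctly on a hand case", {
  # IES TATACG...: TA also at offset 2 from the left boundary
  germ <- c(s1 = paste0(strrep("G", 30), "TATACGGGCCGGCCGGAATTCCGGAACC",
                        "TA", strrep("C", 28)))
  ann <- data.table::data.table(ies_id = "i1", scaffold = "s1",
                                start = 31L, end = 58L, length = 28L)
  out <- ta_positions(ann, germ, window = 10L)
  expect_equal(out[offset == 2L, n_left], 1L)
  expect_equal(out[offset == 3L, n_left], 0L)
  expect_false(0L %in% out$offset)   # canonical TA excluded
})

test_that("internal TA frequency matches the base-composition expectation", {
  cfg <- small_cfg(n_ies = 150L, n_scaffolds = 2L, scaffold_len = 16000L,
                   gc = 0.28, error_rate = 0, parental_error_junctions = 0L)
  g <- generate_genomes(cfg)
  out <- ta_positions(g$ies, g$germline, window = 16L)
  # offsets 9..16 lie in the random core for nearly all IESs:
  # P(TA) = p(T) * p(A) = 0.36 * 0.36 = 0.1296
  frac <- out[offset >= 9L, n_left] / nrow(g$ies)
  expect_lt(abs(mean(frac) - 0.36 * 0.36), 0.04)
})

test_that("alternative boundaries of planted errors show no consensus", {
  cfg <- small_cfg(n_ies = 60L, n_scaffolds = 2L, scaffold_len = 16000L,
                   error_rate = 1, retention_prob = 0, old_mac_fraction = 0)
  g <- generate_genomes(cfg)
  sim <- simulate_reads(g)
  idx <- build_index(g$germline, g$somatic, g$ies)
  events <- collapse_events(classify_reads(sim$reads, idx), g$ies)
  octs <- alt_boundary_octamers(events, g$germline)
  expect_gt(length(octs), 10L)
  expect_true(all(substr(octs, 1, 2) == "TA"))
  # beyond the TA, position 5 is not fixed to the consensus G
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(octs))
  expect_lt(m["G", 5] / length(octs), 0.8)
})
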