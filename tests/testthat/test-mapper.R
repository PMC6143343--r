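test_that("the index holds three probes per IES with the defined content", {
  h <- hand_genome()
  idx <- build_index(h$germline, h$somatic, h$ies, k = 12L, min_anchor = 12L)
  a <- 12L; s <- h$ies$start; e <- h$ies$end; t <- h$ies$somatic_pos
  expect_equal(idx$ies$left_probe, substr(h$germline[["s1"]], s - a, s + a - 1L))
  expect_equal(idx$ies$right_probe, substr(h$germline[["s1"]], e - a + 1L, e + a))
  expect_equal(idx$ies$junction_probe,
               substr(h$somatic[["s1"]], t - a, t + a - 1L))
})

test_that("probe-equal reads classify as boundary / junction support", {
  h <- hand_genome()
  idx <- build_index(h$germline, h$somatic, h$ies)
  ev_l <- classify_read(idx$ies$left_probe, idx)
  expect_equal(ev_l$kind, "IES_PLUS_LEFT")
  expect_equal(ev_l$ies_id, h$ies$ies_id)
  ev_r <- classify_read(idx$ies$right_probe, idx)
  expect_equal(ev_r$kind, "IES_PLUS_RIGHT")
  ev_j <- classify_read(idx$ies$junction_probe, idx)
  expect_equal(ev_j$kind, "IES_MINUS")
  expect_equal(ev_j$a, h$ies$start)
  expect_equal(ev_j$b, h$ies$end)
})

test_that("reads inside an IES or plain germline are uninformative", {
  h <- hand_genome()
  idx <- build_index(h$germline, h$somatic, h$ies)
  inside <- substr(h$germline[["s1"]], h$ies$start + 2L, h$ies$end - 2L)
  expect_equal(classify_read(inside, idx)$kind, "NONE")
  expect_null(detect_deletion(substr(h$germline[["s1"]], 1L, 28L), idx))
})

test_that("detect_deletion recovers a TA-bounded deletion exactly", {
  h <- hand_genome()
  idx <- build_index(h$germline, h$somatic, h$ies)
  s <- h$ies$start; e <- h$ies$end
  read <- paste0(substr(h$germline[["s1"]], s - 14L, s - 1L),
                 substr(h$germline[["s1"]], e + 1L, e + 14L))
  d <- detect_deletion(read, idx)
  expect_equal(d$scaffold, "s1")
  expect_equal(c(d$a, d$b), c(s, e))
  g <- h$germline[["s1"]]
  expect_identical(substr(g, d$a, d$a + 1L), "TA")
  expect_identical(substr(g, d$b + 1L, d$b + 2L), "TA")
})

test_that("index construction validates its inputs", {
  h <- hand_genome()
  g2 <- c(h$germline, h$germline)   # duplicate names
  expect_error(build_index(g2, c(h$somatic, h$somatic), h$ies), "duplicate")
  expect_error(build_index(h$germline, h$somatic, h$ies, min_anchor = 6L),
               "min_anchor")
  expect_error(build_index(h$germline, h$somatic, h$ies, k = 16L,
                           min_anchor = 12L), "k must be")
})

test_that("an empty annotation yields only NONE or contiguous evidence", {
  cfg <- small_cfg(n_ies = 0L)
  g <- generate_genomes(cfg)
  idx <- build_index(g$germline, g$somatic, g$ies)
  sim <- simulate_reads(g)
  ev <- classify_reads(sim$reads[1:200], idx)
  expect_true(all(ev$kind == "NONE"))
})

test_that("planted deletions with full anchors are recovered exactly", {
  cfg <- small_cfg(n_ies = 25L, scaffold_len = 9000L, retention_prob = 0,
                   error_rate = 1, old_mac_fraction = 0, coverage = 60)
  g <- generate_genomes(cfg)
  sim <- simulate_reads(g)
  idx <- build_index(g$germline, g$somatic, g$ies)
  ev <- classify_reads(sim$reads, idx)
  alt <- ev[ev$kind == "ALT_DELETION"]
  expect_gt(nrow(alt), 50L)
  truth <- sim$truth$events
  truth_keys <- vapply(seq_len(nrow(truth)), function(i) {
    ab <- normalize_deletion(idx, truth$scaffold[i], truth$alt_start[i],
                             truth$alt_end[i])
    paste(truth$scaffold[i], ab[1L], ab[2L])
  }, character(1))
  canon_keys <- paste(g$ies$scaffold, g$ies$start, g$ies$end)
  seen <- paste(alt$scaffold, alt$a, alt$b)
  expect_true(all(seen %in% truth_keys))
  # and IES_MINUS intervals coincide with annotated IESs
  minus <- ev[ev$kind == "IES_MINUS"]
  expect_true(all(paste(minus$scaffold, minus$a, minus$b) %in% canon_keys))
})

test_that("deletion normalization is idempotent and TA-led", {
  cfg <- small_cfg(n_ies = 20L, error_rate = 1, retention_prob = 0,
                   scaffold_len = 8000L)
  g <- generate_genomes(cfg)
  idx <- build_index(g$germline, g$somatic, g$ies)
  alt <- g$ies[!is.na(g$ies$alt_start)]
  for (i in seq_len(nrow(alt))) {
    ab1 <- normalize_deletion(idx, alt$scaffold[i], alt$alt_start[i],
                              alt$alt_end[i])
    ab2 <- normalize_deletion(idx, alt$scaffold[i], ab1[1L], ab1[2L])
    expect_identical(ab1, ab2)
    seq <- g$germline[[alt$scaffold[i]]]
    expect_identical(substr(seq, ab1[1L], ab1[1L] + 1L), "TA")
    expect_identical(substr(seq, ab1[2L] + 1L, ab1[2L] + 2L), "TA")
  }
})

test_that("split detection agrees with the brute-force oracle on small genomes", {
  for (seed in c(11L, 12L)) {
    cfg <- small_cfg(n_ies = 12L, scaffold_len = 5000L, seed = seed,
                     retention_prob = 0.4, error_rate = 0.3, coverage = 15)
    g <- generate_genomes(cfg)
    sim <- simulate_reads(g)
    idx <- build_index(g$germline, g$somatic, g$ies)
    reads <- sim$reads$seq[1:400]
    for (rd in reads) {
      got <- detect_deletion(rd, idx)
      want <- oracle_detect(rd, g$germline[[1L]], g$ies)
      if (is.null(want)) expect_null(got)
      else {
        expect_false(is.null(got))
        expect_equal(c(got$a, got$b), unname(want))
      }
    }
  }
})
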