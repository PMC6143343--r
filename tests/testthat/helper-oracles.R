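# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's seed-and-extend / classification
# code paths: they enumerate by string search or direct position arithmetic.

# --- fixtures ---------------------------------------------------------------

small_cfg <- function(...) {
  args <- modifyList(list(n_scaffolds = 1L, scaffold_len = 4000L, n_ies = 10L,
                          coverage = 40, seed = 101L), list(...))
  do.call(sim_config, args)
}

# a tiny hand-built genome pair: one scaffold, one IES, generous flanks
hand_genome <- function() {
  flank_l <- "GGATCCGGAACCGGTTACGCAACGGATT"      # 28 bp
  ies     <- "TACAGTAGCCGGAATTCCGGAACCTAGG"      # 28 bp, starts TA
  flank_r <- "TACCGGAATTGGCCAATTGGAACCGGTT"      # 28 bp, starts TA (kept copy)
  germ <- paste0(flank_l, ies, flank_r)
  soma <- paste0(flank_l, flank_r)
  ann <- data.table::data.table(
    ies_id = "IES.test.0001", scaffold = "s1",
    start = nchar(flank_l) + 1L, end = nchar(flank_l) + nchar(ies),
    length = nchar(ies), somatic_pos = nchar(flank_l) + 1L)
  list(germline = c(s1 = germ), somatic = c(s1 = soma), ies = ann)
}

# --- deletion-detection oracle ---------------------------------------------

all_occurrences <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# brute-force split-read deletion finder: for every split of the read,
# every occurrence of both parts, collect TA-led deletion intervals; pick
# the convention's canonical representative (annotated interval if present,
# else leftmost). Returns NULL when the read is explained by a contiguous
# match, when a seed k-mer is absent/ambiguous, or when no TA-bounded
# deletion explains the read.
oracle_detect <- function(read, germ_seq, ann, min_anchor = 12L, k = 12L) {
  len <- nchar(read)
  if (length(all_occurrences(read, germ_seq)) > 0L) return(NULL)
  k1 <- all_occurrences(substr(read, 1L, k), germ_seq)
  k2 <- all_occurrences(substr(read, len - k + 1L, len), germ_seq)
  if (length(k1) != 1L || length(k2) != 1L) return(NULL)
  is_ta <- function(p) p >= 1L && p + 1L <= nchar(germ_seq) &&
    substr(germ_seq, p, p + 1L) == "TA"
  cand <- list()
  for (i in seq(min_anchor, len - min_anchor)) {
    left <- substr(read, 1L, i); right <- substr(read, i + 1L, len)
    for (pL in all_occurrences(left, germ_seq)) {
      for (qR in all_occurrences(right, germ_seq)) {
        a <- pL + i; b <- qR - 1L
        if (b < a) next
        if (is_ta(a) && is_ta(b + 1L)) cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  # expand each candidate to every TA-led representation of its
  # micro-homology equivalence class, by direct spliced-string comparison
  nl <- nchar(germ_seq)
  expand <- function(a, b) {
    base <- paste0(substr(germ_seq, 1L, a - 1L),
                   substr(germ_seq, b + 1L, nl))
    reps <- list()
    for (delta in -60:60) {
      a2 <- a + delta; b2 <- b + delta
      if (a2 < 1L || b2 + 2L > nl) next
      if (substr(germ_seq, a2, a2 + 1L) != "TA" ||
          substr(germ_seq, b2 + 1L, b2 + 2L) != "TA") next
      if (paste0(substr(germ_seq, 1L, a2 - 1L),
                 substr(germ_seq, b2 + 1L, nl)) == base)
        reps[[length(reps) + 1L]] <- c(a2, b2)
    }
    do.call(rbind, reps)
  }
  m <- unique(do.call(rbind, lapply(cand, function(ab) expand(ab[1], ab[2]))))
  if (!is.null(ann) && nrow(ann)) {
    hit <- which(paste(m[, 1], m[, 2]) %in% paste(ann$start, ann$end))
    if (length(hit)) return(m[hit[1L], ])
  }
  m[which.min(m[, 1L]), ]
}

# --- event-classification oracle -------------------------------------------

# direct boundary-position classifier, written against the taxonomy
# definition rather than the package's category helpers
oracle_classify <- function(scaffold, a, b, ann) {
  sub <- ann[ann$scaffold == scaffold & ann$start <= b & ann$end >= a, ]
  if (nrow(sub) == 0L) return("UNMATCHED")
  ov <- pmin(sub$end, b) - pmax(sub$start, a) + 1L
  sub <- sub[order(-ov, sub$start), ]
  s <- sub$start[1L]; e <- sub$end[1L]
  lcat <- if (a == s) 0L else if (a < s) -1L else 1L   # 0 canon, -1 ext, 1 int
  rcat <- if (b == e) 0L else if (b > e) -1L else 1L
  if (lcat == 0L && rcat == 0L) return("CORRECT")
  if (lcat == 0L || rcat == 0L) {
    other <- if (lcat == 0L) rcat else lcat
    return(if (other == 1L) "PARTIAL_INTERNAL" else "PARTIAL_EXTERNAL")
  }
  if (lcat == 1L && rcat == 1L) return("INTERNAL")
  if (lcat == -1L && rcat == -1L) return("EXTERNAL")
  "OVERLAPPING"
}

# --- exact Mann-Whitney oracle ---------------------------------------------

# exact two-sided MWW p by full enumeration of rank assignments (no ties)
oracle_mww_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_null <- apply(combs, 2L, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-9)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
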