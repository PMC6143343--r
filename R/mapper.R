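# Deterministic seed-and-extend split matcher.
#
# Reads are classified against the germline ("MAC+IES") reference:
#   IES_PLUS_LEFT / IES_PLUS_RIGHT  read spans an IES boundary with at least
#                                   min_anchor exact bases on each side
#   IES_MINUS                       read spans the precise excision junction
#                                   (a deletion equal to an annotated IES)
#   ALT_DELETION                    read spans a TA-bounded deletion that is
#                                   not an annotated IES
#   NONE                            uninformative
#
# Because an excised segment is flanked by a TA direct repeat, a deletion
# interval is ambiguous by steps of 2 bp. All reported intervals are
# normalized to a TA-led representation (interval begins with TA, the
# retained TA copy is the downstream one), preferring the representation that
# coincides with an annotated IES, then the leftmost.

#' Build a junction-mapping index
#'
#' Precomputes a unique k-mer map of the germline genome plus, for every
#' annotated IES, three probe strings of length `2 * min_anchor`: the left
#' and right boundary probes on the germline and the excision-junction probe
#' on the somatic genome.
#'
#' @param germline,somatic named character vectors of scaffold sequences.
#' @param annotation IES annotation table (`ies_id`, `scaffold`, `start`,
#'   `end`, `somatic_pos`).
#' @param k seed length (default 12, must be `<= min_anchor`).
#' @param min_anchor minimum exact match on each side of a junction
#'   (default 12, must be `>= 8`).
#' @return an object of class `junction_index`.
#' @export
build_index <- function(germline, somatic, annotation, k = 12L,
                        min_anchor = 12L) {
  check_that(min_anchor >= 8L, "min_anchor must be >= 8")
  check_that(k <= min_anchor, "k must be <= min_anchor")
  check_that(!anyDuplicated(names(germline)) && !anyDuplicated(names(somatic)),
             "input error: duplicate scaffold names")
  check_that(setequal(names(germline), names(somatic)),
             "germline and somatic scaffold names must match")
  ann <- as.data.table(annotation)
  a <- as.integer(min_anchor)

  if (nrow(ann) > 0L) {
    check_that(all(ann$scaffold %in% names(germline)),
               "annotation references unknown scaffold")
    ann[, left_probe := substr(germline[scaffold], start - a, start + a - 1L),
        by = seq_len(nrow(ann))]
    ann[, right_probe := substr(germline[scaffold], end - a + 1L, end + a),
        by = seq_len(nrow(ann))]
    ann[, junction_probe := substr(somatic[scaffold], somatic_pos - a,
                                   somatic_pos + a - 1L),
        by = seq_len(nrow(ann))]
    check_that(all(nchar(ann$left_probe) == 2L * a) &&
               all(nchar(ann$right_probe) == 2L * a) &&
               all(nchar(ann$junction_probe) == 2L * a),
               "IES too close to a scaffold edge for probes")
  }

  kl <- lapply(names(germline), function(sc) {
    seq <- germline[[sc]]
    n <- nchar(seq) - k + 1L
    if (n < 1L) return(NULL)
    data.table(kmer = substring(seq, seq_len(n), seq_len(n) + k - 1L),
               scaffold = sc, pos = seq_len(n))
  })
  kmap <- rbindlist(kl)
  kmap <- kmap[, .(scaffold = scaffold[1L], pos = pos[1L], n = .N), by = kmer]
  setkey(kmap, kmer)

  # per-scaffold annotated intervals as plain vectors for the hot path
  ann_by_sc <- lapply(names(germline), function(sc) {
    sub <- ann[ann$scaffold == sc]
    list(start = sub$start, end = sub$end, ies_id = sub$ies_id)
  })
  names(ann_by_sc) <- names(germline)

  structure(list(germline = germline, somatic = somatic, ies = ann,
                 k = as.integer(k), min_anchor = a, kmap = kmap,
                 ann_by_sc = ann_by_sc),
            class = "junction_index")
}

# all equivalent representations of a TA-led deletion under the TA direct
# repeat micro-homology; returns the canonical one (annotated if possible,
# else leftmost)
#' Normalize a TA-bounded deletion interval
#'
#' Slides a deletion interval `[a, b]` (1-based inclusive, bases deleted)
#' within its micro-homology equivalence class and returns the canonical
#' TA-led representation: the one equal to an annotated IES interval if any,
#' otherwise the leftmost. Normalizing an already-normalized interval is the
#' identity.
#'
#' @param index a `junction_index`.
#' @param scaffold scaffold name.
#' @param a,b deletion interval, 1-based inclusive.
#' @return integer vector `c(a, b)` of the canonical representation.
#' @export
normalize_deletion <- function(index, scaffold, a, b) {
  normalize_core(index$germline[[scaffold]], a, b, index$ann_by_sc[[scaffold]])
}

normalize_core <- function(seq, a, b, ann) {
  nc <- nchar(seq)
  is_ta <- function(p) p >= 1L && p + 1L <= nc &&
    substr(seq, p, p + 1L) == "TA"
  check_that(is_ta(a) && is_ta(b + 1L),
             "contract violation: interval is not TA-bounded")
  # deleting [a+d, b+d] leaves the same sequence for every d in the
  # micro-homology range [-l, r]; enumerate it, keep TA-led representations
  l <- 0L
  while (a - l - 1L >= 1L &&
         substr(seq, a - l - 1L, a - l - 1L) == substr(seq, b - l, b - l))
    l <- l + 1L
  r <- 0L
  while (b + r + 2L <= nc &&
         substr(seq, a + r, a + r) == substr(seq, b + r + 1L, b + r + 1L))
    r <- r + 1L
  d <- (-l):r
  reps_a <- a + d; reps_b <- b + d
  ok <- reps_a >= 1L & reps_b + 2L <= nc &
    substring(seq, reps_a, reps_a + 1L) == "TA" &
    substring(seq, reps_b + 1L, reps_b + 2L) == "TA"
  reps_a <- reps_a[ok]; reps_b <- reps_b[ok]
  if (!is.null(ann) && length(ann$start)) {
    hit <- which(reps_a %in% ann$start)
    for (h in hit)
      if (any(ann$start == reps_a[h] & ann$end == reps_b[h]))
        return(c(reps_a[h], reps_b[h]))
  }
  i <- which.min(reps_a)
  c(reps_a[i], reps_b[i])
}

# unique k-mer lookup: returns data.table(scaffold, pos, ok)
seed_lookup <- function(index, kmers) {
  hit <- index$kmap[J(kmers)]
  hit[, ok := !is.na(pos) & n == 1L]
  hit
}

#' Detect a TA-bounded deletion supported by one read
#'
#' Seed-and-extend split matching: the read's first and last k-mers anchor it
#' to the germline; if the read is explained as
#' `germline[p..a-1] + germline[b+1..q]` with at least `min_anchor` matching
#' bases on each side and a TA-led deletion `[a, b]`, that interval is
#' returned (normalized). Returns `NULL` for contiguous matches, ambiguous
#' seed placements, or reads not explained by a single TA-bounded deletion.
#'
#' @param read a single read sequence.
#' @param index a `junction_index`.
#' @param min_anchor minimum anchor length; defaults to the index's value.
#' @return `list(scaffold, a, b)` or `NULL`.
#' @export
detect_deletion <- function(read, index, min_anchor = index$min_anchor) {
  len <- nchar(read)
  if (len < 2L * min_anchor) return(NULL)
  k <- index$k
  s1 <- seed_lookup(index, substr(read, 1L, k))
  s2 <- seed_lookup(index, substr(read, len - k + 1L, len))
  if (!s1$ok || !s2$ok || s1$scaffold != s2$scaffold) return(NULL)
  sc <- s1$scaffold
  ab <- detect_core(read, index$germline[[sc]], s1$pos, s2$pos + k - 1L,
                    min_anchor, index$ann_by_sc[[sc]])
  if (is.null(ab)) return(NULL)
  list(scaffold = sc, a = ab[1L], b = ab[2L])
}

# split-match core on plain vectors; p = germline pos of read start seed,
# qe = germline pos of read's last base seed
detect_core <- function(read, seq, p, qe, min_anchor, ann) {
  len <- nchar(read)
  D <- (qe - p + 1L) - len
  if (D <= 0L) return(NULL)

  rr <- charToRaw(read)
  g_pref <- charToRaw(substr(seq, p, min(p + len - 1L, nchar(seq))))
  np <- min(length(rr), length(g_pref))
  mism <- which(rr[seq_len(np)] != g_pref[seq_len(np)])
  P <- if (length(mism)) mism[1L] - 1L else np
  g_suf <- charToRaw(substr(seq, max(1L, qe - len + 1L), qe))
  ns <- min(length(rr), length(g_suf))
  mism <- which(rev(rr)[seq_len(ns)] != rev(g_suf)[seq_len(ns)])
  S <- if (length(mism)) mism[1L] - 1L else ns

  lo <- max(min_anchor, len - S)
  hi <- min(P, len - min_anchor)
  if (lo > hi) return(NULL)
  splits <- lo:hi
  aa <- p + splits
  bb <- aa + D - 1L
  ta <- substring(seq, aa, aa + 1L) == "TA" &
    substring(seq, bb + 1L, bb + 2L) == "TA"
  if (!any(ta)) return(NULL)
  normalize_core(seq, aa[ta][1L], bb[ta][1L], ann)
}

#' Classify reads against the germline and somatic references
#'
#' Vectorized read classification (see the module comment at the top of the
#' mapper source for the evidence kinds). A read spanning both boundaries of
#' a short IES yields one evidence row per boundary; a read supporting an
#' excision junction yields a single `IES_MINUS` row whose interval equals
#' the annotated IES.
#'
#' @param reads a `data.table(read_id, seq)`, or a character vector of read
#'   sequences (ids are generated).
#' @param index a `junction_index`.
#' @param revcomp_fallback if `TRUE`, reads with no seed match are retried
#'   reverse-complemented (the simulator emits forward-strand reads, so this
#'   is off by default).
#' @return a `data.table(read_id, kind, ies_id, scaffold, a, b)` of junction
#'   evidence; uninformative reads appear with `kind == "NONE"`.
#' @export
classify_reads <- function(reads, index, revcomp_fallback = FALSE) {
  if (is.character(reads))
    reads <- data.table(read_id = sprintf("read_%06d", seq_along(reads)),
                        seq = reads)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  n <- nrow(reads)
  none <- function(ids) data.table(read_id = ids, kind = "NONE",
                                   ies_id = NA_character_,
                                   scaffold = NA_character_,
                                   a = NA_integer_, b = NA_integer_)
  if (n == 0L) return(none(character(0)))
  lens <- nchar(reads$seq)
  check_that(all(lens >= 2L * index$min_anchor),
             "reads shorter than 2 * min_anchor")

  k <- index$k
  s1 <- seed_lookup(index, substr(reads$seq, 1L, k))
  if (revcomp_fallback) {
    miss <- which(is.na(s1$pos))
    if (length(miss)) {
      rc <- revcomp(reads$seq[miss])
      s1rc <- seed_lookup(index, substr(rc, 1L, k))
      use <- which(s1rc$ok)
      if (length(use)) {
        reads$seq[miss[use]] <- rc[use]
        s1[miss[use], c("scaffold", "pos", "n", "ok")] <-
          s1rc[use, .(scaffold, pos, n, ok)]
      }
    }
  }

  contig <- rep(FALSE, n)
  usable <- which(s1$ok)
  if (length(usable)) {
    gs <- substring(index$germline[s1$scaffold[usable]], s1$pos[usable],
                    s1$pos[usable] + lens[usable] - 1L)
    contig[usable] <- gs == reads$seq[usable]
  }

  ev <- list()
  # contiguous germline matches: boundary-probe containment by coordinates
  if (nrow(index$ies) > 0L && any(contig)) {
    ci <- which(contig)
    rd <- data.table(i = ci, scaffold = s1$scaffold[ci], p = s1$pos[ci],
                     q = s1$pos[ci] + lens[ci] - 1L)
    a <- index$min_anchor
    for (sc in unique(rd$scaffold)) {
      ann <- index$ies[index$ies$scaffold == sc]
      if (nrow(ann) == 0L) next
      sub <- rd[rd$scaffold == sc]
      rr <- IRanges::IRanges(start = sub$p, end = sub$q)
      probes <- IRanges::IRanges(
        start = c(ann$start - a, ann$end - a + 1L),
        end = c(ann$start + a - 1L, ann$end + a))
      side <- rep(c("IES_PLUS_LEFT", "IES_PLUS_RIGHT"), each = nrow(ann))
      ids <- rep(ann$ies_id, 2L)
      hits <- IRanges::findOverlaps(probes, rr, type = "within")
      if (length(hits)) {
        ev[[length(ev) + 1L]] <- data.table(
          read_id = reads$read_id[sub$i[S4Vectors::subjectHits(hits)]],
          kind = side[S4Vectors::queryHits(hits)],
          ies_id = ids[S4Vectors::queryHits(hits)],
          scaffold = sc, a = NA_integer_, b = NA_integer_)
      }
    }
  }

  # split candidates: everything mapped but not contiguous
  split_idx <- which(s1$ok & !contig)
  if (length(split_idx)) {
    s2 <- seed_lookup(index, substr(reads$seq[split_idx],
                                    lens[split_idx] - k + 1L,
                                    lens[split_idx]))
    keep <- s2$ok & s2$scaffold == s1$scaffold[split_idx]
    keep[is.na(keep)] <- FALSE
    idxs <- split_idx[keep]
    p_of <- s1$pos[idxs]
    qe_of <- s2$pos[keep] + k - 1L
    sc_of <- s1$scaffold[idxs]
    out_id <- character(length(idxs)); out_kind <- character(length(idxs))
    out_ies <- character(length(idxs)); out_sc <- character(length(idxs))
    out_a <- integer(length(idxs)); out_b <- integer(length(idxs))
    n_hit <- 0L
    for (j in seq_along(idxs)) {
      i <- idxs[j]; sc <- sc_of[j]
      ann_sc <- index$ann_by_sc[[sc]]
      ab <- detect_core(reads$seq[i], index$germline[[sc]], p_of[j], qe_of[j],
                        index$min_anchor, ann_sc)
      if (is.null(ab)) next
      n_hit <- n_hit + 1L
      hit <- which(ann_sc$start == ab[1L] & ann_sc$end == ab[2L])
      out_id[n_hit] <- reads$read_id[i]
      out_kind[n_hit] <- if (length(hit)) "IES_MINUS" else "ALT_DELETION"
      out_ies[n_hit] <- if (length(hit)) ann_sc$ies_id[hit[1L]] else NA_character_
      out_sc[n_hit] <- sc; out_a[n_hit] <- ab[1L]; out_b[n_hit] <- ab[2L]
    }
    if (n_hit > 0L) {
      sel <- seq_len(n_hit)
      ev[[length(ev) + 1L]] <- data.table(
        read_id = out_id[sel], kind = out_kind[sel], ies_id = out_ies[sel],
        scaffold = out_sc[sel], a = out_a[sel], b = out_b[sel])
    }
  }

  ev <- rbindlist(ev)
  informative <- if (nrow(ev)) unique(ev$read_id) else character(0)
  rbind(ev, none(setdiff(reads$read_id, informative)))
}

#' Classify a single read
#'
#' Convenience wrapper around [classify_reads()] for one read sequence.
#'
#' @inheritParams classify_reads
#' @param read a single read sequence.
#' @return a `data.table` of evidence rows for this read.
#' @export
classify_read <- function(read, index) {
  classify_reads(data.table(read_id = "read", seq = read), index)
}
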