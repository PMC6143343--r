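# Genome-wide summaries: IRS histograms, excised-set overlaps, size
# distribution contrasts, size-peak fractions, end-motif composition and
# internal-TA availability.

#' Default IES size-peak windows
#'
#' Disjoint, ordered windows (bp) centred on the periodic peaks of the IES
#' length distribution.
#'
#' @return `data.table(label, min_bp, max_bp)`.
#' @export
size_peak_spec <- function() {
  data.table(label = c("26-28", "36-37", "46-47", "55-57", "66-68", "75-77"),
             min_bp = c(26L, 36L, 46L, 55L, 66L, 75L),
             max_bp = c(28L, 37L, 47L, 57L, 68L, 77L))
}

#' Histogram of IES retention scores
#'
#' Counts of defined IRS values in bins of `bin_width` over `[0, 1]`
#' (left-closed bins; the final bin is closed on both sides). Undefined IRS
#' values are reported separately.
#'
#' @param results retention table with an `irs` column, or a numeric vector.
#' @param bin_width bin width (default 0.025).
#' @return `list(breaks, counts, n_undefined)`; `sum(counts)` equals the
#'   number of defined IRS values.
#' @export
irs_histogram <- function(results, bin_width = 0.025) {
  irs <- if (is.numeric(results)) results else as.data.table(results)$irs
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  def <- irs[!is.na(irs)]
  idx <- pmin(findInterval(def, breaks, rightmost.closed = TRUE),
              length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts, n_undefined = sum(is.na(irs)))
}

#' Overlap between two excised-IES sets
#'
#' @param setA,setB character vectors of IES ids.
#' @return `list(a_only, shared, b_only, fraction_b_in_a)`.
#' @export
excised_set_overlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- length(intersect(setA, setB))
  list(a_only = length(setA) - shared, shared = shared,
       b_only = length(setB) - shared,
       fraction_b_in_a = if (length(setB) == 0L) NA_real_ else
         shared / length(setB))
}

#' Compare two IES length distributions
#'
#' Two-sided Mann-Whitney-Wilcoxon test (exact for small samples without
#' ties, normal approximation with tie- and continuity-correction otherwise,
#' as implemented in [stats::wilcox.test()]).
#'
#' @param lensA,lensB numeric vectors of IES lengths (bp).
#' @return `list(median_a, median_b, statistic, p_value)`.
#' @export
compare_lengths <- function(lensA, lensB) {
  check_that(length(lensA) >= 1L && length(lensB) >= 1L,
             "both length samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(lensA, lensB, alternative = "two.sided"))
  list(median_a = stats::median(lensA), median_b = stats::median(lensB),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Fraction of IESs in each size peak
#'
#' For a set of lengths and a genome-wide reference set, the fraction of each
#' set's IESs falling in each peak window.
#'
#' @param lengths lengths (bp) of the IES set of interest.
#' @param reference lengths of the reference set (default: `lengths`).
#' @param spec window table from [size_peak_spec()].
#' @return `data.table(label, min_bp, max_bp, n_set, frac_set, n_ref,
#'   frac_ref)`.
#' @export
size_peak_fractions <- function(lengths, reference = lengths,
                                spec = size_peak_spec()) {
  spec <- copy(as.data.table(spec))
  check_that(all(diff(spec$min_bp) > 0) && all(spec$max_bp >= spec$min_bp) &&
               all(head(spec$max_bp, -1) < tail(spec$min_bp, -1)),
             "size peak windows must be disjoint and ordered")
  count_in <- function(x, lo, hi) sum(x >= lo & x <= hi)
  spec[, n_set := mapply(count_in, min_bp, max_bp,
                         MoreArgs = list(x = lengths))]
  spec[, frac_set := if (length(lengths)) n_set / length(lengths) else 0]
  spec[, n_ref := mapply(count_in, min_bp, max_bp,
                         MoreArgs = list(x = reference))]
  spec[, frac_ref := if (length(reference)) n_ref / length(reference) else 0]
  spec[]
}

#' Select the strongly retained comparison set
#'
#' The `n` IESs with the highest IRS, where `n` defaults to the size of the
#' excised set -- the usual contrast for excised-vs-retained size analyses.
#'
#' @param results retention table from [call_significance()].
#' @param n number of IESs to select.
#' @return character vector of IES ids.
#' @export
top_retained <- function(results, n) {
  res <- copy(as.data.table(results))[!is.na(irs)]
  setorder(res, -irs)
  head(res$ies_id, n)
}

#' Position count matrix of IES end octamers
#'
#' Stacks the first 8 germline bases of every IES (left ends) with the
#' reverse complement of the last 6 IES bases plus the downstream TA copy
#' (right ends), so both ends read TA-inward, matching the 5'-TAYAGYNR-3'
#' consensus orientation. Optionally computes the same matrix for alternative
#' boundaries of classified error events.
#'
#' @param annotation IES annotation table.
#' @param germline named character vector of germline scaffolds.
#' @param which `"both"`, `"left"` or `"right"` ends.
#' @return 4 x 8 base count matrix (rows A, C, G, T); column sums equal the
#'   number of ends counted.
#' @export
end_motif_pwm <- function(annotation, germline, which = c("both", "left", "right")) {
  which <- match.arg(which)
  ann <- as.data.table(annotation)
  octs <- character(0)
  if (which %in% c("both", "left") && nrow(ann))
    octs <- c(octs, substr(germline[ann$scaffold], ann$start, ann$start + 7L))
  if (which %in% c("both", "right") && nrow(ann))
    octs <- c(octs, revcomp(substr(germline[ann$scaffold], ann$end - 5L,
                                   ann$end + 2L)))
  if (length(octs) == 0L)
    return(matrix(0L, 4L, 8L, dimnames = list(c("A", "C", "G", "T"), NULL)))
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(octs))
  out <- matrix(0L, 4L, 8L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (bs in rownames(out)) if (bs %in% rownames(m)) out[bs, ] <- m[bs, ]
  out
}

#' Octamers at alternative boundaries of error events
#'
#' Extracts TA-inward octamers at the non-canonical boundaries of classified
#' events, for motif comparison with the canonical consensus.
#'
#' @param events event table from [collapse_events()].
#' @param germline named character vector of germline scaffolds.
#' @return character vector of octamers (possibly empty).
#' @export
alt_boundary_octamers <- function(events, germline) {
  ev <- as.data.table(events)[klass %in% ERROR_CLASSES]
  if (nrow(ev) == 0L) return(character(0))
  octs <- character(0)
  left_alt <- ev[left_offset != 0L]
  if (nrow(left_alt))
    octs <- c(octs, substr(germline[left_alt$scaffold], left_alt$a,
                           left_alt$a + 7L))
  right_alt <- ev[right_offset != 0L]
  if (nrow(right_alt))
    octs <- c(octs, revcomp(substr(germline[right_alt$scaffold],
                                   right_alt$b - 5L, right_alt$b + 2L)))
  octs
}

#' Internal TA availability near IES boundaries
#'
#' Counts, at each offset `1..window` inside the IES from each canonical
#' boundary, how many IESs have a TA dinucleotide starting there (offset 0,
#' the canonical TA itself, is excluded). Under a uniform random core the
#' per-offset frequency approaches `p(T) * p(A)` of the base composition.
#'
#' @param annotation IES annotation table.
#' @param germline named character vector of germline scaffolds.
#' @param window largest offset scanned; must not exceed the shortest IES.
#' @return `data.table(offset, n_left, n_right, n_ies)`.
#' @export
ta_positions <- function(annotation, germline, window = 20L) {
  ann <- as.data.table(annotation)
  check_that(nrow(ann) == 0L || window <= min(ann$length),
             "window exceeds the shortest IES length")
  out <- data.table(offset = seq_len(window), n_left = 0L, n_right = 0L,
                    n_ies = nrow(ann))
  if (nrow(ann) == 0L) return(out)
  for (i in seq_len(nrow(ann))) {
    seq <- substr(germline[ann$scaffold[i]], ann$start[i], ann$end[i] + 2L)
    tas <- ta_sites(seq)                      # 1-based within IES + junction TA
    left_off <- tas - 1L                      # offset from left TA start
    right_off <- (ann$length[i] + 1L) - tas   # offset from downstream TA start
    for (d in seq_len(window)) {
      if (d %in% left_off) out$n_left[d] <- out$n_left[d] + 1L
      if (d %in% right_off) out$n_right[d] <- out$n_right[d] + 1L
    }
  }
  out[]
}
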