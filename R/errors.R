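# Excision-error taxonomy and de novo accounting.
#
# A TA-bounded deletion [a, b] is compared to its reference IES [s, e]
# (all 1-based inclusive; boundary offsets are reported as observed minus
# canonical TA start, so an internal left boundary is positive and an
# internal right boundary negative):
#   both boundaries canonical          -> CORRECT
#   one canonical, one internal        -> PARTIAL_INTERNAL
#   one canonical, one external        -> PARTIAL_EXTERNAL
#   both internal                      -> INTERNAL
#   both external                      -> EXTERNAL
#   one internal + one external        -> OVERLAPPING
#   no overlap with any IES            -> UNMATCHED
# Each distinct junction counts once, independently of read support.

boundary_category <- function(off_left, off_right, s, e, a, b) {
  left <- ifelse(a == s, "canonical", ifelse(a < s, "external", "internal"))
  right <- ifelse(b == e, "canonical", ifelse(b > e, "external", "internal"))
  list(left = left, right = right)
}

klass_from_categories <- function(left, right) {
  cats <- sort(c(left, right))
  if (left == "canonical" && right == "canonical") return("CORRECT")
  if (any(c(left, right) == "canonical")) {
    other <- setdiff(c(left, right), "canonical")[1L]
    return(if (other == "internal") "PARTIAL_INTERNAL" else "PARTIAL_EXTERNAL")
  }
  if (all(cats == "internal")) return("INTERNAL")
  if (all(cats == "external")) return("EXTERNAL")
  "OVERLAPPING"
}

#' Classify one TA-bounded deletion against the IES annotation
#'
#' Assigns the deletion to the annotated IES with maximal bp overlap (ties
#' broken to the leftmost IES, and the event is flagged `multi_ies`), then
#' derives its error class from where each boundary falls relative to the
#' canonical TA starts. A deletion overlapping no IES is `UNMATCHED` (a
#' TA-indel in MAC-destined sequence).
#'
#' @param scaffold scaffold of the deletion.
#' @param a,b deletion interval, 1-based inclusive, normalized and TA-bounded.
#' @param annotation IES annotation table.
#' @return `list(ies_id, klass, left_offset, right_offset, multi_ies)`;
#'   offsets are `NA` for `UNMATCHED`.
#' @export
classify_event <- function(scaffold, a, b, annotation) {
  ann <- as.data.table(annotation)
  sel <- ann[["scaffold"]] == scaffold & ann[["start"]] <= b &
    ann[["end"]] >= a
  cand <- ann[which(sel)]
  if (nrow(cand) == 0L)
    return(list(ies_id = NA_character_, klass = "UNMATCHED",
                left_offset = NA_integer_, right_offset = NA_integer_,
                multi_ies = FALSE))
  ov <- pmin(cand$end, b) - pmax(cand$start, a) + 1L
  best <- which(ov == max(ov))
  pick <- best[which.min(cand$start[best])]
  s <- cand$start[pick]; e <- cand$end[pick]
  cat <- boundary_category(NULL, NULL, s, e, a, b)
  list(ies_id = cand$ies_id[pick],
       klass = klass_from_categories(cat$left, cat$right),
       left_offset = as.integer(a - s), right_offset = as.integer(b - e),
       multi_ies = nrow(cand) > 1L)
}

#' Collapse junction evidence into distinct excision events
#'
#' One event per distinct `(scaffold, a, b)` deletion among `IES_MINUS` and
#' `ALT_DELETION` evidence, with aggregated read support and the error class
#' from [classify_event()].
#'
#' @param evidences evidence table from [classify_reads()].
#' @param annotation IES annotation table.
#' @return `data.table(scaffold, a, b, read_count, ies_id, klass,
#'   left_offset, right_offset, multi_ies)`, one row per junction.
#' @export
collapse_events <- function(evidences, annotation) {
  ev <- as.data.table(evidences)
  ev <- ev[ev$kind %in% c("IES_MINUS", "ALT_DELETION")]
  if (nrow(ev) == 0L)
    return(data.table(scaffold = character(), a = integer(), b = integer(),
                      read_count = integer(), ies_id = character(),
                      klass = character(), left_offset = integer(),
                      right_offset = integer(), multi_ies = logical()))
  agg <- ev[, .(read_count = .N), by = .(scaffold, a, b)]
  cls <- lapply(seq_len(nrow(agg)), function(i)
    classify_event(agg$scaffold[i], agg$a[i], agg$b[i], annotation))
  agg[, `:=`(ies_id = vapply(cls, `[[`, character(1), "ies_id"),
             klass = vapply(cls, `[[`, character(1), "klass"),
             left_offset = vapply(cls, `[[`, integer(1), "left_offset"),
             right_offset = vapply(cls, `[[`, integer(1), "right_offset"),
             multi_ies = vapply(cls, `[[`, logical(1), "multi_ies"))]
  setorder(agg, scaffold, a, b)
  agg[]
}

#' De novo excision errors by parental subtraction
#'
#' Error junctions present in the autogamous sample but absent from the
#' parental vegetative sample, keyed by the normalized `(scaffold, a, b)`
#' interval. Each junction counts once. The rate is normalized per million
#' mapped reads.
#'
#' @param auto_events,parental_events event tables from [collapse_events()];
#'   only non-`CORRECT` rows are considered errors.
#' @param total_mapped_reads total reads mapped in the autogamous sample.
#' @return `list(events, count, per_million)`.
#' @export
de_novo_errors <- function(auto_events, parental_events, total_mapped_reads) {
  check_that(total_mapped_reads > 0, "undefined rate: total_mapped_reads is 0")
  au <- as.data.table(auto_events)[klass != "CORRECT"]
  pa <- as.data.table(parental_events)[klass != "CORRECT"]
  keyp <- paste(pa$scaffold, pa$a, pa$b)
  keep <- !(paste(au$scaffold, au$a, au$b) %in% keyp)
  dn <- au[keep]
  list(events = dn, count = nrow(dn),
       per_million = nrow(dn) / total_mapped_reads * 1e6)
}

#' Fraction of excision reads supporting erroneous junctions
#'
#' @param events event table from [collapse_events()].
#' @return proportion of excision-read support on non-`CORRECT` junctions
#'   (0 when there are no events).
#' @export
error_read_fraction <- function(events) {
  ev <- as.data.table(events)
  tot <- sum(ev$read_count)
  if (tot == 0L) return(0)
  sum(ev$read_count[ev$klass != "CORRECT"]) / tot
}

#' Boundary-shift spectrum of partial internal errors
#'
#' Histogram of the absolute alternative-boundary shift (TA-start to
#' TA-start) over `PARTIAL_INTERNAL` events, excluding shifts
#' `<= min_shift - 1` bp (alternative boundaries within 2 bp of the canonical
#' one are indistinguishable from junction micro-heterogeneity and are not
#' counted, by default).
#'
#' @param events event table from [collapse_events()].
#' @param min_shift smallest shift counted (default 3).
#' @return `list(counts, mode)`: `counts` is a named integer vector
#'   (shift -> junction count); `mode` the modal shift (smallest on ties,
#'   `NA` if empty).
#' @export
shift_spectrum <- function(events, min_shift = 3L) {
  ev <- as.data.table(events)[klass == "PARTIAL_INTERNAL"]
  sh <- pmax(abs(ev$left_offset), abs(ev$right_offset))
  sh <- sh[sh >= min_shift]
  if (length(sh) == 0L)
    return(list(counts = integer(0), mode = NA_integer_))
  tab <- table(sh)
  counts <- setNames(as.integer(tab), names(tab))
  list(counts = counts,
       mode = as.integer(names(counts)[which.max(counts)]))
}

#' Fraction of IESs with at least one error, stratified by IRS
#'
#' Mirrors the error-prone-IES analysis: among the IESs of each IRS stratum,
#' the fraction carrying at least one classified error junction. The
#' `fully_excised` stratum is `irs < 0.025`; the remaining defined-IRS IESs
#' are binned by quarters of the IRS range.
#'
#' @param results retention table from [call_significance()] (or any table
#'   with `ies_id`, `irs`, `fully_excised`).
#' @param events event table from [collapse_events()].
#' @return `data.table(stratum, n_ies, n_with_error, fraction)`.
#' @export
error_prone_fraction <- function(results, events) {
  res <- copy(as.data.table(results))
  ev <- as.data.table(events)
  err_ids <- unique(ev$ies_id[!is.na(ev$ies_id) & ev$klass != "CORRECT"])
  res[, stratum := ifelse(is.na(irs), "undefined",
                   ifelse(fully_excised, "fully_excised",
                          as.character(cut(irs, c(0, 0.25, 0.5, 0.75, 1),
                                           include.lowest = TRUE))))]
  res[, has_error := ies_id %in% err_ids]
  out <- res[, .(n_ies = .N, n_with_error = sum(has_error),
                 fraction = mean(has_error)), by = stratum]
  setorder(out, stratum)
  out[]
}
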