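# IES retention scores.
#
# A boundary score is the retained fraction plus/(plus+minus) at one IES
# boundary; the IES retention score (IRS) is the mean of the two boundary
# scores. An IES_MINUS read attests excision at *both* boundaries and is
# counted into the minus tally of each side.

#' Tally per-boundary read support
#'
#' @param evidences evidence table from [classify_reads()].
#' @param annotation IES annotation (used so that covered-but-silent IESs
#'   appear with zero counts); optional.
#' @return `data.table(ies_id, side, plus_count, minus_count)` with
#'   `side %in% c("left", "right")`.
#' @export
tally_boundaries <- function(evidences, annotation = NULL) {
  ev <- as.data.table(evidences)
  ids <- if (!is.null(annotation)) as.data.table(annotation)$ies_id else
    sort(unique(ev$ies_id[!is.na(ev$ies_id)]))
  if (!is.null(annotation) && nrow(ev)) {
    bad <- setdiff(ev$ies_id[!is.na(ev$ies_id)], ids)
    check_that(length(bad) == 0L,
               paste("input error: evidence references unknown ies_id:",
                     paste(head(bad), collapse = ", ")))
  }
  base <- CJ(ies_id = ids, side = c("left", "right"))
  if (nrow(ev) == 0L || length(ids) == 0L) {
    base[, `:=`(plus_count = 0L, minus_count = 0L)]
    return(base[])
  }
  plus <- rbind(
    ev[kind == "IES_PLUS_LEFT", .(ies_id, side = "left")],
    ev[kind == "IES_PLUS_RIGHT", .(ies_id, side = "right")])
  plus <- plus[, .(plus_count = .N), by = .(ies_id, side)]
  minus <- ev[kind == "IES_MINUS",
              .(ies_id = rep(ies_id, 2L),
                side = rep(c("left", "right"), each = .N))]
  minus <- minus[, .(minus_count = .N), by = .(ies_id, side)]
  out <- merge(merge(base, plus, by = c("ies_id", "side"), all.x = TRUE),
               minus, by = c("ies_id", "side"), all.x = TRUE)
  out[is.na(plus_count), plus_count := 0L]
  out[is.na(minus_count), minus_count := 0L]
  out[]
}

#' Per-boundary retention score
#'
#' `plus / (plus + minus)`; `NA` (undefined) when the boundary is uncovered.
#'
#' @param plus,minus non-negative read counts (vectorized).
#' @return numeric score in `[0, 1]`, or `NA` where `plus + minus == 0`.
#' @export
boundary_score <- function(plus, minus) {
  check_that(all(plus >= 0) && all(minus >= 0), "counts must be >= 0")
  tot <- plus + minus
  ifelse(tot == 0, NA_real_, plus / tot)
}

#' IES retention score (IRS)
#'
#' Mean of the defined boundary scores; a single defined side carries the
#' score alone; `NA` if both sides are undefined.
#'
#' @param left_score,right_score per-boundary scores (vectorized, may be `NA`).
#' @return numeric IRS in `[0, 1]` or `NA`.
#' @export
retention_score <- function(left_score, right_score) {
  both <- cbind(left_score, right_score)
  rowMeans(both, na.rm = TRUE) * ifelse(rowSums(!is.na(both)) == 0, NA, 1)
}

#' Call significantly retained IESs against a control sample
#'
#' Each boundary's `(plus, minus)` counts are compared to the matched control
#' boundary with a one-sided Fisher exact test for *elevated* retention in
#' the sample, computed as the hypergeometric tail. P-values are
#' Benjamini-Hochberg adjusted across all boundaries of all IESs. An IES is
#' `significantly_retained` when at least one boundary has `q <= alpha`
#' (`policy = "either"`, the default) or when both do (`policy = "both"`);
#' IESs that fail the test form the excised set. `fully_excised` flags
#' `irs < fully_excised_max` (0.025 by default, the lowest IRS histogram bin).
#'
#' Because samples may contain variable amounts of old-MAC DNA, absolute IRS
#' values are not comparable across experiments; the returned table carries a
#' `caveat` attribute restating this.
#'
#' @param sample,control boundary tallies from [tally_boundaries()] with
#'   matching `ies_id`/`side` rows.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param policy `"either"` or `"both"` boundary significance rule.
#' @param fully_excised_max IRS threshold for the fully-excised flag.
#' @return `data.table(ies_id, left_score, right_score, irs, p_left, p_right,
#'   q_left, q_right, significantly_retained, fully_excised)`.
#' @export
call_significance <- function(sample, control, alpha = 0.05,
                              policy = c("either", "both"),
                              fully_excised_max = 0.025) {
  policy <- match.arg(policy)
  s <- as.data.table(sample); ctl <- as.data.table(control)
  if (nrow(s) == 0L) {
    out <- data.table(ies_id = character(), left_score = numeric(),
                      right_score = numeric(), irs = numeric(),
                      p_left = numeric(), p_right = numeric(),
                      q_left = numeric(), q_right = numeric(),
                      significantly_retained = logical(),
                      fully_excised = logical())
    return(out)
  }
  m <- merge(s, ctl, by = c("ies_id", "side"), suffixes = c("", "_ctl"))
  check_that(nrow(m) == nrow(s),
             "sample and control boundaries do not match")
  # one-sided Fisher exact (hypergeometric upper tail) for sample plus-excess
  m[, p := phyper(plus_count - 1L, plus_count + plus_count_ctl,
                  minus_count + minus_count_ctl,
                  plus_count + minus_count, lower.tail = FALSE)]
  m[plus_count + minus_count == 0L, p := 1]
  m[, q := p.adjust(p, method = "BH")]
  m[, score := boundary_score(plus_count, minus_count)]
  wide <- dcast(m, ies_id ~ side, value.var = c("score", "p", "q"))
  setnames(wide, c("score_left", "score_right", "p_left", "p_right",
                   "q_left", "q_right"),
           c("left_score", "right_score", "p_left", "p_right",
             "q_left", "q_right"), skip_absent = TRUE)
  wide[, irs := retention_score(left_score, right_score)]
  sig_l <- !is.na(wide$q_left) & wide$q_left <= alpha &
    !is.na(wide$left_score) & wide$left_score > 0
  sig_r <- !is.na(wide$q_right) & wide$q_right <= alpha &
    !is.na(wide$right_score) & wide$right_score > 0
  wide[, significantly_retained := if (policy == "either") sig_l | sig_r else
    sig_l & sig_r]
  wide[, fully_excised := !is.na(irs) & irs < fully_excised_max]
  out <- wide[, .(ies_id, left_score, right_score, irs, p_left, p_right,
                  q_left, q_right, significantly_retained, fully_excised)]
  setattr(out, "caveat",
          "IRS values are relative: old-MAC contamination makes absolute retention incomparable across experiments")
  out[]
}
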