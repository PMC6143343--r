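#' IES length model
#'
#' *Paramecium* IES lengths follow a sinusoid-shaped distribution with a
#' periodicity close to the helical pitch of B-DNA (~10 bp), a hard minimum of
#' 26 bp, and a depleted ("forbidden") second peak at 36-37 bp. The model is a
#' mixture of Gaussian peaks centred at `min_len + k * period` (k = 0, 1, ...),
#' truncated to `[min_len, max_len]` and rounded to integer base pairs.
#'
#' Default peak weights put most mass on the first peak, nearly none on the
#' 36-37 bp peak, and decaying mass on later peaks, emulating the genome-wide
#' distribution in which 93% of IESs are shorter than 150 bp.
#'
#' @param min_len minimum IES length in bp (default 26; includes one TA copy).
#' @param period peak spacing in bp (default 10.2, one helical turn).
#' @param peak_weights non-negative mixture weights, one per peak; peak `k`
#'   (1-based element `k+1`) is centred at `min_len + k * period`.
#' @param peak_sd within-peak standard deviation in bp.
#' @param max_len maximum sampled length in bp.
#' @return an object of class `length_model`.
#' @examples
#' m <- length_model()
#' summary(sample_ies_length(m, 100))
#' @export
length_model <- function(min_len = 26L, period = 10.2,
                         peak_weights = c(0.30, 0.01, 0.23, 0.20, 0.15, 0.11),
                         peak_sd = 1.0, max_len = 150L) {
  check_that(min_len >= 16L, "min_len must be >= 16 (room for two end octamers)")
  check_that(period > 0, "period must be positive")
  check_that(length(peak_weights) >= 1L && all(peak_weights >= 0),
             "peak_weights must be non-negative")
  check_that(sum(peak_weights) > 0, "invalid model: all peak weights are zero")
  check_that(max_len >= min_len, "max_len must be >= min_len")
  structure(list(min_len = as.integer(min_len), period = period,
                 peak_weights = peak_weights / sum(peak_weights),
                 peak_sd = peak_sd, max_len = as.integer(max_len)),
            class = "length_model")
}

#' Sample IES lengths from a length model
#'
#' Draws integer lengths from the peak mixture of a [length_model()].
#' Draws are truncated by resampling so that every length lies in
#' `[min_len, max_len]`.
#'
#' @param model a [length_model()].
#' @param n number of lengths to draw.
#' @return integer vector of `n` lengths, all `>= model$min_len`.
#' @export
sample_ies_length <- function(model, n = 1L) {
  stopifnot(inherits(model, "length_model"))
  if (n == 0L) return(integer(0))
  centers <- model$min_len + (seq_along(model$peak_weights) - 1L) * model$period
  out <- integer(0)
  guard <- 0L
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    k <- sample.int(length(centers), m, replace = TRUE, prob = model$peak_weights)
    x <- as.integer(round(rnorm(m, mean = centers[k], sd = model$peak_sd)))
    x <- x[x >= model$min_len & x <= model$max_len]
    out <- c(out, x)
    guard <- guard + 1L
    check_that(guard < 1000L, "length model rejects all draws; widen max_len")
  }
  out[seq_len(n)]
}
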