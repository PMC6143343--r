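# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA of length n; AT-richness mirrors the ~72% AT Paramecium genome
random_dna <- function(n, gc = 0.28) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# positions (1-based, start of dinucleotide) of "TA" occurrences in a string
ta_sites <- function(seq) {
  m <- gregexpr("(?=TA)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# assert-like input check with a stage-named error
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# deterministic child seed (< 2^31) derived from a user seed and a tag
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
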