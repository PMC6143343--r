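# Paired germline/somatic genome construction.
#
# Construction guarantees, by design rather than by post-hoc checking:
#   * every IES starts with "TA" and is followed by a second "TA" copy, so
#     excision leaves a single TA at the junction;
#   * excising all annotated intervals from the germline reproduces the
#     somatic scaffold byte-for-byte;
#   * end octamers are drawn from the degenerate 5'-TAYAGYNR-3' consensus
#     (read TA-inward on each strand) at a configurable fidelity.

IUPAC_SETS <- list(Y = c("C", "T"), R = c("A", "G"), N = c("A", "C", "G", "T"))

# one octamer per row, consensus TAYAGYNR with per-position fidelity
sample_octamers <- function(n, fidelity, gc = 0.28) {
  cons <- list("T", "A", IUPAC_SETS$Y, "A", "G", IUPAC_SETS$Y, IUPAC_SETS$N,
               IUPAC_SETS$R)
  bases <- c("A", "C", "G", "T")
  bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  cols <- lapply(seq_len(8L), function(j) {
    if (j <= 2L) return(rep(cons[[j]][1], n))  # boundary TA is invariant
    from_cons <- runif(n) < fidelity
    out <- sample(bases, n, replace = TRUE, prob = bg)
    out[from_cons] <- sample(cons[[j]], sum(from_cons), replace = TRUE)
    out
  })
  do.call(paste0, cols)
}

# spaced insertion sites: n sorted positions in [margin, len-margin] with
# pairwise gaps >= gap
spaced_sites <- function(len, n, gap, margin) {
  if (n == 0L) return(integer(0))
  slack <- (len - 2L * margin) - (n - 1L) * gap
  check_that(slack >= 0L,
             "placement error: not enough scaffold space for requested IESs")
  u <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  as.integer(margin + u + (seq_len(n) - 1L) * gap)
}

plant_ta <- function(seqs, scaf, pos) {
  substr(seqs[[scaf]], pos, pos + 1L) <- "TA"
  seqs
}

#' Generate a paired germline/somatic genome with annotated IESs
#'
#' Builds random AT-rich somatic scaffolds, then inserts `n_ies` TA-bounded
#' IESs to obtain the germline ("MAC+IES") reference. Each insertion happens
#' immediately 5' of a TA dinucleotide on the somatic scaffold, and the IES
#' itself begins with TA, so the germline carries a TA direct repeat of which
#' exactly one copy remains after excision. For every IES an *alternative*
#' erroneous junction is also planned (class drawn from
#' `cfg$error_class_mix`, boundary shifts from `cfg$shift_mod`); where the
#' required alternative TA does not occur naturally it is created by local
#' substitution (applied consistently to both references when it falls in
#' flanking DNA) and flagged in the annotation. Alternative junctions are only
#' planned when the configuration can use them (`error_rate > 0` or
#' `parental_error_junctions > 0`).
#'
#' @param cfg a [sim_config()].
#' @param model a [length_model()].
#' @return an object of class `ies_genomes`: a list with `germline` and
#'   `somatic` (named character vectors of scaffold sequences) and `ies`, a
#'   `data.table` with columns `ies_id, scaffold, start, end, length,
#'   somatic_pos, alt_start, alt_end, alt_class, alt_left_offset,
#'   alt_right_offset, ta_planted`. Coordinates are 1-based inclusive on the
#'   germline; `somatic_pos` is the 1-based somatic position of the retained
#'   TA.
#' @examples
#' g <- generate_genomes(sim_config(n_scaffolds = 1, scaffold_len = 2000,
#'                                  n_ies = 5, seed = 7), length_model())
#' g$ies
#' @export
generate_genomes <- function(cfg = sim_config(), model = length_model()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(model, "length_model"))
  set.seed(child_seed(cfg$seed, "genomes"))
  margin <- max(cfg$min_gap, 60L)
  gap <- cfg$min_gap
  per_scaf <- rep(cfg$n_ies %/% cfg$n_scaffolds, cfg$n_scaffolds)
  extra <- cfg$n_ies %% cfg$n_scaffolds
  if (extra > 0L) per_scaf[seq_len(extra)] <- per_scaf[seq_len(extra)] + 1L

  somatic <- setNames(vapply(seq_len(cfg$n_scaffolds), function(i)
    random_dna(cfg$scaffold_len, cfg$gc), character(1)),
    sprintf("scaffold_%02d", seq_len(cfg$n_scaffolds)))
  germline <- somatic
  rows <- vector("list", cfg$n_scaffolds)
  plan_errors <- cfg$error_rate > 0 || cfg$parental_error_junctions > 0L

  idx0 <- 0L
  for (sc in seq_len(cfg$n_scaffolds)) {
    n <- per_scaf[sc]
    if (n == 0L) { rows[[sc]] <- NULL; next }
    sites <- spaced_sites(cfg$scaffold_len, n, gap, margin)
    for (t in sites) somatic <- plant_ta(somatic, sc, t)
    lens <- sample_ies_length(model, n)
    left_oct <- sample_octamers(n, cfg$consensus_fidelity, cfg$gc)
    right_oct <- sample_octamers(n, cfg$consensus_fidelity, cfg$gc)
    right_hex <- revcomp(substr(right_oct, 3L, 8L))
    cores <- vapply(lens - 14L, random_dna, character(1), gc = cfg$gc)
    ies_seq <- paste0(left_oct, cores, right_hex)

    # assemble germline scaffold and 1-based IES coordinates
    soma <- somatic[[sc]]
    pieces <- character(2L * n + 1L)
    prev <- 1L
    starts <- integer(n); offs <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- substr(soma, prev, sites[i] - 1L)
      pieces[2L * i] <- ies_seq[i]
      starts[i] <- sites[i] + offs
      offs <- offs + lens[i]
      prev <- sites[i]
    }
    pieces[2L * n + 1L] <- substr(soma, prev, nchar(soma))
    germline[[sc]] <- paste(pieces, collapse = "")
    ends <- starts + lens - 1L

    dt <- data.table(
      ies_id = sprintf("IES.%s.%04d", names(somatic)[sc], idx0 + seq_len(n)),
      scaffold = names(somatic)[sc], start = starts, end = ends,
      length = lens, somatic_pos = sites,
      alt_start = NA_integer_, alt_end = NA_integer_,
      alt_class = NA_character_,
      alt_left_offset = NA_integer_, alt_right_offset = NA_integer_,
      ta_planted = FALSE)

    if (plan_errors) {
      classes <- sample(names(cfg$error_class_mix), n, replace = TRUE,
                        prob = cfg$error_class_mix)
      for (i in seq_len(n)) {
        plan <- plan_alt_junction(classes[i], starts[i], ends[i], lens[i],
                                  cfg$shift_mod)
        if (is.null(plan)) next
        dt$alt_start[i] <- plan$a; dt$alt_end[i] <- plan$b
        dt$alt_class[i] <- classes[i]
        dt$alt_left_offset[i] <- plan$a - starts[i]
        dt$alt_right_offset[i] <- plan$b - ends[i]
        # ensure TA at both alternative boundaries
        for (p in plan$ta_needed) {
          if (substr(germline[[sc]], p, p + 1L) != "TA") {
            dt$ta_planted[i] <- TRUE
            germline <- plant_ta(germline, sc, p)
            if (p > ends[i] + 2L) {           # right flank: shared with somatic
              somatic <- plant_ta(somatic, sc, p - offs_at(starts, lens, p))
            } else if (p < starts[i]) {       # left flank
              somatic <- plant_ta(somatic, sc, p - offs_before(starts, lens, p))
            }
          }
        }
      }
    }
    rows[[sc]] <- dt
    idx0 <- idx0 + n
  }

  ies <- rbindlist(rows)
  if (nrow(ies) == 0L)
    ies <- data.table(ies_id = character(), scaffold = character(),
                      start = integer(), end = integer(), length = integer(),
                      somatic_pos = integer(), alt_start = integer(),
                      alt_end = integer(), alt_class = character(),
                      alt_left_offset = integer(), alt_right_offset = integer(),
                      ta_planted = logical())
  structure(list(germline = germline, somatic = somatic, ies = ies,
                 cfg = cfg, model = model),
            class = "ies_genomes")
}

# cumulative inserted length strictly before germline position p
offs_before <- function(starts, lens, p) {
  sum(lens[starts + lens - 1L < p])
}
offs_at <- function(starts, lens, p) offs_before(starts, lens, p)

# Alternative-junction geometry. Canonical IES [s, e] (1-based inclusive,
# TA at s..s+1 and e+1..e+2). The alternative deletion [a, b] must carry TA
# at a..a+1 and b+1..b+2. Internal alternative boundaries keep >= 3 bp away
# from the canonical ones so every planted error survives the > 2 bp shift
# filter of the spectrum analysis. Returns NULL if the IES is too short for
# the requested class.
plan_alt_junction <- function(klass, s, e, len, shift_mod, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    d1 <- sample_shift(shift_mod); d2 <- sample_shift(shift_mod)
    res <- switch(klass,
      PARTIAL_INTERNAL = {
        if (runif(1) < 0.5 && d1 <= len - 4L)       # left canonical
          list(a = s, b = e - d1, ta_needed = e - d1 + 1L)
        else if (d1 <= len - 4L)                    # right canonical
          list(a = s + d1, b = e, ta_needed = s + d1)
        else NULL
      },
      PARTIAL_EXTERNAL = {
        if (runif(1) < 0.5) list(a = s, b = e + d1, ta_needed = e + d1 + 1L)
        else list(a = s - d1, b = e, ta_needed = s - d1)
      },
      INTERNAL = {
        if (d1 + d2 <= len - 6L)
          list(a = s + d1, b = e - d2,
               ta_needed = c(s + d1, e - d2 + 1L))
        else NULL
      },
      EXTERNAL = list(a = s - d1, b = e + d2,
                      ta_needed = c(s - d1, e + d2 + 1L)),
      OVERLAPPING = {
        if (runif(1) < 0.5) {
          if (d1 <= len - 4L)
            list(a = s + d1, b = e + d2,
                 ta_needed = c(s + d1, e + d2 + 1L))
          else NULL
        } else {
          if (d2 <= len - 4L)
            list(a = s - d1, b = e - d2,
                 ta_needed = c(s - d1, e - d2 + 1L))
          else NULL
        }
      },
      stop("unknown error class: ", klass))
    if (!is.null(res) && res$b - res$a >= 1L) return(res)
  }
  NULL
}

#' Excise annotated IES intervals from a germline genome
#'
#' Removes every annotated interval `[start, end]` from its germline scaffold,
#' leaving the downstream TA copy in place. On a consistent annotation this
#' reproduces the somatic genome exactly (the package's round-trip invariant).
#'
#' @param germline named character vector of germline scaffold sequences.
#' @param ies IES annotation table with columns `scaffold`, `start`, `end`.
#' @return named character vector of excised (somatic) scaffolds.
#' @export
excise_intervals <- function(germline, ies) {
  ies <- as.data.table(ies)
  out <- germline
  for (sc in names(germline)) {
    tab <- ies[ies$scaffold == sc]
    if (nrow(tab) == 0L) next
    setorder(tab, start)
    keep_from <- c(1L, tab$end + 1L)
    keep_to <- c(tab$start - 1L, nchar(germline[[sc]]))
    out[[sc]] <- paste(substring(germline[[sc]], keep_from, keep_to),
                       collapse = "")
  }
  out
}
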