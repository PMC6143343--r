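#' Boundary-shift model for erroneous excision
#'
#' Distribution of the distance (in bp, TA-start to TA-start) between an
#' alternative excision boundary and the canonical one. The dominant mode is
#' 10-11 bp -- one helical turn -- with a minority of shifts spread uniformly
#' over a wider window.
#'
#' @param modal_shifts integer vector of preferred shifts (default `c(10, 11)`).
#' @param modal_prob probability that a shift is drawn from `modal_shifts`.
#' @param range inclusive range of the uniform background component.
#' @return an object of class `shift_model`.
#' @export
shift_model <- function(modal_shifts = c(10L, 11L), modal_prob = 0.8,
                        range = c(3L, 20L)) {
  check_that(modal_prob >= 0 && modal_prob <= 1, "modal_prob must be in [0,1]")
  check_that(all(modal_shifts >= 1L), "shifts must be >= 1 bp")
  check_that(range[1] >= 1L && range[2] >= range[1], "invalid shift range")
  structure(list(modal_shifts = as.integer(modal_shifts),
                 modal_prob = modal_prob,
                 range = as.integer(range)),
            class = "shift_model")
}

sample_shift <- function(model, n = 1L) {
  use_mode <- runif(n) < model$modal_prob
  out <- integer(n)
  out[use_mode] <- model$modal_shifts[
    sample.int(length(model$modal_shifts), sum(use_mode), replace = TRUE)]
  out[!use_mode] <- sample(seq(model$range[1], model$range[2]),
                           sum(!use_mode), replace = TRUE)
  out
}

#' Error classes of TA-to-TA excision
#'
#' Taxonomy of erroneous excision events relative to a reference IES
#' `[s, e]`: `PARTIAL_INTERNAL` / `PARTIAL_EXTERNAL` keep one canonical
#' boundary and move the other inside / outside the IES; `INTERNAL` /
#' `EXTERNAL` move both boundaries inside / outside; `OVERLAPPING` uses one
#' internal and one external TA, neither canonical. `CORRECT` is canonical
#' excision and `UNMATCHED` a TA-bounded deletion overlapping no IES.
#'
#' @export
ERROR_CLASSES <- c("PARTIAL_INTERNAL", "PARTIAL_EXTERNAL",
                   "INTERNAL", "EXTERNAL", "OVERLAPPING")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' desk-scale caricature of a *Paramecium* autogamy sequencing experiment:
#' ~100x coverage with 100 nt single-end reads, a partially inhibited
#' excision machinery (uniform retention probability), a small fraction of
#' excision events using an erroneous TA-bounded junction, contamination of
#' the sample by old-MAC (fully rearranged) fragments, and a parental
#' vegetative sample carrying a handful of pre-existing errors.
#'
#' @param n_scaffolds number of somatic scaffolds.
#' @param scaffold_len somatic scaffold length in bp.
#' @param n_ies total number of IESs to plant (spread across scaffolds).
#' @param read_len read length in nt (single-end).
#' @param coverage mean sequencing depth over the germline genome.
#' @param retention_prob probability that a molecule retains a given IES;
#'   either a scalar or a vector of length `n_ies` (per-IES probabilities).
#' @param error_rate probability that an excising molecule uses the planted
#'   erroneous junction instead of the canonical one.
#' @param error_class_mix named numeric distribution over [ERROR_CLASSES];
#'   must sum to 1.
#' @param shift_mod a [shift_model()] for alternative-boundary offsets.
#' @param old_mac_fraction proportion of sample reads drawn from the parental
#'   (fully excised) MAC, emulating old-MAC contamination.
#' @param parental_error_junctions number of IESs given a pre-existing
#'   erroneous junction observable in the parental vegetative sample.
#' @param parental_error_mol_frac fraction of parental molecules carrying each
#'   pre-existing error.
#' @param consensus_fidelity probability that each degenerate position of the
#'   TAYAGYNR end octamer is drawn from the consensus alphabet rather than
#'   uniformly.
#' @param n_molecules size of the simulated molecule pool per scaffold from
#'   which reads are drawn (new-MAC pool; the parental pool has the same size).
#' @param substitution_rate per-base uniform sequencing-error rate (default 0:
#'   the analysis depends on junction content, not base quality).
#' @param gc GC content of simulated DNA (Paramecium is AT-rich).
#' @param min_gap minimum spacing between IES insertion sites on a scaffold.
#' @param seed integer RNG seed; mandatory for reproducible simulation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 2L, scaffold_len = 10000L, n_ies = 40L,
                       read_len = 100L, coverage = 100,
                       retention_prob = 0.5, error_rate = 0.03,
                       error_class_mix = c(PARTIAL_INTERNAL = 0.5,
                                           PARTIAL_EXTERNAL = 0.1,
                                           INTERNAL = 0.15,
                                           EXTERNAL = 0.15,
                                           OVERLAPPING = 0.1),
                       shift_mod = shift_model(),
                       old_mac_fraction = 0.1,
                       parental_error_junctions = 5L,
                       parental_error_mol_frac = 0.2,
                       consensus_fidelity = 0.85,
                       n_molecules = 100L,
                       substitution_rate = 0,
                       gc = 0.28, min_gap = 80L, seed = 1L) {
  probs <- c(retention_prob, error_rate, old_mac_fraction,
             parental_error_mol_frac, consensus_fidelity, substitution_rate)
  check_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  check_that(length(retention_prob) %in% c(1L, n_ies),
             "retention_prob must be scalar or length n_ies")
  check_that(abs(sum(error_class_mix) - 1) < 1e-8, "error_class_mix must sum to 1")
  check_that(all(names(error_class_mix) %in% ERROR_CLASSES),
             "unknown error class in error_class_mix")
  check_that(inherits(shift_mod, "shift_model"), "shift_mod must be a shift_model")
  check_that(n_ies >= 0L && n_scaffolds >= 1L, "bad scaffold/IES counts")
  check_that(read_len >= 24L, "read_len must allow two 12 bp anchors")
  parental_error_junctions <- min(parental_error_junctions, n_ies)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_len = as.integer(scaffold_len),
                 n_ies = as.integer(n_ies), read_len = as.integer(read_len),
                 coverage = coverage, retention_prob = retention_prob,
                 error_rate = error_rate, error_class_mix = error_class_mix,
                 shift_mod = shift_mod, old_mac_fraction = old_mac_fraction,
                 parental_error_junctions = as.integer(parental_error_junctions),
                 parental_error_mol_frac = parental_error_mol_frac,
                 consensus_fidelity = consensus_fidelity,
                 n_molecules = as.integer(n_molecules),
                 substitution_rate = substitution_rate,
                 gc = gc, min_gap = as.integer(min_gap),
                 seed = as.integer(seed)),
            class = "sim_config")
}
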