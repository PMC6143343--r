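# Molecule-pool read simulation.
#
# Each scaffold gives rise to a pool of new-MAC molecules in which every IES
# independently realizes one of three outcomes: retained, correctly excised,
# or erroneously excised through its planted alternative TA-bounded junction.
# A second, parental pool represents the old (vegetative) MAC: fully excised
# except for a configurable set of pre-existing erroneous junctions. Reads
# are fixed-length windows drawn uniformly from molecules; old-MAC
# contamination draws sample reads from the parental pool.

# delete a set of disjoint intervals [from, to] (1-based incl.) from a string
splice_out <- function(seq, from, to) {
  if (length(from) == 0L) return(seq)
  o <- order(from)
  from <- from[o]; to <- to[o]
  paste(substring(seq, c(1L, to + 1L), c(from - 1L, nchar(seq))), collapse = "")
}

build_pool <- function(germ, tab, n_mol, outcome_fun) {
  # outcome_fun(n_mol, n_ies) -> matrix of "R"/"C"/"E"
  n_ies <- nrow(tab)
  out <- outcome_fun(n_mol, n_ies)
  seqs <- character(n_mol)
  for (m in seq_len(n_mol)) {
    oc <- out[m, ]
    cut <- oc != "R"
    from <- ifelse(oc == "E", tab$alt_start, tab$start)[cut]
    to <- ifelse(oc == "E", tab$alt_end, tab$end)[cut]
    seqs[m] <- splice_out(germ, from, to)
  }
  list(seqs = seqs, outcomes = out)
}

draw_windows <- function(pool_seqs, n_reads, read_len) {
  lens <- nchar(pool_seqs)
  check_that(all(lens >= read_len), "config error: read_len exceeds molecule length")
  mol <- sample.int(length(pool_seqs), n_reads, replace = TRUE)
  start <- floor(runif(n_reads) * (lens[mol] - read_len + 1L)) + 1L
  list(mol = mol, start = start,
       seq = substring(pool_seqs[mol], start, start + read_len - 1L))
}

add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    for (p in hit) substr(s, p, p) <- sample(bases, 1L)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate sequencing reads and ground truth from a genome pair
#'
#' Draws single-end reads from molecule pools built on the germline reference
#' (see the package help page for the molecule model). Two read sets are
#' produced: the autogamous *sample* (new-MAC molecules plus an
#' `old_mac_fraction` of reads from the parental pool) and the *parental*
#' vegetative sample (parental pool only, carrying the planted pre-existing
#' errors). Reads are error-free unless `cfg$substitution_rate > 0`.
#'
#' @param genomes an `ies_genomes` object from [generate_genomes()].
#' @param cfg a [sim_config()]; defaults to the one stored in `genomes`.
#' @return a list of class `ies_readsim` with elements
#'   \describe{
#'     \item{reads}{`data.table(read_id, seq)` -- the autogamous sample.}
#'     \item{parental_reads}{`data.table(read_id, seq)` -- the parental sample.}
#'     \item{truth}{list: `read_origin` (per-read origin label and molecule),
#'       `ies` (per-IES realized retention fraction and outcome counts in the
#'       new-MAC pool), `events` (planted erroneous junctions actually
#'       realized, with class and offsets), `parental_error_ids`.}
#'   }
#' @export
simulate_reads <- function(genomes, cfg = genomes$cfg) {
  stopifnot(inherits(genomes, "ies_genomes"))
  set.seed(child_seed(cfg$seed, "reads"))
  ies <- genomes$ies
  rp <- cfg$retention_prob
  if (length(rp) == 1L) rp <- rep(rp, nrow(ies))
  ies <- copy(ies)[, ret_p := rp]

  has_alt <- !is.na(ies$alt_start)
  par_ids <- character(0)
  if (cfg$parental_error_junctions > 0L && any(has_alt)) {
    k <- min(cfg$parental_error_junctions, sum(has_alt))
    par_ids <- sample(ies$ies_id[has_alt], k)
  }

  pools_new <- list(); pools_par <- list()
  outc <- list(); outc_par <- list()
  for (sc in names(genomes$germline)) {
    tab <- ies[ies$scaffold == sc]
    germ <- genomes$germline[[sc]]
    n_i <- nrow(tab)
    new_fun <- function(n_mol, n_ies) {
      m <- matrix("C", n_mol, n_ies)
      if (n_ies == 0L) return(m)
      ret <- matrix(runif(n_mol * n_ies) <
                      matrix(tab$ret_p, n_mol, n_ies, byrow = TRUE),
                    n_mol, n_ies)
      err <- matrix(runif(n_mol * n_ies) < cfg$error_rate, n_mol, n_ies) &
        matrix(!is.na(tab$alt_start), n_mol, n_ies, byrow = TRUE)
      m[ret] <- "R"; m[!ret & err] <- "E"
      m
    }
    par_fun <- function(n_mol, n_ies) {
      m <- matrix("C", n_mol, n_ies)
      if (n_ies == 0L) return(m)
      is_par <- tab$ies_id %in% par_ids
      err <- matrix(runif(n_mol * n_ies) < cfg$parental_error_mol_frac,
                    n_mol, n_ies) &
        matrix(is_par, n_mol, n_ies, byrow = TRUE)
      m[err] <- "E"
      m
    }
    pn <- build_pool(germ, tab, cfg$n_molecules, new_fun)
    pp <- build_pool(germ, tab, cfg$n_molecules, par_fun)
    pools_new[[sc]] <- pn$seqs; pools_par[[sc]] <- pp$seqs
    if (n_i > 0L) {
      outc[[sc]] <- data.table(ies_id = rep(tab$ies_id, each = cfg$n_molecules),
                               outcome = as.vector(pn$outcomes))
      outc_par[[sc]] <- data.table(ies_id = rep(tab$ies_id, each = cfg$n_molecules),
                                   outcome = as.vector(pp$outcomes))
    }
  }

  glen <- nchar(genomes$germline)
  n_total <- max(1L, round(cfg$coverage * sum(glen) / cfg$read_len))
  scaf_of <- sample(names(glen), n_total, replace = TRUE, prob = glen / sum(glen))
  is_old <- runif(n_total) < cfg$old_mac_fraction

  seqs <- character(n_total); mols <- integer(n_total)
  for (sc in names(glen)) {
    for (old in c(FALSE, TRUE)) {
      sel <- which(scaf_of == sc & is_old == old)
      if (length(sel) == 0L) next
      w <- draw_windows(if (old) pools_par[[sc]] else pools_new[[sc]],
                        length(sel), cfg$read_len)
      seqs[sel] <- w$seq; mols[sel] <- w$mol
    }
  }
  seqs <- add_substitutions(seqs, cfg$substitution_rate)
  reads <- data.table(read_id = sprintf("samp_%06d", seq_len(n_total)),
                      seq = seqs)
  read_origin <- data.table(read_id = reads$read_id, scaffold = scaf_of,
                            origin = ifelse(is_old, "old_mac", "new_mac"),
                            molecule = mols)

  slen <- nchar(genomes$somatic)
  n_par <- max(1L, round(cfg$coverage * sum(slen) / cfg$read_len))
  pscaf <- sample(names(slen), n_par, replace = TRUE, prob = slen / sum(slen))
  pseqs <- character(n_par); pmols <- integer(n_par)
  for (sc in names(slen)) {
    sel <- which(pscaf == sc)
    if (length(sel) == 0L) next
    w <- draw_windows(pools_par[[sc]], length(sel), cfg$read_len)
    pseqs[sel] <- w$seq; pmols[sel] <- w$mol
  }
  pseqs <- add_substitutions(pseqs, cfg$substitution_rate)
  parental_reads <- data.table(read_id = sprintf("par_%06d", seq_len(n_par)),
                               seq = pseqs)
  par_origin <- data.table(read_id = parental_reads$read_id, scaffold = pscaf,
                           origin = "parental", molecule = pmols)

  oc <- rbindlist(outc)
  truth_ies <- if (nrow(oc) > 0L) {
    s <- oc[, .(n_retained = sum(outcome == "R"),
                n_correct = sum(outcome == "C"),
                n_error = sum(outcome == "E")), by = ies_id]
    s[, realized_retention := n_retained / (n_retained + n_correct + n_error)]
    merge(ies[, .(ies_id, ret_p)], s, by = "ies_id", sort = FALSE)
  } else data.table(ies_id = character(), ret_p = numeric(),
                    n_retained = integer(), n_correct = integer(),
                    n_error = integer(), realized_retention = numeric())

  ocp <- rbindlist(outc_par)
  events <- ies[has_alt & ies_id %in% unique(c(
    if (nrow(oc)) oc[outcome == "E", unique(ies_id)] else character(0),
    if (nrow(ocp)) ocp[outcome == "E", unique(ies_id)] else character(0))),
    .(ies_id, scaffold, alt_start, alt_end, alt_class,
      alt_left_offset, alt_right_offset)]

  structure(list(reads = reads, parental_reads = parental_reads,
                 truth = list(read_origin = rbind(read_origin, par_origin),
                              ies = truth_ies, events = events,
                              parental_error_ids = par_ids)),
            class = "ies_readsim")
}
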