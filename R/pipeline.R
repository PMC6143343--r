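# Stage orchestration: simulate -> map -> retention -> errors -> report.
# Every stage persists plain-text artifacts (FASTA/FASTQ/GFF3/TSV/JSON) into
# out_dir and can be re-run independently from them.

log_msg <- function(level, ...) {
  lv <- getOption("iesim.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 9L)
  if (ranks[[level]] >= ranks[[lv]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(...)))
}

#' Default run configuration
#'
#' Nested list accepted by [run_pipeline()]: `sim` and `model` hold arguments
#' for [sim_config()] / [length_model()]; `control` overrides simulation
#' fields for the control autogamy experiment (an efficient-excision culture
#' on the same genome); `mapper`, `alpha`, `bin_width` and `min_shift`
#' parametrize the downstream stages.
#'
#' @param seed integer seed applied to sample, control and parental
#'   simulations (child seeds are derived per stage).
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = seed,
       sim = list(n_scaffolds = 2L, scaffold_len = 8000L, n_ies = 40L,
                  coverage = 60, retention_prob = 0.5, error_rate = 0.05),
       model = list(),
       control = list(retention_prob = 0.01, error_rate = 0.02),
       mapper = list(k = 12L, min_anchor = 12L),
       alpha = 0.05, bin_width = 0.025, min_shift = 3L)
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return nested configuration list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config(seed = user$seed %||% 1L)
  modifyList(base, user)
}

build_sim_cfg <- function(config, overrides = list(), seed_tag = "sample") {
  args <- modifyList(config$sim %||% list(), overrides)
  args$seed <- child_seed(config$seed, seed_tag)
  if (!is.null(args$error_class_mix)) args$error_class_mix <-
    unlist(args$error_class_mix)
  if (!is.null(args$shift_mod) && !inherits(args$shift_mod, "shift_model"))
    args$shift_mod <- do.call(shift_model, args$shift_mod)
  do.call(sim_config, args)
}

#' Simulation stage
#'
#' Generates the genome pair and three read sets (autogamous sample, control
#' autogamy, parental vegetative) and writes FASTA/FASTQ/GFF3/TSV artifacts.
#'
#' @param config run configuration (see [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return list with `genomes`, `sample`, `control` (both `ies_readsim`).
#' @export
stage_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- do.call(length_model, config$model %||% list())
  cfg <- build_sim_cfg(config, seed_tag = "sample")
  genomes <- generate_genomes(cfg, model)
  log_msg("info", "simulate: ", length(genomes$germline), " scaffolds, ",
          nrow(genomes$ies), " IESs")
  sample_sim <- simulate_reads(genomes, cfg)
  ctl_cfg <- build_sim_cfg(config, config$control %||% list(), "control")
  control_sim <- simulate_reads(genomes, ctl_cfg)
  log_msg("info", "simulate: sample ", nrow(sample_sim$reads),
          " reads, control ", nrow(control_sim$reads),
          " reads, parental ", nrow(sample_sim$parental_reads), " reads")

  write_fasta(genomes$germline, file.path(out_dir, "germline.fasta"))
  write_fasta(genomes$somatic, file.path(out_dir, "somatic.fasta"))
  write_ies_gff3(genomes$ies, file.path(out_dir, "ies.gff3"))
  write_fastq(sample_sim$reads, file.path(out_dir, "sample.fastq"))
  write_fastq(sample_sim$parental_reads, file.path(out_dir, "parental.fastq"))
  write_fastq(control_sim$reads, file.path(out_dir, "control.fastq"))
  write_tsv_meta(sample_sim$truth$ies, file.path(out_dir, "truth_ies.tsv"),
                 list(seed = config$seed, stage = "simulate"))
  write_tsv_meta(sample_sim$truth$events, file.path(out_dir, "truth_events.tsv"),
                 list(seed = config$seed,
                      parental_error_ids =
                        paste(sample_sim$truth$parental_error_ids,
                              collapse = ",")))
  write_tsv_meta(sample_sim$truth$read_origin,
                 file.path(out_dir, "truth_reads.tsv"),
                 list(seed = config$seed))
  list(genomes = genomes, sample = sample_sim, control = control_sim)
}

#' Mapping stage
#'
#' Builds the junction index from the persisted references and classifies the
#' three read sets; writes one evidence TSV per set.
#'
#' @param config run configuration.
#' @param out_dir directory holding the simulation artifacts.
#' @return list of evidence tables (`sample`, `control`, `parental`) and the
#'   `index`.
#' @export
stage_map <- function(config, out_dir) {
  germline <- read_fasta(file.path(out_dir, "germline.fasta"))
  somatic <- read_fasta(file.path(out_dir, "somatic.fasta"))
  ann <- read_ies_gff3(file.path(out_dir, "ies.gff3"))
  mp <- config$mapper %||% list()
  index <- build_index(germline, somatic, ann, k = mp$k %||% 12L,
                       min_anchor = mp$min_anchor %||% 12L)
  out <- list(index = index)
  for (set in c("sample", "control", "parental")) {
    reads <- read_fastq(file.path(out_dir, paste0(set, ".fastq")))
    ev <- classify_reads(reads, index)
    out[[set]] <- ev
    write_tsv_meta(ev, file.path(out_dir, paste0("evidence_", set, ".tsv")),
                   list(n_reads = nrow(reads), k = index$k,
                        min_anchor = index$min_anchor))
    log_msg("info", "map[", set, "]: ", nrow(reads), " reads, ",
            sum(ev$kind != "NONE"), " informative evidences")
  }
  out
}

#' Retention stage
#'
#' Tallies boundary support for sample and control and calls significantly
#' retained IESs; writes `retention.tsv`.
#'
#' @param config run configuration.
#' @param out_dir directory holding evidence tables.
#' @return the retention `data.table`.
#' @export
stage_retention <- function(config, out_dir) {
  ann <- read_ies_gff3(file.path(out_dir, "ies.gff3"))
  ev_s <- read_tsv_meta(file.path(out_dir, "evidence_sample.tsv"))
  ev_c <- read_tsv_meta(file.path(out_dir, "evidence_control.tsv"))
  res <- call_significance(tally_boundaries(ev_s, ann),
                           tally_boundaries(ev_c, ann),
                           alpha = config$alpha %||% 0.05)
  write_tsv_meta(res, file.path(out_dir, "retention.tsv"),
                 list(alpha = config$alpha %||% 0.05,
                      caveat = attr(res, "caveat")))
  log_msg("info", "retention: ", sum(res$significantly_retained),
          " significantly retained / ", nrow(res), " IESs")
  res
}

#' Error stage
#'
#' Collapses excision events for the sample and parental sets, subtracts
#' parental junctions to obtain de novo errors, and writes event tables plus
#' an error summary.
#'
#' @param config run configuration.
#' @param out_dir directory holding evidence tables.
#' @return list: `events`, `parental_events`, `de_novo`, `summary`.
#' @export
stage_errors <- function(config, out_dir) {
  ann <- read_ies_gff3(file.path(out_dir, "ies.gff3"))
  ev_s <- read_tsv_meta(file.path(out_dir, "evidence_sample.tsv"))
  ev_p <- read_tsv_meta(file.path(out_dir, "evidence_parental.tsv"))
  n_mapped <- length(unique(ev_s$read_id[ev_s$kind != "NONE"]))
  events <- collapse_events(ev_s, ann)
  pevents <- collapse_events(ev_p, ann)
  dn <- de_novo_errors(events, pevents, max(n_mapped, 1L))
  spec <- shift_spectrum(dn$events, min_shift = config$min_shift %||% 3L)
  summary <- list(
    total_error_junctions = sum(events$klass != "CORRECT"),
    de_novo_junctions = dn$count,
    de_novo_per_million = dn$per_million,
    error_read_fraction = error_read_fraction(events),
    modal_shift = spec$mode,
    class_distribution = {
      err <- events[events$klass != "CORRECT"]
      if (nrow(err)) as.list(prop.table(table(err$klass))) else list()
    })
  write_tsv_meta(events, file.path(out_dir, "events_sample.tsv"),
                 list(n_mapped = n_mapped))
  write_tsv_meta(pevents, file.path(out_dir, "events_parental.tsv"), list())
  write_tsv_meta(dn$events, file.path(out_dir, "events_de_novo.tsv"),
                 list(per_million = dn$per_million))
  log_msg("info", "errors: ", summary$total_error_junctions,
          " error junctions, ", dn$count, " de novo")
  list(events = events, parental_events = pevents, de_novo = dn,
       summary = summary)
}

#' Report stage
#'
#' Summarizes retention and error results: IRS histogram, excised-vs-retained
#' length contrast, size-peak fractions, shift spectrum, end-motif counts and
#' internal-TA availability. Writes `report.json`.
#'
#' @param config run configuration.
#' @param out_dir directory holding upstream artifacts.
#' @return the report list, invisibly written as JSON.
#' @export
stage_report <- function(config, out_dir) {
  ann <- read_ies_gff3(file.path(out_dir, "ies.gff3"))
  germline <- read_fasta(file.path(out_dir, "germline.fasta"))
  res <- read_tsv_meta(file.path(out_dir, "retention.tsv"))
  events <- read_tsv_meta(file.path(out_dir, "events_sample.tsv"))
  dn <- read_tsv_meta(file.path(out_dir, "events_de_novo.tsv"))

  hist <- irs_histogram(res, bin_width = config$bin_width %||% 0.025)
  excised <- res$ies_id[!res$significantly_retained & !is.na(res$irs)]
  retained <- top_retained(res, length(excised))
  len_of <- setNames(ann$length, ann$ies_id)
  cmp <- if (length(excised) && length(retained))
    compare_lengths(len_of[excised], len_of[retained]) else NULL
  peaks <- size_peak_fractions(len_of[excised], reference = ann$length)
  spec <- shift_spectrum(dn, min_shift = config$min_shift %||% 3L)
  pwm <- end_motif_pwm(ann, germline)
  tap <- if (nrow(ann)) ta_positions(ann, germline,
                                     window = min(20L, min(ann$length)))
         else NULL
  report <- list(
    n_ies = nrow(ann),
    irs_histogram = list(breaks = hist$breaks, counts = hist$counts,
                         n_undefined = hist$n_undefined),
    n_excised = length(excised), n_retained_top = length(retained),
    length_comparison = cmp,
    size_peak_fractions = peaks,
    shift_spectrum = list(counts = as.list(spec$counts), mode = spec$mode),
    end_motif_counts = as.data.frame(pwm),
    ta_positions = tap,
    error_prone = error_prone_fraction(res, events))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  log_msg("info", "report: ", length(excised), " excised IESs; report.json written")
  report
}

#' Run the full pipeline
#'
#' simulate -> map -> retention -> errors -> report, with all intermediate
#' artifacts persisted under `out_dir`. Re-running with the same
#' configuration and seed reproduces every output byte-for-byte.
#'
#' @param config run configuration list (see [default_run_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @param out_dir output directory.
#' @return list with the results of every stage.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("iesim_")) {
  if (is.character(config)) config <- read_run_config(config)
  check_that(!is.null(config$seed), "seed is mandatory for simulate")
  sim <- stage_simulate(config, out_dir)
  map <- stage_map(config, out_dir)
  retention <- stage_retention(config, out_dir)
  errors <- stage_errors(config, out_dir)
  report <- stage_report(config, out_dir)
  invisible(list(sim = sim, map = map, retention = retention, errors = errors,
                 report = report, out_dir = out_dir))
}
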