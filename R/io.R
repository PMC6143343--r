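# Standard-format I/O. FASTA/FASTQ via Biostrings, GFF3 via rtracklayer
# (1-based inclusive on disk, same as the in-memory convention), and plain
# TSV tables with '# key=value' metadata lines so each pipeline stage can be
# re-run from its persisted inputs.

#' Write a named character vector of scaffolds as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads as FASTQ (constant quality)
#' @param reads `data.table(read_id, seq)`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return `data.table(read_id, seq)`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

#' Write an IES annotation as GFF3
#'
#' Intervals are written 1-based inclusive per the GFF3 convention (the
#' in-memory representation uses the same convention, so coordinates pass
#' through unchanged). Alternative-junction plan columns travel as GFF3
#' attributes when present.
#'
#' @param ies IES annotation table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ies_gff3 <- function(ies, path) {
  ies <- as.data.table(ies)
  n <- nrow(ies)
  if (n == 0L) {                      # header-only file for empty annotations
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (n) ies$scaffold else character(0),
    ranges = IRanges::IRanges(start = ies$start, end = ies$end),
    source = rep("iesim", n),
    type = rep("internal_eliminated_sequence", n),
    ID = ies$ies_id)
  S4Vectors::mcols(gr)$somatic_pos <- ies$somatic_pos
  for (col in c("alt_start", "alt_end", "alt_class",
                "alt_left_offset", "alt_right_offset", "ta_planted"))
    if (col %in% names(ies)) S4Vectors::mcols(gr)[[col]] <- ies[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an IES annotation from GFF3
#' @param path GFF3 file written by [write_ies_gff3()].
#' @return IES annotation `data.table`.
#' @export
read_ies_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  cols <- list(
    ies_id = as.character(mc$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    length = GenomicRanges::width(gr))
  for (col in c("somatic_pos", "alt_start", "alt_end", "alt_left_offset",
                "alt_right_offset"))
    if (col %in% names(mc)) cols[[col]] <- as.integer(mc[[col]])
  if ("alt_class" %in% names(mc)) cols$alt_class <- as.character(mc$alt_class)
  if ("ta_planted" %in% names(mc)) cols$ta_planted <- as.logical(mc$ta_planted)
  as.data.table(cols)
}

#' Write a TSV table with '# key=value' metadata lines
#' @param x data.frame/data.table.
#' @param path output file.
#' @param meta named list of metadata scalars.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, meta[[nm]]), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_meta()]
#' @param path TSV file.
#' @return `data.table` with a `meta` attribute (named character vector).
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^# ", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  meta <- character(0)
  if (n_meta > 0L) {
    kv <- sub("^# ", "", lines[seq_len(n_meta)])
    meta <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  }
  out <- fread(text = lines[(n_meta + 1L):length(lines)], sep = "\t",
               header = TRUE)
  setattr(out, "meta", meta)
  out
}
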