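#' Read and write genomes as FASTA
#'
#' Genomes are held in memory as named lists of chromosome strings; files go
#' through Biostrings.
#'
#' @param path FASTA file.
#' @return Named list of chromosome strings.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.list(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_genome_fasta
#' @param genome Named list of chromosome strings.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write interval tables as BED (0-based half-open)
#'
#' @param path BED file.
#' @return Data frame `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df(gr)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' @rdname read_bed
#' @param intervals Data frame `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = intervals$strand %||% "*")
  if (!is.null(intervals$name)) gr$name <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write signal tracks as bedGraph
#'
#' @param path bedGraph file.
#' @return Data frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_df(gr)
  df$score <- gr$score
  df
}

#' @rdname read_bedgraph
#' @param track Data frame `chrom`, `start`, `end`, `score`.
#' @export
write_bedgraph <- function(track, path) {
  validate_intervals(track, "track")
  gr <- df_to_granges(track)
  gr$score <- track$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}
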