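# -- sequence-format I/O -------------------------------------------------------
#
# Readers for per-allele FASTA and per-read FASTQ inputs using the
# "sample|locus" record-id convention, and a FASTQ writer for simulated read
# tables. Biostrings does the format handling.

require_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA/FASTQ input; install it or use ",
         "the TSV interfaces")
}

split_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("record id not in 'sample|locus' form: ", ids[bad[1]])
  list(sample = vapply(parts, `[`, character(1), 1),
       locus = vapply(parts, `[`, character(1), 2))
}

#' Read per-allele consensus sequences from FASTA
#'
#' Record ids follow the `sample|locus` convention; anything after a space
#' is ignored.
#'
#' @param path FASTA file.
#' @return Data frame (sample, locus, sequence).
#' @export
read_sequences_fasta <- function(path) {
  require_biostrings()
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*", "", names(x))
  parts <- split_ids(ids)
  data.frame(sample = parts$sample, locus = parts$locus,
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read sequencing reads from FASTQ into an aggregated read table
#'
#' Record ids follow the `sample|locus` convention (one record per read);
#' identical reads are aggregated into (sample, locus, sequence, count).
#'
#' @param path FASTQ file.
#' @return Data frame (sample, locus, sequence, count).
#' @export
read_reads_fastq <- function(path) {
  require_biostrings()
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub(" .*", "", names(x))
  parts <- split_ids(ids)
  tab <- data.frame(sample = parts$sample, locus = parts$locus,
                    sequence = as.character(x), stringsAsFactors = FALSE)
  agg <- stats::aggregate(cnt ~ sample + locus + sequence,
                          data = cbind(tab, cnt = 1L), FUN = sum)
  names(agg)[names(agg) == "cnt"] <- "count"
  agg[order(agg$sample, agg$locus), ]
}

#' Write an aggregated read table as FASTQ
#'
#' Expands counts into individual records named
#' `sample|locus|<serial>`, with uniform placeholder qualities (the
#' simulator models no per-base error).
#'
#' @param reads Data frame (sample, locus, sequence, count).
#' @param path Output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    n <- reads$count[i]
    seq <- reads$sequence[i]
    qual <- strrep("I", nchar(seq))
    ids <- sprintf("@%s|%s|%d", reads$sample[i], reads$locus[i], seq_len(n))
    writeLines(rbind(ids, seq, "+", qual), con)
  }
  invisible(path)
}

#' Variants-by-samples presence matrix
#'
#' 0/1 matrix (variant id x sample) from an [extract_variants()] table, for
#' summary-figure style displays.
#'
#' @param variants Output of [extract_variants()].
#' @param samples Sample ids for the columns (defaults to all carriers).
#' @return Integer matrix.
#' @export
variant_matrix <- function(variants, samples = NULL) {
  carriers <- strsplit(variants$carriers, ";", fixed = TRUE)
  if (is.null(samples)) samples <- sort(unique(unlist(carriers)))
  m <- matrix(0L, nrow = nrow(variants), ncol = length(samples),
              dimnames = list(variants$id, samples))
  for (i in seq_along(carriers))
    m[i, intersect(carriers[[i]], samples)] <- 1L
  m
}
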