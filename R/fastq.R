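# Paired-read container and FASTQ I/O.
#
# A read-pair table ("read pairs tibble") has one row per fragment copy:
#   read_id   unique pair name
#   r1_seq, r1_qual, r2_seq, r2_qual   reads as sequenced (5'->3'), Phred+33
# plus any bookkeeping columns (umi, fragment_id, ...).

#' Write paired reads to FASTQ
#'
#' @param reads Read pairs tibble (`read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`).
#' @param r1_path,r2_path Output paths; a `.gz` suffix gzips the output.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  emit <- function(path, ids, seqs, quals) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  }
  emit(r1_path, reads$read_id, reads$r1_seq, reads$r1_qual)
  emit(r2_path, reads$read_id, reads$r2_seq, reads$r2_qual)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read pairs tibble
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped). Records must be
#'   name-paired in order.
#' @return Read pairs tibble.
#' @export
read_fastq <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    tibble(
      read_id = sub("\\s.*$", "", names(x)),
      seq = unname(as.character(x)),
      qual = unname(as.character(S4Vectors::mcols(x)$qualities))
    )
  }
  r1 <- rd(r1_path)
  r2 <- rd(r2_path)
  if (nrow(r1) != nrow(r2) || any(r1$read_id != r2$read_id)) {
    stop("R1 and R2 FASTQs are not name-paired")
  }
  tibble(
    read_id = r1$read_id,
    r1_seq = r1$seq, r1_qual = r1$qual,
    r2_seq = r2$seq, r2_qual = r2$qual
  )
}
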