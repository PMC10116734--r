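# Gapless seed-and-verify alignment of paired reads to a single transcript.
#
# The libraries this package simulates and calls contain substitutions only
# (InDel simulation and calling are out of scope), so alignment reduces to
# placing each read at its unique gapless offset on the forward or reverse
# strand of the transcript. Seeds are exact k-mers taken at three read
# offsets; candidates are verified by full-length mismatch counting, and the
# placement with the fewest mismatches wins (ties: leftmost start, then "+"
# strand). An external aligner can be substituted via a command template (see
# `external_aligner()`), but the internal backend is the default and is fully
# deterministic.
#
# An alignments tibble has one row per aligned mate:
#   read_id, mate (1/2), strand, start, end (1-based inclusive), seq, qual
#   (both in reference orientation), nm (mismatch count vs the reference).

#' Align paired reads to a transcript reference
#'
#' Gapless, end-to-end placement of each mate on the transcript (either
#' strand), keeping only proper pairs (both mates placed, opposite strands).
#'
#' @param reads Read pairs tibble (see [read_fastq()]); an optional `umi`
#'   column is carried through.
#' @param ref A [transcript_reference()].
#' @param seed_len Seed k-mer length.
#' @param max_mismatch_frac Maximum fraction of mismatched bases for a valid
#'   placement.
#' @return Alignments tibble; attribute `n_unaligned` counts read pairs
#'   dropped (no placement or not a proper pair).
#' @export
align_reads <- function(reads, ref, seed_len = 15L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(ref, "transcript_ref"))
  refseq <- ref$sequence
  reflen <- nchar(refseq)
  refraw <- charToRaw(refseq)
  idx <- kmer_index(refseq, seed_len)

  place <- function(s) {
    # returns c(strand, start, nm) or NULL
    len <- nchar(s)
    if (len < seed_len || len > reflen) return(NULL)
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else revcomp(s)
      qraw <- charToRaw(q)
      offs <- unique(c(1L, (len - seed_len) %/% 2L + 1L, len - seed_len + 1L))
      starts <- integer(0)
      for (off in offs) {
        hit <- idx[[substr(q, off, off + seed_len - 1L)]]
        if (!is.null(hit)) starts <- c(starts, hit - off + 1L)
      }
      starts <- unique(starts)
      starts <- starts[starts >= 1L & starts + len - 1L <= reflen]
      for (st in starts) {
        nm <- sum(refraw[st:(st + len - 1L)] != qraw)
        if (nm <= max_mismatch_frac * len &&
            (is.null(best) || nm < best$nm ||
             (nm == best$nm && st < best$start))) {
          best <- list(strand = strand, start = st, nm = nm)
        }
      }
      if (!is.null(best) && best$nm == 0L) break
    }
    best
  }

  # align each distinct sequence once
  all_seqs <- c(reads$r1_seq, reads$r2_seq)
  useq <- unique(all_seqs)
  hits <- lapply(useq, place)
  names(hits) <- useq

  build_mate <- function(seqs, quals, mate) {
    h <- hits[seqs]
    ok <- !vapply(h, is.null, logical(1))
    strand <- ifelse(ok, vapply(h, function(z) if (is.null(z)) "" else z$strand, character(1)), NA)
    start <- ifelse(ok, vapply(h, function(z) if (is.null(z)) NA_real_ else as.numeric(z$start), numeric(1)), NA)
    nm <- ifelse(ok, vapply(h, function(z) if (is.null(z)) NA_real_ else as.numeric(z$nm), numeric(1)), NA)
    len <- nchar(seqs)
    aseq <- seqs
    aqual <- quals
    neg <- ok & strand == "-"
    if (any(neg)) {
      aseq[neg] <- revcomp(seqs[neg])
      aqual[neg] <- vapply(quals[neg], function(q) {
        intToUtf8(rev(utf8ToInt(q)))
      }, character(1))
    }
    tibble(
      read_id = reads$read_id, mate = mate,
      strand = strand, start = as.integer(start),
      end = as.integer(start + len - 1L),
      seq = aseq, qual = aqual, nm = as.integer(nm),
      aligned = ok
    )
  }

  a1 <- build_mate(reads$r1_seq, reads$r1_qual, 1L)
  a2 <- build_mate(reads$r2_seq, reads$r2_qual, 2L)
  proper <- a1$aligned & a2$aligned & a1$strand != a2$strand
  out <- dplyr::bind_rows(a1[proper, ], a2[proper, ])
  out$aligned <- NULL
  if ("umi" %in% names(reads)) {
    out <- dplyr::left_join(out,
      dplyr::select(reads, "read_id", "umi"),
      by = "read_id"
    )
  }
  out <- dplyr::arrange(out, .data$read_id, .data$mate)
  attr(out, "n_unaligned") <- sum(!proper)
  out
}

#' @noRd
kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("reference shorter than seed length")
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  e <- split(seq_len(n - k + 1L), kmers)
  list2env(e, hash = TRUE, size = length(e))
}

#' Run an external aligner via a command template
#'
#' Escape hatch for users who prefer a dedicated short-read aligner. The
#' template receives `{r1}`, `{r2}`, `{ref_fasta}` and `{out_sam}`
#' placeholders; the resulting SAM can be imported with [read_alignments_sam()].
#'
#' @param template Command template string.
#' @param r1,r2 FASTQ paths.
#' @param ref A [transcript_reference()] (written to a temporary FASTA).
#' @param out_sam Output SAM path.
#' @return `out_sam`, invisibly.
#' @export
external_aligner <- function(template, r1, r2, ref, out_sam) {
  if (!nzchar(Sys.which(strsplit(template, "\\s+")[[1]][1]))) {
    stop("external aligner not found; check the command template configuration")
  }
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", ref$transcript_id), ref$sequence), fa)
  cmd <- template
  for (kv in list(c("\\{r1\\}", r1), c("\\{r2\\}", r2),
                  c("\\{ref_fasta\\}", fa), c("\\{out_sam\\}", out_sam))) {
    cmd <- gsub(kv[1], kv[2], cmd)
  }
  status <- system(cmd)
  if (status != 0L) stop("external aligner exited with status ", status)
  invisible(out_sam)
}

#' Read position (0-based cycle in the sequenced read) of a reference position
#' @noRd
read_cycle_at <- function(strand, start, end, ref_pos) {
  ifelse(strand == "+", ref_pos - start, end - ref_pos)
}
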