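# Text emission of VCF, bedgraph and SAM, and import of VCF/SAM/BAM.
# Emission is written directly (these are line formats the package fully
# controls); parsing goes through vcfR / Rsamtools.

#' Write a truth VCF for simulated variants
#'
#' @param truth Truth tibble from [apply_edits()].
#' @param ref A [transcript_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, ref, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$transcript_id, nchar(ref$sequence)),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Requested variant frequency\">",
    "##INFO=<ID=RC,Number=1,Type=Integer,Description=\"Realized edited fragment count\">",
    "##INFO=<ID=RF,Number=1,Type=Float,Description=\"Realized frequency (RC / fragment coverage)\">",
    "##INFO=<ID=COV,Number=1,Type=Integer,Description=\"Fragment coverage at POS\">",
    "##INFO=<ID=UNPLACEABLE,Number=0,Type=Flag,Description=\"Requested count not achieved\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf(
    "AF=%s;RC=%d;RF=%s;COV=%d%s",
    format(truth$target_frequency, scientific = FALSE, trim = TRUE),
    truth$realized_count,
    format(truth$realized_frequency, digits = 8, trim = TRUE),
    truth$coverage,
    ifelse(truth$unplaceable, ";UNPLACEABLE", "")
  )
  rec <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
    ref$transcript_id, truth$pos, truth$ref, truth$alt, info
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read variant specs from a VCF
#'
#' Reads POS/REF/ALT and the `AF` INFO key (target frequency) into the spec
#' tibble layout used by [plan_edits()].
#'
#' @param path VCF path.
#' @return Tibble with `pos`, `ref`, `alt`, `target_frequency`.
#' @export
read_vcf_specs <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  tibble(
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    target_frequency = af
  )
}

#' Write variant calls to VCF
#'
#' @param calls Calls tibble from [aggregate_variants()] / [run_call()].
#' @param ref A [transcript_reference()].
#' @param path Output path.
#' @param params Optional named list echoed into the header as
#'   `##mavecall_params=`.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, ref, path, params = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$transcript_id, nchar(ref$sequence)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP, di_nt_MNP or tri_nt_MNP\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Fragment coverage at POS\">",
    "##INFO=<ID=CAO,Number=1,Type=Integer,Description=\"Supporting fragment count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"CAO / DP\">",
    "##INFO=<ID=CODON,Number=1,Type=String,Description=\"ref>alt codon(s)\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Amino acid change\">",
    "##INFO=<ID=NNK,Number=1,Type=Integer,Description=\"Matches NNK mutagenesis signature\">",
    "##INFO=<ID=R1BQ,Number=1,Type=Float,Description=\"Median R1 supporting base quality\">",
    "##INFO=<ID=R2BQ,Number=1,Type=Float,Description=\"Median R2 supporting base quality\">",
    "##INFO=<ID=R2POS,Number=1,Type=Float,Description=\"Median R2 supporting read position\">",
    "##INFO=<ID=R2NM,Number=1,Type=Float,Description=\"Median R2 supporting edit distance\">",
    if (!is.null(params)) {
      sprintf("##mavecall_params=%s",
        paste(names(params), unlist(params), sep = "=", collapse = " "))
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf(
    "TYPE=%s;DP=%d;CAO=%d;AF=%s;CODON=%s;AA=%s;NNK=%d;R1BQ=%s;R2BQ=%s;R2POS=%s;R2NM=%s",
    calls$variant_type, calls$coverage, calls$count,
    format(calls$frequency, digits = 8, trim = TRUE),
    paste0(calls$ref_codons, ">", calls$alt_codons), calls$aa_change,
    as.integer(calls$matches_signature),
    format(calls$r1_median_bq, trim = TRUE),
    format(calls$r2_median_bq, trim = TRUE),
    format(calls$r2_median_read_pos, trim = TRUE),
    format(calls$r2_median_nm, trim = TRUE)
  )
  rec <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
    ref$transcript_id, calls$pos, calls$ref, calls$alt, info
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a fragment-coverage track as bedgraph (0-based half-open)
#'
#' @param coverage Coverage tibble (`contig`, `start`, `end`, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  writeLines(
    sprintf("%s\t%d\t%d\t%d", coverage$contig, coverage$start,
            coverage$end, coverage$depth),
    path
  )
  invisible(path)
}

#' Write alignments as SAM
#'
#' Gapless records (CIGAR `<len>M`) with MD/NM tags, proper-pair flags set.
#'
#' @param alignments Alignments tibble.
#' @param ref A [transcript_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref, path) {
  a <- dplyr::arrange(alignments, .data$read_id, .data$mate)
  w <- tidyr::pivot_wider(
    dplyr::mutate(a, len = .data$end - .data$start + 1L),
    id_cols = "read_id",
    names_from = "mate",
    values_from = c("strand", "start", "seq", "qual", "len", "nm")
  )
  refraw <- charToRaw(ref$sequence)
  md_of <- function(seq, start) {
    sraw <- charToRaw(seq)
    rraw <- refraw[start:(start + length(sraw) - 1L)]
    d <- which(rraw != sraw)
    if (!length(d)) return(as.character(length(sraw)))
    parts <- character(0)
    prev <- 0L
    for (p in d) {
      parts <- c(parts, as.character(p - prev - 1L), rawToChar(rraw[p]))
      prev <- p
    }
    paste0(paste(parts, collapse = ""), length(sraw) - prev)
  }
  mk_line <- function(qn, strand, start, seq, qual, nm, m_strand, m_start,
                      first, tlen) {
    flag <- 1L + 2L + if (strand == "-") 16L else 0L
    flag <- flag + if (m_strand == "-") 32L else 0L
    flag <- flag + if (first) 64L else 128L
    sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tNM:i:%d\tMD:Z:%s",
      qn, flag, ref$transcript_id, start, nchar(seq), m_start, tlen,
      seq, qual, nm, md_of(seq, start)
    )
  }
  lines <- character(2L * nrow(w))
  for (i in seq_len(nrow(w))) {
    lo <- min(w$start_1[i], w$start_2[i])
    hi <- max(w$start_1[i] + w$len_1[i], w$start_2[i] + w$len_2[i]) - 1L
    tl <- hi - lo + 1L
    t1 <- if (w$start_1[i] <= w$start_2[i]) tl else -tl
    lines[2L * i - 1L] <- mk_line(
      w$read_id[i], w$strand_1[i], w$start_1[i], w$seq_1[i], w$qual_1[i],
      w$nm_1[i], w$strand_2[i], w$start_2[i], TRUE, t1
    )
    lines[2L * i] <- mk_line(
      w$read_id[i], w$strand_2[i], w$start_2[i], w$seq_2[i], w$qual_2[i],
      w$nm_2[i], w$strand_1[i], w$start_1[i], FALSE, -t1
    )
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$transcript_id, nchar(ref$sequence)),
    lines
  ), path)
  invisible(path)
}

#' Import alignments from SAM/BAM
#'
#' Reads paired, gapless records (CIGAR `<len>M`) into the alignments tibble
#' layout. Records with InDel or clipped CIGARs are dropped with a warning
#' count. Requires Rsamtools.
#'
#' @param path SAM or BAM path.
#' @return Alignments tibble.
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  gapless <- grepl("^\\d+M$", x$cigar)
  if (any(!gapless, na.rm = TRUE)) {
    warning(sum(!gapless, na.rm = TRUE), " non-gapless records dropped")
  }
  keep <- which(gapless & !is.na(x$pos))
  flag <- x$flag[keep]
  tibble(
    read_id = x$qname[keep],
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    start = x$pos[keep],
    end = x$pos[keep] + as.integer(sub("M$", "", x$cigar[keep])) - 1L,
    seq = as.character(x$seq[keep]),
    qual = as.character(x$qual[keep]),
    nm = if (!is.null(x$tag$NM)) as.integer(x$tag$NM[keep]) else NA_integer_
  ) |>
    dplyr::arrange(.data$read_id, .data$mate)
}
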