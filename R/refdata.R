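# Transcript reference, coordinate conventions and codon-level annotation.
#
# Coordinates: user-facing variant positions (`pos`) are 1-based transcript
# coordinates, matching VCF. CDS bounds are stored 0-based half-open
# (`cds_start` inclusive, `cds_end` exclusive); BED and bedgraph output stay
# 0-based half-open.

#' Construct a transcript reference
#'
#' The coordinate frame shared by all other functions in the package: a single
#' transcript sequence with explicit CDS bounds. The CDS must be a whole number
#' of codons; the standard genetic code is used for translation.
#'
#' @param sequence Character scalar of A/C/G/T.
#' @param cds_start,cds_end CDS bounds, 0-based half-open.
#' @param transcript_id Identifier used as the contig name in VCF/bedgraph
#'   output.
#' @return An object of class `transcript_ref`.
#' @export
#' @examples
#' ref <- transcript_reference("ATGGCTAAGTAA", 0, 12)
#' ref
transcript_reference <- function(sequence, cds_start, cds_end,
                                 transcript_id = "tx1") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must contain only A/C/G/T (no ambiguity codes)")
  }
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  cds_len <- cds_end - cds_start
  if (cds_len < 3L || cds_len %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3")
  }
  if (cds_start < 0L || cds_end > nchar(sequence)) {
    stop("CDS bounds fall outside the sequence")
  }
  structure(
    list(
      transcript_id = transcript_id,
      sequence = sequence,
      cds_start = cds_start,
      cds_end = cds_end
    ),
    class = "transcript_ref"
  )
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat(sprintf(
    "<transcript_ref> %s: %d nt, CDS [%d, %d) (%d codons)\n",
    x$transcript_id, nchar(x$sequence), x$cds_start, x$cds_end,
    (x$cds_end - x$cds_start) %/% 3L
  ))
  invisible(x)
}

#' Read a transcript reference from FASTA
#'
#' @param fasta Path to a FASTA file; the first record is used.
#' @param cds_start,cds_end CDS bounds (0-based half-open). When `NULL`, the
#'   whole sequence is taken as CDS.
#' @return A [transcript_reference()].
#' @export
read_transcript_fasta <- function(fasta, cds_start = NULL, cds_end = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta)
  id <- sub("\\s.*$", "", names(seqs)[1])
  s <- as.character(seqs[[1]])
  if (is.null(cds_start)) cds_start <- 0L
  if (is.null(cds_end)) cds_end <- nchar(s)
  transcript_reference(s, cds_start, cds_end, transcript_id = id)
}

#' Extract reference bases (1-based inclusive coordinates)
#' @noRd
ref_seq_at <- function(ref, start, end) {
  substring(ref$sequence, start, end)
}

aa3 <- function(codons) {
  aa1 <- Biostrings::GENETIC_CODE[codons]
  out <- unname(Biostrings::AMINO_ACID_CODE[aa1])
  out[aa1 == "*"] <- "Ter"
  out
}

#' Annotate a SNP or MNP at codon and protein level
#'
#' Resolves a 1-3 nt substitution against the CDS: which codon(s) it spans,
#' the reference and alternate codons, and the amino-acid change. Variants
#' spanning more than one codon are annotated with all affected codons and
#' flagged `multi_codon`.
#'
#' @param ref A [transcript_reference()].
#' @param pos 1-based transcript coordinate of the first changed base.
#' @param ref_allele,alt_allele Equal-length allele strings (1-3 nt).
#' @return One-row tibble with columns `pos`, `ref`, `alt`, `cds_pos`,
#'   `variant_type` (`SNP`, `di_nt_MNP`, `tri_nt_MNP`), `ref_codons`,
#'   `alt_codons`, `aa_change` (e.g. `"Ala2Lys"`), `aa_pos`, `silent`,
#'   `multi_codon`, `matches_signature` (NNK codon signature, see
#'   [matches_nnk()]).
#' @export
#' @examples
#' ref <- transcript_reference("ATGGCTAAGTAA", 0, 12)
#' annotate_variant(ref, 6, "T", "A") # GCT -> GCA, silent
annotate_variant <- function(ref, pos, ref_allele, alt_allele) {
  stopifnot(inherits(ref, "transcript_ref"))
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  len <- nchar(ref_allele)
  if (len != nchar(alt_allele)) stop("alleles must have equal length")
  if (len < 1L || len > 3L) stop("allele length must be 1-3 nt")
  if (grepl("[^ACGT]", ref_allele) || grepl("[^ACGT]", alt_allele)) {
    stop("alleles must contain only A/C/G/T")
  }
  if (ref_allele == alt_allele) stop("ref and alt alleles are identical")
  pos <- as.integer(pos)
  p0 <- pos - 1L # 0-based first base
  if (p0 < ref$cds_start || p0 + len > ref$cds_end) {
    stop("variant does not fall fully inside the CDS")
  }
  obs <- ref_seq_at(ref, pos, pos + len - 1L)
  if (obs != ref_allele) {
    bad <- which(charToRaw(obs) != charToRaw(ref_allele))[1]
    stop(sprintf(
      "reference mismatch at transcript position %d: reference has '%s', ref_allele has '%s'",
      pos + bad - 1L, substr(obs, bad, bad), substr(ref_allele, bad, bad)
    ))
  }

  cds_pos <- p0 - ref$cds_start + 1L # 1-based CDS coordinate
  codon_idx <- unique((seq.int(cds_pos, cds_pos + len - 1L) - 1L) %/% 3L) # 0-based
  multi_codon <- length(codon_idx) > 1L

  ref_codons <- character(0)
  alt_codons <- character(0)
  for (ci in codon_idx) {
    c_start <- ref$cds_start + 3L * ci + 1L # 1-based transcript coord
    rc <- ref_seq_at(ref, c_start, c_start + 2L)
    ac <- rc
    for (k in seq_len(len)) {
      off <- (pos + k - 1L) - c_start + 1L
      if (off >= 1L && off <= 3L) substr(ac, off, off) <- substr(alt_allele, k, k)
    }
    ref_codons <- c(ref_codons, rc)
    alt_codons <- c(alt_codons, ac)
  }
  ref_aa <- aa3(ref_codons)
  alt_aa <- aa3(alt_codons)
  aa_num <- codon_idx + 1L
  aa_change <- paste(sprintf("%s%d%s", ref_aa, aa_num, alt_aa), collapse = ",")
  silent <- all(ref_aa == alt_aa)
  vt <- c("SNP", "di_nt_MNP", "tri_nt_MNP")[len]

  ann <- tibble(
    pos = pos, ref = ref_allele, alt = alt_allele,
    cds_pos = cds_pos,
    variant_type = vt,
    ref_codons = paste(ref_codons, collapse = ","),
    alt_codons = paste(alt_codons, collapse = ","),
    aa_change = aa_change,
    aa_pos = aa_num[1],
    silent = silent,
    multi_codon = multi_codon
  )
  ann$matches_signature <- matches_nnk(ref, ann)
  ann
}

#' Annotate a table of variants
#'
#' Row-wise [annotate_variant()] over a tibble with `pos`, `ref`, `alt`.
#'
#' @param ref A [transcript_reference()].
#' @param variants Tibble with columns `pos`, `ref`, `alt`; other columns are
#'   kept.
#' @return `variants` with annotation columns appended.
#' @export
annotate_variants <- function(ref, variants) {
  ann_cols <- c(
    "cds_pos", "variant_type", "ref_codons", "alt_codons", "aa_change",
    "aa_pos", "silent", "multi_codon", "matches_signature"
  )
  if (nrow(variants) == 0L) {
    tmpl <- tibble(
      cds_pos = integer(0), variant_type = character(0),
      ref_codons = character(0), alt_codons = character(0),
      aa_change = character(0), aa_pos = integer(0),
      silent = logical(0), multi_codon = logical(0),
      matches_signature = logical(0)
    )
    return(dplyr::bind_cols(variants, tmpl))
  }
  ann <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(p, r, a) annotate_variant(ref, p, r, a)
  )
  ann <- dplyr::bind_rows(ann)
  dplyr::bind_cols(
    variants,
    ann[setdiff(names(ann), c("pos", "ref", "alt"))]
  )
}

#' Does a variant match the NNK codon-mutagenesis signature?
#'
#' NNK mutagenesis replaces a whole codon with NNK (N = any base, K = G or T),
#' so every library variant changes exactly one codon and leaves an alternate
#' codon whose third base is G or T. The test is evaluated on the alternate
#' codon only; multi-codon variants never match.
#'
#' @param ref A [transcript_reference()] (unused beyond interface symmetry).
#' @param ann Annotation row(s) from [annotate_variant()].
#' @return Logical vector, one value per annotation row.
#' @export
matches_nnk <- function(ref, ann) {
  third <- substr(ann$alt_codons, 3, 3)
  !ann$multi_codon & third %in% c("G", "T")
}
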