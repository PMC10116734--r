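# The variant caller: concordant mismatch enumeration in filtered read pairs,
# greedy <=3-nt MNP merging, aggregation to counts/frequencies with
# per-mismatch quality features, and fragment-coverage computation.

#' Variant-calling filters
#'
#' @param min_count Minimum supporting fragments to report a call (`-m`).
#' @param min_bq Minimum Phred base quality in both mates (`-q`).
#' @param max_nm Maximum per-mate edit distance; pairs with a worse mate are
#'   discarded entirely (`-e`).
#' @param signature `"NNK"` to apply the codon-mutagenesis signature, or
#'   `NULL`.
#' @param signature_action Drop non-matching calls, or keep and flag them.
#' @return A `call_filters` list.
#' @export
call_filters <- function(min_count = 2L, min_bq = 30L, max_nm = 10L,
                         signature = NULL,
                         signature_action = c("drop", "flag")) {
  stopifnot(min_count >= 1L, min_bq >= 0L, max_nm >= 0L)
  structure(
    list(
      min_count = as.integer(min_count), min_bq = as.integer(min_bq),
      max_nm = as.integer(max_nm), signature = signature,
      signature_action = match.arg(signature_action)
    ),
    class = "call_filters"
  )
}

#' Enumerate mate-concordant mismatches
#'
#' A pair is discarded entirely when either mate's edit distance exceeds
#' `max_nm`. A mismatch is emitted at a position iff both mates align across
#' it, both call the same non-reference A/C/G/T base, and both base qualities
#' are at least `min_bq` and non-zero (primer-masked bases never participate).
#' Positions covered by one mate only are uncallable.
#'
#' @param alignments Alignments tibble (proper pairs).
#' @param ref A [transcript_reference()].
#' @param filters A [call_filters()].
#' @return Mismatch observation tibble: one row per concordant mismatch with
#'   `read_id`, `ref_pos`, `ref_base`, `alt_base`, per-mate base qualities,
#'   0-based read positions, edit distances, and `sample_strand` (R1 strand).
#' @export
enumerate_concordant_mismatches <- function(alignments, ref, filters) {
  if (!nzchar(alignments$qual[1] %||% "x")) stop("alignments carry no base qualities")
  aln <- alignments
  if (!"nm" %in% names(aln) || anyNA(aln$nm)) aln$nm <- alignment_nm(aln, ref)
  # pair-level edit distance filter
  bad <- unique(aln$read_id[aln$nm > filters$max_nm])
  aln <- aln[!aln$read_id %in% bad, ]
  if (nrow(aln) == 0L) return(empty_observations())

  refraw <- charToRaw(ref$sequence)
  rows <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    sraw <- charToRaw(aln$seq[i])
    d <- which(refraw[aln$start[i]:aln$end[i]] != sraw)
    if (!length(d)) next
    pos <- aln$start[i] + d - 1L
    rows[[i]] <- tibble(
      read_id = aln$read_id[i], mate = aln$mate[i],
      strand = aln$strand[i],
      ref_pos = pos,
      ref_base = rawToChar(refraw[pos], multiple = TRUE),
      alt_base = rawToChar(sraw[d], multiple = TRUE),
      bq = as.integer(charToRaw(aln$qual[i])[d]) - 33L,
      read_pos = as.integer(read_cycle_at(aln$strand[i], aln$start[i],
                                          aln$end[i], pos)),
      nm = aln$nm[i]
    )
  }
  mm <- dplyr::bind_rows(rows)
  if (nrow(mm) == 0L) return(empty_observations())
  mm <- mm[mm$alt_base %in% DNA_BASES, ] # N and other ambiguity codes never call

  m1 <- mm[mm$mate == 1L, ]
  m2 <- mm[mm$mate == 2L, ]
  obs <- dplyr::inner_join(
    dplyr::select(m1, "read_id", "ref_pos", "ref_base", "alt_base",
      r1_strand = "strand", r1_bq = "bq", r1_read_pos = "read_pos", r1_nm = "nm"),
    dplyr::select(m2, "read_id", "ref_pos", "alt_base",
      r2_bq = "bq", r2_read_pos = "read_pos", r2_nm = "nm"),
    by = c("read_id", "ref_pos", "alt_base")
  )
  q <- max(1L, filters$min_bq) # masked (BQ 0) bases never participate
  obs <- obs[obs$r1_bq >= q & obs$r2_bq >= q &
               obs$r1_bq >= filters$min_bq & obs$r2_bq >= filters$min_bq, ]
  obs$sample_strand <- obs$r1_strand
  obs$r1_strand <- NULL
  dplyr::arrange(obs, .data$read_id, .data$ref_pos)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @noRd
empty_observations <- function() {
  tibble(
    read_id = character(0), ref_pos = integer(0), ref_base = character(0),
    alt_base = character(0), r1_bq = integer(0), r1_read_pos = integer(0),
    r1_nm = integer(0), r2_bq = integer(0), r2_read_pos = integer(0),
    r2_nm = integer(0), sample_strand = character(0)
  )
}

#' Merge nearby phased mismatches of a pair into MNP components
#'
#' Greedy left-to-right: consecutive mismatches of one read pair merge into a
#' single component while the total reference span stays at most 3 nt
#' (positions i and j merge iff j - i <= 2); a gap position inside a merged
#' span takes the reference base (the read matches the reference there, which
#' is why no mismatch was recorded). No component ever spans more than 3 nt
#' and no haplotype calls are made.
#'
#' @param obs Mismatch observations from
#'   [enumerate_concordant_mismatches()] (any number of pairs).
#' @param ref A [transcript_reference()].
#' @return Component tibble: one row per observation, with `pos`, `ref`,
#'   `alt` identifying the merged variant the observation belongs to.
#' @export
merge_mnps <- function(obs, ref) {
  if (nrow(obs) == 0L) {
    return(dplyr::mutate(obs, pos = integer(0), ref = character(0),
                         alt = character(0)))
  }
  obs <- dplyr::arrange(obs, .data$read_id, .data$ref_pos)
  comp <- integer(nrow(obs))
  cid <- 0L
  last_id <- ""
  comp_start <- -10L
  for (i in seq_len(nrow(obs))) {
    if (obs$read_id[i] != last_id ||
        obs$ref_pos[i] - comp_start > 2L) {
      cid <- cid + 1L
      comp_start <- obs$ref_pos[i]
      last_id <- obs$read_id[i]
    }
    comp[i] <- cid
  }
  obs$component <- comp
  comps <- obs |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      read_id = .data$read_id[1],
      pos = min(.data$ref_pos),
      span_end = max(.data$ref_pos),
      .groups = "drop"
    )
  comps$ref <- ref_seq_at(ref, comps$pos, comps$span_end)
  comps$alt <- comps$ref
  for (i in seq_len(nrow(obs))) {
    k <- obs$component[i]
    off <- obs$ref_pos[i] - comps$pos[k] + 1L
    substr(comps$alt[k], off, off) <- obs$alt_base[i]
  }
  out <- dplyr::left_join(
    obs,
    dplyr::select(comps, "component", "pos", "ref", "alt"),
    by = "component"
  )
  out$component <- NULL
  out
}

#' Fragment coverage after masking, as a bedgraph-style track
#'
#' Per reference position, the number of fragments with at least one unmasked
#' (BQ > 0) base aligned across it; both mates of a fragment count once.
#' Adjacent equal-depth positions are merged into 0-based half-open intervals.
#'
#' @param alignments Alignments tibble.
#' @param ref A [transcript_reference()].
#' @return Coverage tibble (`contig`, `start`, `end`, `depth`), 0-based
#'   half-open, non-overlapping, sorted.
#' @export
compute_fragment_coverage <- function(alignments, ref) {
  L <- nchar(ref$sequence)
  if (nrow(alignments) == 0L) {
    return(tibble(contig = character(0), start = integer(0),
                  end = integer(0), depth = integer(0)))
  }
  # unmasked runs per mate
  runs <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    q <- as.integer(charToRaw(alignments$qual[i])) - 33L
    r <- rle(q > 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      runs[[i]] <- tibble(
        read_id = alignments$read_id[i],
        start = alignments$start[i] + starts[keep] - 1L,
        end = alignments$start[i] + ends[keep] - 1L
      )
    }
  }
  runs <- dplyr::bind_rows(runs)
  if (nrow(runs) == 0L) {
    return(tibble(contig = ref$transcript_id, start = 0L, end = L, depth = 0L))
  }
  # per-fragment union, then depth
  ir <- IRanges::IRanges(start = runs$start, end = runs$end)
  by_frag <- IRanges::reduce(S4Vectors::split(ir, runs$read_id))
  cov <- IRanges::coverage(unlist(by_frag), width = L)
  rl <- S4Vectors::runLength(cov)
  rv <- S4Vectors::runValue(cov)
  ends <- cumsum(rl)
  tibble(
    contig = ref$transcript_id,
    start = as.integer(ends - rl), # 0-based half-open
    end = as.integer(ends),
    depth = as.integer(rv)
  )
}

#' Depth at 1-based positions from a coverage track
#' @noRd
coverage_at <- function(coverage, pos) {
  idx <- findInterval(pos - 1L, coverage$start)
  safe <- pmax(idx, 1L)
  out <- coverage$depth[safe]
  out[idx < 1L | (pos - 1L) >= coverage$end[safe]] <- 0L
  out
}

#' Aggregate per-pair components into variant calls
#'
#' Identical `(pos, ref, alt)` components are counted once per fragment,
#' thresholded at `min_count`, annotated at codon/protein level, and given
#' per-mismatch feature summaries (lower medians) plus per-sample-strand
#' summaries for RACE-like designs. Frequency is supporting fragments divided
#' by fragment coverage at the variant's leftmost position.
#'
#' @param components Output of [merge_mnps()].
#' @param coverage Output of [compute_fragment_coverage()].
#' @param filters A [call_filters()].
#' @param ref A [transcript_reference()].
#' @return Calls tibble, one row per called variant.
#' @export
aggregate_variants <- function(components, coverage, filters, ref) {
  if (nrow(components) == 0L) return(empty_calls())
  med <- lower_median
  calls <- components |>
    dplyr::group_by(.data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      count = dplyr::n_distinct(.data$read_id),
      n_mismatches = dplyr::n(),
      r1_median_bq = med(.data$r1_bq),
      r2_median_bq = med(.data$r2_bq),
      r1_median_read_pos = med(.data$r1_read_pos),
      r2_median_read_pos = med(.data$r2_read_pos),
      r1_median_nm = med(.data$r1_nm),
      r2_median_nm = med(.data$r2_nm),
      n_plus = dplyr::n_distinct(.data$read_id[.data$sample_strand == "+"]),
      n_minus = dplyr::n_distinct(.data$read_id[.data$sample_strand == "-"]),
      r1_median_bq_plus = med(.data$r1_bq[.data$sample_strand == "+"]),
      r1_median_bq_minus = med(.data$r1_bq[.data$sample_strand == "-"]),
      r2_median_bq_plus = med(.data$r2_bq[.data$sample_strand == "+"]),
      r2_median_bq_minus = med(.data$r2_bq[.data$sample_strand == "-"]),
      r2_median_read_pos_plus = med(.data$r2_read_pos[.data$sample_strand == "+"]),
      r2_median_read_pos_minus = med(.data$r2_read_pos[.data$sample_strand == "-"]),
      r2_median_nm_plus = med(.data$r2_nm[.data$sample_strand == "+"]),
      r2_median_nm_minus = med(.data$r2_nm[.data$sample_strand == "-"]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$count >= filters$min_count)
  if (nrow(calls) == 0L) return(empty_calls())
  calls$coverage <- coverage_at(coverage, calls$pos)
  if (any(calls$coverage < calls$count)) {
    stop("internal error: supporting count exceeds fragment coverage")
  }
  calls$frequency <- calls$count / calls$coverage
  calls <- annotate_variants(ref, calls)
  if (!is.null(filters$signature) && filters$signature == "NNK" &&
      filters$signature_action == "drop") {
    calls <- calls[calls$matches_signature, ]
  }
  dplyr::arrange(calls, .data$pos, .data$ref, .data$alt)
}

#' @noRd
empty_calls <- function() {
  tibble(
    pos = integer(0), ref = character(0), alt = character(0),
    count = integer(0), n_mismatches = integer(0),
    r1_median_bq = numeric(0), r2_median_bq = numeric(0),
    r1_median_read_pos = numeric(0), r2_median_read_pos = numeric(0),
    r1_median_nm = numeric(0), r2_median_nm = numeric(0),
    n_plus = integer(0), n_minus = integer(0),
    r1_median_bq_plus = numeric(0), r1_median_bq_minus = numeric(0),
    r2_median_bq_plus = numeric(0), r2_median_bq_minus = numeric(0),
    r2_median_read_pos_plus = numeric(0), r2_median_read_pos_minus = numeric(0),
    r2_median_nm_plus = numeric(0), r2_median_nm_minus = numeric(0),
    coverage = integer(0), frequency = numeric(0),
    cds_pos = integer(0), variant_type = character(0),
    ref_codons = character(0), alt_codons = character(0),
    aa_change = character(0), aa_pos = integer(0), silent = logical(0),
    multi_codon = logical(0), matches_signature = logical(0)
  )
}

#' Run the full variant-calling pipeline
#'
#' trim -> align -> \[consensus dedup\] -> \[primer masking\] -> concordant
#' mismatch enumeration -> MNP merging -> aggregation -> annotation. Accepts
#' either raw reads (aligned internally) or pre-computed alignments.
#'
#' @param reads Read pairs tibble, or `NULL` when `alignments` is given.
#' @param ref A [transcript_reference()].
#' @param filters A [call_filters()].
#' @param alignments Optional pre-computed alignments tibble.
#' @param primers Optional primer tibble; enables base-quality masking.
#' @param method Library method, `"amplicon"` or `"race_like"` (masking
#'   buffer and strand features).
#' @param umi_pattern Optional UMI length/pattern; enables UMI extraction
#'   (from reads) and consensus deduplication when `dedup = TRUE`.
#' @param dedup Run UMI consensus deduplication?
#' @param outdir Optional output directory; writes `calls.vcf`,
#'   `summary.txt` (one row per mismatch participating in a primary call) and
#'   `coverage.bedgraph`.
#' @param seed Integer seed (consensus tie-breaks).
#' @return An object of class `mave_calls`: `calls`, `summary` (per-mismatch
#'   rows), `coverage`, `log` (stage read counts), `filters`.
#' @export
run_call <- function(reads = NULL, ref, filters = call_filters(),
                     alignments = NULL, primers = NULL,
                     method = c("amplicon", "race_like"),
                     umi_pattern = NULL, dedup = FALSE,
                     outdir = NULL, seed = 1L) {
  method <- match.arg(method)
  log <- list()
  if (is.null(alignments)) {
    stopifnot(!is.null(reads))
    log$input_pairs <- nrow(reads)
    if (!is.null(umi_pattern)) reads <- extract_umis(reads, umi_pattern)
    reads <- trim_reads(reads)
    alignments <- align_reads(reads, ref)
    log$unaligned_pairs <- attr(alignments, "n_unaligned")
  }
  log$aligned_pairs <- length(unique(alignments$read_id))
  if (dedup) {
    groups <- group_umis_directional(alignments)
    alignments <- consensus_deduplicate(groups, alignments, ref, seed = seed)
    log$dedup_pairs <- length(unique(alignments$read_id))
  }
  if (!is.null(primers) && nrow(primers) > 0L) {
    alignments <- mask_primers(alignments, primers, method = method)
    log$masked_mates <- nrow(attr(alignments, "mask_report"))
  }
  coverage <- compute_fragment_coverage(alignments, ref)
  obs <- enumerate_concordant_mismatches(alignments, ref, filters)
  log$concordant_mismatches <- nrow(obs)
  components <- merge_mnps(obs, ref)
  calls <- aggregate_variants(components, coverage, filters, ref)
  log$calls <- nrow(calls)
  # per-mismatch summary restricted to mismatches of primary (reported) calls
  summary <- dplyr::semi_join(
    components, calls, by = c("pos", "ref", "alt")
  )
  out <- structure(
    list(
      calls = calls, summary = summary, coverage = coverage,
      log = log, filters = filters, ref = ref, method = method
    ),
    class = "mave_calls"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_calls_vcf(calls, ref, file.path(outdir, "calls.vcf"),
      params = list(
        m = filters$min_count, q = filters$min_bq, e = filters$max_nm,
        s = filters$signature %||% "none"
      )
    )
    utils::write.table(summary, file.path(outdir, "summary.txt"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_bedgraph(coverage, file.path(outdir, "coverage.bedgraph"))
  }
  out
}

#' @export
print.mave_calls <- function(x, ...) {
  cat(sprintf(
    "<mave_calls> %d variants (%s) from %d pairs; %d concordant mismatches\n",
    nrow(x$calls),
    paste(names(table(x$calls$variant_type)),
          table(x$calls$variant_type), sep = ":", collapse = " "),
    x$log$aligned_pairs %||% NA_integer_, x$log$concordant_mismatches
  ))
  invisible(x)
}
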