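# Deterministic spike-in of SNPs/MNPs into pre-existing paired alignments.
#
# Editing is fragment-based: each selected read pair carries exactly one
# variant, fragments are never edited twice, and (with conversion_buffer > 0)
# a fragment with a pre-existing mismatch near the edit site is ineligible, so
# an edited variant can never merge with a neighbouring error into a
# higher-order allele ("variant conversion").

#' Plan which fragments receive which variants
#'
#' For each requested variant, the realized count is
#' `round(target_frequency x fragment coverage at pos)` (half away from zero,
#' floored at 1 when the position is covered). Fragments are sampled uniformly
#' without replacement among those that (a) cover every edited position in at
#' least one mate, (b) carry no pre-existing mismatch within
#' `conversion_buffer` nt of any edited position, and (c) are not claimed by
#' another variant. Requests at the same coordinate therefore receive disjoint
#' fragment sets.
#'
#' @param specs Tibble with `pos` (1-based), `ref`, `alt`,
#'   `target_frequency` (each in (0,1)).
#' @param alignments Alignments tibble (see [align_reads()]).
#' @param ref A [transcript_reference()].
#' @param seed Integer seed for fragment sampling.
#' @param conversion_buffer Buffer in nt for the conversion prohibition; 0
#'   disables it. Default 3 (the caller's MNP merge window).
#' @return An object of class `edit_plan`: `specs` (with `coverage`,
#'   `realized_count`, `achieved_count`, `unplaceable`), `targets`
#'   (fragment-to-variant assignments), `seed`, `conversion_buffer`.
#' @export
plan_edits <- function(specs, alignments, ref, seed = 1L,
                       conversion_buffer = 3L) {
  stopifnot(all(c("pos", "ref", "alt", "target_frequency") %in% names(specs)))
  if (any(specs$target_frequency <= 0 | specs$target_frequency >= 1)) {
    stop("target_frequency must lie in (0, 1)")
  }
  if (any(nchar(specs$ref) != nchar(specs$alt))) {
    stop("ref and alt alleles must have equal length")
  }
  if (nrow(specs) == 0L) {
    return(structure(
      list(
        specs = dplyr::mutate(specs, coverage = integer(0),
          realized_count = integer(0), achieved_count = integer(0),
          unplaceable = logical(0)),
        targets = tibble(spec_idx = integer(0), read_id = character(0),
                         pos = integer(0), ref = character(0),
                         alt = character(0)),
        seed = seed, conversion_buffer = as.integer(conversion_buffer)
      ),
      class = "edit_plan"
    ))
  }
  obs <- ref_seq_at(ref, specs$pos, specs$pos + nchar(specs$ref) - 1L)
  if (any(obs != specs$ref)) {
    bad <- which(obs != specs$ref)[1]
    stop(sprintf(
      "spec %d: reference at pos %d is '%s', not '%s'",
      bad, specs$pos[bad], obs[bad], specs$ref[bad]
    ))
  }
  set.seed(derive_seed(seed, 31L))

  mm <- mismatch_table(alignments, ref)
  mm_by_frag <- split(mm$ref_pos, mm$read_id)

  # per-fragment mate spans
  spans <- alignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      s1 = .data$start[match(1L, .data$mate)],
      e1 = .data$end[match(1L, .data$mate)],
      s2 = .data$start[match(2L, .data$mate)],
      e2 = .data$end[match(2L, .data$mate)],
      .groups = "drop"
    )

  claimed <- character(0)
  targets <- list()
  out <- specs
  out$coverage <- NA_integer_
  out$realized_count <- NA_integer_
  out$achieved_count <- NA_integer_
  out$unplaceable <- FALSE

  for (i in seq_len(nrow(specs))) {
    p1 <- specs$pos[i]
    p2 <- p1 + nchar(specs$ref[i]) - 1L
    cov1 <- !is.na(spans$s1) & spans$s1 <= p1 & spans$e1 >= p1
    cov2 <- !is.na(spans$s2) & spans$s2 <= p1 & spans$e2 >= p1
    coverage <- sum(cov1 | cov2)
    full1 <- !is.na(spans$s1) & spans$s1 <= p1 & spans$e1 >= p2
    full2 <- !is.na(spans$s2) & spans$s2 <= p1 & spans$e2 >= p2
    eligible <- spans$read_id[full1 | full2]
    b <- as.integer(conversion_buffer)
    if (b > 0L && length(eligible)) {
      lo <- p1 - b
      hi <- p2 + b
      dirty <- vapply(eligible, function(f) {
        mp <- mm_by_frag[[f]]
        !is.null(mp) && any(mp >= lo & mp <= hi)
      }, logical(1))
      eligible <- eligible[!dirty]
    }
    eligible <- setdiff(eligible, claimed)
    realized <- if (coverage > 0L) {
      max(1L, as.integer(round_half_away(specs$target_frequency[i] * coverage)))
    } else {
      0L
    }
    take <- min(realized, length(eligible))
    chosen <- if (take > 0L) sort(sample(sort(eligible), take)) else character(0)
    claimed <- c(claimed, chosen)
    out$coverage[i] <- coverage
    out$realized_count[i] <- realized
    out$achieved_count[i] <- take
    out$unplaceable[i] <- take < realized || realized == 0L
    if (take > 0L) {
      targets[[i]] <- tibble(
        spec_idx = i, read_id = chosen,
        pos = p1, ref = specs$ref[i], alt = specs$alt[i]
      )
    }
  }
  if (any(out$unplaceable)) {
    warning(sprintf(
      "%d variant(s) unplaceable at the requested count; achieved counts reported",
      sum(out$unplaceable)
    ))
  }
  structure(
    list(
      specs = out,
      targets = if (length(targets)) dplyr::bind_rows(targets) else
        tibble(spec_idx = integer(0), read_id = character(0),
               pos = integer(0), ref = character(0), alt = character(0)),
      seed = seed, conversion_buffer = as.integer(conversion_buffer)
    ),
    class = "edit_plan"
  )
}

#' Pre-existing mismatches of every mate against the reference
#' @noRd
mismatch_table <- function(alignments, ref) {
  refraw <- charToRaw(ref$sequence)
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    sraw <- charToRaw(alignments$seq[i])
    d <- which(refraw[alignments$start[i]:alignments$end[i]] != sraw)
    if (length(d)) {
      rows[[i]] <- tibble(
        read_id = alignments$read_id[i], mate = alignments$mate[i],
        ref_pos = alignments$start[i] + d - 1L,
        read_base = substring(alignments$seq[i], d, d)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      read_id = character(0), mate = integer(0),
      ref_pos = integer(0), read_base = character(0)
    )
  }
  out
}

#' Apply an edit plan to alignments, emitting edited reads and a truth set
#'
#' Every targeted mate that covers (fully or partially) the edited reference
#' positions has the alternate bases substituted with base qualities
#' preserved; all other reads pass through byte-identical. A mate partially
#' covering an MNP is edited on the covered prefix/suffix so the two mates
#' never disagree with the planned allele.
#'
#' @param plan An `edit_plan` from [plan_edits()].
#' @param alignments The same alignments tibble the plan was built from.
#' @return A list: `reads` (read pairs tibble, sequencer orientation),
#'   `truth` (one row per spec with `realized_count` = fragments actually
#'   edited and `realized_frequency` = count / fragment coverage at `pos`).
#' @export
apply_edits <- function(plan, alignments) {
  stopifnot(inherits(plan, "edit_plan"))
  aln <- alignments
  tg <- plan$targets
  if (nrow(tg)) {
    key <- split(seq_len(nrow(tg)), tg$read_id)
    touch <- which(aln$read_id %in% tg$read_id)
    for (i in touch) {
      for (j in key[[aln$read_id[i]]]) {
        p1 <- tg$pos[j]
        len <- nchar(tg$ref[j])
        # covered sub-interval of the allele for this mate
        lo <- max(p1, aln$start[i])
        hi <- min(p1 + len - 1L, aln$end[i])
        if (lo > hi) next
        off_read <- lo - aln$start[i] + 1L
        off_alt <- lo - p1 + 1L
        if (off_read < 1L || off_read + (hi - lo) > nchar(aln$seq[i])) {
          stop("edit coordinates fall outside mate ", aln$read_id[i])
        }
        substr(aln$seq[i], off_read, off_read + (hi - lo)) <-
          substr(tg$alt[j], off_alt, off_alt + (hi - lo))
      }
    }
  }
  truth <- plan$specs
  truth$realized_count <- truth$achieved_count
  truth$realized_frequency <- ifelse(
    truth$coverage > 0L, truth$realized_count / truth$coverage, NA_real_
  )
  list(reads = alignments_to_reads(aln), truth = truth)
}

#' Convert an alignments tibble back to sequencer-orientation read pairs
#' @noRd
alignments_to_reads <- function(aln) {
  w <- tidyr::pivot_wider(
    dplyr::select(aln, "read_id", "mate", "strand", "seq", "qual"),
    names_from = "mate", values_from = c("strand", "seq", "qual")
  )
  flip <- function(seqs, quals, strands) {
    neg <- strands == "-"
    seqs[neg] <- revcomp(seqs[neg])
    quals[neg] <- vapply(quals[neg], function(q) intToUtf8(rev(utf8ToInt(q))),
      character(1)
    )
    list(seqs, quals)
  }
  f1 <- flip(w$seq_1, w$qual_1, w$strand_1)
  f2 <- flip(w$seq_2, w$qual_2, w$strand_2)
  out <- tibble(
    read_id = w$read_id,
    r1_seq = f1[[1]], r1_qual = f1[[2]],
    r2_seq = f2[[1]], r2_qual = f2[[2]]
  )
  umi <- unique(dplyr::select(aln, "read_id", dplyr::any_of("umi")))
  if ("umi" %in% names(umi)) out <- dplyr::left_join(out, umi, by = "read_id")
  out
}

#' Re-align edited reads end-to-end
#'
#' Produces valid alignments (with mismatch counts) for edited reads, for
#' downstream calling or SAM export. Uses the internal gapless aligner by
#' default; pass `template` to delegate to an external aligner.
#'
#' @param reads Read pairs tibble from [apply_edits()].
#' @param ref A [transcript_reference()].
#' @param template Optional external-aligner command template (see
#'   [external_aligner()]).
#' @return Alignments tibble.
#' @export
realign_edited <- function(reads, ref, template = NULL) {
  if (nrow(reads) == 0L) {
    return(tibble(
      read_id = character(0), mate = integer(0), strand = character(0),
      start = integer(0), end = integer(0), seq = character(0),
      qual = character(0), nm = integer(0)
    ))
  }
  if (!is.null(template)) {
    r1 <- tempfile(fileext = "_R1.fastq")
    r2 <- tempfile(fileext = "_R2.fastq")
    sam <- tempfile(fileext = ".sam")
    write_fastq(reads, r1, r2)
    external_aligner(template, r1, r2, ref, sam)
    return(read_alignments_sam(sam))
  }
  align_reads(reads, ref)
}
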