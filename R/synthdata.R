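# Synthetic targeted-sequencing libraries: amplicon and RACE-like designs over
# a coding reference, with UMIs, PCR duplicates, substitution-biased errors and
# a full provenance ledger. Everything downstream (simulator, caller, error
# models) is exercised against these libraries.
#
# Error model: the six strand-collapsed substitution-class rates are applied at
# the *molecule* (fragment) level, so both mates of a pair inherit the error --
# this is the library-preparation (PCR) error channel that survives
# mate-concordance filtering. A separate `read_error_rate` models sequencer
# miscalls on individual reads (mostly removed by concordance), and
# `primer_error_rate` models oligo synthesis errors restricted to
# primer-derived read segments (removed by primer masking). Injected
# sequencer miscalls carry reduced base qualities (`error_bq_shift`).

SUB_CLASSES <- c(
  "A>C/T>G", "A>G/T>C", "A>T/T>A",
  "C>A/G>T", "C>G/G>C", "C>T/G>A"
)

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Strand-collapsed substitution class of ref>alt single-base changes
#'
#' Six levels, e.g. `"C>A/G>T"`; changes from G or T are folded onto their
#' complement.
#'
#' @param from,to Single reference and alternate bases (vectorised).
#' @return Character vector of class labels.
#' @export
substitution_class <- function(from, to) {
  flip <- from %in% c("G", "T")
  f <- ifelse(flip, COMP[from], from)
  t <- ifelse(flip, COMP[to], to)
  lab <- paste0(f, ">", t, "/", COMP[f], ">", COMP[t])
  stopifnot(all(lab %in% SUB_CLASSES | is.na(lab)))
  lab
}

#' Sequencing-error profile for the library generator
#'
#' @param rates Named numeric of per-base molecule-level error rates for the
#'   six substitution classes (see `substitution_class()`); each in
#'   \[0, 0.05\]. The default (all zero) yields error-free molecules.
#' @param read_error_rate Per-base sequencer miscall rate on individual reads.
#' @param primer_error_rate Per-base synthesis error rate within
#'   primer-derived segments.
#' @param bq_start,bq_decay,bq_sd Base-quality model: Phred at cycle 1, linear
#'   decay per cycle, Gaussian jitter.
#' @param error_bq_shift Phred shift applied to sequencer-miscall bases.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(rates = stats::setNames(numeric(6), SUB_CLASSES),
                          read_error_rate = 0,
                          primer_error_rate = 0,
                          bq_start = 37, bq_decay = 0.02, bq_sd = 0,
                          error_bq_shift = -12) {
  full <- stats::setNames(numeric(6), SUB_CLASSES)
  full[names(rates)] <- rates
  if (any(full < 0 | full > 0.05)) stop("class rates must lie in [0, 0.05]")
  structure(
    list(
      rates = full, read_error_rate = read_error_rate,
      primer_error_rate = primer_error_rate,
      bq_start = bq_start, bq_decay = bq_decay, bq_sd = bq_sd,
      error_bq_shift = error_bq_shift
    ),
    class = "error_profile"
  )
}

#' Library design: layout, read length, UMIs, duplication
#'
#' @param method `"amplicon"` (tiled primer pairs; fragments are amplicons) or
#'   `"race_like"` (one gene-specific primer end, one random end, stranded).
#' @param primers Primer tibble (`contig`, `start`, `end` 0-based half-open,
#'   `strand`, `name`). For amplicon designs, rows pair up as `<tile>_F` /
#'   `<tile>_R`. May be empty (single implicit fragment spanning the target,
#'   the full-overlap preset).
#' @param read_len Read length for both mates.
#' @param umi_len UMI length prepended to R1 (0 disables UMIs).
#' @param duplication_rate Expected number of extra PCR copies per fragment
#'   (Poisson).
#' @param fragment_len_mean,fragment_len_sd,fragment_len_min,fragment_len_max
#'   Truncated-normal fragment length model (RACE-like designs only).
#' @return An object of class `library_design`.
#' @export
library_design <- function(method = c("amplicon", "race_like"),
                           primers = empty_primers(),
                           read_len = 150L, umi_len = 0L,
                           duplication_rate = 0,
                           fragment_len_mean = 200, fragment_len_sd = 20,
                           fragment_len_min = 150, fragment_len_max = 250) {
  method <- match.arg(method)
  structure(
    list(
      method = method, primers = primers,
      read_len = as.integer(read_len), umi_len = as.integer(umi_len),
      duplication_rate = duplication_rate,
      fragment_len_mean = fragment_len_mean, fragment_len_sd = fragment_len_sd,
      fragment_len_min = fragment_len_min, fragment_len_max = fragment_len_max
    ),
    class = "library_design"
  )
}

#' @noRd
empty_primers <- function(contig = "tx1") {
  tibble(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), name = character(0)
  )
}

#' Tiled amplicon primer layout over a transcript
#'
#' Lays out forward/reverse primer pairs so amplicons of span `tile_span` tile
#' the target with the given overlap.
#'
#' @param ref A [transcript_reference()].
#' @param tile_span Amplicon span in nt (default: the read length assumption,
#'   150).
#' @param primer_len Primer length.
#' @param tile_overlap Overlap between adjacent amplicons (provides
#'   readthrough coverage over primer sites).
#' @return Primer tibble (0-based half-open, stranded).
#' @export
amplicon_tiles <- function(ref, tile_span = 150L, primer_len = 20L,
                           tile_overlap = 40L) {
  L <- nchar(ref$sequence)
  tile_span <- min(tile_span, L)
  if (L <= tile_span) {
    starts <- 0L
  } else {
    n_tiles <- max(2L, ceiling((L - tile_span) / (tile_span - tile_overlap)) + 1L)
    starts <- as.integer(round(seq(0L, L - tile_span, length.out = n_tiles)))
  }
  dplyr::bind_rows(purrr::imap(starts, function(s, i) {
    tibble(
      contig = ref$transcript_id,
      start = c(s, s + tile_span - primer_len),
      end = c(s + primer_len, s + tile_span),
      strand = c("+", "-"),
      name = paste0("tile", i, c("_F", "_R"))
    )
  }))
}

#' Gene-specific primer layout for a RACE-like design
#'
#' @param ref A [transcript_reference()].
#' @param spacing Spacing between gene-specific primers, nt.
#' @param primer_len Primer length.
#' @return Primer tibble with alternating +/- strand gene-specific primers.
#' @export
race_primers <- function(ref, spacing = 100L, primer_len = 20L) {
  L <- nchar(ref$sequence)
  starts <- seq(0L, max(0L, L - primer_len), by = spacing)
  strands <- rep(c("+", "-"), length.out = length(starts))
  tibble(
    contig = ref$transcript_id,
    start = as.integer(starts), end = as.integer(starts + primer_len),
    strand = strands,
    name = paste0("gsp", seq_along(starts))
  )
}

#' Random coding reference
#'
#' ATG start, random internal codons with no in-frame stops, terminal stop
#' codon. The whole sequence is CDS.
#'
#' @param length_codons Total codon count including start and stop (>= 10).
#' @param seed Integer seed.
#' @return A [transcript_reference()].
#' @export
make_reference <- function(length_codons, seed = 1L) {
  length_codons <- as.integer(length_codons)
  if (length_codons < 10L) stop("reference must be at least 10 codons")
  set.seed(derive_seed(seed, 11L))
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  internal <- sample(setdiff(codons, stops), length_codons - 2L, replace = TRUE)
  seq <- paste0("ATG", paste(internal, collapse = ""), sample(stops, 1L))
  transcript_reference(seq, 0L, nchar(seq), transcript_id = "synthtx")
}

#' Simulate a sequencing library from a design and error profile
#'
#' Draws fragments per the design, injects molecule-, read- and primer-channel
#' substitution errors at the profile's rates, emits UMIs and PCR duplicates,
#' and returns reads plus a complete provenance ledger. An all-zero profile
#' yields error-free reads.
#'
#' @param ref A [transcript_reference()].
#' @param design A [library_design()].
#' @param n_fragments Number of unique fragments (pre-duplication).
#' @param profile An [error_profile()].
#' @param seed Integer seed.
#' @return A list of class `mave_library`: `reads` (read pairs tibble, UMI
#'   already prepended to R1 when designed), `fragments`, `errors` (injected
#'   error ledger), `primers`, `design`, `ref`, `seed`.
#' @export
simulate_library <- function(ref, design, n_fragments, profile = error_profile(),
                             seed = 1L) {
  stopifnot(inherits(ref, "transcript_ref"), inherits(design, "library_design"))
  set.seed(derive_seed(seed, 21L))
  L <- nchar(ref$sequence)
  rl <- design$read_len
  n <- as.integer(n_fragments)

  pr <- design$primers
  pr1 <- if (nrow(pr)) dplyr::mutate(pr, s1 = .data$start + 1L, e1 = .data$end) else pr

  if (design$method == "amplicon") {
    if (nrow(pr)) {
      fw <- pr1[pr1$strand == "+", ]
      rv <- pr1[pr1$strand == "-", ]
      tile <- sub("_F$", "", fw$name)
      stopifnot(nrow(fw) == nrow(rv))
      idx <- sample.int(nrow(fw), n, replace = TRUE)
      fstart <- fw$s1[idx]
      fend <- rv$e1[idx]
      fstrand <- rep("+", n)
      ftile <- tile[idx]
      syn_left <- fw$e1[idx] # last 1-based pos of left synthetic segment
      syn_right <- rv$s1[idx] # first 1-based pos of right synthetic segment
    } else {
      fstart <- rep(1L, n)
      fend <- rep(L, n)
      fstrand <- rep("+", n)
      ftile <- rep(NA_character_, n)
      syn_left <- rep(0L, n)
      syn_right <- rep(L + 1L, n)
    }
  } else { # race_like
    if (!nrow(pr)) stop("RACE-like designs require gene-specific primers")
    idx <- sample.int(nrow(pr1), n, replace = TRUE)
    flen <- as.integer(pmin(
      pmax(
        round(stats::rnorm(n, design$fragment_len_mean, design$fragment_len_sd)),
        design$fragment_len_min
      ),
      design$fragment_len_max
    ))
    plus <- pr1$strand[idx] == "+"
    fstart <- ifelse(plus, pr1$s1[idx], pmax(1L, pr1$e1[idx] - flen + 1L))
    fend <- ifelse(plus, pmin(L, pr1$s1[idx] + flen - 1L), pr1$e1[idx])
    fstrand <- pr1$strand[idx]
    ftile <- pr1$name[idx]
    syn_left <- ifelse(plus, pr1$e1[idx], 0L)
    syn_right <- ifelse(plus, L + 1L, pr1$s1[idx])
  }
  fstart <- as.integer(fstart)
  fend <- as.integer(fend)
  flens <- fend - fstart + 1L

  fragment_id <- sprintf("f%06d", seq_len(n))
  umi <- if (design$umi_len > 0L) {
    vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, design$umi_len, replace = TRUE), collapse = "")
    }, character(1))
  } else {
    rep(NA_character_, n)
  }

  # --- molecule-level errors (library-prep channel + primer channel)
  refv <- strsplit(ref$sequence, "")[[1]]
  base_tot <- vapply(DNA_BASES, function(b) {
    sum(profile$rates[substitution_class(rep(b, 3), setdiff(DNA_BASES, b))])
  }, numeric(1))

  frag_of <- rep.int(seq_len(n), flens)
  ref_pos <- rep.int(fstart, flens) + sequence(flens) - 1L
  synthetic <- ref_pos <= rep.int(as.integer(syn_left), flens) |
    ref_pos >= rep.int(as.integer(syn_right), flens)
  b <- refv[ref_pos]
  u <- stats::runif(length(ref_pos))
  rate <- ifelse(synthetic, profile$primer_error_rate, base_tot[b])
  hit <- which(u < rate)

  mol_err <- tibble(
    fragment_idx = frag_of[hit], ref_pos = ref_pos[hit],
    from = b[hit], channel = ifelse(synthetic[hit], "primer", "molecule")
  )
  if (nrow(mol_err)) {
    mol_err$to <- vapply(seq_len(nrow(mol_err)), function(i) {
      alts <- setdiff(DNA_BASES, mol_err$from[i])
      if (mol_err$channel[i] == "primer") {
        sample(alts, 1L)
      } else {
        w <- profile$rates[substitution_class(rep(mol_err$from[i], 3), alts)]
        sample(alts, 1L, prob = w)
      }
    }, character(1))
  } else {
    mol_err$to <- character(0)
  }

  # fragment sequences with molecule errors applied
  fseq <- substring(ref$sequence, fstart, fend)
  if (nrow(mol_err)) {
    for (i in seq_len(nrow(mol_err))) {
      fi <- mol_err$fragment_idx[i]
      off <- mol_err$ref_pos[i] - fstart[fi] + 1L
      substr(fseq[fi], off, off) <- mol_err$to[i]
    }
  }

  # --- PCR duplicates and reads
  copies <- 1L + stats::rpois(n, design$duplication_rate)
  copy_frag <- rep.int(seq_len(n), copies)
  copy_num <- sequence(copies)
  read_id <- sprintf("%s.d%d", fragment_id[copy_frag], copy_num)
  nc <- length(copy_frag)

  rl1 <- pmin(rl, flens[copy_frag])
  cstart <- fstart[copy_frag]
  cend <- fend[copy_frag]
  cplus <- fstrand[copy_frag] == "+"

  # aligned-orientation substrings for each mate
  left_seq <- substring(fseq[copy_frag], 1L, rl1)
  right_seq <- substring(fseq[copy_frag], flens[copy_frag] - rl1 + 1L, flens[copy_frag])
  r1_seq <- ifelse(cplus, left_seq, revcomp(right_seq))
  r2_seq <- ifelse(cplus, revcomp(right_seq), left_seq)
  # reference positions of R1/R2 5' ends and spans (for ledger mapping)
  r1_start <- ifelse(cplus, cstart, cend - rl1 + 1L)
  r2_start <- ifelse(cplus, cend - rl1 + 1L, cstart)

  # --- read-level sequencer miscalls (never in synthetic segments)
  read_err <- list()
  if (profile$read_error_rate > 0) {
    for (mate in 1:2) {
      seqs <- if (mate == 1L) r1_seq else r2_seq
      n_bases <- nchar(seqs)
      cyc_read <- rep.int(seq_len(nc), n_bases)
      cycle <- sequence(n_bases)
      # reference position of each cycle
      mstart <- if (mate == 1L) r1_start else r2_start
      mplus <- if (mate == 1L) cplus else !cplus
      rp <- ifelse(mplus[cyc_read], mstart[cyc_read] + cycle - 1L,
        mstart[cyc_read] + n_bases[cyc_read] - cycle
      )
      syn <- rp <= syn_left[copy_frag[cyc_read]] |
        rp >= syn_right[copy_frag[cyc_read]]
      hit <- which(!syn & stats::runif(length(cycle)) < profile$read_error_rate)
      if (length(hit)) {
        ri <- cyc_read[hit]
        cyc <- cycle[hit]
        fromr <- substr(seqs[ri], cyc, cyc) # note: recycled scalar ops below
        fromr <- vapply(seq_along(hit), function(j) substr(seqs[ri[j]], cyc[j], cyc[j]), character(1))
        tor <- vapply(fromr, function(fb) sample(setdiff(DNA_BASES, fb), 1L), character(1))
        for (j in seq_along(hit)) {
          substr(seqs[ri[j]], cyc[j], cyc[j]) <- tor[j]
        }
        if (mate == 1L) r1_seq <- seqs else r2_seq <- seqs
        read_err[[mate]] <- tibble(
          read_idx = ri, mate = mate, cycle = cyc,
          ref_pos = rp[hit], from_read = fromr, to_read = tor
        )
      }
    }
  }
  read_err <- dplyr::bind_rows(read_err)
  if (nrow(read_err) == 0L) {
    read_err <- tibble(
      read_idx = integer(0), mate = integer(0), cycle = integer(0),
      ref_pos = integer(0), from_read = character(0), to_read = character(0)
    )
  }

  # --- base qualities
  make_quals <- function(seqs, err_tbl) {
    lens <- nchar(seqs)
    if (profile$bq_sd == 0 && nrow(err_tbl) == 0L) {
      by_len <- vapply(sort(unique(lens)), function(l) {
        q <- pmin(40L, pmax(2L, as.integer(round(
          profile$bq_start - profile$bq_decay * (seq_len(l) - 1L)
        ))))
        intToUtf8(q + 33L)
      }, character(1))
      names(by_len) <- as.character(sort(unique(lens)))
      return(unname(by_len[as.character(lens)]))
    }
    ridx <- rep.int(seq_along(seqs), lens)
    cyc <- sequence(lens)
    q <- profile$bq_start - profile$bq_decay * (cyc - 1L) +
      stats::rnorm(length(cyc), 0, profile$bq_sd)
    if (nrow(err_tbl)) {
      key <- paste(err_tbl$read_idx, err_tbl$cycle)
      shift <- match(paste(ridx, cyc), key)
      q[!is.na(shift)] <- q[!is.na(shift)] + profile$error_bq_shift
    }
    q <- pmin(40L, pmax(2L, as.integer(round(q))))
    vapply(split(q, ridx), function(v) intToUtf8(v + 33L), character(1),
      USE.NAMES = FALSE
    )
  }
  r1_qual <- make_quals(r1_seq, dplyr::filter(read_err, .data$mate == 1L))
  r2_qual <- make_quals(r2_seq, dplyr::filter(read_err, .data$mate == 2L))

  # --- UMI prepended to R1 as sequenced
  if (design$umi_len > 0L) {
    r1_seq <- paste0(umi[copy_frag], r1_seq)
    r1_qual <- paste0(strrep(rawToChar(as.raw(37L + 33L)), design$umi_len), r1_qual)
  }

  errors <- dplyr::bind_rows(
    if (nrow(mol_err)) {
      dplyr::mutate(mol_err,
        fragment_id = fragment_id[.data$fragment_idx],
        class = substitution_class(.data$from, .data$to),
        read_id = NA_character_, mate = NA_integer_, cycle = NA_integer_
      )
    },
    if (nrow(read_err)) {
      # express read-level errors on the reference strand for class accounting
      mplus <- ifelse(read_err$mate == 1L, cplus[read_err$read_idx], !cplus[read_err$read_idx])
      fr <- ifelse(mplus, read_err$from_read, COMP[read_err$from_read])
      to <- ifelse(mplus, read_err$to_read, COMP[read_err$to_read])
      tibble(
        fragment_idx = copy_frag[read_err$read_idx],
        fragment_id = fragment_id[copy_frag[read_err$read_idx]],
        read_id = read_id[read_err$read_idx],
        mate = read_err$mate, cycle = read_err$cycle,
        ref_pos = read_err$ref_pos,
        from = unname(fr), to = unname(to),
        class = substitution_class(fr, to),
        channel = "read"
      )
    }
  )
  if (is.null(errors) || nrow(errors) == 0L) {
    errors <- tibble(
      fragment_idx = integer(0), fragment_id = character(0),
      read_id = character(0), mate = integer(0), cycle = integer(0),
      ref_pos = integer(0), from = character(0), to = character(0),
      class = character(0), channel = character(0)
    )
  }

  reads <- tibble(
    read_id = read_id,
    fragment_id = fragment_id[copy_frag],
    umi = umi[copy_frag],
    r1_seq = r1_seq, r1_qual = r1_qual,
    r2_seq = r2_seq, r2_qual = r2_qual
  )
  fragments <- tibble(
    fragment_id = fragment_id, start = fstart, end = fend,
    strand = fstrand, tile = ftile, umi = umi, n_copies = copies
  )
  structure(
    list(
      reads = reads, fragments = fragments, errors = errors,
      primers = pr, design = design, ref = ref, seed = seed
    ),
    class = "mave_library"
  )
}

#' @export
print.mave_library <- function(x, ...) {
  cat(sprintf(
    "<mave_library> %d fragments, %d read pairs, %d injected errors (%s design)\n",
    nrow(x$fragments), nrow(x$reads), nrow(x$errors), x$design$method
  ))
  invisible(x)
}

#' Provenance-based alignments for a simulated library
#'
#' Converts a `mave_library` to an alignments tibble directly from the
#' generator's ledger (every read's origin is known exactly), bypassing the
#' aligner. UMI bases prepended to R1 are not part of the alignment.
#'
#' @param lib A `mave_library` from [simulate_library()].
#' @return Alignments tibble (same layout as [align_reads()]).
#' @export
ledger_alignments <- function(lib) {
  fr <- lib$fragments
  reads <- lib$reads
  fidx <- match(reads$fragment_id, fr$fragment_id)
  rl <- lib$design$read_len
  flen <- fr$end[fidx] - fr$start[fidx] + 1L
  rl1 <- pmin(rl, flen)
  plus <- fr$strand[fidx] == "+"
  ul <- lib$design$umi_len

  r1_sequenced <- substring(reads$r1_seq, ul + 1L)
  r1_qual <- substring(reads$r1_qual, ul + 1L)
  mk <- function(mate, seqs, quals) {
    mplus <- if (mate == 1L) plus else !plus
    start <- ifelse(
      xor(mate == 2L, plus),
      fr$start[fidx], fr$end[fidx] - rl1 + 1L
    )
    aseq <- ifelse(mplus, seqs, revcomp(seqs))
    aqual <- quals
    neg <- !mplus
    if (any(neg)) {
      aqual[neg] <- vapply(quals[neg], function(q) intToUtf8(rev(utf8ToInt(q))),
        character(1)
      )
    }
    tibble(
      read_id = reads$read_id, mate = mate,
      strand = ifelse(mplus, "+", "-"),
      start = as.integer(start), end = as.integer(start + rl1 - 1L),
      seq = aseq, qual = aqual,
      umi = reads$umi
    )
  }
  a1 <- mk(1L, r1_sequenced, r1_qual)
  a2 <- mk(2L, reads$r2_seq, reads$r2_qual)
  out <- dplyr::arrange(dplyr::bind_rows(a1, a2), .data$read_id, .data$mate)
  out$nm <- alignment_nm(out, lib$ref)
  dplyr::relocate(out, "nm", .after = "qual")
}

#' Per-mate mismatch count against the reference
#' @noRd
alignment_nm <- function(aln, ref) {
  refraw <- charToRaw(ref$sequence)
  vapply(seq_len(nrow(aln)), function(i) {
    sum(refraw[aln$start[i]:aln$end[i]] != charToRaw(aln$seq[i]))
  }, integer(1))
}

#' Write primers to 6-column BED
#'
#' @param primers Primer tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_bed <- function(primers, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    primers$contig, primers$start, primers$end, primers$name,
    0L, primers$strand
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a 6-column primer BED
#'
#' @param path BED path.
#' @return Primer tibble (0-based half-open).
#' @export
read_primer_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
    col.names = c("contig", "start", "end", "name", "score", "strand"),
    colClasses = c("character", "integer", "integer", "character", "integer", "character")
  )
  tibble(
    contig = x$contig, start = x$start, end = x$end,
    strand = x$strand, name = x$name
  )
}
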