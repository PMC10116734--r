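# Shared fixtures and independent oracles, all built in code.

# A fixed 30-nt reference (10 codons), whole sequence CDS.
tiny_ref <- function() {
  transcript_reference("ATGGCTAAGCGATCCTTAGACCAGTGGTAA", 0, 30, "toy")
}

const_qual <- function(n, q = 37L) strrep(rawToChar(as.raw(q + 33L)), n)

# Build one proper pair of gapless alignments by reference coordinates.
# Mismatches are introduced by giving explicit sequences; qualities default
# to Q37 everywhere.
toy_pair <- function(ref, read_id, s1, e1, s2, e2,
                     seq1 = NULL, seq2 = NULL, q1 = NULL, q2 = NULL,
                     strand1 = "+", umi = NA_character_) {
  sub <- function(a, b) substr(ref$sequence, a, b)
  seq1 <- seq1 %||% sub(s1, e1)
  seq2 <- seq2 %||% sub(s2, e2)
  q1 <- q1 %||% const_qual(nchar(seq1))
  q2 <- q2 %||% const_qual(nchar(seq2))
  aln <- tibble::tibble(
    read_id = read_id, mate = c(1L, 2L),
    strand = c(strand1, if (strand1 == "+") "-" else "+"),
    start = c(s1, s2), end = c(e1, e2),
    seq = c(seq1, seq2), qual = c(q1, q2),
    umi = umi
  )
  aln$nm <- mavecall:::alignment_nm(aln, ref)
  aln
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force variant caller (oracle) ----------------------
# Straightforward per-position loops; no shared code with the package paths
# it checks beyond trivial accessors.
oracle_call <- function(alignments, ref, min_count = 2L, min_bq = 30L,
                        max_nm = 10L) {
  refv <- strsplit(ref$sequence, "")[[1]]
  L <- length(refv)
  pairs <- split(seq_len(nrow(alignments)), alignments$read_id)
  comp_rows <- list()
  # coverage: per position, fragments with >=1 unmasked base across it
  covmat <- integer(L)
  for (ids in pairs) {
    a <- alignments[ids, ]
    covered <- rep(FALSE, L)
    for (r in seq_len(nrow(a))) {
      qs <- utf8ToInt(a$qual[r]) - 33L
      for (p in a$start[r]:a$end[r]) {
        if (qs[p - a$start[r] + 1L] > 0L) covered[p] <- TRUE
      }
    }
    covmat <- covmat + covered
  }
  for (ids in pairs) {
    a <- alignments[ids, ]
    if (nrow(a) != 2L) next
    nm <- integer(2)
    for (r in 1:2) {
      sv <- strsplit(a$seq[r], "")[[1]]
      nm[r] <- sum(sv != refv[a$start[r]:a$end[r]])
    }
    if (any(nm > max_nm)) next
    lo <- max(a$start)
    hi <- min(a$end)
    if (lo > hi) next
    mm_pos <- integer(0)
    mm_alt <- character(0)
    for (p in lo:hi) {
      b1 <- substr(a$seq[1], p - a$start[1] + 1L, p - a$start[1] + 1L)
      b2 <- substr(a$seq[2], p - a$start[2] + 1L, p - a$start[2] + 1L)
      q1 <- utf8ToInt(substr(a$qual[1], p - a$start[1] + 1L, p - a$start[1] + 1L)) - 33L
      q2 <- utf8ToInt(substr(a$qual[2], p - a$start[2] + 1L, p - a$start[2] + 1L)) - 33L
      if (b1 == b2 && b1 != refv[p] && b1 %in% c("A", "C", "G", "T") &&
          q1 >= max(min_bq, 1L) && q2 >= max(min_bq, 1L)) {
        mm_pos <- c(mm_pos, p)
        mm_alt <- c(mm_alt, b1)
      }
    }
    if (!length(mm_pos)) next
    for (blk in oracle_merge(mm_pos)) {
      p1 <- mm_pos[blk[1]]
      p2 <- mm_pos[blk[length(blk)]]
      rr <- paste(refv[p1:p2], collapse = "")
      aa <- refv[p1:p2]
      for (k in blk) aa[mm_pos[k] - p1 + 1L] <- mm_alt[k]
      comp_rows[[length(comp_rows) + 1L]] <- tibble::tibble(
        read_id = a$read_id[1], pos = p1, ref = rr,
        alt = paste(aa, collapse = "")
      )
    }
  }
  if (!length(comp_rows)) {
    return(tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), count = integer(0),
                          frequency = numeric(0)))
  }
  comp <- dplyr::bind_rows(comp_rows)
  agg <- dplyr::summarise(
    dplyr::group_by(comp, pos, ref, alt),
    count = dplyr::n_distinct(read_id), .groups = "drop"
  )
  agg <- agg[agg$count >= min_count, ]
  agg$frequency <- agg$count / covmat[agg$pos]
  dplyr::arrange(agg, pos, ref, alt)
}

# Exhaustive leftmost-maximal partition of sorted mismatch positions into
# blocks of reference span <= 3 nt.
oracle_merge <- function(pos) {
  n <- length(pos)
  if (n == 0L) return(list())
  partitions <- function(idx) {
    if (!length(idx)) return(list(list()))
    out <- list()
    for (k in seq_along(idx)) {
      block <- idx[1:k]
      if (pos[idx[k]] - pos[idx[1]] > 2L) break
      for (rest in partitions(idx[-(1:k)])) {
        out[[length(out) + 1L]] <- c(list(block), rest)
      }
    }
    out
  }
  all_parts <- partitions(seq_len(n))
  # leftmost-maximal: lexicographically largest first-block sizes
  sizes <- lapply(all_parts, function(pp) vapply(pp, length, integer(1)))
  best <- 1L
  for (i in seq_along(all_parts)[-1]) {
    a <- sizes[[i]]
    b <- sizes[[best]]
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] != b[k]) {
        if (a[k] > b[k]) best <- i
        break
      }
    }
  }
  all_parts[[best]]
}

# Random toy alignment sets for the oracle-equivalence corpus.
random_toy_set <- function(ref, n_pairs, seed, p_mismatch = 0.08,
                           mask_first = 0L) {
  set.seed(seed)
  L <- nchar(ref$sequence)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    s1 <- sample(1:(L - 14L), 1)
    e1 <- min(L, s1 + sample(10:20, 1))
    s2 <- max(1L, s1 - sample(0:4, 1))
    e2 <- min(L, e1 + sample(0:4, 1))
    mut <- function(s, a, b) {
      v <- strsplit(substr(ref$sequence, a, b), "")[[1]]
      for (k in seq_along(v)) {
        if (stats::runif(1) < p_mismatch) {
          v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1)
        }
      }
      paste(v, collapse = "")
    }
    sq1 <- mut(ref$sequence, s1, e1)
    sq2 <- mut(ref$sequence, s2, e2)
    # occasionally make mates agree on a mismatch (concordant candidates)
    if (stats::runif(1) < 0.8) {
      p <- sample(max(s1, s2):min(e1, e2), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(ref$sequence, p, p)), 1)
      substr(sq1, p - s1 + 1L, p - s1 + 1L) <- b
      substr(sq2, p - s2 + 1L, p - s2 + 1L) <- b
    }
    q1 <- const_qual(nchar(sq1))
    q2 <- const_qual(nchar(sq2))
    if (mask_first > 0L && i %% 3L == 0L) {
      substr(q1, 1L, mask_first) <- strrep("!", mask_first)
    }
    rows[[i]] <- toy_pair(ref, sprintf("t%03d", i), s1, e1, s2, e2,
                          seq1 = sq1, seq2 = sq2, q1 = q1, q2 = q2)
  }
  dplyr::bind_rows(rows)
}

# A clean record template mimicking an annotated call row: an NNK-matching
# single-codon SNP at the third base of codon 3.
clean_record <- function(tref) {
  rb <- substr(tref$sequence, 9, 9)
  tibble::tibble(
    pos = 9L, ref = rb,
    alt = setdiff(c("G", "T"), rb)[1],
    variant_type = "SNP", count = 5L, frequency = 1e-3,
    n_plus = 3L, n_minus = 2L,
    matches_signature = TRUE, multi_codon = FALSE,
    aa_change = "Xxx3Yyy", error_prob = 0.1
  )
}

toy_examples <- function(n = 120, separable = TRUE, seed = 1) {
  set.seed(seed)
  lab <- factor(rep(c("error", "true_variant"), each = n / 2),
                levels = c("error", "true_variant"))
  shift <- if (separable) 8 else 0
  tibble::tibble(
    label = lab,
    # decisive features take one exact value per class (wide margin, no
    # boundary ambiguity for any model family); one feature is pure noise
    log10_frequency = ifelse(lab == "error", -4, -4 + shift / 4),
    r1_median_bq = ifelse(lab == "error", 25, 25 + shift),
    r2_median_bq = stats::rnorm(n, 30, 1),
    r2_median_nm = ifelse(lab == "error", 3, 1)
  )
}
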