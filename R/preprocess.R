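# Read preprocessing between FASTQ and variant calling: UMI extraction,
# optional trimming, primer base-quality masking and UMI directional-adjacency
# consensus deduplication.

#' Extract UMIs from the R1 5' end into a column (and the read name)
#'
#' @param reads Read pairs tibble.
#' @param umi_pattern Either an integer UMI length or an anchored regex such
#'   as `"(?P<umi_1>[ATCGN]{16})"` (the `{n}` quantifier gives the length).
#'   Length 0 returns the input unchanged.
#' @return Read pairs tibble with the UMI removed from `r1_seq`/`r1_qual`,
#'   stored in `umi` and appended to `read_id` after `"_"`. Pairs whose R1 is
#'   shorter than the UMI are dropped; the count is in attribute `n_dropped`.
#' @export
extract_umis <- function(reads, umi_pattern) {
  len <- if (is.numeric(umi_pattern)) {
    as.integer(umi_pattern)
  } else {
    m <- regmatches(umi_pattern, regexpr("\\{(\\d+)\\}", umi_pattern))
    if (!length(m)) stop("cannot determine UMI length from pattern")
    as.integer(gsub("[{}]", "", m))
  }
  if (len == 0L) {
    attr(reads, "n_dropped") <- 0L
    return(reads)
  }
  short <- nchar(reads$r1_seq) < len
  out <- reads[!short, ]
  out$umi <- substr(out$r1_seq, 1L, len)
  out$r1_seq <- substring(out$r1_seq, len + 1L)
  out$r1_qual <- substring(out$r1_qual, len + 1L)
  out$read_id <- paste0(out$read_id, "_", out$umi)
  attr(out, "n_dropped") <- sum(short)
  out
}

#' Adapter/quality trimming (delegated)
#'
#' Pass-through by default; when `use_fastp = TRUE`, delegates to the fastp
#' tool for adapter and 3' quality trimming.
#'
#' @param reads Read pairs tibble.
#' @param use_fastp Run fastp (must be on PATH)?
#' @param args Extra fastp arguments.
#' @return Read pairs tibble.
#' @export
trim_reads <- function(reads, use_fastp = FALSE, args = "") {
  if (!use_fastp) return(reads)
  if (!nzchar(Sys.which("fastp"))) stop("fastp not found on PATH")
  r1 <- tempfile(fileext = "_R1.fastq")
  r2 <- tempfile(fileext = "_R2.fastq")
  o1 <- tempfile(fileext = "_R1.trim.fastq")
  o2 <- tempfile(fileext = "_R2.trim.fastq")
  write_fastq(reads, r1, r2)
  status <- system2("fastp", c(
    "-i", r1, "-I", r2, "-o", o1, "-O", o2,
    "--json", tempfile(), "--html", tempfile(), args
  ), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("fastp exited with status ", status)
  out <- read_fastq(o1, o2)
  if ("umi" %in% names(reads)) {
    out <- dplyr::left_join(out, dplyr::select(reads, "read_id", "umi"),
      by = "read_id"
    )
  }
  out
}

#' Primer base-quality masking
#'
#' Determines, for each mate independently, which primers originated it:
#' (1) a same-strand primer whose aligned span (extended by a buffer upstream
#' of the primer 5' end) contains the read 5' end, or (2) an opposite-strand
#' primer whose span (same extension) contains the read 3' end. Read bases
#' overlapping an originating primer's aligned span get base quality 0; those
#' bases are excluded from variant calling and fragment coverage. The buffer
#' is 15 nt for amplicon designs and 3 nt for RACE-like designs. Base calls
#' are never changed; pre-mask qualities are kept in `qual_premask`.
#'
#' @param alignments Alignments tibble.
#' @param primers Primer tibble (0-based half-open, stranded).
#' @param method `"amplicon"` or `"race_like"` (sets the buffer).
#' @return Masked alignments; attribute `mask_report` is a tibble with one
#'   row per masked mate (`read_id`, `mate`, `primers`, `n_masked`).
#' @export
mask_primers <- function(alignments, primers,
                         method = c("amplicon", "race_like")) {
  method <- match.arg(method)
  buffer <- if (method == "amplicon") 15L else 3L
  if (nrow(primers) == 0L) {
    attr(alignments, "mask_report") <- tibble(
      read_id = character(0), mate = integer(0),
      primers = character(0), n_masked = integer(0)
    )
    return(alignments)
  }
  if (any(!nzchar(alignments$qual))) stop("alignments carry no base qualities")
  p <- dplyr::mutate(primers, s1 = .data$start + 1L, e1 = .data$end)
  # window containing a read end for the origination test: the aligned primer
  # span plus `buffer` nt upstream of the primer 5' end
  p$lo <- p$s1 - ifelse(p$strand == "+", buffer, 0L)
  p$hi <- p$e1 + ifelse(p$strand == "-", buffer, 0L)

  aln <- alignments
  if (!"qual_premask" %in% names(aln)) aln$qual_premask <- aln$qual
  rep_rows <- list()
  five_p <- ifelse(aln$strand == "+", aln$start, aln$end)
  three_p <- ifelse(aln$strand == "+", aln$end, aln$start)
  for (i in seq_len(nrow(aln))) {
    same <- p$strand == aln$strand[i] & five_p[i] >= p$lo & five_p[i] <= p$hi
    opp <- p$strand != aln$strand[i] & three_p[i] >= p$lo & three_p[i] <= p$hi
    orig <- which(same | opp)
    if (!length(orig)) next
    n_masked <- 0L
    q <- aln$qual[i]
    for (j in orig) {
      lo <- max(p$s1[j], aln$start[i])
      hi <- min(p$e1[j], aln$end[i])
      if (lo > hi) next
      o1 <- lo - aln$start[i] + 1L
      o2 <- hi - aln$start[i] + 1L
      substr(q, o1, o2) <- strrep("!", o2 - o1 + 1L)
      n_masked <- n_masked + (o2 - o1 + 1L)
    }
    aln$qual[i] <- q
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      read_id = aln$read_id[i], mate = aln$mate[i],
      primers = paste(p$name[orig], collapse = ","),
      n_masked = n_masked
    )
  }
  report <- if (length(rep_rows)) dplyr::bind_rows(rep_rows) else tibble(
    read_id = character(0), mate = integer(0),
    primers = character(0), n_masked = integer(0)
  )
  attr(aln, "mask_report") <- report
  aln
}

#' Group read pairs by UMI and R1 position (directional adjacency)
#'
#' Within each stratum of identical R1 leftmost coordinate, UMIs are joined by
#' directed edges from A to B when their Hamming distance is 1 and
#' `count(A) >= 2 * count(B) - 1`; connected components are grown breadth-first
#' from the highest-count UMIs. Each resulting group is one unique fragment.
#'
#' @param alignments Alignments tibble with a `umi` column.
#' @return Tibble with one row per group: `group_id`, `umi` (seed UMI),
#'   `r1_pos`, `members` (list of read ids), `n_members`. Pairs without a UMI
#'   are excluded (warning).
#' @export
group_umis_directional <- function(alignments) {
  r1 <- alignments[alignments$mate == 1L, ]
  if (!"umi" %in% names(r1)) stop("alignments carry no umi column")
  missing_umi <- is.na(r1$umi)
  if (any(missing_umi)) {
    warning(sum(missing_umi), " read pair(s) without UMI excluded from grouping")
    r1 <- r1[!missing_umi, ]
  }
  out <- list()
  gid <- 0L
  for (pos in sort(unique(r1$start))) {
    rr <- r1[r1$start == pos, ]
    cnt <- sort(table(rr$umi), decreasing = TRUE)
    umis <- names(cnt)
    # canonical order: count desc, then UMI lexicographic
    ord <- order(-as.integer(cnt), umis)
    umis <- umis[ord]
    counts <- as.integer(cnt)[ord]
    assigned <- rep(NA_integer_, length(umis))
    for (s in seq_along(umis)) {
      if (!is.na(assigned[s])) next
      gid <- gid + 1L
      assigned[s] <- gid
      frontier <- s
      while (length(frontier)) {
        nxt <- integer(0)
        for (u in frontier) {
          cand <- which(is.na(assigned))
          for (v in cand) {
            if (nchar(umis[u]) == nchar(umis[v]) &&
                counts[u] >= 2L * counts[v] - 1L &&
                hamming(umis[u], umis[v]) == 1L) {
              assigned[v] <- gid
              nxt <- c(nxt, v)
            }
          }
        }
        frontier <- nxt
      }
      grp <- which(assigned == gid)
      members <- rr$read_id[rr$umi %in% umis[grp]]
      n_mem <- length(members)
      out[[gid]] <- tibble(
        group_id = sprintf("g%06d", gid),
        umi = umis[s], r1_pos = pos,
        members = list(members), n_members = n_mem
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Consensus deduplication of UMI groups
#'
#' One consensus read pair per group: at each aligned reference position the
#' consensus base is the majority base among duplicates covering it. Ties are
#' broken by (i) reference match, (ii) higher supporting base quality,
#' (iii) seeded random choice. The consensus base quality is the maximum
#' quality among duplicates supporting the chosen base.
#'
#' @param groups Output of [group_umis_directional()].
#' @param alignments The alignments the groups were built from.
#' @param ref A [transcript_reference()].
#' @param seed Integer seed for random tie-breaks.
#' @return Deduplicated alignments tibble (one pair per group; `read_id` is
#'   the group id).
#' @export
consensus_deduplicate <- function(groups, alignments, ref, seed = 1L) {
  set.seed(derive_seed(seed, 41L))
  refv <- strsplit(ref$sequence, "")[[1]]
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    members <- groups$members[[g]]
    stopifnot(length(members) >= 1L)
    sub <- alignments[alignments$read_id %in% members, ]
    for (m in c(1L, 2L)) {
      dm <- sub[sub$mate == m, ]
      if (nrow(dm) == 0L) next
      if (nrow(dm) == 1L) {
        cons <- dm
        cons$read_id <- groups$group_id[g]
        rows[[length(rows) + 1L]] <- cons
        next
      }
      lo <- min(dm$start)
      hi <- max(dm$end)
      width <- hi - lo + 1L
      cons_seq <- refv[lo:hi]
      cons_q <- rep(0L, width)
      covered <- rep(FALSE, width)
      # votes per position
      for (p in lo:hi) {
        cov <- which(dm$start <= p & dm$end >= p)
        if (!length(cov)) next
        covered[p - lo + 1L] <- TRUE
        off <- p - dm$start[cov] + 1L
        bases <- substr(dm$seq[cov], off, off)
        quals <- vapply(seq_along(cov), function(k) {
          utf8ToInt(substr(dm$qual[cov[k]], off[k], off[k])) - 33L
        }, integer(1))
        tab <- sort(table(bases), decreasing = TRUE)
        top <- names(tab)[as.integer(tab) == max(tab)]
        if (length(top) == 1L) {
          chosen <- top
        } else if (refv[p] %in% top) {
          chosen <- refv[p]
        } else {
          maxq <- vapply(top, function(bb) max(quals[bases == bb]), integer(1))
          best <- top[maxq == max(maxq)]
          chosen <- if (length(best) == 1L) best else sample(best, 1L)
        }
        cons_seq[p - lo + 1L] <- chosen
        cons_q[p - lo + 1L] <- max(quals[bases == chosen])
      }
      # positions inside the union span covered by no duplicate keep the
      # reference base at quality 0 (never callable)
      rows[[length(rows) + 1L]] <- tibble(
        read_id = groups$group_id[g], mate = m,
        strand = dm$strand[1L],
        start = lo, end = hi,
        seq = paste(cons_seq, collapse = ""),
        qual = intToUtf8(ifelse(covered, cons_q, 0L) + 33L),
        umi = groups$umi[g]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$nm <- alignment_nm(out, ref)
  dplyr::arrange(out, .data$read_id, .data$mate)
}
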