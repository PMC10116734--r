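test_that("UMI extraction moves the 5' prefix to the name and drops short reads", {
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    r1_seq = c(paste0("ACGTACGTACGTACGT", strrep("G", 30)), strrep("A", 10)),
    r1_qual = c(strrep("I", 46), strrep("I", 10)),
    r2_seq = strrep("C", 30), r2_qual = strrep("I", 30)
  )
  out <- extract_umis(reads, "(?P<umi_1>[ATCGN]{16})")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_equal(out$umi, "ACGTACGTACGTACGT")
  expect_equal(out$r1_seq, strrep("G", 30))
  expect_equal(nchar(out$r1_qual), 30)
  expect_match(out$read_id, "_ACGTACGTACGTACGT$")

  # zero-length pattern is the identity
  same <- extract_umis(reads, 0)
  expect_identical(same$r1_seq, reads$r1_seq)
})

test_that("primer origination rules and buffers mask exactly the primer spans", {
  ref <- make_reference(30, seed = 40) # 90 nt
  # one + primer at 0-based [10, 15) (1-based 11..15) and one - primer at
  # [40, 45) (1-based 41..45)
  primers <- tibble::tibble(
    contig = ref$transcript_id, start = c(10L, 40L), end = c(15L, 45L),
    strand = c("+", "-"), name = c("pF", "pR")
  )

  # read starting exactly at the + primer start is masked over the primer span
  a <- toy_pair(ref, "exact", 11, 35, 11, 35)
  m <- mask_primers(a, primers, "amplicon")
  q1 <- utf8ToInt(m$qual[m$mate == 1]) - 33L
  expect_equal(which(q1 == 0L), 1:5) # positions 11..15 of the read
  # base calls never change; pre-mask qualities are preserved for unmasking
  expect_identical(m$seq, a$seq)
  expect_identical(m$qual_premask, a$qual)

  # 10 nt upstream of the primer 5' end: masked under the 15-nt amplicon
  # buffer, NOT masked under the 3-nt RACE buffer
  b <- toy_pair(ref, "up10", 1, 35, 1, 35)
  mb <- mask_primers(b, primers, "amplicon")
  expect_gt(nrow(attr(mb, "mask_report")), 0)
  q1 <- utf8ToInt(mb$qual[mb$mate == 1]) - 33L
  expect_equal(which(q1 == 0L), 11:15)
  mr <- mask_primers(b, primers, "race_like")
  expect_false(any(utf8ToInt(mr$qual[mr$mate == 1]) - 33L == 0L))

  # readthrough: a read from the adjacent tile covers the whole - primer
  # span but neither end satisfies an origination criterion -> never masked
  d <- toy_pair(ref, "readthrough", 17, 70, 17, 70, strand1 = "+")
  md <- mask_primers(d, primers, "amplicon")
  expect_equal(nrow(attr(md, "mask_report")), 0)
  expect_identical(md$qual, d$qual)

  # criterion (2): a + read stopping at the - primer's 5' end gets its 3'
  # segment masked (opposite-strand primer)
  e <- toy_pair(ref, "stop", 17, 45, 17, 45)
  me <- mask_primers(e, primers, "amplicon")
  q1 <- utf8ToInt(me$qual[me$mate == 1]) - 33L
  expect_equal(which(q1 == 0L), (41:45) - 17L + 1L)

  # empty primer list is a no-op
  m0 <- mask_primers(a, primers[0, ], "amplicon")
  expect_identical(m0$qual, a$qual)
})

test_that("directional adjacency groups match the hand-computed count cases", {
  ref <- tiny_ref()
  mk <- function(umi, n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      toy_pair(ref, sprintf("%s_%d", umi, i), 1, 20, 5, 25, umi = umi)
    }))
  }
  # single UMI, 7 duplicates -> one group of 7
  g1 <- group_umis_directional(mk("AAAA", 7))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$n_members, 7)

  # AAAA(10) + AAAT(3): 10 >= 2*3-1 -> one group
  g2 <- group_umis_directional(dplyr::bind_rows(mk("AAAA", 10), mk("AAAT", 3)))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$umi, "AAAA")
  expect_equal(g2$n_members, 13)

  # AAAA(10) + AAAT(6): 10 < 2*6-1 -> two groups
  g3 <- group_umis_directional(dplyr::bind_rows(mk("AAAA", 10), mk("AAAT", 6)))
  expect_equal(nrow(g3), 2)
  expect_setequal(g3$n_members, c(10, 6))

  # different R1 positions never merge
  far <- dplyr::bind_rows(
    mk("AAAA", 4),
    dplyr::mutate(toy_pair(ref, "x", 3, 22, 6, 25, umi = "AAAA"))
  )
  g4 <- group_umis_directional(far)
  expect_equal(nrow(g4), 2)
})

test_that("grouping is invariant to input read order", {
  ref <- tiny_ref()
  aln <- dplyr::bind_rows(lapply(1:12, function(i) {
    umi <- c("AAAA", "AAAT", "GGGG")[(i %% 3) + 1]
    toy_pair(ref, sprintf("r%02d", i), 1, 20, 5, 25, umi = umi)
  }))
  g_fwd <- group_umis_directional(aln)
  set.seed(1)
  g_shuf <- group_umis_directional(aln[sample(nrow(aln)), ])
  norm <- function(g) {
    g$members <- lapply(g$members, sort)
    g[order(g$umi), c("umi", "r1_pos", "n_members", "members")]
  }
  expect_equal(norm(g_fwd), norm(g_shuf), ignore_attr = TRUE)
})

test_that("consensus voting follows majority then reference, BQ, random order", {
  ref <- tiny_ref()
  p <- 10L
  ref_base <- substr(ref$sequence, p, p)
  other <- setdiff(c("A", "C", "G", "T"), ref_base)
  mk <- function(id, base, bq = 37L) {
    sq <- substr(ref$sequence, 1, 20)
    substr(sq, p, p) <- base
    q <- const_qual(20)
    substr(q, p, p) <- rawToChar(as.raw(bq + 33L))
    toy_pair(ref, id, 1, 20, 1, 20, seq1 = sq, seq2 = sq,
             q1 = q, q2 = q, umi = "AAAA")
  }
  groups_of <- function(aln) group_umis_directional(aln)

  # strict majority: A,A,G -> A
  aln <- dplyr::bind_rows(mk("d1", other[1]), mk("d2", other[1]), mk("d3", other[2]))
  cons <- consensus_deduplicate(groups_of(aln), aln, ref)
  expect_equal(substr(cons$seq[1], p, p), other[1])

  # two-way tie, one matches the reference -> reference wins
  aln <- dplyr::bind_rows(mk("d1", ref_base), mk("d2", other[1]))
  cons <- consensus_deduplicate(groups_of(aln), aln, ref)
  expect_equal(substr(cons$seq[1], p, p), ref_base)

  # two-way tie, neither matches -> higher BQ wins; consensus BQ is the max
  # among supporters of the chosen base
  aln <- dplyr::bind_rows(mk("d1", other[1], bq = 30L), mk("d2", other[2], bq = 20L))
  cons <- consensus_deduplicate(groups_of(aln), aln, ref)
  expect_equal(substr(cons$seq[1], p, p), other[1])
  expect_equal(utf8ToInt(substr(cons$qual[1], p, p)) - 33L, 30L)

  # full tie -> seeded random choice, deterministic under the seed
  aln <- dplyr::bind_rows(mk("d1", other[1], 30L), mk("d2", other[2], 30L))
  c1 <- consensus_deduplicate(groups_of(aln), aln, ref, seed = 5)
  c2 <- consensus_deduplicate(groups_of(aln), aln, ref, seed = 5)
  expect_identical(c1$seq, c2$seq)
  expect_true(substr(c1$seq[1], p, p) %in% other)
})

test_that("singleton groups pass through unchanged and pair count equals group count", {
  ref <- make_reference(40, seed = 30)
  des <- library_design("amplicon", read_len = 120, umi_len = 6,
                        duplication_rate = 1)
  lib <- simulate_library(ref, des, 60, error_profile(), seed = 31)
  aln <- ledger_alignments(lib)
  groups <- group_umis_directional(aln)
  cons <- consensus_deduplicate(groups, aln, ref, seed = 32)
  expect_equal(length(unique(cons$read_id)), nrow(groups))
  # a singleton group's consensus equals its input pair exactly
  single <- groups[groups$n_members == 1, ]
  expect_gt(nrow(single), 0)
  g <- single[1, ]
  orig <- aln[aln$read_id == g$members[[1]][1], ]
  got <- cons[cons$read_id == g$group_id, ]
  expect_equal(got$seq, orig$seq)
  expect_equal(got$qual, orig$qual)
  expect_equal(got$start, orig$start)
})

test_that("deduplication collapses coverage uniformly", {
  ref <- make_reference(40, seed = 33)
  des <- library_design("amplicon", read_len = 120, umi_len = 8,
                        duplication_rate = 2)
  lib <- simulate_library(ref, des, 80, error_profile(), seed = 34)
  aln <- ledger_alignments(lib)
  cov_before <- compute_fragment_coverage(aln, ref)
  groups <- group_umis_directional(aln)
  cons <- consensus_deduplicate(groups, aln, ref, seed = 35)
  cov_after <- compute_fragment_coverage(cons, ref)
  # same footprint, uniformly collapsed depth
  expect_equal(cov_after$depth[cov_after$depth > 0] /
                 cov_before$depth[cov_before$depth > 0],
               rep(nrow(groups) / length(unique(aln$read_id)),
                   sum(cov_after$depth > 0)))
})
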