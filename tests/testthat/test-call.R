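default_filters <- function(...) call_filters(min_count = 2, min_bq = 30,
                                              max_nm = 10, ...)

coverage_depths <- function(cov, pos1) {
  vapply(pos1, function(p) {
    row <- cov[cov$start <= p - 1 & cov$end >= p, ]
    if (nrow(row) == 0) 0L else row$depth[1]
  }, integer(1))
}

test_that("concordance: only mismatches seen identically in both mates are emitted", {
  ref <- tiny_ref()
  f <- default_filters()

  # perfect pair: nothing
  perfect <- toy_pair(ref, "p0", 1, 25, 3, 28)
  expect_equal(nrow(enumerate_concordant_mismatches(perfect, ref, f)), 0)

  # R1 calls G, R2 calls the reference: discordant, nothing
  p <- 12L
  rb <- substr(ref$sequence, p, p)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  sq1 <- substr(ref$sequence, 1, 25)
  substr(sq1, p, p) <- ab
  disc <- toy_pair(ref, "p1", 1, 25, 1, 25, seq1 = sq1)
  expect_equal(nrow(enumerate_concordant_mismatches(disc, ref, f)), 0)

  # both mates call the same alt with BQ 35/33: one observation with features
  sq2 <- sq1
  q1 <- const_qual(25, 35L)
  q2 <- const_qual(25, 33L)
  conc <- toy_pair(ref, "p2", 1, 25, 1, 25, seq1 = sq1, seq2 = sq2,
                   q1 = q1, q2 = q2)
  obs <- enumerate_concordant_mismatches(conc, ref, f)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$ref_pos, p)
  expect_equal(obs$alt_base, ab)
  expect_equal(obs$r1_bq, 35L)
  expect_equal(obs$r2_bq, 33L)
  expect_equal(obs$r1_nm, 1L)
  expect_equal(obs$r1_read_pos, p - 1L) # 0-based cycle on the + mate
  expect_equal(obs$r2_read_pos, 25L - p) # 0-based cycle on the - mate

  # below min_bq in one mate: nothing
  q2low <- const_qual(25, 20L)
  low <- toy_pair(ref, "p3", 1, 25, 1, 25, seq1 = sq1, seq2 = sq2, q2 = q2low)
  expect_equal(nrow(enumerate_concordant_mismatches(low, ref, f)), 0)

  # masked base (BQ 0) never participates, even at min_bq 0
  qmask <- const_qual(25, 0L)
  masked <- toy_pair(ref, "p4", 1, 25, 1, 25, seq1 = sq1, seq2 = sq2, q2 = qmask)
  f0 <- call_filters(min_count = 1, min_bq = 0, max_nm = 10)
  expect_equal(nrow(enumerate_concordant_mismatches(masked, ref, f0)), 0)

  # positions covered by one mate only yield nothing
  sq_tail <- substr(ref$sequence, 20, 28)
  substr(sq_tail, 9, 9) <- setdiff(c("A","C","G","T"),
                                   substr(ref$sequence, 28, 28))[1]
  onemate <- toy_pair(ref, "p5", 1, 25, 20, 28, seq2 = sq_tail)
  expect_equal(nrow(enumerate_concordant_mismatches(onemate, ref, f0)), 0)
})

test_that("pairs exceeding the edit-distance cap are discarded entirely", {
  ref <- tiny_ref()
  sq <- substr(ref$sequence, 1, 25)
  for (p in c(3, 8, 14)) {
    substr(sq, p, p) <- setdiff(c("A","C","G","T"), substr(sq, p, p))[1]
  }
  pair <- toy_pair(ref, "hi_nm", 1, 25, 1, 25, seq1 = sq, seq2 = sq)
  f <- call_filters(min_count = 1, min_bq = 30, max_nm = 2)
  expect_equal(nrow(enumerate_concordant_mismatches(pair, ref, f)), 0)
  f2 <- call_filters(min_count = 1, min_bq = 30, max_nm = 3)
  expect_equal(nrow(enumerate_concordant_mismatches(pair, ref, f2)), 3)
})

test_that("MNP merging follows the 3-nt reference span rule", {
  ref <- tiny_ref()
  f <- call_filters(min_count = 1, min_bq = 30)
  mk_obs <- function(positions) {
    sq <- substr(ref$sequence, 1, 25)
    for (p in positions) {
      substr(sq, p, p) <- setdiff(c("A","C","G","T"), substr(sq, p, p))[1]
    }
    pair <- toy_pair(ref, "m", 1, 25, 1, 25, seq1 = sq, seq2 = sq)
    enumerate_concordant_mismatches(pair, ref, f)
  }

  # positions 5 and 7 (span 3): one tri-nt-span MNP with the reference base
  # carried at the gap position
  c1 <- merge_mnps(mk_obs(c(5, 7)), ref)
  expect_equal(unique(c1$pos), 5L)
  expect_equal(unique(nchar(c1$ref)), 3L)
  expect_equal(substr(unique(c1$alt), 2, 2), substr(ref$sequence, 6, 6))

  # positions 5 and 9: two separate SNPs
  c2 <- merge_mnps(mk_obs(c(5, 9)), ref)
  expect_equal(sort(unique(c2$pos)), c(5L, 9L))
  expect_true(all(nchar(c2$ref) == 1L))

  # 5,6,7: one tri-nt MNP
  c3 <- merge_mnps(mk_obs(5:7), ref)
  expect_equal(unique(c3$pos), 5L)
  expect_equal(unique(nchar(c3$ref)), 3L)
})

test_that("merging matches exhaustive enumeration over all placements in a 10-nt window", {
  ref <- tiny_ref()
  f <- call_filters(min_count = 1, min_bq = 30)
  window <- 11:20
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(window, k, simplify = FALSE)
  }), recursive = FALSE)
  for (positions in combos) {
    sq <- substr(ref$sequence, 1, 25)
    for (p in positions) {
      substr(sq, p, p) <- setdiff(c("A","C","G","T"), substr(sq, p, p))[1]
    }
    pair <- toy_pair(ref, "w", 1, 25, 1, 25, seq1 = sq, seq2 = sq)
    obs <- enumerate_concordant_mismatches(pair, ref, f)
    got <- unique(merge_mnps(obs, ref)[, c("pos", "ref", "alt")])
    got <- got[order(got$pos), ]
    # oracle: exhaustive leftmost-maximal partition into <=3-nt-span blocks
    blocks <- oracle_merge(positions)
    refv <- strsplit(ref$sequence, "")[[1]]
    want <- dplyr::bind_rows(lapply(blocks, function(blk) {
      p1 <- positions[blk[1]]
      p2 <- positions[blk[length(blk)]]
      aa <- refv[p1:p2]
      for (k in blk) {
        aa[positions[k] - p1 + 1L] <-
          substr(sq, positions[k], positions[k])
      }
      tibble::tibble(pos = p1, ref = paste(refv[p1:p2], collapse = ""),
                     alt = paste(aa, collapse = ""))
    }))
    expect_equal(as.data.frame(got), as.data.frame(want),
                 info = paste(positions, collapse = ","))
    expect_true(all(nchar(got$ref) <= 3))
  }
})

test_that("fragment coverage counts fragments once and respects masking", {
  ref <- make_reference(40, seed = 50) # 120 nt
  # one fully overlapping pair over 1..100 -> depth 1 throughout
  a <- toy_pair(ref, "a", 1, 100, 1, 100)
  cov <- compute_fragment_coverage(a, ref)
  expect_equal(coverage_depths(cov, c(1, 50, 100)), c(1L, 1L, 1L))

  # two pairs tiling 1..100 and 51..120: depths 1, 2, 1
  b <- dplyr::bind_rows(a, toy_pair(ref, "b", 51, 120, 51, 120))
  cov2 <- compute_fragment_coverage(b, ref)
  expect_equal(coverage_depths(cov2, c(10, 75, 110)), c(1L, 2L, 1L))

  # a primer-masked segment with no other fragment has depth 0
  q <- const_qual(100)
  substr(q, 1, 20) <- strrep("!", 20)
  c3 <- toy_pair(ref, "c", 1, 100, 1, 100, q1 = q, q2 = q)
  cov3 <- compute_fragment_coverage(c3, ref)
  expect_equal(coverage_depths(cov3, c(5, 20, 21, 60)), c(0L, 0L, 1L, 1L))

  # conservation: sum depth x width equals unmasked fragment-covered bases
  expect_equal(sum(cov2$depth * (cov2$end - cov2$start)), 100L + 70L)
  expect_equal(sum(cov3$depth * (cov3$end - cov3$start)), 80L)
})

test_that("aggregation thresholds, frequencies and distinct-allele counting", {
  ref <- tiny_ref()
  f1 <- call_filters(min_count = 1, min_bq = 30)
  p <- 10L
  rb <- substr(ref$sequence, p, p)
  ab <- setdiff(c("A","C","G","T"), rb)[1]
  snp_pair <- function(id) {
    sq <- substr(ref$sequence, 1, 25)
    substr(sq, p, p) <- ab
    toy_pair(ref, id, 1, 25, 1, 25, seq1 = sq, seq2 = sq)
  }
  dimnp_pair <- function(id) {
    sq <- substr(ref$sequence, 1, 25)
    substr(sq, p, p) <- ab
    nb <- setdiff(c("A","C","G","T"), substr(sq, p + 1, p + 1))[1]
    substr(sq, p + 1, p + 1) <- nb
    toy_pair(ref, id, 1, 25, 1, 25, seq1 = sq, seq2 = sq)
  }
  clean_pair <- function(id) toy_pair(ref, id, 1, 25, 1, 25)

  # the same SNP in 3 fragments plus one fragment carrying it inside a
  # di-nt MNP: distinct alleles with counts 3 and 1
  aln <- dplyr::bind_rows(
    snp_pair("s1"), snp_pair("s2"), snp_pair("s3"), dimnp_pair("d1"),
    clean_pair("c1"), clean_pair("c2")
  )
  obs <- enumerate_concordant_mismatches(aln, ref, f1)
  comp <- merge_mnps(obs, ref)
  cov <- compute_fragment_coverage(aln, ref)
  calls <- aggregate_variants(comp, cov, f1, ref)
  expect_equal(nrow(calls), 2)
  snp <- calls[calls$variant_type == "SNP", ]
  mnp <- calls[calls$variant_type == "di_nt_MNP", ]
  expect_equal(snp$count, 3L)
  expect_equal(mnp$count, 1L)
  expect_equal(snp$frequency, 3 / 6)

  # min_count 2 drops the single-fragment MNP
  f2 <- call_filters(min_count = 2, min_bq = 30)
  calls2 <- aggregate_variants(comp, cov, f2, ref)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$variant_type, "SNP")

  # uniqueness of reported alleles
  expect_false(any(duplicated(calls[c("pos", "ref", "alt")])))
})

test_that("calls equal the brute-force oracle on random toy alignment sets", {
  ref <- make_reference(20, seed = 60) # 60 nt
  for (s in 1:12) {
    aln <- random_toy_set(ref, n_pairs = sample(5:20, 1), seed = 100 + s,
                          mask_first = if (s %% 2 == 0) 3L else 0L)
    for (m in c(1L, 2L)) {
      got <- run_call(alignments = aln, ref = ref,
                      filters = call_filters(min_count = m, min_bq = 30,
                                             max_nm = 10))
      want <- oracle_call(aln, ref, min_count = m, min_bq = 30, max_nm = 10)
      gg <- got$calls[, c("pos", "ref", "alt", "count", "frequency")]
      expect_equal(as.data.frame(gg), as.data.frame(want),
                   info = paste("set", s, "min_count", m))
    }
  }
})

test_that("single-mate errors never produce calls (concordance specificity)", {
  ref <- make_reference(30, seed = 61)
  des <- library_design("amplicon", read_len = 90)
  prof <- error_profile(read_error_rate = 3e-3) # sequencer channel only
  lib <- simulate_library(ref, des, 400, prof, seed = 62)
  aln <- ledger_alignments(lib)
  res <- run_call(alignments = aln, ref = ref,
                  filters = call_filters(min_count = 1, min_bq = 2))
  # a call would need the same read-level miscall at the same position in
  # both mates; verify every reported call is such a double event
  if (nrow(res$calls) > 0) {
    err <- lib$errors
    for (i in seq_len(nrow(res$calls))) {
      hits <- err[err$ref_pos == res$calls$pos[i] & err$mate == 1L, ]
      hits2 <- err[err$ref_pos == res$calls$pos[i] & err$mate == 2L, ]
      expect_true(nrow(hits) > 0 && nrow(hits2) > 0)
    }
  }
  succeed()
})

test_that("per-variant summary rows cover exactly the supporting fragments", {
  ref <- make_reference(25, seed = 63)
  des <- library_design("amplicon", read_len = 75)
  lib <- simulate_library(ref, des, 40, error_profile(), seed = 64)
  aln <- ledger_alignments(lib)
  panel <- sample_variant_panel(ref, 6, seed = 65)
  panel$target_frequency <- 0.15
  plan <- plan_edits(panel, aln, ref, seed = 66)
  ed <- apply_edits(plan, aln)
  res <- run_call(ed$reads, ref, call_filters(min_count = 2, min_bq = 30))
  for (i in seq_len(nrow(res$calls))) {
    rows <- res$summary[res$summary$pos == res$calls$pos[i] &
                          res$summary$ref == res$calls$ref[i] &
                          res$summary$alt == res$calls$alt[i], ]
    expect_equal(length(unique(rows$read_id)), res$calls$count[i])
  }
  # no reported MNP spans more than 3 reference nt
  expect_true(all(nchar(res$calls$ref) <= 3))
})

test_that("run_call writes VCF/summary/bedgraph and echoes parameters", {
  ref <- make_reference(20, seed = 67)
  des <- library_design("amplicon", read_len = 60)
  lib <- simulate_library(ref, des, 30, error_profile(), seed = 68)
  aln <- ledger_alignments(lib)
  panel <- sample_variant_panel(ref, 2, seed = 69)
  panel$target_frequency <- 0.2
  plan <- plan_edits(panel, aln, ref, seed = 70)
  ed <- apply_edits(plan, aln)
  outdir <- tempfile()
  res <- run_call(ed$reads, ref,
                  call_filters(2, 30, 10, signature = "NNK",
                               signature_action = "flag"),
                  outdir = outdir)
  vcf <- readLines(file.path(outdir, "calls.vcf"))
  expect_true(any(grepl("mavecall_params=m=2 q=30 e=10 s=NNK", vcf)))
  expect_equal(sum(!startsWith(vcf, "#")), nrow(res$calls))
  smry <- utils::read.delim(file.path(outdir, "summary.txt"))
  expect_equal(nrow(smry), nrow(res$summary))
  bg <- utils::read.delim(file.path(outdir, "coverage.bedgraph"), header = FALSE)
  expect_equal(nrow(bg), nrow(res$coverage))
})
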