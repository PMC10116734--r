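make_bg <- function(n = 10, seed = 1, len_codons = 40) {
  ref <- make_reference(len_codons, seed = seed)
  des <- library_design("amplicon", read_len = nchar(ref$sequence))
  lib <- simulate_library(ref, des, n, error_profile(), seed = seed)
  list(ref = ref, lib = lib, aln = ledger_alignments(lib))
}

test_that("realized counts follow round(frequency x coverage) with floor 1", {
  bg <- make_bg(10, seed = 2)
  ref_base <- substr(bg$ref$sequence, 30, 30)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  specs <- tibble::tibble(pos = 30L, ref = ref_base, alt = alt,
                          target_frequency = 0.5)
  plan <- plan_edits(specs, bg$aln, bg$ref, seed = 3)
  expect_equal(plan$specs$coverage, 10L)
  expect_equal(plan$specs$realized_count, 5L)
  expect_equal(nrow(plan$targets), 5L)

  # tiny frequency still edits one fragment
  specs$target_frequency <- 1e-4
  plan2 <- plan_edits(specs, bg$aln, bg$ref, seed = 3)
  expect_equal(plan2$specs$realized_count, 1L)
})

test_that("two specs at the same coordinate receive disjoint fragment sets", {
  bg <- make_bg(10, seed = 4)
  ref_base <- substr(bg$ref$sequence, 50, 50)
  alts <- setdiff(c("A", "C", "G", "T"), ref_base)
  specs <- tibble::tibble(
    pos = 50L, ref = ref_base, alt = alts[1:2],
    target_frequency = 0.2
  )
  plan <- plan_edits(specs, bg$aln, bg$ref, seed = 5)
  expect_equal(plan$specs$achieved_count, c(2L, 2L))
  f1 <- plan$targets$read_id[plan$targets$spec_idx == 1]
  f2 <- plan$targets$read_id[plan$targets$spec_idx == 2]
  expect_length(intersect(f1, f2), 0)
})

test_that("fragments with nearby pre-existing mismatches are ineligible (conversion prohibition)", {
  ref <- tiny_ref()
  # 5 fragments covering the whole 30-nt reference; one carries an error
  # 1 nt from the edit site
  aln <- dplyr::bind_rows(lapply(1:5, function(i) {
    sq <- substr(ref$sequence, 1, 30)
    if (i == 3) substr(sq, 11, 11) <- setdiff(c("A","C","G","T"),
                                              substr(sq, 11, 11))[1]
    toy_pair(ref, paste0("p", i), 1, 30, 1, 30, seq1 = sq, seq2 = sq)
  }))
  ref_base <- substr(ref$sequence, 10, 10)
  specs <- tibble::tibble(pos = 10L, ref = ref_base,
                          alt = setdiff(c("A","C","G","T"), ref_base)[1],
                          target_frequency = 0.8)
  plan <- plan_edits(specs, aln, ref, seed = 6, conversion_buffer = 3)
  expect_equal(plan$specs$realized_count, 4L)
  expect_false("p3" %in% plan$targets$read_id)
  # brute-force eligibility: every non-p3 fragment is clean near the site
  expect_setequal(plan$targets$read_id, paste0("p", c(1, 2, 4, 5)))
  # with the prohibition disabled, p3 becomes eligible
  specs$target_frequency <- 0.99
  plan0 <- plan_edits(specs, aln, ref, seed = 6, conversion_buffer = 0)
  expect_true("p3" %in% plan0$targets$read_id)
})

test_that("insufficient eligible fragments reports unplaceable with achieved count", {
  bg <- make_bg(4, seed = 7)
  ref_base <- substr(bg$ref$sequence, 20, 20)
  specs <- tibble::tibble(pos = 20L, ref = ref_base,
                          alt = setdiff(c("A","C","G","T"), ref_base)[1:2],
                          target_frequency = 0.9)
  expect_warning(
    plan <- plan_edits(specs, bg$aln, bg$ref, seed = 8),
    "unplaceable"
  )
  expect_true(any(plan$specs$unplaceable))
  expect_equal(sum(plan$specs$achieved_count), 4L) # all fragments consumed once
})

test_that("an empty plan passes reads through byte-identical", {
  bg <- make_bg(6, seed = 9)
  specs <- tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), target_frequency = numeric(0))
  plan <- plan_edits(specs, bg$aln, bg$ref, seed = 10)
  out <- apply_edits(plan, bg$aln)
  orig <- bg$lib$reads
  m <- match(orig$read_id, out$reads$read_id)
  expect_false(anyNA(m))
  expect_identical(orig$r1_seq, out$reads$r1_seq[m])
  expect_identical(orig$r1_qual, out$reads$r1_qual[m])
  expect_identical(orig$r2_seq, out$reads$r2_seq[m])
  expect_identical(orig$r2_qual, out$reads$r2_qual[m])
  expect_equal(nrow(out$truth), 0)
})

test_that("MNP edits hit both covering mates; partial coverage edits the covered suffix", {
  ref <- tiny_ref()
  # "full": both mates cover positions 10-11. "partial": R1 ends at 10 so it
  # covers only the first MNP base; R2 covers both.
  aln <- dplyr::bind_rows(
    toy_pair(ref, "full", 1, 20, 5, 25),
    toy_pair(ref, "partial", 1, 10, 5, 25)
  )
  rr <- substr(ref$sequence, 10, 11)
  alt <- chartr("ACGT", "CAAC", rr) # differs at both positions
  specs <- tibble::tibble(pos = 10L, ref = rr, alt = alt,
                          target_frequency = 0.9)
  plan <- plan_edits(specs, aln, ref, seed = 11, conversion_buffer = 0)
  expect_equal(plan$specs$achieved_count, 2L)
  out <- apply_edits(plan, aln)
  re_aln <- align_reads(out$reads, ref, seed_len = 8)
  full <- re_aln[re_aln$read_id == "full", ]
  expect_true(all(substr(full$seq, 10 - full$start + 1, 11 - full$start + 1) == alt))
  # the partially covering R1 of "partial" is edited on the covered prefix
  part <- re_aln[re_aln$read_id == "partial", ]
  r1 <- part[part$mate == 1, ]
  r2 <- part[part$mate == 2, ]
  expect_equal(substr(r1$seq, 10, 10), substr(alt, 1, 1))
  expect_equal(substr(r2$seq, 10 - r2$start + 1, 11 - r2$start + 1), alt)
})

test_that("editing conserves read count and touches only planned positions", {
  bg <- make_bg(50, seed = 12)
  panel <- sample_variant_panel(bg$ref, 5, seed = 13)
  panel$target_frequency <- 0.1
  plan <- plan_edits(panel, bg$aln, bg$ref, seed = 14)
  out <- apply_edits(plan, bg$aln)
  expect_equal(nrow(out$reads), nrow(bg$lib$reads))
  # byte-diff oracle: unplanned reads identical, planned reads differ only
  # at planned offsets
  orig <- bg$lib$reads
  m <- match(orig$read_id, out$reads$read_id)
  planned <- split(plan$targets, plan$targets$read_id)
  for (i in seq_len(nrow(orig))) {
    a <- orig[i, ]
    b <- out$reads[m[i], ]
    if (!a$read_id %in% names(planned)) {
      expect_identical(a$r1_seq, b$r1_seq)
      expect_identical(a$r2_seq, b$r2_seq)
    } else {
      d1 <- which(charToRaw(a$r1_seq) != charToRaw(b$r1_seq))
      tg <- planned[[a$read_id]]
      allowed <- unlist(lapply(seq_len(nrow(tg)), function(j) {
        tg$pos[j]:(tg$pos[j] + nchar(tg$ref[j]) - 1L)
      }))
      # R1 is the + strand read starting at position 1 here
      expect_true(all(d1 %in% allowed))
    }
    expect_identical(a$r1_qual, b$r1_qual) # qualities always preserved
    expect_identical(a$r2_qual, b$r2_qual)
  }
})

test_that("planning and editing are deterministic given the seed", {
  bg <- make_bg(30, seed = 15)
  panel <- sample_variant_panel(bg$ref, 8, seed = 16)
  panel$target_frequency <- 0.15
  p1 <- suppressWarnings(plan_edits(panel, bg$aln, bg$ref, seed = 17))
  p2 <- suppressWarnings(plan_edits(panel, bg$aln, bg$ref, seed = 17))
  expect_identical(p1$targets, p2$targets)
  o1 <- apply_edits(p1, bg$aln)
  o2 <- apply_edits(p2, bg$aln)
  expect_identical(o1$reads, o2$reads)
  expect_identical(o1$truth, o2$truth)
  p3 <- suppressWarnings(plan_edits(panel, bg$aln, bg$ref, seed = 18))
  expect_false(identical(p1$targets$read_id, p3$targets$read_id))
})

test_that("truth VCF round-trips through the VCF reader", {
  skip_if_not_installed("vcfR")
  bg <- make_bg(20, seed = 19)
  panel <- sample_variant_panel(bg$ref, 4, seed = 20)
  panel$target_frequency <- 0.2
  plan <- plan_edits(panel, bg$aln, bg$ref, seed = 21)
  out <- apply_edits(plan, bg$aln)
  vcf <- tempfile(fileext = ".vcf")
  write_truth_vcf(out$truth, bg$ref, vcf)
  back <- read_vcf_specs(vcf)
  expect_equal(back$pos, out$truth$pos)
  expect_equal(back$ref, out$truth$ref)
  expect_equal(back$alt, out$truth$alt)
  expect_equal(back$target_frequency, out$truth$target_frequency)
})

test_that("realigning edited error-free reads yields NM equal to the allele change", {
  bg <- make_bg(10, seed = 22)
  ref_base <- substr(bg$ref$sequence, 40, 40)
  specs <- tibble::tibble(pos = 40L, ref = ref_base,
                          alt = setdiff(c("A","C","G","T"), ref_base)[1],
                          target_frequency = 0.3)
  plan <- plan_edits(specs, bg$aln, bg$ref, seed = 23)
  out <- apply_edits(plan, bg$aln)
  re <- realign_edited(out$reads, bg$ref)
  edited <- re[re$read_id %in% plan$targets$read_id, ]
  expect_true(all(edited$nm == 1L))
  clean <- re[!re$read_id %in% plan$targets$read_id, ]
  expect_true(all(clean$nm == 0L))
  # empty input gives empty output
  expect_equal(nrow(realign_edited(out$reads[0, ], bg$ref)), 0)
})
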