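# In-silico validation dataset: error-free full-overlap background with a
# known panel of spiked-in SNPs/MNPs, the package's core round-trip check.

#' Build the in-silico validation dataset
#'
#' Generates an error-free paired-end background in which both mates span the
#' whole target (read length = reference length), samples `n_variants`
#' distinct SNP/MNP specs (default mix: 25% SNPs, the rest split between
#' di- and tri-nt MNPs), and edits each into exactly `per_variant_pairs` read
#' pairs with the spike-in simulator. With the defaults every truth variant
#' sits at frequency `per_variant_pairs / n_pairs` = 10/10,000 = 0.1%.
#'
#' @param ref A [transcript_reference()] short enough to be spanned by one
#'   read (default generator: [make_reference()] with 50 codons -> 150 nt).
#' @param n_pairs Background read pairs.
#' @param n_variants Number of distinct variants to introduce.
#' @param per_variant_pairs Read pairs edited per variant.
#' @param snp_prop Proportion of SNPs among sampled variants.
#' @param seed Integer seed.
#' @return List: `reads` (edited read pairs tibble), `truth` (truth tibble),
#'   `ref`, `library` (the untouched background `mave_library`).
#' @export
build_validation_dataset <- function(ref = make_reference(50, seed = 1L),
                                     n_pairs = 10000L, n_variants = 187L,
                                     per_variant_pairs = 10L,
                                     snp_prop = 0.25, seed = 1L) {
  L <- nchar(ref$sequence)
  design <- library_design(method = "amplicon", read_len = L)
  lib <- simulate_library(ref, design, n_pairs, error_profile(), seed = seed)
  specs <- sample_variant_panel(ref, n_variants, snp_prop, seed = seed)
  specs$target_frequency <- per_variant_pairs / n_pairs
  aln <- ledger_alignments(lib)
  plan <- plan_edits(specs, aln, ref, seed = seed, conversion_buffer = 3L)
  if (any(plan$specs$unplaceable)) {
    stop(
      "variants could not be placed at the requested count: ",
      paste(sprintf("%d%s>%s", plan$specs$pos[plan$specs$unplaceable],
                    plan$specs$ref[plan$specs$unplaceable],
                    plan$specs$alt[plan$specs$unplaceable]),
            collapse = ", ")
    )
  }
  edited <- apply_edits(plan, aln)
  list(reads = edited$reads, truth = edited$truth, ref = ref, library = lib)
}

#' Sample a panel of distinct SNP/MNP specs inside the CDS
#'
#' All allele bases differ from the reference; `(pos, ref, alt)` triples are
#' unique.
#'
#' @param ref A [transcript_reference()].
#' @param n Number of variants.
#' @param snp_prop Proportion of SNPs; remainder split evenly between di- and
#'   tri-nt MNPs.
#' @param seed Integer seed.
#' @return Spec tibble (`pos`, `ref`, `alt`).
#' @export
sample_variant_panel <- function(ref, n, snp_prop = 0.25, seed = 1L) {
  set.seed(derive_seed(seed, 51L))
  lo <- ref$cds_start + 1L
  hi <- ref$cds_end
  seen <- character(0)
  out <- vector("list", n)
  k <- 0L
  guard <- 0L
  while (k < n) {
    guard <- guard + 1L
    if (guard > 50L * n) stop("target too short for ", n, " distinct variants")
    u <- stats::runif(1)
    len <- if (u < snp_prop) 1L else if (u < snp_prop + (1 - snp_prop) / 2) 2L else 3L
    pos <- sample(lo:(hi - len + 1L), 1L)
    rr <- ref_seq_at(ref, pos, pos + len - 1L)
    alt <- paste(vapply(strsplit(rr, "")[[1]], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1)), collapse = "")
    key <- paste(pos, rr, alt)
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    out[[k]] <- tibble(pos = pos, ref = rr, alt = alt)
  }
  dplyr::bind_rows(out)
}
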