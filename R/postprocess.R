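# Post-calling filter chain and negative-control background subtraction,
# producing clean per-replicate variant tables for downstream statistics.

#' Filter-chain configuration
#'
#' The seven sequential criteria: (1) inside the mutagenized target region;
#' (2) matches the NNK signature; (3) single-codon change; (4) SNP count >= 2
#' and MNP count >= 1; (5) no strong strand bias (RACE-like only, strand count
#' difference <= 64); (6) not predicted an error by the classifier in all
#' replicates (cutoff 0.49); (7) observed in all replicates.
#'
#' @param target_start,target_end Mutagenized target region, 1-based
#'   inclusive transcript coordinates (`NULL` = whole CDS).
#' @param require_signature Apply criterion 2?
#' @param single_codon_only Apply criterion 3?
#' @param min_snp_count,min_mnp_count Criterion 4 thresholds.
#' @param max_strand_diff Criterion 5 threshold (RACE-like).
#' @param race_like Is the library RACE-like (criterion 5 active)?
#' @param rf_cutoff Criterion 6 probability cutoff.
#' @param require_all_replicates Apply criterion 7?
#' @return A `filter_config` list.
#' @export
filter_config <- function(target_start = NULL, target_end = NULL,
                          require_signature = TRUE,
                          single_codon_only = TRUE,
                          min_snp_count = 2L, min_mnp_count = 1L,
                          max_strand_diff = 64L, race_like = FALSE,
                          rf_cutoff = 0.49,
                          require_all_replicates = TRUE) {
  stopifnot(min_snp_count >= 0L, min_mnp_count >= 0L, max_strand_diff >= 0L)
  structure(
    list(
      target_start = target_start, target_end = target_end,
      require_signature = require_signature,
      single_codon_only = single_codon_only,
      min_snp_count = as.integer(min_snp_count),
      min_mnp_count = as.integer(min_mnp_count),
      max_strand_diff = as.integer(max_strand_diff),
      race_like = race_like,
      rf_cutoff = rf_cutoff,
      require_all_replicates = require_all_replicates
    ),
    class = "filter_config"
  )
}

#' Subtract negative-control background frequencies
#'
#' For each mutagenized call with an identical-allele NC call, records the
#' adjusted log10 frequency `log10(f_mut) - log10(f_nc)` alongside the raw
#' value. Variants absent from the NC carry adjustment 0 and are flagged
#' `nc_absent`.
#'
#' @param mut_calls Calls tibble of a mutagenized library.
#' @param nc_calls Calls tibble of the matched negative control.
#' @return `mut_calls` with `nc_frequency`, `nc_adjusted_log10_frequency` and
#'   `nc_absent` appended.
#' @export
subtract_nc_background <- function(mut_calls, nc_calls) {
  nc <- dplyr::select(nc_calls, "pos", "ref", "alt", nc_frequency = "frequency")
  out <- dplyr::left_join(mut_calls, nc, by = c("pos", "ref", "alt"))
  out$nc_absent <- is.na(out$nc_frequency)
  out$nc_adjusted_log10_frequency <- ifelse(
    out$nc_absent, 0, log10(out$frequency) - log10(out$nc_frequency)
  )
  out
}

#' Apply the sequential post-calling filter chain
#'
#' Criteria run in the documented order; records removed by each criterion
#' are counted in the attrition ledger. Output is the union of surviving
#' variants keyed by `(pos, ref, alt)` with per-replicate counts and
#' frequencies.
#'
#' @param replicates Named list of replicate calls tibbles.
#' @param config A [filter_config()].
#' @param model Optional `error_model` bundle (required when criterion 6 is
#'   active and replicates lack an `error_prob` column).
#' @param ref A [transcript_reference()] (feature extraction for criterion 6).
#' @param method Feature schema method for criterion 6.
#' @return A list: `table` (filtered union, wide per-replicate columns) and
#'   `attrition` (tibble of records removed per criterion, per replicate
#'   union).
#' @export
apply_filter_chain <- function(replicates, config, model = NULL, ref = NULL,
                               method = c("amplicon", "race_like")) {
  method <- match.arg(method)
  stopifnot(length(replicates) >= 1L)
  if (is.data.frame(replicates)) replicates <- list(rep1 = replicates)
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }

  # per-call error probabilities for criterion 6
  use_rf <- config$rf_cutoff < 1
  if (use_rf) {
    have_prob <- all(vapply(replicates, function(tbl) {
      "error_prob" %in% names(tbl)
    }, logical(1)))
    if (!have_prob) {
      if (is.null(model)) {
        stop("criterion 6 (classifier filter) requires a model or precomputed error_prob")
      }
      replicates <- lapply(replicates, function(tbl) {
        tbl$error_prob <- predict_error_prob(model, tbl, ref, method = method)
        tbl
      })
    }
  }

  long <- dplyr::bind_rows(replicates, .id = "replicate")
  n_reps <- length(replicates)
  attr_tbl <- tibble(criterion = character(0), removed = integer(0))
  note <- function(name, before, after) {
    attr_tbl <<- dplyr::bind_rows(
      attr_tbl, tibble(criterion = name, removed = before - after)
    )
  }

  # (1) target region
  ts <- config$target_start
  te <- config$target_end
  n0 <- nrow(long)
  if (!is.null(ts) && !is.null(te)) {
    long <- long[long$pos >= ts & long$pos + nchar(long$ref) - 1L <= te, ]
  }
  note("1_target_region", n0, nrow(long))

  # (2) NNK signature
  n0 <- nrow(long)
  if (config$require_signature) long <- long[long$matches_signature, ]
  note("2_nnk_signature", n0, nrow(long))

  # (3) single codon
  n0 <- nrow(long)
  if (config$single_codon_only) long <- long[!long$multi_codon, ]
  note("3_single_codon", n0, nrow(long))

  # (4) type-specific count
  n0 <- nrow(long)
  is_snp <- long$variant_type == "SNP"
  long <- long[(is_snp & long$count >= config$min_snp_count) |
                 (!is_snp & long$count >= config$min_mnp_count), ]
  note("4_min_count", n0, nrow(long))

  # (5) strand bias (RACE-like only)
  n0 <- nrow(long)
  if (config$race_like) {
    diffs <- abs(long$n_plus - long$n_minus)
    long <- long[diffs <= config$max_strand_diff, ]
  }
  note("5_strand_bias", n0, nrow(long))

  # (6) classifier: drop variants predicted error in ALL replicates
  n0 <- nrow(long)
  if (use_rf && nrow(long)) {
    flag <- long$error_prob > config$rf_cutoff
    err_by_key <- tapply(flag, paste(long$pos, long$ref, long$alt), all)
    n_by_key <- tapply(flag, paste(long$pos, long$ref, long$alt), length)
    all_err <- names(err_by_key)[err_by_key & n_by_key == n_reps]
    long <- long[!paste(long$pos, long$ref, long$alt) %in% all_err, ]
  }
  note("6_classifier", n0, nrow(long))

  # (7) observed in all replicates
  n0 <- nrow(long)
  if (config$require_all_replicates && nrow(long)) {
    key <- paste(long$pos, long$ref, long$alt)
    keep <- names(which(tapply(long$replicate, key, dplyr::n_distinct) == n_reps))
    long <- long[key %in% keep, ]
  }
  note("7_all_replicates", n0, nrow(long))

  wide <- long |>
    dplyr::select("replicate", "pos", "ref", "alt", "variant_type",
      "aa_change", "count", "frequency") |>
    tidyr::pivot_wider(
      names_from = "replicate",
      values_from = c("count", "frequency")
    ) |>
    dplyr::arrange(.data$pos, .data$ref, .data$alt)
  list(table = wide, attrition = attr_tbl)
}
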