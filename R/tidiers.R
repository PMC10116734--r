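# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn run_call Tidy the calls of a `mave_calls` result.
#' @param x A `mave_calls` object.
#' @param ... Unused.
#' @method tidy mave_calls
#' @export
tidy.mave_calls <- function(x, ...) {
  as_tibble(x$calls)
}

#' @describeIn run_call One-row summary of a `mave_calls` result.
#' @method glance mave_calls
#' @export
glance.mave_calls <- function(x, ...) {
  tibble(
    n_calls = nrow(x$calls),
    n_snp = sum(x$calls$variant_type == "SNP"),
    n_di_mnp = sum(x$calls$variant_type == "di_nt_MNP"),
    n_tri_mnp = sum(x$calls$variant_type == "tri_nt_MNP"),
    n_pairs = x$log$aligned_pairs %||% NA_integer_,
    n_concordant_mismatches = x$log$concordant_mismatches,
    min_count = x$filters$min_count,
    min_bq = x$filters$min_bq,
    max_nm = x$filters$max_nm
  )
}

#' @describeIn train_and_evaluate Per-fold accuracies of a `cv_report`.
#' @param x A `cv_report` object.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble(
    fold = seq_along(x$fold_accuracy),
    accuracy = x$fold_accuracy
  )
}

#' @describeIn train_and_evaluate One-row CV summary of a `cv_report`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    model_kind = x$model_kind, n_folds = x$n_folds,
    mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy
  )
}
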