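# ggplot2 views of the main result types.

#' Fragment-coverage track plot
#'
#' @param coverage Coverage tibble from [compute_fragment_coverage()].
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage) {
  df <- tidyr::uncount(
    dplyr::mutate(coverage, w = .data$end - .data$start),
    weights = .data$w, .id = "off"
  )
  df$position <- df$start + df$off
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "transcript position (1-based)", y = "fragment coverage"
    ) +
    ggplot2::theme_minimal()
}

#' Substitution-class spectrum of an injected-error ledger or call set
#'
#' @param x Either the `errors` ledger of a `mave_library` or a calls tibble
#'   (SNPs classified by their changed base).
#' @return A ggplot of class proportions.
#' @export
plot_error_spectrum <- function(x) {
  cls <- if ("class" %in% names(x)) {
    x$class
  } else {
    snp <- x[x$variant_type == "SNP", ]
    substitution_class(snp$ref, snp$alt)
  }
  tab <- table(factor(cls, levels = SUB_CLASSES))
  df <- tibble(class = names(tab), n = as.integer(tab))
  df$proportion <- df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution class", y = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Feature-importance plot for a random-forest error model
#'
#' @param cv A `cv_report` from [train_and_evaluate()] (rf only).
#' @param top_n Number of features shown.
#' @return A ggplot.
#' @export
plot_importance <- function(cv, top_n = 15L) {
  if (is.null(cv$importance)) stop("no importances (not a random forest?)")
  df <- utils::head(cv$importance, top_n)
  df$feature <- stats::reorder(df$feature, df$mean_decrease_accuracy)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_decrease_accuracy, y = .data$feature
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Frequency-by-type view of a call set
#'
#' @param object A `mave_calls` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mave_calls
#' @export
autoplot.mave_calls <- function(object, ...) {
  df <- object$calls
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$variant_type, y = log10(.data$frequency)
  )) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "log10 variant frequency") +
    ggplot2::theme_minimal()
}
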