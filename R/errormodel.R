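# Machine-learning error correction: build balanced labeled datasets by
# composing the spike-in simulator and the caller on a negative-control
# library, train binary classifiers on the caller's quality features, and
# filter calls by predicted error probability.

AMPLICON_FEATURES <- c(
  "log10_frequency", "variant_type", "matches_signature", "substitution",
  "upstream_nt", "downstream_nt", "r1_median_bq", "r2_median_bq",
  "r2_median_read_pos", "r2_median_nm"
)
RACE_FEATURES <- c(
  AMPLICON_FEATURES,
  "r1_median_bq_plus", "r1_median_bq_minus",
  "r2_median_bq_plus", "r2_median_bq_minus",
  "r2_median_read_pos_plus", "r2_median_read_pos_minus",
  "r2_median_nm_plus", "r2_median_nm_minus",
  "strand_count_diff"
)

#' Quality-feature table for variant calls
#'
#' The classifier features extracted by the caller: log10 frequency, variant
#' type, mutagenesis-signature match, strand-collapsed substitution class of
#' the first changed base, flanking reference bases, and per-mate median
#' quality summaries. RACE-like designs add per-sample-strand summaries and
#' the strand count difference (19 features in total; 10 for amplicon).
#'
#' @param calls Calls tibble from [aggregate_variants()] / [run_call()].
#' @param ref A [transcript_reference()].
#' @param method `"amplicon"` or `"race_like"` (feature schema).
#' @return Tibble of features, rows aligned with `calls`.
#' @export
call_features <- function(calls, ref, method = c("amplicon", "race_like")) {
  method <- match.arg(method)
  if (nrow(calls) == 0L) {
    cols <- if (method == "amplicon") AMPLICON_FEATURES else RACE_FEATURES
    out <- tibble(.rows = 0)
    for (cc in cols) out[[cc]] <- numeric(0)
    return(out)
  }
  first_diff <- mapply(function(r, a) {
    which(charToRaw(r) != charToRaw(a))[1]
  }, calls$ref, calls$alt)
  fb <- substr(calls$ref, first_diff, first_diff)
  tb <- substr(calls$alt, first_diff, first_diff)
  L <- nchar(ref$sequence)
  up_pos <- calls$pos - 1L
  dn_pos <- calls$pos + nchar(calls$ref)
  ft <- tibble(
    log10_frequency = log10(calls$frequency),
    variant_type = factor(calls$variant_type,
      levels = c("SNP", "di_nt_MNP", "tri_nt_MNP")),
    matches_signature = calls$matches_signature,
    substitution = factor(substitution_class(fb, tb), levels = SUB_CLASSES),
    upstream_nt = factor(
      ifelse(up_pos >= 1L, substring(ref$sequence, up_pos, up_pos), "N"),
      levels = c(DNA_BASES, "N")),
    downstream_nt = factor(
      ifelse(dn_pos <= L, substring(ref$sequence, dn_pos, dn_pos), "N"),
      levels = c(DNA_BASES, "N")),
    r1_median_bq = calls$r1_median_bq,
    r2_median_bq = calls$r2_median_bq,
    r2_median_read_pos = calls$r2_median_read_pos,
    r2_median_nm = calls$r2_median_nm
  )
  if (method == "race_like") {
    ft$r1_median_bq_plus <- calls$r1_median_bq_plus
    ft$r1_median_bq_minus <- calls$r1_median_bq_minus
    ft$r2_median_bq_plus <- calls$r2_median_bq_plus
    ft$r2_median_bq_minus <- calls$r2_median_bq_minus
    ft$r2_median_read_pos_plus <- calls$r2_median_read_pos_plus
    ft$r2_median_read_pos_minus <- calls$r2_median_read_pos_minus
    ft$r2_median_nm_plus <- calls$r2_median_nm_plus
    ft$r2_median_nm_minus <- calls$r2_median_nm_minus
    ft$strand_count_diff <- abs(calls$n_plus - calls$n_minus)
    # per-feature rough fix: strand-specific summaries are missing when a
    # strand has no observations; impute the feature median
    for (cc in setdiff(RACE_FEATURES, AMPLICON_FEATURES)) {
      v <- ft[[cc]]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      ft[[cc]] <- v
    }
  }
  ft
}

#' Component-mismatch weight per variant type (SNP=1, di=2, tri=3)
#' @noRd
type_weight <- function(variant_type) {
  c(SNP = 1L, di_nt_MNP = 2L, tri_nt_MNP = 3L)[variant_type]
}

#' Sample a balanced truth set against a negative-control call set
#'
#' Draws NNK-consistent single-codon variant specs (type mix: `snp_prop`
#' SNPs, remainder split between di- and tri-nt MNPs) with target frequencies
#' resampled from the mutagenized library's empirical frequency distribution,
#' stopping when the cumulative component-mismatch count (SNP=1, di=2, tri=3)
#' reaches the number of false-positive mismatches in the NC call set (same
#' weighting).
#'
#' @param nc_calls Caller output on the negative control (min count 1).
#' @param mut_calls Caller output on a mutagenized library (frequency donor).
#' @param ref A [transcript_reference()].
#' @param snp_prop SNP proportion in the truth set.
#' @param seed Integer seed.
#' @return Spec tibble (`pos`, `ref`, `alt`, `target_frequency`).
#' @export
build_balanced_truthset <- function(nc_calls, mut_calls, ref,
                                    snp_prop = 0.25, seed = 1L) {
  if (nrow(nc_calls) == 0L) {
    stop("negative-control call set is empty; nothing to balance against")
  }
  target <- sum(type_weight(nc_calls$variant_type))
  if (target == 0L) stop("negative-control call set has no mismatches")
  set.seed(derive_seed(seed, 61L))
  freq_pool <- mut_calls$frequency
  if (length(freq_pool) == 0L) freq_pool <- nc_calls$frequency
  freq_pool <- pmin(pmax(freq_pool, 1e-6), 0.999)

  n_codons <- (ref$cds_end - ref$cds_start) %/% 3L
  seen <- character(0)
  out <- list()
  got <- 0L
  guard <- 0L
  while (got < target) {
    guard <- guard + 1L
    if (guard > 10000L + 200L * target) {
      stop("unable to sample a balanced truth set for this target region")
    }
    remaining <- target - got
    repeat {
      u <- stats::runif(1)
      len <- if (u < snp_prop) 1L else if (u < snp_prop + (1 - snp_prop) / 2) 2L else 3L
      if (len <= remaining) break
    }
    v <- sample_nnk_change(ref, n_codons, len)
    if (is.null(v)) next
    key <- paste(v$pos, v$ref, v$alt)
    if (key %in% seen) next
    seen <- c(seen, key)
    v$target_frequency <- sample(freq_pool, 1L)
    out[[length(out) + 1L]] <- v
    got <- got + len
  }
  dplyr::bind_rows(out)
}

#' One NNK-consistent single-codon change of a given span
#' @noRd
sample_nnk_change <- function(ref, n_codons, len) {
  ci <- sample.int(n_codons, 1L) - 1L
  c_start <- ref$cds_start + 3L * ci + 1L
  rc <- ref_seq_at(ref, c_start, c_start + 2L)
  # offsets within the codon the variant spans (contiguous len bases)
  off <- sample.int(3L - len + 1L, 1L)
  ac <- rc
  for (k in off:(off + len - 1L)) {
    b <- substr(rc, k, k)
    alts <- if (k == 3L) setdiff(c("G", "T"), b) else setdiff(DNA_BASES, b)
    if (!length(alts)) return(NULL)
    substr(ac, k, k) <- sample(alts, 1L)
  }
  # resulting codon must carry the NNK third base
  if (!substr(ac, 3L, 3L) %in% c("G", "T")) return(NULL)
  tibble(
    pos = c_start + off - 1L,
    ref = substr(rc, off, off + len - 1L),
    alt = substr(ac, off, off + len - 1L)
  )
}

#' Build a labeled training dataset by simulating into an NC background
#'
#' Edits the truth set into the negative-control alignments, re-runs the
#' caller on the edited reads, and labels each call `true_variant` iff its
#' `(pos, ref, alt)` is in the truth set. Calls outside the CDS or with
#' frequency >= 0.3 are excluded.
#'
#' @param nc_alignments Alignments tibble of the negative-control library.
#' @param truthset Spec tibble from [build_balanced_truthset()].
#' @param ref A [transcript_reference()].
#' @param filters A [call_filters()] (typically min count 1, signature
#'   flagged not dropped so the signature stays a feature).
#' @param method Library method for the feature schema.
#' @param seed Integer seed.
#' @return Tibble: `label` (factor error/true_variant), features, and the
#'   call identity columns `pos`, `ref`, `alt`, `frequency`.
#' @export
generate_training_dataset <- function(nc_alignments, truthset, ref,
                                      filters = call_filters(
                                        min_count = 1L,
                                        signature = "NNK",
                                        signature_action = "flag"
                                      ),
                                      method = c("amplicon", "race_like"),
                                      seed = 1L) {
  method <- match.arg(method)
  plan <- plan_edits(truthset, nc_alignments, ref, seed = seed)
  edited <- apply_edits(plan, nc_alignments)
  res <- run_call(edited$reads, ref, filters, method = method, seed = seed)
  calls <- res$calls
  calls <- calls[calls$pos > ref$cds_start &
                   calls$pos + nchar(calls$ref) - 1L <= ref$cds_end &
                   calls$frequency < 0.3, ]
  truth_key <- paste(truthset$pos, truthset$ref, truthset$alt)
  lab <- ifelse(paste(calls$pos, calls$ref, calls$alt) %in% truth_key,
    "true_variant", "error"
  )
  ft <- call_features(calls, ref, method = method)
  dplyr::bind_cols(
    tibble(
      label = factor(lab, levels = c("error", "true_variant")),
      pos = calls$pos, ref = calls$ref, alt = calls$alt,
      frequency = calls$frequency
    ),
    ft
  )
}

# --- model fitting ---------------------------------------------------------

#' Numeric design matrix for a feature tibble (factors one-hot encoded)
#' @noRd
feature_matrix <- function(ft, schema) {
  ft <- ft[schema$features]
  for (cc in names(ft)) {
    if (is.logical(ft[[cc]])) ft[[cc]] <- as.numeric(ft[[cc]])
    if (is.numeric(ft[[cc]]) && anyNA(ft[[cc]])) {
      v <- ft[[cc]]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      ft[[cc]] <- v
    }
  }
  mm <- stats::model.matrix(~ . - 1, data = as.data.frame(ft))
  storage.mode(mm) <- "double"
  mm
}

#' Stratified fold assignment
#' @noRd
make_folds <- function(label, k) {
  fold <- integer(length(label))
  for (lv in levels(label)) {
    idx <- which(label == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_model <- function(kind, x, y, hp) {
  switch(kind,
    rf = randomForest::randomForest(
      x = as.data.frame(x), y = y,
      mtry = hp$mtry, ntree = 500L, importance = TRUE
    ),
    gbm = xgboost::xgboost(
      x, y,
      nrounds = hp$nrounds, max_depth = hp$max_depth, learning_rate = 0.3,
      nthreads = 1L, verbosity = 0
    ),
    glm_elasticnet = glmnet::glmnet(
      x, y, family = "binomial", alpha = hp$alpha, lambda = hp$lambda
    ),
    svc = e1071::svm(
      x = x, y = y, kernel = "radial", cost = hp$cost, probability = TRUE,
      scale = apply(x, 2, stats::sd) > 0
    ),
    knn = list(x = x, y = y, k = hp$k, features = hp$features)
  )
}

predict_prob_true <- function(kind, model, x) {
  switch(kind,
    rf = stats::predict(model, as.data.frame(x), type = "prob")[, "true_variant"],
    gbm = as.numeric(stats::predict(model, x)), # prob of the 2nd level (true_variant)
    glm_elasticnet = as.numeric(stats::predict(model, x, type = "response")),
    svc = {
      p <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
      p[, "true_variant"]
    },
    knn = {
      xs <- x[, model$features, drop = FALSE]
      tr <- model$x[, model$features, drop = FALSE]
      mu <- colMeans(tr)
      sdv <- apply(tr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      pr <- class::knn(
        scale(tr, mu, sdv), scale(xs, mu, sdv), model$y,
        k = min(model$k, nrow(tr)), prob = TRUE
      )
      pw <- attr(pr, "prob") # proportion of votes for the winning class
      ifelse(pr == "true_variant", pw, 1 - pw)
    }
  )
}

hp_grid <- function(kind, p) {
  switch(kind,
    rf = lapply(unique(pmax(1L, c(2L, floor(sqrt(p)), floor(p / 2)))),
                function(m) list(mtry = m)),
    gbm = list(
      list(nrounds = 50L, max_depth = 2L),
      list(nrounds = 100L, max_depth = 3L)
    ),
    glm_elasticnet = do.call(c, lapply(c(0, 0.5, 1), function(a) {
      lapply(c(0.1, 0.01, 0.001), function(l) list(alpha = a, lambda = l))
    })),
    svc = lapply(c(0.1, 1, 10), function(cst) list(cost = cst)),
    knn = lapply(c(3L, 5L, 7L), function(k) list(k = k))
  )
}

#' Pick hyperparameters on a tuning subset (internal holdout accuracy)
#' @noRd
tune_hp <- function(kind, x, y, idx_tune, all_features) {
  xt <- x[idx_tune, , drop = FALSE]
  yt <- y[idx_tune]
  if (length(unique(yt)) < 2L || length(yt) < 10L) {
    hp <- hp_grid(kind, ncol(x))[[1]]
    if (kind == "knn") hp$features <- all_features
    return(hp)
  }
  inner <- make_folds(yt, 5L)
  score_hp <- function(hp) {
    acc <- vapply(seq_len(5L), function(f) {
      tr <- inner != f
      if (length(unique(yt[tr])) < 2L) return(NA_real_)
      # small tuning splits trip sample-size warnings in some fitters;
      # they are expected here and not informative
      m <- suppressWarnings(fit_model(kind, xt[tr, , drop = FALSE], yt[tr], hp))
      p <- suppressWarnings(predict_prob_true(kind, m, xt[!tr, , drop = FALSE]))
      mean((p > 0.5) == (yt[!tr] == "true_variant"))
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }
  if (kind == "knn") {
    # greedy forward selection over 3-10 features, then k from the grid
    chosen <- character(0)
    pool <- all_features
    best_overall <- NULL
    while (length(chosen) < min(10L, length(all_features))) {
      scores <- vapply(pool, function(fnew) {
        hp <- list(k = 5L, features = c(chosen, fnew))
        score_hp(hp)
      }, numeric(1))
      chosen <- c(chosen, pool[which.max(scores)])
      pool <- setdiff(pool, chosen)
      if (length(chosen) >= 3L &&
          (is.null(best_overall) || max(scores) > best_overall$score)) {
        best_overall <- list(features = chosen, score = max(scores))
      }
      if (!length(pool)) break
    }
    if (is.null(best_overall)) {
      best_overall <- list(features = chosen, score = 0)
    }
    ks <- vapply(c(3L, 5L, 7L), function(k) {
      score_hp(list(k = k, features = best_overall$features))
    }, numeric(1))
    return(list(k = c(3L, 5L, 7L)[which.max(ks)],
                features = best_overall$features))
  }
  grid <- hp_grid(kind, ncol(x))
  scores <- vapply(grid, score_hp, numeric(1))
  grid[[which.max(scores)]]
}

#' Train and evaluate an error-correction classifier
#'
#' Nested 10-fold cross-validation: within each outer fold, 20% of the
#' training data tunes hyperparameters (5-fold CV over a small grid; for kNN
#' additionally greedy forward selection of 3-10 features), the model is
#' refit on the full training fold and scored on the held-out fold. The final
#' model is refit on all data with hyperparameters tuned the same way.
#' Random forests report mean-decrease-in-accuracy feature importances.
#'
#' @param examples Output of [generate_training_dataset()] (or any tibble
#'   with a two-level `label` factor plus feature columns).
#' @param model_kind One of `"rf"`, `"gbm"`, `"glm_elasticnet"`, `"knn"`,
#'   `"svc"`.
#' @param seed Integer seed.
#' @param n_folds Outer CV folds.
#' @param tune_frac Fraction of each training fold used for tuning.
#' @param cutoff Error-probability cutoff stored in the bundle.
#' @return A list: `model` (class `error_model` bundle) and `cv` (class
#'   `cv_report`: per-fold accuracy, mean/sd, importances).
#' @export
train_and_evaluate <- function(examples, model_kind = c(
                                 "rf", "gbm", "glm_elasticnet", "knn", "svc"
                               ),
                               seed = 1L, n_folds = 10L, tune_frac = 0.2,
                               cutoff = 0.5) {
  model_kind <- match.arg(model_kind)
  y <- examples$label
  if (!is.factor(y)) y <- factor(y, levels = c("error", "true_variant"))
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  feat_cols <- setdiff(names(examples), c("label", "pos", "ref", "alt", "frequency"))
  schema <- list(features = feat_cols)
  x <- feature_matrix(examples, schema)
  set.seed(derive_seed(seed, 71L))

  fold <- make_folds(y, n_folds)
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    tune_idx <- sample(tr, max(10L, round(tune_frac * length(tr))))
    hp <- tune_hp(model_kind, x, y, tune_idx, colnames(x))
    m <- fit_model(model_kind, x[tr, , drop = FALSE], y[tr], hp)
    p <- predict_prob_true(model_kind, m, x[te, , drop = FALSE])
    fold_acc[f] <- mean((p > 0.5) == (y[te] == "true_variant"))
  }

  tune_idx <- sample(seq_along(y), max(10L, round(tune_frac * length(y))))
  hp <- tune_hp(model_kind, x, y, tune_idx, colnames(x))
  final <- fit_model(model_kind, x, y, hp)
  importance <- NULL
  if (model_kind == "rf") {
    imp <- randomForest::importance(final, type = 1, scale = TRUE)
    importance <- tibble(
      feature = rownames(imp),
      mean_decrease_accuracy = as.numeric(imp[, 1])
    ) |> dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy))
  }
  cv <- structure(
    list(
      fold_accuracy = fold_acc,
      mean_accuracy = mean(fold_acc),
      sd_accuracy = stats::sd(fold_acc),
      importance = importance,
      model_kind = model_kind, n_folds = n_folds
    ),
    class = "cv_report"
  )
  bundle <- structure(
    list(
      model = final, kind = model_kind, hp = hp,
      schema = schema, feature_columns = colnames(x),
      cutoff = cutoff, seed = seed, n_examples = length(y)
    ),
    class = "error_model"
  )
  list(model = bundle, cv = cv)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s, %d-fold CV accuracy %.3f +/- %.3f\n",
    x$model_kind, x$n_folds, x$mean_accuracy, x$sd_accuracy
  ))
  invisible(x)
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> %s on %d examples, %d features, cutoff %.2f\n",
    x$kind, x$n_examples, length(x$schema$features), x$cutoff
  ))
  invisible(x)
}

#' Predicted error probability for calls
#'
#' @param model An `error_model` bundle.
#' @param calls Calls tibble.
#' @param ref A [transcript_reference()].
#' @param method Feature schema method.
#' @return Numeric vector of error probabilities.
#' @export
predict_error_prob <- function(model, calls, ref,
                               method = c("amplicon", "race_like")) {
  method <- match.arg(method)
  ft <- call_features(calls, ref, method = method)
  missing <- setdiff(model$schema$features, names(ft))
  extra <- setdiff(names(ft), model$schema$features)
  if (length(missing)) {
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "),
      if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  x <- feature_matrix(ft, model$schema)
  x <- x[, model$feature_columns, drop = FALSE]
  1 - predict_prob_true(model$kind, model$model, x)
}

#' Filter calls by predicted error probability
#'
#' Calls with predicted error probability strictly above `cutoff` are removed
#' (or flagged). With a list of replicate call tables, a variant is removed
#' only when it is predicted an error in ALL replicates.
#'
#' @param calls Calls tibble, or a named list of replicate calls tibbles.
#' @param model An `error_model` bundle.
#' @param ref A [transcript_reference()].
#' @param cutoff Probability cutoff (default: the bundle's).
#' @param action `"drop"` removes failing calls; `"flag"` appends columns.
#' @param method Feature schema method.
#' @return Filtered calls tibble (or list), with `error_prob` and
#'   `predicted_error` columns appended.
#' @export
score_and_filter <- function(calls, model, ref, cutoff = model$cutoff,
                             action = c("drop", "flag"),
                             method = c("amplicon", "race_like")) {
  action <- match.arg(action)
  method <- match.arg(method)
  score1 <- function(tbl) {
    tbl$error_prob <- if (nrow(tbl)) {
      predict_error_prob(model, tbl, ref, method = method)
    } else {
      numeric(0)
    }
    tbl$predicted_error <- tbl$error_prob > cutoff
    tbl
  }
  if (is.data.frame(calls)) {
    out <- score1(calls)
    if (action == "drop") out <- out[!out$predicted_error, ]
    return(out)
  }
  reps <- lapply(calls, score1)
  keys <- lapply(reps, function(tbl) paste(tbl$pos, tbl$ref, tbl$alt))
  err_keys <- lapply(reps, function(tbl) {
    paste(tbl$pos, tbl$ref, tbl$alt)[tbl$predicted_error]
  })
  all_err <- Reduce(intersect, err_keys)
  lapply(reps, function(tbl) {
    k <- paste(tbl$pos, tbl$ref, tbl$alt)
    tbl$predicted_error_all_reps <- k %in% all_err
    if (action == "drop") tbl[!tbl$predicted_error_all_reps, ] else tbl
  })
}
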