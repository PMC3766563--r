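#' Run the full benchmark protocol end-to-end
#'
#' Loads a positive/negative FASTA pair, encodes the 420-dimensional
#' composition matrix, evaluates the naive Bayes classifier by jackknife on
#' (a) the full 420 features and (b) a reduced subset (by default the
#' shipped [antiox_reference_features]; optionally a fresh CFS selection),
#' reporting each model at the theta = 0 operating point and at the
#' threshold tuned on the held-out scores. If an independent FASTA of
#' antioxidant proteins is given, a model fitted on the whole training set
#' is applied to it and per-protein calls are reported.
#'
#' @param pos_fasta,neg_fasta Training FASTA paths (positive / negative).
#' @param independent_fasta Optional FASTA of independent positives.
#' @param subset Feature names for the reduced model, a `feature_subset`,
#'   or `"select"` to run [best_first_select()] on the training matrix.
#' @param seed Seed (used only when `subset = "select"` is extended to
#'   cross-validated selection downstream; kept for manifest completeness).
#' @return A list with elements `full420` and `reduced`, each containing
#'   `theta0` and `tuned` evaluation reports, plus `subset_used`,
#'   `class_counts`, and (optionally) `independent`.
#' @export
replicate_benchmark <- function(pos_fasta, neg_fasta,
                                independent_fasta = NULL,
                                subset = antiox_reference_features,
                                seed = 1L) {
  ds <- load_labeled(pos_fasta, neg_fasta)
  fm <- encode_dataset(ds)
  y <- ds$labels

  eval_both <- function(mat) {
    rep0 <- jackknife(mat, y, theta = 0)
    th <- as.numeric(tune_theta(rep0$per_sample$score, y))
    pred <- as.integer(rep0$per_sample$score >= th)
    tuned <- make_eval_report(rep0$per_sample$id, y, rep0$per_sample$score,
                              pred, "jackknife", th)
    list(theta0 = rep0, tuned = tuned)
  }

  if (identical(subset, "select")) {
    subset <- best_first_select(fm, y)
  }
  subset_names <- if (inherits(subset, "feature_subset")) subset$names else subset
  out <- list(
    class_counts = c(pos = sum(y == 1L), neg = sum(y == 0L)),
    subset_used = subset_names,
    full420 = eval_both(fm),
    reduced = eval_both(subset_columns(fm, subset_names))
  )

  if (!is.null(independent_fasta)) {
    ind <- read_fasta(independent_fasta)
    ind <- validate_records(ind, "drop")$kept
    ind_fm <- subset_columns(encode_dataset(ind), subset_names)
    model <- nb_fit(subset_columns(fm, subset_names), y)
    out$independent <- independent_test(model, ind_fm)
  }
  out
}
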