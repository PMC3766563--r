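# Naive Bayes over composition features.
#
# The classifier compares the two class posteriors through the log
# posterior-odds
#   log P(C=1|F)/P(C=0|F) = log P(C=1)/P(C=0) + sum_i log P(f_i|C=1)/P(f_i|C=0)
# under the conditional-independence assumption, and predicts the
# antioxidant class (1) when the score is >= the decision threshold theta.
# theta trades sensitivity against specificity and can be tuned on training
# scores.

var_floor <- function(rng) pmax(1e-9, (0.01 * rng)^2)

#' Fit a naive Bayes model on a feature matrix
#'
#' Class priors are Laplace-smoothed frequencies `(n_c + 1) / (N + 2)`.
#' With the default Gaussian density, each feature gets a per-class mean
#' and sample variance, the variance floored at
#' `max(1e-9, (0.01 * feature range)^2)` so constant features cannot
#' produce infinite log-ratios. The `"multinomial"` variant instead
#' discretizes each feature with [discretize_mdl()] and uses
#' Laplace-smoothed bin probabilities per class.
#'
#' @param fm Numeric feature matrix (samples x features, named columns).
#' @param labels Binary labels (1 = antioxidant) aligned with rows.
#' @param theta Decision threshold stored with the model (default 0, i.e.
#'   plain posterior comparison).
#' @param density `"gaussian"` (default) or `"multinomial"`.
#' @return An `antiox_nb` model object.
#' @export
nb_fit <- function(fm, labels, theta = 0,
                   density = c("gaussian", "multinomial")) {
  density <- match.arg(density)
  y <- as_binary_labels(labels)
  stopifnot(is.matrix(fm), nrow(fm) == length(y))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) {
    stop("each class needs at least 2 samples (variance undefined otherwise)")
  }
  n <- n1 + n0
  prior_pos <- (n1 + 1) / (n + 2)
  prior_neg <- (n0 + 1) / (n + 2)
  model <- list(
    prior_pos = prior_pos, prior_neg = prior_neg,
    feature_names = colnames(fm), theta = theta, density = density,
    n_pos = n1, n_neg = n0
  )
  X1 <- fm[y == 1L, , drop = FALSE]
  X0 <- fm[y == 0L, , drop = FALSE]
  if (density == "gaussian") {
    mu1 <- colMeans(X1)
    mu0 <- colMeans(X0)
    v1 <- (colSums(X1^2) - n1 * mu1^2) / (n1 - 1)
    v0 <- (colSums(X0^2) - n0 * mu0^2) / (n0 - 1)
    rng <- apply(fm, 2, max) - apply(fm, 2, min)
    floor_ <- var_floor(rng)
    model$mean_pos <- mu1
    model$mean_neg <- mu0
    model$var_pos <- pmax(v1, floor_)
    model$var_neg <- pmax(v0, floor_)
  } else {
    p <- ncol(fm)
    cuts <- vector("list", p)
    logp1 <- vector("list", p)
    logp0 <- vector("list", p)
    for (j in seq_len(p)) {
      cj <- discretize_mdl(fm[, j], y)
      nb <- length(cj) + 1L
      b1 <- tabulate(findInterval(X1[, j], cj) + 1L, nb)
      b0 <- tabulate(findInterval(X0[, j], cj) + 1L, nb)
      cuts[[j]] <- cj
      logp1[[j]] <- log((b1 + 1) / (n1 + nb))
      logp0[[j]] <- log((b0 + 1) / (n0 + nb))
    }
    model$cuts <- cuts
    model$log_prob_pos <- logp1
    model$log_prob_neg <- logp0
  }
  structure(model, class = "antiox_nb")
}

as_model_matrix <- function(model, x) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1L,
                dimnames = list(NULL, names(x) %||% model$feature_names))
  }
  p <- length(model$feature_names)
  if (ncol(x) != p) {
    stop("feature dimension mismatch: model expects ", p, " features, got ",
         ncol(x))
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(x))
    if (length(missing)) {
      stop("feature name mismatch; missing: ", paste(missing, collapse = ", "))
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  x
}

#' Log posterior-odds score of samples under a naive Bayes model
#'
#' Returns `log(prior_pos/prior_neg) + sum_i log(p_i(x_i|1)/p_i(x_i|0))`,
#' finite for all finite inputs thanks to the variance floor (Gaussian) or
#' Laplace smoothing (multinomial). Positive scores favour the antioxidant
#' class.
#'
#' @param model An `antiox_nb` model.
#' @param x Feature vector or matrix matching `model$feature_names`.
#' @return Numeric vector of scores, one per sample.
#' @export
nb_log_odds <- function(model, x) {
  stopifnot(inherits(model, "antiox_nb"))
  x <- as_model_matrix(model, x)
  n <- nrow(x)
  base <- log(model$prior_pos / model$prior_neg)
  if (model$density == "gaussian") {
    l1 <- -0.5 * (log(2 * pi * model$var_pos)[col(x)] +
                    sweep(x, 2, model$mean_pos)^2 /
                    model$var_pos[col(x)])
    l0 <- -0.5 * (log(2 * pi * model$var_neg)[col(x)] +
                    sweep(x, 2, model$mean_neg)^2 /
                    model$var_neg[col(x)])
    scores <- base + rowSums(l1 - l0)
  } else {
    acc <- rep(base, n)
    for (j in seq_along(model$cuts)) {
      bin <- findInterval(x[, j], model$cuts[[j]]) + 1L
      acc <- acc + model$log_prob_pos[[j]][bin] - model$log_prob_neg[[j]][bin]
    }
    scores <- acc
  }
  stats::setNames(as.numeric(scores), rownames(x))
}

#' Predict classes from a naive Bayes model
#'
#' Class 1 (antioxidant) iff the log posterior-odds is `>= theta`; ties go
#' to class 1.
#'
#' @param model An `antiox_nb` model.
#' @param x Feature vector or matrix.
#' @param theta Decision threshold (default: the model's stored theta).
#' @return A list with `class` (integer 0/1 vector) and `score`
#'   (log posterior-odds).
#' @export
nb_predict <- function(model, x, theta = model$theta) {
  score <- nb_log_odds(model, x)
  list(class = as.integer(score >= theta), score = score)
}

#' Tune the decision threshold on scored training data
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus the two infinite sentinels (everything positive /
#' everything negative). The threshold maximizing the objective is
#' returned; ties pick the smallest threshold.
#'
#' @param scores Finite per-sample log posterior-odds.
#' @param labels Binary labels aligned with `scores`.
#' @param objective `"accuracy"` (default) or `"youden"` (Sn + Sp - 1).
#' @return The chosen threshold (may be `-Inf`/`Inf` in degenerate cases),
#'   with the achieved objective value as attribute `"objective"`.
#' @export
tune_theta <- function(scores, labels, objective = c("accuracy", "youden")) {
  objective <- match.arg(objective)
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  if (length(unique(y)) < 2L) stop("both classes required to tune theta")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  vals <- vapply(cand, function(th) {
    pred <- scores >= th
    tp <- sum(pred & y == 1L)
    tn <- sum(!pred & y == 0L)
    if (objective == "accuracy") {
      (tp + tn) / length(y)
    } else {
      tp / np + tn / nn - 1
    }
  }, numeric(1))
  best <- which.max(vals)  # which.max takes the first (smallest) maximizer
  structure(cand[best], objective = vals[best])
}

#' Serialize a naive Bayes model to JSON
#'
#' @param model An `antiox_nb` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nb_write_json <- function(model, path) {
  stopifnot(inherits(model, "antiox_nb"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a naive Bayes model serialized with [nb_write_json()]
#'
#' @param path JSON path.
#' @return An `antiox_nb` model.
#' @export
nb_read_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mean_pos", "mean_neg", "var_pos", "var_neg")) {
    if (!is.null(m[[f]])) {
      m[[f]] <- stats::setNames(as.numeric(m[[f]]), m$feature_names)
    }
  }
  structure(m, class = "antiox_nb")
}

#' @export
print.antiox_nb <- function(x, ...) {
  cat("Naive Bayes antioxidant model (", x$density, " densities)\n", sep = "")
  cat("  features:", length(x$feature_names),
      " priors:", format(x$prior_pos, digits = 3), "/",
      format(x$prior_neg, digits = 3),
      " theta:", format(x$theta, digits = 3), "\n")
  invisible(x)
}
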