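# Cross-validated evaluation: jackknife (leave-one-out), stratified k-fold,
# independent test sets; confusion-matrix metrics, ROC curve and auROC.

#' Confusion-matrix metrics
#'
#' TP/TN/FP/FN counts and the derived rates
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/N`, computed with
#' integer arithmetic before division. A rate whose denominator class is
#' absent is reported as `NA` and named in `notes`.
#'
#' @param pred Binary predictions (1 = antioxidant).
#' @param truth Binary true labels.
#' @return List with `TP`, `TN`, `FP`, `FN`, `Sn`, `Sp`, `Acc`, `notes`.
#' @export
confusion_metrics <- function(pred, truth) {
  p <- as_binary_labels(pred)
  y <- as_binary_labels(truth)
  if (length(p) != length(y)) stop("pred and truth must have equal length")
  tp <- sum(p == 1L & y == 1L)
  tn <- sum(p == 0L & y == 0L)
  fp <- sum(p == 1L & y == 0L)
  fn <- sum(p == 0L & y == 1L)
  notes <- character(0)
  sn <- if (tp + fn > 0L) tp / (tp + fn) else {
    notes <- c(notes, "Sn undefined: no positive samples")
    NA_real_
  }
  sp <- if (tn + fp > 0L) tn / (tn + fp) else {
    notes <- c(notes, "Sp undefined: no negative samples")
    NA_real_
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       Sn = sn, Sp = sp, Acc = (tp + tn) / length(y), notes = notes)
}

#' ROC curve and auROC from scores
#'
#' Sweeps the decision threshold over all distinct scores; tied scores form
#' a single ROC segment (equivalent to the half-credit rank convention).
#' auROC is the trapezoidal area, which equals the rank statistic
#' `(#\\{pos > neg\\} + 0.5 * #\\{pos = neg\\}) / (n_pos * n_neg)`.
#'
#' @param scores Finite per-sample scores, larger = more antioxidant-like.
#' @param truth Binary true labels.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`,
#'   starting at (0,0) and ending at (1,1)) and `auroc`.
#' @export
roc_auroc <- function(scores, truth) {
  y <- as_binary_labels(truth)
  stopifnot(length(scores) == length(y))
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(y)) < 2L) stop("ROC requires both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yo <- y[o]
  np <- sum(yo == 1L)
  nn <- length(yo) - np
  tp <- cumsum(yo == 1L)
  fp <- cumsum(yo == 0L)
  block_end <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- c(0, tp[block_end] / np)
  fpr <- c(0, fp[block_end] / nn)
  auroc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[block_end])),
       auroc = auroc)
}

make_eval_report <- function(ids, truth, scores, pred, protocol, theta_used) {
  cm <- confusion_metrics(pred, truth)
  roc <- if (length(unique(truth)) > 1L) roc_auroc(scores, truth) else NULL
  structure(
    list(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN,
         Sn = cm$Sn, Sp = cm$Sp, Acc = cm$Acc, notes = cm$notes,
         roc_points = roc$points, auroc = roc$auroc,
         per_sample = data.frame(id = ids, truth = truth, score = scores,
                                 pred = pred, stringsAsFactors = FALSE,
                                 row.names = NULL),
         protocol = protocol, theta_used = theta_used),
    class = "antiox_eval"
  )
}

#' @export
print.antiox_eval <- function(x, ...) {
  cat("Evaluation (", paste(deparse(x$protocol), collapse = ""), ")\n", sep = "")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  Sn=%s Sp=%s Acc=%s auROC=%s (theta=%s)\n",
              format(100 * x$Sn, digits = 4), format(100 * x$Sp, digits = 4),
              format(100 * x$Acc, digits = 4),
              if (is.null(x$auroc)) "NA" else format(x$auroc, digits = 3),
              format(x$theta_used[1L], digits = 3)))
  for (nt in x$notes) cat(" ", nt, "\n")
  invisible(x)
}

# second-largest / second-smallest per column, plus multiplicity of extremes
col_extremes <- function(X) {
  ap <- function(f) apply(X, 2, f)
  mx <- ap(max)
  mn <- ap(min)
  mx2 <- ap(function(v) -sort(-v, partial = 2)[2L])
  mn2 <- ap(function(v) sort(v, partial = 2)[2L])
  list(max = mx, min = mn, max2 = mx2, min2 = mn2,
       n_max = colSums(X == rep(mx, each = nrow(X))),
       n_min = colSums(X == rep(mn, each = nrow(X))))
}

# Exact leave-one-out log-odds under the Gaussian NB, computed from class
# sufficient statistics (identical to refitting n models, but O(n p)).
loo_scores_gaussian <- function(fm, y) {
  n <- nrow(fm)
  pos <- y == 1L
  neg <- !pos
  n1 <- sum(pos)
  n0 <- sum(neg)
  if (n1 < 3L || n0 < 3L) stop("jackknife with Gaussian NB needs >= 3 samples per class")
  S1 <- colSums(fm[pos, , drop = FALSE])
  S0 <- colSums(fm[neg, , drop = FALSE])
  Q1 <- colSums(fm[pos, , drop = FALSE]^2)
  Q0 <- colSums(fm[neg, , drop = FALSE]^2)
  ex <- col_extremes(fm)
  scores <- numeric(n)

  score_block <- function(idx, own) {
    X <- fm[idx, , drop = FALSE]
    m <- nrow(X)
    if (own == 1L) {
      nc <- n1 - 1L
      mu_o <- sweep(-X, 2, S1, `+`) / nc
      v_o <- (sweep(-X^2, 2, Q1, `+`) - nc * mu_o^2) / (nc - 1L)
      mu_f <- matrix(S0 / n0, m, ncol(fm), byrow = TRUE)
      v_f <- matrix((Q0 - n0 * (S0 / n0)^2) / (n0 - 1L), m, ncol(fm),
                    byrow = TRUE)
      pr <- log((nc + 1) / (n + 1)) - log((n0 + 1) / (n + 1))
    } else {
      nc <- n0 - 1L
      mu_o <- sweep(-X, 2, S0, `+`) / nc
      v_o <- (sweep(-X^2, 2, Q0, `+`) - nc * mu_o^2) / (nc - 1L)
      mu_f <- matrix(S1 / n1, m, ncol(fm), byrow = TRUE)
      v_f <- matrix((Q1 - n1 * (S1 / n1)^2) / (n1 - 1L), m, ncol(fm),
                    byrow = TRUE)
      pr <- log((n1 + 1) / (n + 1)) - log((nc + 1) / (n + 1))
    }
    # training range excludes the held-out row: adjust unique extremes
    mxm <- matrix(ex$max, m, ncol(fm), byrow = TRUE)
    mnm <- matrix(ex$min, m, ncol(fm), byrow = TRUE)
    at_max <- X == mxm & matrix(ex$n_max, m, ncol(fm), byrow = TRUE) == 1L
    at_min <- X == mnm & matrix(ex$n_min, m, ncol(fm), byrow = TRUE) == 1L
    mxm[at_max] <- matrix(ex$max2, m, ncol(fm), byrow = TRUE)[at_max]
    mnm[at_min] <- matrix(ex$min2, m, ncol(fm), byrow = TRUE)[at_min]
    fl <- var_floor(mxm - mnm)
    v_o <- pmax(v_o, fl)
    v_f <- pmax(v_f, fl)
    if (own == 1L) {
      l1 <- -0.5 * (log(2 * pi * v_o) + (X - mu_o)^2 / v_o)
      l0 <- -0.5 * (log(2 * pi * v_f) + (X - mu_f)^2 / v_f)
    } else {
      l1 <- -0.5 * (log(2 * pi * v_f) + (X - mu_f)^2 / v_f)
      l0 <- -0.5 * (log(2 * pi * v_o) + (X - mu_o)^2 / v_o)
    }
    pr + rowSums(l1 - l0)
  }

  scores[pos] <- score_block(which(pos), 1L)
  scores[neg] <- score_block(which(neg), 0L)
  scores
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sample is in turn singled out as the test sample and a naive Bayes
#' model is fitted on the remaining n-1 samples; the held-out log
#' posterior-odds are collected, the confusion matrix is formed at the
#' requested threshold, and auROC is computed on the n held-out scores.
#' Fully deterministic. For the default Gaussian density with a fixed
#' threshold, the leave-one-out scores are computed exactly from class
#' sufficient statistics rather than by n refits.
#'
#' @param fm Feature matrix.
#' @param labels Binary labels (>= 3 samples per class).
#' @param theta Fixed decision threshold (default 0), used when
#'   `theta_policy = "fixed"`.
#' @param density Passed to [nb_fit()].
#' @param theta_policy `"fixed"` (one global theta) or `"tune"` (theta
#'   tuned on each fold's training scores, maximizing accuracy).
#' @param trainer Optional custom trainer `function(X, y)` returning an
#'   object with a working [nb_log_odds()] method or a scoring closure
#'   `function(newX) -> scores`; mainly for testing.
#' @return An `antiox_eval` report.
#' @export
jackknife <- function(fm, labels, theta = 0, density = "gaussian",
                      theta_policy = c("fixed", "tune"), trainer = NULL) {
  theta_policy <- match.arg(theta_policy)
  y <- as_binary_labels(labels)
  stopifnot(is.matrix(fm), nrow(fm) == length(y))
  n <- nrow(fm)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("each class needs >= 2 members so every training fold keeps both")
  }
  ids <- rownames(fm) %||% paste0("s", seq_len(n))

  if (is.null(trainer) && density == "gaussian" && theta_policy == "fixed") {
    scores <- loo_scores_gaussian(fm, y)
    pred <- as.integer(scores >= theta)
    return(make_eval_report(ids, y, scores, pred, "jackknife", theta))
  }

  scores <- numeric(n)
  pred <- integer(n)
  thetas <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- fm[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) stop("class collapse in training fold ", i)
    score_fun <- if (is.null(trainer)) {
      m <- nb_fit(Xtr, ytr, density = density)
      function(X) nb_log_odds(m, X)
    } else {
      tr <- trainer(Xtr, ytr)
      if (is.function(tr)) tr else function(X) nb_log_odds(tr, X)
    }
    scores[i] <- score_fun(fm[i, , drop = FALSE])
    thetas[i] <- if (theta_policy == "tune") {
      as.numeric(tune_theta(score_fun(Xtr), ytr))
    } else {
      theta
    }
    pred[i] <- as.integer(scores[i] >= thetas[i])
  }
  make_eval_report(ids, y, scores, pred, "jackknife",
                   if (theta_policy == "tune") thetas else theta)
}

#' Stratified fold assignment
#'
#' Seeded shuffle within each class followed by round-robin assignment, so
#' per-class fold sizes differ by at most one.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  y <- as_binary_labels(labels)
  n <- length(y)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of samples")
  folds <- integer(n)
  with_seed(seed, {
    # one global round-robin cycle over the class-shuffled samples keeps
    # per-class fold sizes within 1 AND spreads samples over all k folds
    ordered <- unlist(lapply(c(1L, 0L), function(cls) {
      idx <- which(y == cls)
      idx[sample.int(length(idx))]
    }))
    folds[ordered] <- rep_len(seq_len(k), n)
  })
  folds
}

#' Stratified k-fold cross-validated evaluation
#'
#' Each sample is tested exactly once by a model fitted on the other folds;
#' metrics are pooled over the held-out predictions.
#'
#' @param fm Feature matrix.
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param theta,density,theta_policy As in [jackknife()].
#' @return An `antiox_eval` report (protocol records k and seed).
#' @export
kfold <- function(fm, labels, k = 10L, seed = 1L, theta = 0,
                  density = "gaussian", theta_policy = c("fixed", "tune")) {
  theta_policy <- match.arg(theta_policy)
  y <- as_binary_labels(labels)
  stopifnot(is.matrix(fm), nrow(fm) == length(y))
  n <- nrow(fm)
  folds <- stratified_folds(y, k, seed)
  ids <- rownames(fm) %||% paste0("s", seq_len(n))
  scores <- numeric(n)
  pred <- integer(n)
  thetas <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) stop("class collapse in training fold ", f)
    m <- nb_fit(fm[!test, , drop = FALSE], ytr, density = density)
    scores[test] <- nb_log_odds(m, fm[test, , drop = FALSE])
    th <- if (theta_policy == "tune") {
      as.numeric(tune_theta(nb_log_odds(m, fm[!test, , drop = FALSE]), ytr))
    } else {
      theta
    }
    thetas[test] <- th
    pred[test] <- as.integer(scores[test] >= th)
  }
  make_eval_report(ids, y, scores, pred,
                   list(protocol = "kfold", k = k, seed = seed),
                   if (theta_policy == "tune") thetas else theta)
}

#' Evaluate a fitted model on an independent test set
#'
#' Predictions are reported in input order with the calls labeled
#' `"Antioxidant"` / `"Nonantioxidant"`, together with the count of correct
#' predictions. Rates whose class is absent from the test set are `NA`.
#'
#' @param model A fitted `antiox_nb` model.
#' @param fm Feature matrix of the test samples (model's features).
#' @param labels True labels; defaults to all 1 (a positive-only panel).
#' @param theta Threshold (default: model's).
#' @return An `antiox_eval` report with extra fields `calls` and
#'   `n_correct`.
#' @export
independent_test <- function(model, fm, labels = NULL, theta = model$theta) {
  stopifnot(inherits(model, "antiox_nb"), is.matrix(fm))
  if (nrow(fm) == 0L) stop("empty test set")
  y <- if (is.null(labels)) rep(1L, nrow(fm)) else as_binary_labels(labels)
  stopifnot(nrow(fm) == length(y))
  pr <- nb_predict(model, fm, theta = theta)
  ids <- rownames(fm) %||% paste0("s", seq_len(nrow(fm)))
  cm <- confusion_metrics(pr$class, y)
  rep_ <- make_eval_report(ids, y, pr$score, pr$class, "independent", theta)
  rep_$calls <- ifelse(pr$class == 1L, "Antioxidant", "Nonantioxidant")
  rep_$n_correct <- sum(pr$class == y)
  rep_
}
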