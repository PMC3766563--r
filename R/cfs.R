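# Correlation-based feature-subset selection (CFS).
#
# Correlations are symmetrical uncertainties between MDL-discretized
# features (Fayyad-Irani recursive entropy minimization) and the binary
# class. A subset of k features is scored by the CFS merit
#   k * rcf_bar / sqrt(k + k*(k-1) * rff_bar)
# where rcf_bar is the mean feature-class correlation (reward) and rff_bar
# the mean pairwise feature-feature correlation (redundancy penalty).
# Subsets are searched best-first with backtracking.

# entropy (bits) of a two-class count pair, vectorized over splits
ent2 <- function(a, b) {
  n <- a + b
  h <- numeric(length(n))
  pos <- n > 0
  pa <- a[pos] / n[pos]
  pb <- b[pos] / n[pos]
  ta <- ifelse(pa > 0, pa * log2(pa), 0)
  tb <- ifelse(pb > 0, pb * log2(pb), 0)
  h[pos] <- -(ta + tb)
  h
}

mdl_split <- function(v, y) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  n1 <- sum(y)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) return(numeric(0))
  cand <- which(diff(v) > 0)
  if (!length(cand)) return(numeric(0))
  c1L <- cumsum(y)[cand]
  c0L <- cand - c1L
  c1R <- n1 - c1L
  c0R <- n0 - c0L
  entL <- ent2(c0L, c1L)
  entR <- ent2(c0R, c1R)
  info <- (cand / n) * entL + ((n - cand) / n) * entR
  best <- which.min(info)
  i <- cand[best]
  entS <- ent2(n0, n1)
  gain <- entS - info[best]
  k1 <- (c0L[best] > 0) + (c1L[best] > 0)
  k2 <- (c0R[best] > 0) + (c1R[best] > 0)
  # MDL acceptance: gain must pay for encoding the partition (2 classes here)
  delta <- log2(3^2 - 2) - (2 * entS - k1 * entL[best] - k2 * entR[best])
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (v[i] + v[i + 1L]) / 2
  c(mdl_split(v[seq_len(i)], y[seq_len(i)]),
    cut,
    mdl_split(v[(i + 1L):n], y[(i + 1L):n]))
}

#' Supervised MDL discretization of a numeric feature
#'
#' Recursive entropy-minimization cut points accepted by the minimum
#' description length stopping criterion (Fayyad-Irani). May return no cuts
#' (feature collapses to a single bin), in particular whenever the labels
#' or the values are constant.
#'
#' @param values Numeric vector (one value per sample).
#' @param labels Binary class labels aligned with `values`.
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
discretize_mdl <- function(values, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(values) == length(y))
  if (length(values) < 2L) return(numeric(0))
  o <- order(values)
  sort(mdl_split(values[o], y[o]))
}

# symmetrical uncertainty on integer-coded vectors (codes in 1..nx / 1..ny)
su_codes <- function(xi, nx, yi, ny) {
  n <- length(xi)
  px <- tabulate(xi, nbins = nx) / n
  py <- tabulate(yi, nbins = ny) / n
  hx <- entropy_p(px)
  hy <- entropy_p(py)
  if (hx == 0 || hy == 0) return(0)
  joint <- tabulate((xi - 1L) * ny + yi, nbins = nx * ny)
  hxy <- entropy_counts(joint)
  mi <- hx + hy - hxy
  min(1, max(0, 2 * mi / (hx + hy)))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' `2 * I(x; y) / (H(x) + H(y))`, the normalized mutual information used as
#' the correlation measure of CFS. Defined as 0 when either marginal
#' entropy is 0. Symmetric and bounded in \\[0, 1\\].
#'
#' @param x,y Discrete vectors of equal length (any atomic type or factor).
#' @return A number in \\[0, 1\\].
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  xf <- as.integer(factor(x))
  yf <- as.integer(factor(y))
  su_codes(xf, max(xf), yf, max(yf))
}

#' Build the correlation cache for CFS on a feature matrix
#'
#' Discretizes every feature against the class with [discretize_mdl()],
#' computes all feature-class symmetrical uncertainties, and prepares a
#' lazily-filled matrix of pairwise feature-feature symmetrical
#' uncertainties.
#'
#' @param fm Numeric feature matrix (samples x features, named columns).
#' @param labels Binary labels aligned with rows.
#' @return A `correlation_cache` object.
#' @export
correlation_cache <- function(fm, labels) {
  y <- as_binary_labels(labels)
  stopifnot(is.matrix(fm), nrow(fm) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(fm)
  codes <- matrix(0L, nrow(fm), p)
  nbins <- integer(p)
  for (j in seq_len(p)) {
    cuts <- discretize_mdl(fm[, j], y)
    codes[, j] <- findInterval(fm[, j], cuts) + 1L
    nbins[j] <- length(cuts) + 1L
  }
  yc <- y + 1L
  rcf <- vapply(seq_len(p), function(j) {
    su_codes(codes[, j], nbins[j], yc, 2L)
  }, numeric(1))
  env <- new.env(parent = emptyenv())
  env$su <- matrix(NA_real_, p, p)
  diag(env$su) <- 1
  env$filled <- logical(p)
  structure(
    list(codes = codes, nbins = nbins, y = yc, rcf = rcf,
         feature_names = colnames(fm) %||% paste0("f", seq_len(p)),
         env = env),
    class = "correlation_cache"
  )
}

# fill (if needed) and return column j of the pairwise-SU matrix
su_pair_col <- function(cache, j) {
  env <- cache$env
  if (env$filled[j]) return(env$su[, j])
  p <- length(cache$nbins)
  col <- env$su[, j]
  todo <- which(is.na(col))
  if (cache$nbins[j] == 1L) {
    col[todo] <- 0
  } else {
    xj <- cache$codes[, j]
    nj <- cache$nbins[j]
    for (i in todo) {
      col[i] <- su_codes(cache$codes[, i], cache$nbins[i], xj, nj)
    }
  }
  col[j] <- 1
  env$su[, j] <- col
  env$su[j, ] <- col
  env$filled[j] <- TRUE
  col
}

#' CFS merit of a feature subset
#'
#' `k * rcf_bar / sqrt(k + k*(k-1) * rff_bar)` with `rcf_bar` the mean
#' feature-class symmetrical uncertainty over the subset and `rff_bar` the
#' mean pairwise feature-feature symmetrical uncertainty. The empty subset
#' has merit 0 by convention.
#'
#' @param subset Character vector of feature names (or integer indices).
#' @param cache A [correlation_cache()].
#' @return The merit, a non-negative number.
#' @export
cfs_merit <- function(subset, cache) {
  stopifnot(inherits(cache, "correlation_cache"))
  if (is.character(subset)) {
    idx <- match(subset, cache$feature_names)
    if (anyNA(idx)) {
      stop("unknown feature name(s): ",
           paste(subset[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(subset)
  }
  if (anyDuplicated(idx)) stop("subset names must be unique")
  k <- length(idx)
  if (k == 0L) return(0)
  rcf_sum <- sum(cache$rcf[idx])
  if (k == 1L) return(rcf_sum)
  rff_sum <- 0
  for (m in seq_len(k - 1L)) {
    col <- su_pair_col(cache, idx[m])
    rff_sum <- rff_sum + sum(col[idx[(m + 1L):k]])
  }
  rcf_sum / sqrt(k + 2 * rff_sum)
}

#' Best-first CFS subset search
#'
#' Starts from the empty subset, repeatedly expands the best-merit
#' unexpanded subset on the open list by all single-feature additions, and
#' backtracks to the next best unexpanded subset when an expansion does not
#' help. Terminates after `max_stale` consecutive expansions that fail to
#' improve the best merit found. Ties between equal-merit subsets prefer
#' the smaller subset, then lexicographic feature order, so the search is
#' deterministic.
#'
#' @param fm Numeric feature matrix (samples x features).
#' @param labels Binary labels aligned with rows.
#' @param max_stale Consecutive non-improving expansions tolerated
#'   (default 5).
#' @param cache Optional precomputed [correlation_cache()].
#' @return A `feature_subset`: list with `names` (in order of addition) and
#'   `merit`.
#' @export
best_first_select <- function(fm, labels, max_stale = 5L, cache = NULL) {
  if (is.null(cache)) cache <- correlation_cache(fm, labels)
  p <- length(cache$rcf)
  if (p < 1L) stop("at least one feature required")

  node_key <- function(idx) paste0("s:", paste(sort.int(idx), collapse = ","))
  # open list as parallel vectors for fast argmax with deterministic ties
  open_nodes <- vector("list", 256L)
  open_merit <- rep(-Inf, 256L)
  open_size <- rep(NA_integer_, 256L)
  open_key <- rep(NA_character_, 256L)
  n_open <- 0L
  push <- function(node) {
    n_open <<- n_open + 1L
    if (n_open > length(open_nodes)) {
      grow <- length(open_nodes)
      length(open_nodes) <<- 2L * grow
      open_merit <<- c(open_merit, rep(-Inf, grow))
      open_size <<- c(open_size, rep(NA_integer_, grow))
      open_key <<- c(open_key, rep(NA_character_, grow))
    }
    open_nodes[[n_open]] <<- node
    open_merit[n_open] <<- node$merit
    open_size[n_open] <<- length(node$idx)
    open_key[n_open] <<- node$key
  }

  closed <- new.env(parent = emptyenv())
  root <- list(idx = integer(0), merit = 0, rcf_sum = 0, rff_sum = 0,
               key = "s:")
  push(root)
  best <- root
  stale <- 0L
  eps <- 1e-10
  max_expansions <- 10000L

  better_than_best <- function(merit, idx) {
    if (merit > best$merit + eps) return(TRUE)
    if (merit < best$merit - eps) return(FALSE)
    # equal merit: prefer smaller subset, then lexicographic names
    if (length(idx) != length(best$idx)) return(length(idx) < length(best$idx))
    a <- paste(sort(cache$feature_names[idx]), collapse = ",")
    b <- paste(sort(cache$feature_names[best$idx]), collapse = ",")
    a < b
  }

  for (iter in seq_len(max_expansions)) {
    # pop the best unexpanded node (max merit; ties -> smaller, then lexical)
    live <- which(open_merit > -Inf)
    if (!length(live)) break
    ord <- live[order(-open_merit[live], open_size[live], open_key[live])]
    pick <- NA_integer_
    for (i in ord) {
      if (!exists(open_nodes[[i]]$key, envir = closed, inherits = FALSE)) {
        pick <- i
        break
      }
      open_merit[i] <- -Inf  # already expanded via another path
    }
    if (is.na(pick)) break
    node <- open_nodes[[pick]]
    open_merit[pick] <- -Inf
    assign(node$key, TRUE, envir = closed)

    k <- length(node$idx) + 1L
    pair_sum <- numeric(p)
    for (j in node$idx) pair_sum <- pair_sum + su_pair_col(cache, j)
    rcf_sums <- node$rcf_sum + cache$rcf
    rff_sums <- node$rff_sum + pair_sum
    merits <- rcf_sums / sqrt(k + 2 * rff_sums)
    merits[node$idx] <- -Inf

    improved <- FALSE
    cand <- setdiff(seq_len(p), node$idx)
    # push promising children; order by merit for stable behaviour
    cand <- cand[order(-merits[cand], cand)]
    for (f in cand) {
      child_idx <- c(node$idx, f)
      key <- node_key(child_idx)
      if (exists(key, envir = closed, inherits = FALSE)) next
      child <- list(idx = child_idx, merit = merits[f],
                    rcf_sum = rcf_sums[f], rff_sum = rff_sums[f], key = key)
      push(child)
      if (better_than_best(child$merit, child_idx)) {
        if (child$merit > best$merit + eps) improved <- TRUE
        best <- child
      }
    }
    stale <- if (improved) 0L else stale + 1L
    if (stale >= max_stale) break
  }

  structure(list(names = cache$feature_names[best$idx], merit = best$merit),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("CFS feature subset:", length(x$names), "features, merit",
      format(x$merit, digits = 4), "\n")
  if (length(x$names)) cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated CFS feature selection
#'
#' Runs [best_first_select()] inside each training fold of a stratified
#' k-fold split, and on the full data. The consensus subset contains the
#' features selected in at least half of the folds, ordered by selection
#' frequency (ties broken by feature order).
#'
#' @param fm Feature matrix.
#' @param labels Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param max_stale Passed to [best_first_select()].
#' @return A list with `consensus` (feature_subset with merit on the full
#'   data), `per_fold` (list of feature_subsets), `frequency` (named count
#'   vector), and `full_data` (subset selected on all samples).
#' @export
crossval_select <- function(fm, labels, k = 10L, seed = 1L, max_stale = 5L) {
  y <- as_binary_labels(labels)
  if (k < 2L) stop("k must be at least 2")
  folds <- stratified_folds(y, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    train <- folds != f
    if (length(unique(y[train])) < 2L) {
      stop("a training fold lost one class; reduce k")
    }
    best_first_select(fm[train, , drop = FALSE], y[train],
                      max_stale = max_stale)
  })
  all_names <- unlist(lapply(per_fold, `[[`, "names"))
  freq <- table(factor(all_names, levels = colnames(fm)))
  freq <- freq[freq > 0]
  freq <- freq[order(-as.integer(freq), match(names(freq), colnames(fm)))]
  consensus_names <- names(freq)[freq >= ceiling(k / 2)]
  full_cache <- correlation_cache(fm, y)
  consensus <- structure(
    list(names = consensus_names,
         merit = cfs_merit(consensus_names, full_cache)),
    class = "feature_subset"
  )
  full_data <- best_first_select(fm, y, max_stale = max_stale,
                                 cache = full_cache)
  list(consensus = consensus, per_fold = per_fold,
       frequency = as.integer(freq) |> stats::setNames(names(freq)),
       full_data = full_data)
}
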