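# shared fixtures and independent brute-force oracles, built in code

random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# dictionary-counting oracles for the composition encodings
brute_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(AA_ALPHABET20, function(a) sum(chars == a), numeric(1)) / nchar(seq)
}

brute_dpc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  wins <- paste0(chars[-L], chars[-1])
  vapply(DIPEPTIDES400, function(d) sum(wins == d), numeric(1)) / (L - 1)
}

# pairwise-rank oracle for auROC
rank_auroc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive CFS oracle: max merit over all non-empty subsets
exhaustive_best_merit <- function(fm, labels) {
  cache <- correlation_cache(fm, labels)
  p <- ncol(fm)
  best <- 0
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    m <- cfs_merit(idx, cache)
    if (m > best) best <- m
  }
  best
}

# two well-separated Gaussian feature clouds wrapped as a feature matrix
gauss_blobs <- function(n_per_class, p = 4, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per_class * p, mean = 0), ncol = p),
    matrix(stats::rnorm(n_per_class * p, mean = sep / sqrt(p)), ncol = p)
  )
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("s", seq_len(2 * n_per_class))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# small labeled dataset with an obvious composition margin
separable_dataset <- function(n_per_class = 6, seed = 5) {
  pos_bias <- stats::setNames(rep(0.01, 20), AA_ALPHABET20)
  pos_bias[c("C", "G")] <- 0.41
  neg_bias <- stats::setNames(rep(0.01, 20), AA_ALPHABET20)
  neg_bias[c("L", "K")] <- 0.41
  synth_generate(synth_spec(
    n_pos = n_per_class, n_neg = n_per_class, length_range = c(80L, 120L),
    residue_bias = list(pos = pos_bias / sum(pos_bias),
                        neg = neg_bias / sum(neg_bias)),
    dipeptide_bias = NULL, seed = seed
  ))
}

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(records, path)
  path
}
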