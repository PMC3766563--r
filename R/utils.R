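# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce labels to an integer 0/1 vector (1 = antioxidant / positive class).
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    labels <- suppressWarnings(as.numeric(labels))
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary (0 = nonantioxidant, 1 = antioxidant)")
  }
  y
}

# Shannon entropy (bits) of a probability vector; zeros dropped.
entropy_p <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

# Entropy (bits) of a vector of counts.
entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  entropy_p(counts / n)
}
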