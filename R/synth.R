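# Seeded generator of labeled synthetic protein datasets with controllable
# class-dependent composition signal, used for end-to-end testing of the
# encode -> select -> classify -> evaluate pipeline.

# Swiss-Prot-like background amino-acid frequencies (renormalized).
BACKGROUND_AA_FREQ <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f <- f[AA_ALPHABET20]
  f / sum(f)
})

#' Specification for a synthetic labeled protein dataset
#'
#' Defaults emulate the benchmark conditions of the antioxidant problem:
#' 254 positive and 1567 negative proteins of 50-300 residues, a
#' Swiss-Prot-like background residue distribution for the negative class,
#' a positive class with doubled C and G frequencies, and three dipeptides
#' (CP, CG, WC) enriched 5-fold in the positive class via a first-order
#' Markov transition tilt.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Integer (min, max) sequence lengths, min >= 2.
#' @param residue_bias List with elements `pos` and `neg`, each a named
#'   20-simplex of residue probabilities (order [AA_ALPHABET20]).
#' @param dipeptide_bias Named numeric vector of positive-class enrichment
#'   multipliers keyed by dipeptide name (e.g. `c(CP = 5)`), or NULL for
#'   independent residue draws.
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_pos = 254L, n_neg = 1567L,
                       length_range = c(50L, 300L),
                       residue_bias = NULL,
                       dipeptide_bias = c(CP = 5, CG = 5, WC = 5),
                       seed = 1L) {
  if (is.null(residue_bias)) {
    pos <- BACKGROUND_AA_FREQ
    pos[c("C", "G")] <- 2 * pos[c("C", "G")]
    residue_bias <- list(pos = pos / sum(pos), neg = BACKGROUND_AA_FREQ)
  }
  for (cls in c("pos", "neg")) {
    p <- residue_bias[[cls]]
    if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("residue_bias$", cls, " must be a 20-simplex")
    }
    names(residue_bias[[cls]]) <- AA_ALPHABET20
  }
  if (!is.null(dipeptide_bias)) {
    bad <- setdiff(names(dipeptide_bias), DIPEPTIDES400)
    if (length(bad) || is.null(names(dipeptide_bias))) {
      stop("dipeptide_bias must be named by dipeptides; bad: ",
           paste(bad, collapse = ", "))
    }
  }
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1L] >= 2L, length_range[1L] <= length_range[2L])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 residue_bias = residue_bias,
                 dipeptide_bias = dipeptide_bias, seed = as.integer(seed)),
            class = "synth_spec")
}

# class transition matrix: row a -> prob of next residue b, proportional to
# p[b] times the enrichment multiplier of dipeptide ab (positive class only)
transition_matrix <- function(p, mult) {
  T_ <- matrix(p, 20L, 20L, byrow = TRUE,
               dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  if (!is.null(mult)) {
    for (dp in names(mult)) {
      a <- substr(dp, 1L, 1L)
      b <- substr(dp, 2L, 2L)
      T_[a, b] <- T_[a, b] * mult[[dp]]
    }
    T_ <- T_ / rowSums(T_)
  }
  T_
}

sample_class_sequences <- function(n, lmin, lmax, p, mult) {
  lens <- if (lmin == lmax) rep(lmin, n) else sample(lmin:lmax, n, replace = TRUE)
  maxlen <- max(lens)
  cumT <- t(apply(transition_matrix(p, mult), 1, cumsum))
  states <- matrix(0L, n, maxlen)
  states[, 1L] <- sample.int(20L, n, replace = TRUE, prob = p)
  for (t in 2L:maxlen) {
    u <- stats::runif(n)
    cur <- states[, t - 1L]
    nxt <- integer(n)
    for (s in unique(cur)) {
      sel <- cur == s
      nxt[sel] <- findInterval(u[sel], cumT[s, ]) + 1L
    }
    nxt[nxt > 20L] <- 20L  # guard against cumulative rounding at 1
    states[, t] <- nxt
  }
  vapply(seq_len(n), function(i) {
    paste(AA_ALPHABET20[states[i, seq_len(lens[i])]], collapse = "")
  }, character(1))
}

#' Generate a labeled synthetic dataset
#'
#' Sequences are drawn residue-wise from the class residue distribution;
#' when dipeptide enrichments are specified for the positive class they are
#' implemented as a first-order Markov transition tilt with row
#' renormalization (independent draws cannot express dipeptide-specific
#' signal). Byte-identical output for identical spec and seed.
#'
#' @param spec A [synth_spec()].
#' @return A `labeled_dataset` (FASTA-writable via [write_fasta()]).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    pos_seqs <- sample_class_sequences(
      spec$n_pos, spec$length_range[1L], spec$length_range[2L],
      spec$residue_bias$pos, spec$dipeptide_bias)
    neg_seqs <- sample_class_sequences(
      spec$n_neg, spec$length_range[1L], spec$length_range[2L],
      spec$residue_bias$neg, NULL)
  })
  ids <- c(sprintf("POS%04d", seq_len(spec$n_pos)),
           sprintf("NEG%04d", seq_len(spec$n_neg)))
  records <- data.frame(id = ids, description = ids,
                        sequence = c(pos_seqs, neg_seqs),
                        stringsAsFactors = FALSE)
  new_labeled_dataset(records,
                      rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)))
}

#' Write the canonical small test-fixture suite
#'
#' Creates, under `out_dir`: a strongly separable positive/negative FASTA
#' pair, a no-signal (null) pair, a degenerate file of length-2 sequences,
#' a single-class file, and a file containing sequences with nonstandard
#' letters (B, X, Z, U) that the validator must reject. Label tables are
#' written alongside.
#'
#' @param out_dir Writable directory (created if missing).
#' @param seed Seed controlling the generated sequences.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  put <- function(name, records) {
    p <- file.path(out_dir, name)
    write_fasta(records, p)
    paths[[name]] <<- p
    p
  }

  # separable: positive sequences dominated by C/G, negatives by L/K
  extreme_pos <- BACKGROUND_AA_FREQ
  extreme_pos[] <- 0.01
  extreme_pos[c("C", "G")] <- (1 - 0.18) / 2
  extreme_pos <- extreme_pos / sum(extreme_pos)
  extreme_neg <- BACKGROUND_AA_FREQ
  extreme_neg[] <- 0.01
  extreme_neg[c("L", "K")] <- (1 - 0.18) / 2
  extreme_neg <- extreme_neg / sum(extreme_neg)
  sep <- synth_generate(synth_spec(
    n_pos = 12L, n_neg = 12L, length_range = c(60L, 120L),
    residue_bias = list(pos = extreme_pos, neg = extreme_neg),
    dipeptide_bias = NULL, seed = seed))
  put("separable_pos.fasta", sep$records[sep$labels == 1L, ])
  put("separable_neg.fasta", sep$records[sep$labels == 0L, ])
  write_labels(sep, file.path(out_dir, "separable_labels.tsv"))
  paths[["separable_labels.tsv"]] <- file.path(out_dir, "separable_labels.tsv")

  # null: identical composition in both classes
  null_ds <- synth_generate(synth_spec(
    n_pos = 200L, n_neg = 200L, length_range = c(50L, 200L),
    residue_bias = list(pos = BACKGROUND_AA_FREQ, neg = BACKGROUND_AA_FREQ),
    dipeptide_bias = NULL, seed = seed + 1L))
  put("null_pos.fasta", null_ds$records[null_ds$labels == 1L, ])
  put("null_neg.fasta", null_ds$records[null_ds$labels == 0L, ])

  put("length2.fasta", data.frame(id = c("t1", "t2", "t3"),
                                  sequence = c("AC", "CA", "GG")))
  put("single_class.fasta", sep$records[sep$labels == 1L, ][1:3, ])
  put("invalid.fasta", data.frame(
    id = c("okay", "hasB", "hasX", "hasZ", "hasU"),
    sequence = c("MKVLA", "MBKVA", "MXKVA", "MZKVA", "MUKVA")))

  invisible(unlist(paths))
}
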