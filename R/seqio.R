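#' Read a FASTA file of protein sequences
#'
#' Parses a (possibly multi-record) FASTA file. The record id is the first
#' whitespace-delimited token of the header; the full header is retained as
#' the description. Sequence lines are concatenated and uppercased. No
#' alphabet validation is applied at this stage — see [validate_records()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @seealso [validate_records()], [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  head_lines <- readLines(path, warn = FALSE)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(head_lines[[1L]], ">")) {
    stop("malformed FASTA (sequence data before first header): ", path)
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  data.frame(
    id = ids,
    description = headers,
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write protein records to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description` (used as the header when present).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  headers <- if ("description" %in% names(records) &&
                 all(nzchar(records$description))) {
    records$description
  } else {
    records$id
  }
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Validate protein records against the 20-letter amino-acid alphabet
#'
#' Sequences containing any character outside the 20 standard one-letter
#' codes are rejected: this removes ambiguous letters (B, X, Z), the
#' nonstandard residues U (selenocysteine) and O (pyrrolysine), and gap or
#' stop symbols (`-`, `*`). Kept sequences are canonicalized to uppercase.
#' Fragment records cannot be recognized from sequence alone, so an optional
#' id-exclusion list is accepted for that purpose.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param policy `"drop"` (default) rejects offending records and returns
#'   them with reasons; `"fail"` raises an error on the first invalid record.
#' @param exclude_ids Optional character vector of record ids to reject
#'   (reason `"excluded-id"`), e.g. known protein fragments.
#' @return A list with elements `kept` (valid records, uppercase) and
#'   `rejected` (data.frame of `id`, `reason`).
#' @export
validate_records <- function(records, policy = c("drop", "fail"),
                             exclude_ids = character()) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  seqs <- toupper(records$sequence)
  reasons <- character(nrow(records))
  bad_chr <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  empty <- !nzchar(seqs)
  reasons[bad_chr] <- "nonstandard-letter"
  reasons[empty] <- "empty-sequence"
  reasons[records$id %in% exclude_ids] <- "excluded-id"
  bad <- nzchar(reasons)
  if (policy == "fail" && any(bad)) {
    i <- which(bad)[1L]
    stop("invalid sequence for record '", records$id[i], "': ", reasons[i])
  }
  kept <- records[!bad, , drop = FALSE]
  kept$sequence <- seqs[!bad]
  rownames(kept) <- NULL
  rejected <- data.frame(id = records$id[bad], reason = reasons[bad],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(kept = kept, rejected = rejected)
}

new_labeled_dataset <- function(records, labels) {
  stopifnot(nrow(records) == length(labels))
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)]
    stop("duplicate record ids in dataset: ", paste(unique(dup), collapse = ", "))
  }
  structure(list(records = records, labels = as_binary_labels(labels)),
            class = "labeled_dataset")
}

#' Load a labeled dataset from positive and negative FASTA files
#'
#' Records from `pos_fasta` receive label 1 (antioxidant), records from
#' `neg_fasta` label 0 (nonantioxidant). Records are validated per
#' [validate_records()]; ids must be unique across the two files.
#'
#' @param pos_fasta,neg_fasta FASTA paths for the two classes.
#' @param validate Apply alphabet validation (default TRUE, policy `"drop"`).
#' @param exclude_ids Passed to [validate_records()].
#' @return A `labeled_dataset`: list with `records` (data.frame) and
#'   `labels` (integer 0/1 vector aligned with `records`).
#' @export
load_labeled <- function(pos_fasta, neg_fasta, validate = TRUE,
                         exclude_ids = character()) {
  pos <- read_fasta(pos_fasta)
  neg <- read_fasta(neg_fasta)
  if (validate) {
    pos <- validate_records(pos, "drop", exclude_ids)$kept
    neg <- validate_records(neg, "drop", exclude_ids)$kept
  }
  if (nrow(pos) == 0L) warning("positive class is empty after validation")
  if (nrow(neg) == 0L) warning("negative class is empty after validation")
  records <- rbind(pos, neg)
  new_labeled_dataset(records, rep(c(1L, 0L), c(nrow(pos), nrow(neg))))
}

#' Load a labeled dataset from one FASTA file plus a label table
#'
#' Alternative layout to [load_labeled()]: a single FASTA and a two-column
#' tab-separated table `id<TAB>label` with labels in {0, 1}.
#'
#' @param fasta FASTA path containing all sequences.
#' @param labels_tsv Path to the label table (no header).
#' @param validate,exclude_ids As in [load_labeled()].
#' @return A `labeled_dataset`.
#' @export
load_labeled_table <- function(fasta, labels_tsv, validate = TRUE,
                               exclude_ids = character()) {
  records <- read_fasta(fasta)
  if (validate) {
    records <- validate_records(records, "drop", exclude_ids)$kept
  }
  tab <- utils::read.delim(labels_tsv, header = FALSE, sep = "\t",
                           colClasses = c("character", "integer"),
                           col.names = c("id", "label"))
  idx <- match(records$id, tab$id)
  if (anyNA(idx)) {
    stop("no label for record(s): ",
         paste(records$id[is.na(idx)], collapse = ", "))
  }
  new_labeled_dataset(records, tab$label[idx])
}

#' Write the label table of a dataset as TSV
#'
#' @param ds A `labeled_dataset`.
#' @param path Output path (`id<TAB>label`, no header).
#' @return `path`, invisibly.
#' @export
write_labels <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  utils::write.table(
    data.frame(id = ds$records$id, label = ds$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled protein dataset:", nrow(x$records), "records (",
      sum(x$labels == 1L), "antioxidant /", sum(x$labels == 0L),
      "nonantioxidant )\n")
  invisible(x)
}
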