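# Reading, validating, labeling and partitioning DNA sequence window sets.

#' Read DNA sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) and returns
#' the uppercased sequences in record order, named by their headers. Bases
#' outside `{A,C,G,T}` are rejected by default because benchmark window sets
#' are clean and silent coercion hides data errors; with
#' `allow_ambiguous = TRUE`, IUPAC-ambiguous input characters (e.g. `N`) are
#' kept and match a motif symbol only when that symbol's base set covers
#' the input character's base set.
#'
#' @param path Path to a FASTA file.
#' @param allow_ambiguous Accept IUPAC ambiguity codes in the input
#'   sequences (default `FALSE`).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  seqs <- toupper(as.character(set))
  allowed <- if (allow_ambiguous) names(SEQ_CODES) else BASE_SYMBOLS
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L)
      stop("record '", names(seqs)[i], "' in '", path,
           "' contains disallowed character(s): ",
           paste(bad, collapse = ", "),
           if (!allow_ambiguous) " (set allow_ambiguous = TRUE to accept IUPAC codes)",
           call. = FALSE)
  }
  seqs
}

#' Construct a labeled DNA window dataset
#'
#' Bundles positive- and negative-class sequences into the container used by
#' the whole pipeline. Sequences whose length differs from the modal length
#' are discarded (see [discard_short()]), so every retained window has the
#' same `window_length`.
#'
#' @param positives,negatives Character vectors of DNA sequences (uppercase
#'   or lowercase), e.g. from [read_fasta()].
#' @param anchor_offset Optional 0-based index of the biological site (e.g.
#'   a splice junction) within each window; used only for anchor-relative
#'   position reporting.
#' @return A `dna_dataset` object: list with `sequences`, `labels` (factor
#'   with levels `negative`, `positive`), `window_length`, `anchor_offset`,
#'   and `n_discarded`.
#' @export
dna_dataset <- function(positives, negatives, anchor_offset = NULL) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must be non-empty", call. = FALSE)
  ds <- structure(
    list(sequences = unname(toupper(c(positives, negatives))),
         labels = factor(rep(c("positive", "negative"),
                             c(length(positives), length(negatives))),
                         levels = c("negative", "positive")),
         window_length = NA_integer_,
         anchor_offset = anchor_offset,
         n_discarded = 0L),
    class = "dna_dataset")
  ds <- discard_short(ds)
  if (!is.null(anchor_offset)) {
    if (anchor_offset < 0L || anchor_offset >= ds$window_length)
      stop("anchor_offset must lie in [0, window_length)", call. = FALSE)
  }
  ds
}

#' Load a labeled dataset from two FASTA files
#'
#' @param pos_path,neg_path FASTA files holding the positive- and
#'   negative-class sequences.
#' @inheritParams dna_dataset
#' @inheritParams read_fasta
#' @return A `dna_dataset`; see [dna_dataset()].
#' @export
load_dataset <- function(pos_path, neg_path, anchor_offset = NULL,
                         allow_ambiguous = FALSE) {
  dna_dataset(read_fasta(pos_path, allow_ambiguous),
              read_fasta(neg_path, allow_ambiguous),
              anchor_offset = anchor_offset)
}

#' Drop sequences whose length differs from the modal length
#'
#' Fixed-length windows are required by every positional operator and by the
#' classifiers. The modal sequence length is kept; shorter sequences are
#' discarded, and longer outliers are discarded symmetrically to keep the
#' feature matrix rectangular. Idempotent.
#'
#' @param dataset A `dna_dataset`.
#' @return The filtered `dna_dataset`, with `window_length` set and the
#'   number of discarded sequences accumulated in `n_discarded`.
#' @export
discard_short <- function(dataset) {
  stopifnot(inherits(dataset, "dna_dataset"))
  lens <- nchar(dataset$sequences)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])
  keep <- lens == modal
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("discarding ", n_drop, " sequence(s) with length != ", modal)
    if (n_drop > 0.1 * length(lens))
      warning("more than 10% of sequences discarded by the length filter",
              call. = FALSE)
  }
  dataset$sequences <- dataset$sequences[keep]
  dataset$labels <- dataset$labels[keep]
  dataset$window_length <- modal
  dataset$n_discarded <- dataset$n_discarded + n_drop
  if (!all(c("negative", "positive") %in% dataset$labels))
    stop("a class became empty after length filtering", call. = FALSE)
  dataset
}

#' @export
print.dna_dataset <- function(x, ...) {
  cat("<dna_dataset> ", sum(x$labels == "positive"), " positive + ",
      sum(x$labels == "negative"), " negative windows of ",
      x$window_length, " nt", sep = "")
  if (!is.null(x$anchor_offset))
    cat("; anchor at offset ", x$anchor_offset, sep = "")
  if (x$n_discarded > 0L)
    cat(" (", x$n_discarded, " discarded by length filter)", sep = "")
  cat("\n")
  invisible(x)
}

# Subset a dataset by index, preserving metadata.
dataset_subset <- function(dataset, idx) {
  dataset$sequences <- dataset$sequences[idx]
  dataset$labels <- dataset$labels[idx]
  dataset
}

#' Stratified k-fold partition of a labeled dataset
#'
#' Splits the dataset into `k` disjoint folds in which the class ratio is
#' within one member of the global ratio. Stratification matters here
#' because the benchmark tasks are heavily unbalanced and unstratified folds
#' can lose the positive class entirely.
#'
#' @param dataset A `dna_dataset`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List of `k` elements, each `list(train = <indices>, test =
#'   <indices>)`, 1-based into `dataset$sequences`.
#' @export
stratified_kfold <- function(dataset, k, seed) {
  stopifnot(inherits(dataset, "dna_dataset"), k >= 2L)
  counts <- table(dataset$labels)
  if (any(counts < k))
    stop("each class needs at least k = ", k, " members; have ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  assignment <- integer(length(dataset$labels))
  with_seed(seed, {
    for (cl in levels(dataset$labels)) {
      idx <- which(dataset$labels == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
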