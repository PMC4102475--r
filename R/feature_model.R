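# The feature-tree language: IUPAC motifs combined by boolean, positional,
# shift, regional and correlational operators; matching semantics,
# vectorized evaluation, counting, and the s-expression serialization.
#
# Coordinates are 0-based, half-open throughout the internal representation
# and the serialized form; anchor-relative positions appear only in reports.

MOTIF_OPS <- c("matches", "matches_at", "matches_shift", "matches_region")
BOOL_OPS <- c("and", "or", "not", "corr")

new_node <- function(op, ...) structure(list(op = op, ...), class = "feature_node")

check_motif <- function(motif, alphabet = iupac_alphabet()) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop("motif must be a non-empty string", call. = FALSE)
  syms <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bad <- setdiff(syms, alphabet)
  if (length(bad) > 0L)
    stop("motif '", motif, "' uses symbol(s) outside the active alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  motif
}

check_bool <- function(x, what) {
  if (!inherits(x, "feature_node"))
    stop(what, " must be a feature node", call. = FALSE)
  x
}

#' Feature-node constructors
#'
#' Build the nodes of the feature-tree language. Every node is boolean-valued
#' on a sequence window:
#' * `ft_matches(motif)` — the IUPAC motif occurs anywhere in the window;
#' * `ft_matches_at(motif, position)` — an occurrence starts exactly at the
#'   0-based `position`;
#' * `ft_matches_shift(motif, position, shift)` — an occurrence starts within
#'   `position +/- shift` (symmetric window around the expected position);
#' * `ft_matches_region(motif, region_start, region_length)` — an occurrence
#'   starts in the half-open interval
#'   `[region_start, region_start + region_length)`;
#' * `ft_and(a, b)`, `ft_or(a, b)`, `ft_not(a)` — boolean combinations;
#' * `ft_corr(a, b, shift)` — co-occurrence of two sub-features. When both
#'   children are motif-rooted, the node demands an ordered 5'-to-3'
#'   co-occurrence: a qualifying start of `a`'s motif followed by a
#'   qualifying start of `b`'s motif with an inter-motif gap between 0 and
#'   `shift` nt. Otherwise it degrades to the conjunction of the children.
#'
#' @param motif IUPAC motif string over the active alphabet.
#' @param position,region_start 0-based window offsets.
#' @param shift Non-negative slack in nt.
#' @param region_length Region width in nt (>= 1).
#' @param a,b,x Child feature nodes.
#' @param alphabet Alphabet used to validate motif symbols.
#' @return A `feature_node`.
#' @examples
#' f <- ft_and(ft_matches("GAT"), ft_not(ft_matches("CCC")))
#' evaluate_feature(f, "GGATG")
#' @name feature_nodes
NULL

#' @rdname feature_nodes
#' @export
ft_matches <- function(motif, alphabet = iupac_alphabet())
  new_node("matches", motif = check_motif(motif, alphabet))

#' @rdname feature_nodes
#' @export
ft_matches_at <- function(motif, position, alphabet = iupac_alphabet()) {
  stopifnot(position >= 0L)
  new_node("matches_at", motif = check_motif(motif, alphabet),
           position = as.integer(position))
}

#' @rdname feature_nodes
#' @export
ft_matches_shift <- function(motif, position, shift,
                             alphabet = iupac_alphabet()) {
  stopifnot(position >= 0L, shift >= 0L)
  new_node("matches_shift", motif = check_motif(motif, alphabet),
           position = as.integer(position), shift = as.integer(shift))
}

#' @rdname feature_nodes
#' @export
ft_matches_region <- function(motif, region_start, region_length,
                              alphabet = iupac_alphabet()) {
  stopifnot(region_start >= 0L, region_length >= 1L)
  new_node("matches_region", motif = check_motif(motif, alphabet),
           region_start = as.integer(region_start),
           region_length = as.integer(region_length))
}

#' @rdname feature_nodes
#' @export
ft_and <- function(a, b) new_node("and", left = check_bool(a, "left child"),
                                  right = check_bool(b, "right child"))

#' @rdname feature_nodes
#' @export
ft_or <- function(a, b) new_node("or", left = check_bool(a, "left child"),
                                 right = check_bool(b, "right child"))

#' @rdname feature_nodes
#' @export
ft_not <- function(x) new_node("not", child = check_bool(x, "child"))

#' @rdname feature_nodes
#' @export
ft_corr <- function(a, b, shift) {
  stopifnot(shift >= 0L)
  new_node("corr", left = check_bool(a, "left child"),
           right = check_bool(b, "right child"), shift = as.integer(shift))
}

is_motif_node <- function(node) node$op %in% MOTIF_OPS

node_children <- function(node) {
  switch(node$op,
         and = , or = , corr = list(node$left, node$right),
         not = list(node$child),
         list())
}

#' Tree shape statistics
#'
#' `tree_size()` counts nodes, `tree_depth()` measures the depth (a single
#' node has depth 1). Used by bloat control and parsimony tie-breaking.
#'
#' @param node A `feature_node`.
#' @return Integer.
#' @export
tree_size <- function(node) {
  1L + sum(vapply(node_children(node), tree_size, integer(1L)))
}

#' @rdname tree_size
#' @export
tree_depth <- function(node) {
  kids <- node_children(node)
  if (length(kids) == 0L) return(1L)
  1L + max(vapply(kids, tree_depth, integer(1L)))
}

# ---- matching machinery -----------------------------------------------------

# Occurrence matrix of a motif over an encoded sequence matrix E (n x L):
# logical n x (L - k + 1), entry [i, p] TRUE iff the motif occurs in
# sequence i starting at 0-based position p - 1. A cache environment keyed
# by motif string avoids recomputation across trees sharing motifs.
motif_occ_matrix <- function(motif, E, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[motif]])) return(cache[[motif]])
  n <- nrow(E); L <- ncol(E); k <- nchar(motif)
  if (k > L) {
    occ <- matrix(logical(0), nrow = n, ncol = 0L)
  } else {
    W <- L - k + 1L
    syms <- strsplit(motif, "", fixed = TRUE)[[1L]]
    occ <- matrix(TRUE, nrow = n, ncol = W)
    for (i in seq_len(k)) {
      allowed <- IUPAC_COVERS[syms[i], ]
      occ <- occ & matrix(allowed[E[, i:(i + W - 1L), drop = FALSE]],
                          nrow = n, ncol = W)
    }
  }
  if (!is.null(cache)) cache[[motif]] <- occ
  occ
}

#' Occurrence positions of an IUPAC motif in one sequence
#'
#' All (possibly overlapping) 0-based start positions at which the motif
#' matches, where each motif symbol matches the bases of its IUPAC set.
#'
#' @param motif IUPAC motif string.
#' @param sequence DNA string over `{A,C,G,T}` (IUPAC-ambiguous characters
#'   allowed; they match only motif symbols that cover them).
#' @return Sorted integer vector of 0-based start positions; empty when the
#'   motif is longer than the sequence.
#' @examples
#' motif_occurrences("CG", "CGCG")  # 0 2
#' motif_occurrences("RY", "GT")    # 0
#' @export
motif_occurrences <- function(motif, sequence) {
  check_motif(motif)
  E <- encode_sequences(toupper(sequence))
  occ <- motif_occ_matrix(motif, E)
  which(occ[1L, ]) - 1L
}

# Columns (1-based) of the occurrence matrix that qualify under a motif
# node's positional constraint. W is the number of possible starts.
qualifying_cols <- function(node, W) {
  if (W < 1L) return(integer(0))
  all_cols <- seq_len(W)
  switch(node$op,
    matches = all_cols,
    matches_at = {
      p <- node$position + 1L
      if (p >= 1L && p <= W) p else integer(0)
    },
    matches_shift = {
      lo <- max(1L, node$position - node$shift + 1L)
      hi <- min(W, node$position + node$shift + 1L)
      if (lo > hi) integer(0) else lo:hi
    },
    matches_region = {
      lo <- max(1L, node$region_start + 1L)
      hi <- min(W, node$region_start + node$region_length)
      if (lo > hi) integer(0) else lo:hi
    },
    stop("not a motif-rooted node: ", node$op, call. = FALSE))
}

# Qualifying-start matrix for a motif-rooted node: logical n x W with
# non-qualifying columns dropped to FALSE implicitly (we subset columns).
qualifying_occ <- function(node, E, cache) {
  occ <- motif_occ_matrix(node$motif, E, cache)
  cols <- qualifying_cols(node, ncol(occ))
  list(occ = occ, cols = cols)
}

# Vectorized evaluation of a node over an encoded matrix -> logical n-vector.
eval_node <- function(node, E, cache = NULL) {
  n <- nrow(E)
  switch(node$op,
    and = eval_node(node$left, E, cache) & eval_node(node$right, E, cache),
    or = eval_node(node$left, E, cache) | eval_node(node$right, E, cache),
    not = !eval_node(node$child, E, cache),
    corr = eval_corr(node, E, cache),
    {
      q <- qualifying_occ(node, E, cache)
      if (length(q$cols) == 0L) rep(FALSE, n)
      else rowSums(q$occ[, q$cols, drop = FALSE]) > 0L
    })
}

# Correlational node: ordered co-occurrence when both children are
# motif-rooted (gap between end of left match and start of right match in
# [0, shift]); conjunction of child truth values otherwise.
eval_corr <- function(node, E, cache) {
  n <- nrow(E)
  if (is_motif_node(node$left) && is_motif_node(node$right)) {
    kL <- nchar(node$left$motif)
    qL <- qualifying_occ(node$left, E, cache)
    qR <- qualifying_occ(node$right, E, cache)
    if (length(qL$cols) == 0L || length(qR$cols) == 0L) return(rep(FALSE, n))
    WL <- ncol(qL$occ); WR <- ncol(qR$occ)
    maskL <- matrix(FALSE, n, WL); maskL[, qL$cols] <- qL$occ[, qL$cols]
    maskR <- matrix(FALSE, n, WR); maskR[, qR$cols] <- qR$occ[, qR$cols]
    hit <- rep(FALSE, n)
    for (g in 0:node$shift) {
      # right start (0-based) = left start + kL + g  =>  column offset kL + g
      iL <- seq_len(WL)
      iR <- iL + kL + g
      ok <- iR <= WR
      if (!any(ok)) break
      hit <- hit | rowSums(maskL[, iL[ok], drop = FALSE] &
                             maskR[, iR[ok], drop = FALSE]) > 0L
    }
    hit
  } else {
    eval_node(node$left, E, cache) & eval_node(node$right, E, cache)
  }
}

#' Evaluate a feature tree on sequences
#'
#' @param tree A `feature_node` (or `feature_tree`).
#' @param x A character vector of equal-length DNA sequences or a
#'   `dna_dataset`.
#' @return Logical vector, one element per sequence.
#' @examples
#' evaluate_feature(ft_matches_at("CG", 1), c("ACGT", "CGTA"))
#' @export
evaluate_feature <- function(tree, x) {
  tree <- as_feature_node(tree)
  E <- as_encoded(x)
  eval_node(tree, E)
}

#' Count qualifying motif occurrences
#'
#' Number of occurrence starts satisfying the positional constraint of a
#' motif-rooted feature (`ft_matches`, `ft_matches_at`, `ft_matches_shift`,
#' `ft_matches_region`). Counts are undefined for boolean-combination roots,
#' which raise an error.
#'
#' @inheritParams evaluate_feature
#' @return Non-negative integer vector, one count per sequence.
#' @examples
#' match_count(ft_matches("CG"), "CGCG")  # 2
#' @export
match_count <- function(tree, x) {
  tree <- as_feature_node(tree)
  if (!is_motif_node(tree))
    stop("match counts are only defined for motif-rooted features, not '",
         tree$op, "'", call. = FALSE)
  E <- as_encoded(x)
  q <- qualifying_occ(tree, E, NULL)
  if (length(q$cols) == 0L) rep(0L, nrow(E))
  else as.integer(rowSums(q$occ[, q$cols, drop = FALSE]))
}

as_feature_node <- function(x) {
  if (inherits(x, "feature_tree")) return(x$root)
  if (inherits(x, "feature_node")) return(x)
  stop("expected a feature node or feature tree", call. = FALSE)
}

as_encoded <- function(x) {
  if (inherits(x, "dna_dataset")) encode_sequences(x$sequences)
  else if (is.matrix(x) && is.integer(x)) x
  else encode_sequences(toupper(x))
}

# ---- serialization ----------------------------------------------------------

#' Serialize a feature tree to its s-expression form
#'
#' One feature per line in feature files; the canonical string round-trips
#' through [parse_feature()]. Positions are 0-based.
#'
#' @param tree A `feature_node` or `feature_tree`.
#' @return Single character string, e.g.
#'   `"(and (matches CCTGG) (matches GAGGC))"`.
#' @export
serialize_feature <- function(tree) {
  node <- as_feature_node(tree)
  ser <- function(n) {
    switch(n$op,
      matches = paste0("(matches ", n$motif, ")"),
      matches_at = paste0("(matches-at ", n$motif, " ", n$position, ")"),
      matches_shift = paste0("(matches-shift ", n$motif, " ", n$position,
                             " ", n$shift, ")"),
      matches_region = paste0("(matches-region ", n$motif, " ",
                              n$region_start, " ", n$region_length, ")"),
      and = paste0("(and ", ser(n$left), " ", ser(n$right), ")"),
      or = paste0("(or ", ser(n$left), " ", ser(n$right), ")"),
      not = paste0("(not ", ser(n$child), ")"),
      corr = paste0("(corr ", ser(n$left), " ", ser(n$right), " ",
                    n$shift, ")"))
  }
  ser(node)
}

#' Parse a feature from its s-expression form
#'
#' @param text A single s-expression, e.g. `"(matches-at GT 30)"`.
#' @param alphabet Alphabet used to validate motif symbols.
#' @return A `feature_node`.
#' @export
parse_feature <- function(text, alphabet = iupac_alphabet()) {
  toks <- tokenize_sexpr(text)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  peek <- function() if (st$pos <= nrow(toks)) toks$tok[st$pos] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) stop("parse error: unexpected end of input at character ",
                       nchar(text) + 1L, call. = FALSE)
    st$pos <- st$pos + 1L
    t
  }
  expect <- function(t) {
    got <- advance()
    if (got != t) stop("parse error at character ", toks$at[st$pos - 1L],
                       ": expected '", t, "', got '", got, "'", call. = FALSE)
  }
  int_arg <- function(what) {
    t <- advance()
    v <- suppressWarnings(as.integer(t))
    if (is.na(v)) stop("parse error at character ", toks$at[st$pos - 1L],
                       ": expected an integer ", what, ", got '", t, "'",
                       call. = FALSE)
    v
  }
  # arguments are read into locals before each constructor call: R's lazy
  # evaluation would otherwise consume tokens in an undefined order
  node <- function() {
    expect("(")
    head <- advance()
    out <- switch(head,
      matches = ft_matches(advance(), alphabet),
      `matches-at` = {
        m <- advance(); p <- int_arg("position")
        ft_matches_at(m, p, alphabet)
      },
      `matches-shift` = {
        m <- advance(); p <- int_arg("position"); s <- int_arg("shift")
        ft_matches_shift(m, p, s, alphabet)
      },
      `matches-region` = {
        m <- advance(); rs <- int_arg("start"); rl <- int_arg("length")
        ft_matches_region(m, rs, rl, alphabet)
      },
      and = { l <- node(); r <- node(); ft_and(l, r) },
      or = { l <- node(); r <- node(); ft_or(l, r) },
      not = ft_not(node()),
      corr = { l <- node(); r <- node(); ft_corr(l, r, int_arg("shift")) },
      stop("parse error at character ", toks$at[st$pos - 1L],
           ": unknown operator '", head, "'", call. = FALSE))
    expect(")")
    out
  }
  out <- node()
  if (!is.na(peek()))
    stop("parse error at character ", toks$at[st$pos],
         ": trailing input '", peek(), "'", call. = FALSE)
  out
}

tokenize_sexpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  toks <- character(0); ats <- integer(0)
  buf <- ""; buf_at <- 0L
  flush_buf <- function() {
    if (nzchar(buf)) { toks <<- c(toks, buf); ats <<- c(ats, buf_at); buf <<- "" }
  }
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", ")")) {
      flush_buf()
      toks <- c(toks, ch); ats <- c(ats, i)
    } else if (grepl("^\\s$", ch)) {
      flush_buf()
    } else {
      if (!nzchar(buf)) buf_at <- i
      buf <- paste0(buf, ch)
    }
  }
  flush_buf()
  data.frame(tok = toks, at = ats, stringsAsFactors = FALSE)
}

#' Read and write feature files
#'
#' Feature files hold one s-expression per line; blank lines and `#`
#' comments are ignored. `write_features()` appends each feature's fitness
#' as a trailing comment when available.
#'
#' @param path File path.
#' @param features List of `feature_node`s.
#' @param fitness Optional numeric vector of fitness values, same length.
#' @param alphabet Alphabet used when parsing.
#' @return `read_features()`: list of `feature_node`s.
#' @export
read_features <- function(path, alphabet = iupac_alphabet()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_feature, alphabet = alphabet)
}

#' @rdname read_features
#' @export
write_features <- function(features, path, fitness = NULL) {
  lines <- vapply(features, serialize_feature, character(1L))
  if (!is.null(fitness))
    lines <- paste0(lines, "  # fitness=", format(fitness, digits = 6))
  writeLines(lines, path)
  invisible(path)
}

# ---- vectorization ----------------------------------------------------------

#' Transform sequences into a feature matrix
#'
#' Evaluates every feature on every sequence. In `"occurrence"` mode the
#' matrix is 0/1 (feature present in the window); in `"count"` mode entries
#' are qualifying-occurrence counts, which requires every feature to be
#' motif-rooted.
#'
#' @param dataset A `dna_dataset`.
#' @param features Non-empty list of `feature_node`s.
#' @param mode `"occurrence"` or `"count"`.
#' @return A `feature_matrix`: list with `x` (numeric matrix, sequences in
#'   rows, features in columns named by their serialization), `labels`, and
#'   `mode`.
#' @export
vectorize <- function(dataset, features, mode = c("occurrence", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "dna_dataset"))
  if (length(features) == 0L) stop("`features` must be non-empty", call. = FALSE)
  features <- lapply(features, as_feature_node)
  E <- encode_sequences(dataset$sequences)
  cache <- new.env(parent = emptyenv())
  cols <- lapply(features, function(f) {
    if (mode == "occurrence") {
      as.integer(eval_node(f, E, cache))
    } else {
      if (!is_motif_node(f))
        stop("count mode requires motif-rooted features; got '", f$op, "'",
             call. = FALSE)
      q <- qualifying_occ(f, E, cache)
      if (length(q$cols) == 0L) rep(0L, nrow(E))
      else as.integer(rowSums(q$occ[, q$cols, drop = FALSE]))
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- vapply(features, serialize_feature, character(1L))
  feature_matrix(x, dataset$labels, mode)
}

#' Construct a feature matrix from raw columns
#'
#' Mostly used internally by [vectorize()] and [spectrum_features()];
#' exported so that externally computed feature columns can flow into
#' [cfs_merit()], [efs_select()] and [nb_train()].
#'
#' @param x Numeric matrix, sequences in rows and features in columns.
#' @param labels Class labels (factor with levels `negative`/`positive`,
#'   or 0/1).
#' @param mode `"occurrence"` or `"count"`.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, mode = "occurrence") {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  structure(list(x = x, labels = labels, mode = mode),
            class = "feature_matrix")
}
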