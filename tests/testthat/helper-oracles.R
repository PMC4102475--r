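# Independent oracles: string-based brute-force implementations of the
# matching semantics, the evaluation metrics and the subset merit, kept
# deliberately separate from the package's vectorized code paths.

iupac_sets_oracle <- list(
  G = "G", A = "A", T = "T", C = "C",
  R = c("G", "A"), Y = c("T", "C"), M = c("A", "C"), K = c("G", "T"),
  S = c("G", "C"), W = c("A", "T"),
  H = c("A", "C", "T"), B = c("G", "T", "C"), V = c("G", "C", "A"),
  D = c("G", "A", "T"), N = c("G", "A", "T", "C"))

# Every concrete string a degenerate motif stands for (Cartesian product).
oracle_expand_motif <- function(motif) {
  sets <- iupac_sets_oracle[strsplit(motif, "")[[1L]]]
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)), 1L,
        function(r) paste(rev(r), collapse = ""))
}

# 0-based occurrence starts by direct window-by-window string comparison.
oracle_occurrences <- function(motif, sequence) {
  k <- nchar(motif)
  L <- nchar(sequence)
  if (k > L) return(integer(0))
  expansions <- oracle_expand_motif(motif)
  hits <- integer(0)
  for (p in 0:(L - k)) {
    if (substr(sequence, p + 1L, p + k) %in% expansions)
      hits <- c(hits, p)
  }
  hits
}

# Occurrence starts qualifying under a motif node's positional constraint.
oracle_qualifying <- function(node, sequence) {
  occ <- oracle_occurrences(node$motif, sequence)
  switch(node$op,
    matches = occ,
    matches_at = occ[occ == node$position],
    matches_shift = occ[occ >= node$position - node$shift &
                          occ <= node$position + node$shift],
    matches_region = occ[occ >= node$region_start &
                           occ < node$region_start + node$region_length])
}

oracle_eval <- function(node, sequence) {
  op <- node$op
  if (op %in% c("matches", "matches_at", "matches_shift", "matches_region"))
    return(length(oracle_qualifying(node, sequence)) > 0L)
  if (op == "and")
    return(oracle_eval(node$left, sequence) && oracle_eval(node$right, sequence))
  if (op == "or")
    return(oracle_eval(node$left, sequence) || oracle_eval(node$right, sequence))
  if (op == "not")
    return(!oracle_eval(node$child, sequence))
  # correlational
  motif_ops <- c("matches", "matches_at", "matches_shift", "matches_region")
  if (node$left$op %in% motif_ops && node$right$op %in% motif_ops) {
    oL <- oracle_qualifying(node$left, sequence)
    oR <- oracle_qualifying(node$right, sequence)
    kL <- nchar(node$left$motif)
    for (a in oL) for (b in oR) {
      gap <- b - (a + kL)
      if (gap >= 0L && gap <= node$shift) return(TRUE)
    }
    return(FALSE)
  }
  oracle_eval(node$left, sequence) && oracle_eval(node$right, sequence)
}

# auROC by explicit enumeration of positive/negative pairs.
oracle_auroc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels == "positive") else labels
  sp <- scores[y == 1L]
  sn <- scores[y == 0L]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# auPRC by explicit threshold enumeration with step-wise integration.
oracle_auprc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels == "positive") else labels
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1L)
  area <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1L)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_info_gain <- function(column, labels) {
  h <- oracle_entropy(labels)
  for (v in unique(column)) {
    sub <- labels[column == v]
    h <- h - length(sub) / length(labels) * oracle_entropy(sub)
  }
  h
}

# CFS merit computed directly from its defining quantities.
oracle_merit <- function(subset, x, labels) {
  y <- if (is.factor(labels)) as.integer(labels == "positive") else labels
  k <- length(subset)
  if (k == 0L) return(0)
  phi <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    abs(cor(a, b))
  }
  rcf <- mean(sapply(subset, function(j) phi(x[, j], y)))
  if (k == 1L) return(rcf)
  pairs <- combn(subset, 2L)
  rff <- mean(apply(pairs, 2L, function(p) phi(x[, p[1L]], x[, p[2L]])))
  k * rcf / sqrt(k + k * (k - 1L) * rff)
}

# Random trees for oracle-equivalence testing: every node variant reachable,
# motifs short enough for full expansion (<= 4^5 concrete strings).
rand_motif_for_oracle <- function(max_len = 5L) {
  len <- sample(2:max_len, 1L)
  paste(sample(names(iupac_sets_oracle), len, replace = TRUE), collapse = "")
}

rand_tree_for_oracle <- function(depth, window_length) {
  if (depth <= 1L || runif(1L) < 0.35) {
    m <- rand_motif_for_oracle()
    return(switch(sample(4L, 1L),
      ft_matches(m),
      ft_matches_at(m, sample(0:(window_length - 1L), 1L)),
      ft_matches_shift(m, sample(0:(window_length - 1L), 1L), sample(0:4, 1L)),
      ft_matches_region(m, sample(0:(window_length - 1L), 1L), sample(1:8, 1L))))
  }
  switch(sample(4L, 1L),
    ft_and(rand_tree_for_oracle(depth - 1L, window_length),
           rand_tree_for_oracle(depth - 1L, window_length)),
    ft_or(rand_tree_for_oracle(depth - 1L, window_length),
          rand_tree_for_oracle(depth - 1L, window_length)),
    ft_not(rand_tree_for_oracle(depth - 1L, window_length)),
    ft_corr(rand_tree_for_oracle(depth - 1L, window_length),
            rand_tree_for_oracle(depth - 1L, window_length),
            sample(0:5, 1L)))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
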