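# Feature subset selection: a generational GA over bitstrings indexing the
# hall of fame, maximizing the correlation-based (CFS) merit — high
# feature-class correlation, low feature-feature redundancy.

#' Configuration for the subset-selection GA
#'
#' @param pop_size Constant population size.
#' @param generations Number of generations.
#' @param p_bitflip Per-bit mutation probability; `NULL` (default) means
#'   `1/L` where `L` is the hall-of-fame size.
#' @param p_swap Per-bit uniform-crossover swap probability.
#' @param seed Integer seed.
#' @return An `efs_config` list.
#' @export
efs_config <- function(pop_size = 200L, generations = 100L,
                       p_bitflip = NULL, p_swap = 0.5, seed = 1L) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              p_bitflip = p_bitflip, p_swap = p_swap, seed = as.integer(seed))
  stopifnot(cfg$pop_size > 0L, cfg$generations > 0L,
            is.null(p_bitflip) || (p_bitflip >= 0 && p_bitflip <= 1),
            p_swap >= 0, p_swap <= 1)
  structure(cfg, class = "efs_config")
}

#' Feature-class correlation of a binary feature column
#'
#' Absolute Pearson correlation (the phi coefficient) between a 0/1 feature
#' column and the 0/1 class vector. Zero-variance columns score 0 by
#' convention.
#'
#' @param column Numeric/integer 0/1 vector.
#' @param labels Factor or 0/1 vector of the same length.
#' @return Correlation in `[0, 1]`.
#' @export
feature_class_correlation <- function(column, labels) {
  y <- as_label01(labels)
  stopifnot(length(column) == length(y))
  if (stats::sd(column) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(column, y))
}

as_label01 <- function(labels) {
  if (is.factor(labels)) as.integer(labels == "positive")
  else as.integer(labels)
}

# Precompute the correlation structure of a feature matrix once per run:
# rcf[j] = class correlation of column j; rff[j, k] = absolute pairwise
# Pearson correlation (0 for zero-variance columns).
correlation_structure <- function(matrix_x, labels) {
  y <- as_label01(labels)
  p <- ncol(matrix_x)
  sds <- apply(matrix_x, 2L, stats::sd)
  rcf <- numeric(p)
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) rcf[ok] <- abs(suppressWarnings(
    stats::cor(matrix_x[, ok, drop = FALSE], y)))
  rff <- matrix(0, p, p)
  if (sum(ok) >= 2L) {
    sub <- abs(suppressWarnings(stats::cor(matrix_x[, ok, drop = FALSE])))
    sub[is.na(sub)] <- 0
    rff[ok, ok] <- sub
  }
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

#' Correlation-based merit of a feature subset
#'
#' The CFS heuristic: for a subset of `k` features with mean feature-class
#' correlation `rcf` and mean absolute pairwise feature-feature correlation
#' `rff`, the merit is `k * rcf / sqrt(k + k * (k - 1) * rff)`. It rewards
#' subsets whose members each correlate with the class while correlating
#' little with each other; the empty subset has merit 0.
#'
#' @param subset Integer vector of column indices into `matrix`.
#' @param matrix A `feature_matrix` (see [vectorize()]) or a plain numeric
#'   matrix of 0/1 columns (then `labels` must be given).
#' @param labels Class labels when `matrix` is a plain matrix.
#' @return Non-negative merit.
#' @export
cfs_merit <- function(subset, matrix, labels = NULL) {
  if (inherits(matrix, "feature_matrix")) {
    labels <- matrix$labels
    matrix <- matrix$x
  }
  cs <- correlation_structure(matrix, labels)
  merit_from_structure(subset, cs)
}

merit_from_structure <- function(subset, cs) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf <- mean(cs$rcf[subset])
  if (k == 1L) return(rcf)
  sub <- cs$rff[subset, subset]
  rff <- (sum(sub) - k) / (k * (k - 1L))
  k * rcf / sqrt(k + k * (k - 1L) * rff)
}

#' Select a feature subset from a hall of fame by genetic search
#'
#' Generational GA over fixed-length bitstrings, one bit per hall-of-fame
#' feature. The occurrence matrix and its correlation structure are computed
#' once; each generation, parents are drawn by fitness-proportional
#' selection on the merit (uniform fallback when all merits are 0),
#' offspring arise by uniform crossover (each bit swapped with probability
#' `p_swap`) followed by bit-flip mutation (each bit flipped with
#' probability `p_bitflip`), and replace the parents entirely. The globally
#' best genome across all generations is returned.
#'
#' @param hof A `hall_of_fame` from [efc_evolve()], a plain list of feature
#'   nodes, or a precomputed `feature_matrix` (then `dataset` is ignored
#'   and the returned `features` are `NULL`).
#' @param dataset A `dna_dataset`.
#' @param config An [efs_config()].
#' @param verbose Print one log line per generation.
#' @return List with `features` (selected feature nodes), `indices` (into
#'   the hall of fame), `genome` (the best bitstring), `merit`, and
#'   `trajectory` (best merit per generation, non-decreasing).
#' @export
efs_select <- function(hof, dataset = NULL, config = efs_config(),
                       verbose = FALSE) {
  if (inherits(hof, "feature_matrix")) {
    trees <- NULL
    fm <- hof
  } else {
    trees <- if (inherits(hof, "hall_of_fame")) hof$trees else hof
    if (length(trees) == 0L) stop("hall of fame is empty", call. = FALSE)
    fm <- vectorize(dataset, trees, mode = "occurrence")
  }
  cs <- correlation_structure(fm$x, fm$labels)
  L <- ncol(fm$x)
  p_flip <- if (is.null(config$p_bitflip)) 1 / L else config$p_bitflip
  n <- config$pop_size

  best_genome <- NULL
  best_merit <- -Inf
  traj <- numeric(config$generations)

  with_seed(config$seed, {
    pop <- matrix(stats::runif(n * L) < 0.5, nrow = n, ncol = L)
    for (g in seq_len(config$generations)) {
      merits <- apply(pop, 1L, function(bits) {
        merit_from_structure(which(bits), cs)
      })
      gen_best <- which.max(merits)
      if (merits[gen_best] > best_merit) {
        best_merit <- merits[gen_best]
        best_genome <- pop[gen_best, ]
      }
      traj[g] <- best_merit
      if (verbose)
        message(sprintf("gen %3d  best merit %.4f (global %.4f)",
                        g - 1L, merits[gen_best], best_merit))
      if (g == config$generations) break
      total <- sum(merits)
      pick <- function(m) {
        if (total <= 0) sample.int(n, m, replace = TRUE)
        else sample.int(n, m, replace = TRUE, prob = merits)
      }
      parents_a <- pick(n)
      parents_b <- pick(n)
      nxt <- matrix(FALSE, nrow = n, ncol = L)
      for (i in seq_len(n)) {
        a <- pop[parents_a[i], ]
        b <- pop[parents_b[i], ]
        swap <- stats::runif(L) < config$p_swap
        child <- ifelse(swap, b, a)
        flip <- stats::runif(L) < p_flip
        nxt[i, ] <- xor(child, flip)
      }
      pop <- nxt
    }
  })
  idx <- which(best_genome)
  list(features = if (is.null(trees)) NULL else trees[idx], indices = idx,
       genome = best_genome, merit = best_merit, trajectory = traj)
}
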