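# Naive Bayes over feature vectors and the evaluation statistics used
# throughout: auROC, auPRC, entropy/information gain, stratified
# cross-validation of the full pipeline, paired t-tests, and the k-mer
# spectrum baseline.

#' Train a naive Bayes model on a feature matrix
#'
#' Bernoulli mode (the default for the boolean occurrence features built
#' here) estimates per-class feature-presence probabilities with add-one
#' (Laplace) smoothing. KDE mode fits a per-feature, per-class Gaussian
#' kernel density (Silverman rule-of-thumb bandwidth) and suits count-mode
#' vectors.
#'
#' @param matrix A `feature_matrix` from [vectorize()] or a plain numeric
#'   matrix (then `labels` is required).
#' @param labels Class labels (factor with levels `negative`, `positive`,
#'   or 0/1).
#' @param mode `"bernoulli"` or `"kde"`.
#' @return An `nb_model`.
#' @export
nb_train <- function(matrix, labels = NULL, mode = c("bernoulli", "kde")) {
  mode <- match.arg(mode)
  if (inherits(matrix, "feature_matrix")) {
    labels <- matrix$labels
    matrix <- matrix$x
  }
  if (is.null(dim(matrix)) || ncol(matrix) == 0L || nrow(matrix) == 0L)
    stop("feature matrix is empty", call. = FALSE)
  y <- as_label01(labels)
  stopifnot(length(y) == nrow(matrix))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  n <- length(y)
  priors <- c(neg = sum(y == 0L) / n, pos = sum(y == 1L) / n)
  if (mode == "bernoulli") {
    if (!all(matrix %in% c(0, 1)))
      stop("bernoulli mode requires a 0/1 matrix; use mode = \"kde\" for counts",
           call. = FALSE)
    cond <- function(cl) {
      rows <- y == cl
      (colSums(matrix[rows, , drop = FALSE]) + 1) / (sum(rows) + 2)
    }
    theta <- cbind(neg = cond(0L), pos = cond(1L))
    structure(list(mode = mode, priors = priors, theta = theta,
                   p = ncol(matrix)),
              class = "nb_model")
  } else {
    kde <- lapply(c(neg = 0L, pos = 1L), function(cl) {
      rows <- y == cl
      lapply(seq_len(ncol(matrix)), function(j) {
        v <- matrix[rows, j]
        bw <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
        if (!is.finite(bw) || bw <= 0) bw <- 0.5  # degenerate spread
        list(values = v, bw = bw)
      })
    })
    structure(list(mode = mode, priors = priors, kde = kde, p = ncol(matrix)),
              class = "nb_model")
  }
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Positive-class posterior scores from a naive Bayes model
#'
#' Log-space accumulation of the class-conditional log likelihoods plus log
#' priors, normalized so the two class posteriors sum to 1 per example.
#'
#' @param model An `nb_model` from [nb_train()].
#' @param matrix A `feature_matrix` or plain numeric matrix with the same
#'   number of features the model was trained on.
#' @return Numeric vector of posterior probabilities of the positive class.
#' @export
nb_score <- function(model, matrix) {
  if (inherits(matrix, "feature_matrix")) matrix <- matrix$x
  if (ncol(matrix) != model$p)
    stop("feature count mismatch: model has ", model$p, ", matrix has ",
         ncol(matrix), call. = FALSE)
  n <- nrow(matrix)
  ll <- matrix(0, nrow = n, ncol = 2L)
  if (model$mode == "bernoulli") {
    for (ci in 1:2) {
      th <- model$theta[, ci]
      ll[, ci] <- matrix %*% log(th) + (1 - matrix) %*% log(1 - th)
    }
  } else {
    for (ci in 1:2) {
      for (j in seq_len(model$p)) {
        k <- model$kde[[ci]][[j]]
        ll[, ci] <- ll[, ci] + vapply(matrix[, j], function(x) {
          log_mean_exp(stats::dnorm(x, mean = k$values, sd = k$bw, log = TRUE))
        }, numeric(1L))
      }
    }
  }
  lp <- sweep(ll, 2L, log(model$priors), "+")
  1 / (1 + exp(lp[, 1L] - lp[, 2L]))
}

#' Area under the ROC curve
#'
#' Computed by the pairwise-ordering identity: the fraction of
#' positive/negative pairs ranked correctly, ties counting one half
#' (equivalently the Mann-Whitney U statistic divided by the number of
#' pairs).
#'
#' @param scores Numeric scores, larger meaning more confidently positive.
#' @param labels Class labels; both classes must be present.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_label01(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("auROC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: examples are swept from the highest to the lowest
#' score, tied scores processed as one threshold group, and precision is
#' accumulated against the recall increment at each threshold (no linear
#' interpolation between PR points, which is known to be biased).
#'
#' @inheritParams auroc
#' @return auPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_label01(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("auPRC needs at least one positive", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  grp_last <- cumsum(rle(s)$lengths)  # last index of each tied group
  tp <- cumsum(y)[grp_last]
  pred_pos <- grp_last
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Shannon entropy of a label vector, in bits
#'
#' `H(D) = -sum_i p_i log2 p_i` over the class proportions, with
#' `0 * log 0 = 0`.
#'
#' @param labels Class labels (any discrete vector).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(labels) {
  stopifnot(length(labels) > 0L)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for the class labels
#'
#' Entropy of the labels minus the weighted entropy within each group
#' defined by the distinct values of the feature column:
#' `IG(F, D) = H(D) - sum_j |D_j|/|D| * H(D_j)`.
#'
#' @param column Discrete feature values.
#' @param labels Class labels, same length.
#' @return Information gain in bits (non-negative, at most `H(D)`).
#' @export
info_gain <- function(column, labels) {
  stopifnot(length(column) == length(labels))
  h <- entropy_bits(labels)
  n <- length(labels)
  cond <- 0
  for (v in unique(column)) {
    idx <- column == v
    cond <- cond + sum(idx) / n * entropy_bits(labels[idx])
  }
  h - cond
}

#' Paired two-tailed t-test with a zero-variance guard
#'
#' Thin wrapper around the textbook paired t-test that handles the
#' degenerate zero-variance difference explicitly: identical vectors give
#' `t = 0, p = 1`; a constant non-zero difference is reported as infinitely
#' significant (`p = 0`).
#'
#' @param metrics_a,metrics_b Equal-length paired numeric vectors, `n >= 2`.
#' @param conf_level Confidence level; the test is reported significant when
#'   `p < 1 - conf_level` (default 95%).
#' @return List with `t`, `p`, and `significant`.
#' @export
paired_ttest <- function(metrics_a, metrics_b, conf_level = 0.95) {
  stopifnot(length(metrics_a) == length(metrics_b))
  n <- length(metrics_a)
  if (n < 2L) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- metrics_a - metrics_b
  alpha <- 1 - conf_level
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, significant = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE))
  }
  tt <- stats::t.test(metrics_a, metrics_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha)
}

#' k-mer spectrum baseline features
#'
#' Enumerates every length-`k` substring over `{A,C,G,T}` observed in the
#' data (overlapping occurrences counted) and returns the sequences-by-kmers
#' matrix, the standard compositional baseline the evolved features are
#' compared against.
#'
#' @param dataset A `dna_dataset`.
#' @param k k-mer length, `1 <= k <= window_length`.
#' @param mode `"count"` for occurrence counts, `"occurrence"` for 0/1.
#' @return A `feature_matrix` whose columns are the observed k-mers.
#' @export
spectrum_features <- function(dataset, k, mode = c("count", "occurrence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "dna_dataset"), k >= 1L,
            k <= dataset$window_length)
  x <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(dataset$sequences), width = k)
  x <- x[, colSums(x) > 0, drop = FALSE]
  if (mode == "occurrence") x <- (x > 0) + 0L
  structure(list(x = x, labels = dataset$labels, mode = mode, k = k),
            class = "feature_matrix")
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each of `n_runs` replicate runs, performs stratified `k`-fold
#' cross-validation in which feature construction ([efc_evolve()]), subset
#' selection ([efs_select()]) and naive Bayes training all see only the
#' training split of each fold; the held-out fold is scored with the frozen
#' model. Reports per-fold auROC/auPRC, their per-run means, grand means
#' across runs, and pooled-prediction values per run (test scores of all
#' folds concatenated before curve construction).
#'
#' @param dataset A `dna_dataset`.
#' @param efc_cfg,efs_cfg Stage configurations; their `seed` fields are
#'   overridden by seeds derived from `seed`.
#' @param k Number of folds.
#' @param n_runs Number of replicate runs (the two EAs are stochastic).
#' @param seed Master seed.
#' @param nb_mode Passed to [nb_train()].
#' @return An `eval_report`: list with `folds` (data frame), `runs` (data
#'   frame with per-run mean and pooled metrics), `grand_auroc`,
#'   `grand_auprc`, and `mean_n_features`.
#' @export
cross_validate <- function(dataset, efc_cfg = efc_config(),
                           efs_cfg = efs_config(), k = 10L, n_runs = 10L,
                           seed = 1L, nb_mode = "bernoulli") {
  fold_rows <- list()
  run_rows <- list()
  for (r in seq_len(n_runs)) {
    folds <- stratified_kfold(dataset, k, derive_seed(seed, "folds", r))
    pooled_scores <- numeric(0)
    pooled_labels <- dataset$labels[0]
    for (f in seq_len(k)) {
      train <- dataset_subset(dataset, folds[[f]]$train)
      test <- dataset_subset(dataset, folds[[f]]$test)
      efc_cfg$seed <- derive_seed(seed, "efc", r, f)
      efs_cfg$seed <- derive_seed(seed, "efs", r, f)
      hof <- efc_evolve(train, efc_cfg)
      sel <- efs_select(hof, train, efs_cfg)
      feats <- if (length(sel$features) > 0L) sel$features else hof$trees[1L]
      model <- nb_train(vectorize(train, feats), mode = nb_mode)
      scores <- nb_score(model, vectorize(test, feats))
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        run = r, fold = f, n_features = length(feats),
        auroc = auroc(scores, test$labels),
        auprc = auprc(scores, test$labels))
      pooled_scores <- c(pooled_scores, scores)
      pooled_labels <- c(pooled_labels, test$labels)
    }
    fr <- do.call(rbind, fold_rows)
    fr <- fr[fr$run == r, ]
    run_rows[[r]] <- data.frame(
      run = r, mean_auroc = mean(fr$auroc), mean_auprc = mean(fr$auprc),
      pooled_auroc = auroc(pooled_scores, pooled_labels),
      pooled_auprc = auprc(pooled_scores, pooled_labels))
  }
  folds_df <- do.call(rbind, fold_rows)
  runs_df <- do.call(rbind, run_rows)
  structure(list(folds = folds_df, runs = runs_df,
                 grand_auroc = mean(runs_df$mean_auroc),
                 grand_auprc = mean(runs_df$mean_auprc),
                 mean_n_features = mean(folds_df$n_features)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", max(x$folds$run), " run(s) x ",
      max(x$folds$fold), "-fold CV\n", sep = "")
  cat(sprintf("  grand-mean auROC %.4f, auPRC %.4f; mean %.1f features/fold\n",
              x$grand_auroc, x$grand_auprc, x$mean_n_features))
  invisible(x)
}

# Deterministic stage seed derived from a master seed and labels; keeps all
# streams independent and below 2^31.
derive_seed <- function(master, ...) {
  s <- paste(master, ..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}
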