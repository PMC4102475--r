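test_that("naive Bayes priors, smoothing and degenerate inputs", {
  y <- factor(rep(c("positive", "negative"), each = 4L),
              levels = c("negative", "positive"))
  x <- cbind(f = c(1, 1, 1, 1, 0, 0, 0, 0))
  m <- nb_train(x, y)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # add-one smoothing: P(f=1 | pos) = (4+1)/(4+2)
  expect_equal(unname(m$theta["f", "pos"]), 5 / 6)
  expect_equal(unname(m$theta["f", "neg"]), 1 / 6)
  s <- nb_score(m, x)
  expect_true(min(s[1:4]) > max(s[5:8]))  # perfect feature ranks perfectly
  expect_equal(auroc(s, y), 1)
  expect_error(nb_train(x[1:4, , drop = FALSE], y[1:4]), "both classes")
  expect_error(nb_train(matrix(numeric(0), 0L, 0L), y[0]), "empty")
  expect_error(nb_score(m, cbind(x, x)), "mismatch")
})

test_that("posterior scores are proper probabilities summing to one", {
  withr::with_seed(61L, {
    x <- matrix(rbinom(200L, 1L, 0.4), 20L, 10L)
    y <- rep(c(1L, 0L), 10L)
    m <- nb_train(x, y)
    s_pos <- nb_score(m, x)
    expect_true(all(s_pos >= 0 & s_pos <= 1))
    # complement model: swap labels -> scores must be 1 - s_pos
    m2 <- nb_train(x, 1L - y)
    expect_equal(nb_score(m2, x), 1 - s_pos, tolerance = 1e-12)
  })
})

test_that("bernoulli NB matches e1071 rankings on binary features", {
  skip_if_not_installed("e1071")
  withr::with_seed(62L, {
    x <- matrix(rbinom(300L, 1L, 0.35), 30L, 10L)
    y <- factor(rep(c("positive", "negative"), 15L),
                levels = c("negative", "positive"))
    m <- nb_train(x, y)
    s <- nb_score(m, x)
    df <- as.data.frame(lapply(as.data.frame(x), function(v)
      factor(v, levels = c(0L, 1L))))
    em <- e1071::naiveBayes(df, y, laplace = 1)
    es <- predict(em, df, type = "raw")[, "positive"]
    expect_equal(s, unname(es), tolerance = 1e-9)
  })
})

test_that("KDE mode agrees with bernoulli ranking on binary features", {
  withr::with_seed(63L, {
    x <- matrix(rbinom(200L, 1L, 0.4), 20L, 10L)
    y <- rep(c(1L, 0L), 10L)
    mb <- nb_train(x, y, mode = "bernoulli")
    mk <- nb_train(x, y, mode = "kde")
    # the two point-mass KDEs and the smoothed Bernoulli agree on ordering
    # up to smoothing-induced near-ties
    expect_gt(cor(nb_score(mb, x), nb_score(mk, x), method = "spearman"),
              0.99)
    expect_equal(auroc(nb_score(mk, x), y), auroc(nb_score(mb, x), y),
                 tolerance = 0.05)
  })
})

test_that("auROC equals the pairwise-ordering value", {
  expect_equal(auroc(c(0.9, 0.8, 0.35, 0.4), c(1, 1, 1, 0)), 2 / 3)
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  withr::with_seed(71L, {
    for (rep in 1:200) {
      n <- sample(5:30, 1L)
      s <- round(runif(n), sample(1:3, 1L))  # induce ties
      y <- rbinom(n, 1L, 0.5)
      if (length(unique(y)) < 2L) next
      expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
      # Mann-Whitney U / (n1 n2) equivalence
      u <- wilcox.test(s[y == 1L], s[y == 0L], exact = FALSE)$statistic
      expect_equal(auroc(s, y), unname(u) / (sum(y == 1L) * sum(y == 0L)),
                   tolerance = 1e-12)
    }
  })
})

test_that("auPRC equals step-wise threshold integration", {
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               oracle_auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)))
  expect_equal(auprc(c(0.9, 0.8), c(1, 1)), 1)  # all positives
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)  # perfect ranking
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
  withr::with_seed(72L, {
    for (rep in 1:200) {
      n <- sample(5:30, 1L)
      s <- round(runif(n), sample(1:3, 1L))
      y <- rbinom(n, 1L, 0.4)
      if (sum(y) == 0L) next
      expect_lt(abs(auprc(s, y) - oracle_auprc(s, y)), 1e-12)
    }
  })
})

test_that("entropy and information gain match the defining formulas", {
  expect_equal(entropy_bits(rep(c(1, 0), each = 4L)), 1)
  expect_equal(entropy_bits(rep(1, 5L)), 0)
  expect_equal(entropy_bits(rep(c(1, 0), c(3L, 1L))),
               -0.75 * log2(0.75) - 0.25 * log2(0.25))
  y <- rep(c(1, 0), each = 6L)
  expect_equal(info_gain(y, y), entropy_bits(y))
  expect_equal(info_gain(rep(1, 12L), y), 0)
  withr::with_seed(73L, {
    for (rep in 1:200) {
      n <- sample(6:40, 1L)
      col <- sample(0:3, n, replace = TRUE)
      y <- rbinom(n, 1L, 0.5)
      ig <- info_gain(col, y)
      expect_lt(abs(ig - oracle_info_gain(col, y)), 1e-12)
      expect_gte(ig, -1e-12)
      expect_lte(ig, entropy_bits(y) + 1e-12)
    }
  })
})

test_that("paired t-test matches the textbook formula and handles ties", {
  r <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_false(r$significant)
  r2 <- paired_ttest(c(1, 2, 3), c(0, 1, 2))  # constant difference 1
  expect_equal(r2$p, 0)
  expect_true(r2$significant)
  expect_error(paired_ttest(1, 2), "n >= 2")
  withr::with_seed(74L, {
    for (rep in 1:50) {
      n <- sample(3:20, 1L)
      a <- rnorm(n); b <- rnorm(n)
      r3 <- paired_ttest(a, b)
      d <- a - b
      expect_equal(r3$t, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
      expect_equal(r3$p, t.test(a, b, paired = TRUE)$p.value)
    }
  })
})

test_that("spectrum features count overlapping k-mers", {
  ds <- dna_dataset("ACGT", "AAAC")
  f1 <- spectrum_features(ds, 1L)
  expect_equal(f1$x[1L, c("A", "C", "G", "T")], c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(unname(f1$x[2L, "A"]), 3L)
  f2 <- spectrum_features(ds, 2L)
  expect_equal(unname(f2$x[2L, "AA"]), 2L)  # overlapping counting
  expect_lte(ncol(f2$x), 16L)
  occ <- spectrum_features(ds, 2L, mode = "occurrence")
  expect_true(all(occ$x %in% c(0L, 1L)))
  # spectrum columns feed information gain like any other feature
  ig <- apply(f2$x, 2L, info_gain, labels = ds$labels)
  expect_true(all(ig >= 0))
})

test_that("cross-validation isolates folds and is reproducible", {
  sim <- generate_dataset(plant_spec(
    40L, 45L, 45L,
    plants = list(plant("GGTAAGGT", 15L, jitter = 1L,
                        prob_in_positive = 1, prob_in_negative = 0)),
    seed = 8L))
  efc_cfg <- efc_config(pop_size_initial = 150L, generations = 15L,
                        pop_size_floor = 60L, hof_top_k = 10L,
                        hof_seed_m = 20L, hof_capacity = 50L, seed = 1L)
  efs_cfg <- efs_config(pop_size = 60L, generations = 20L, seed = 1L)
  rep1 <- cross_validate(sim$dataset, efc_cfg, efs_cfg, k = 3L, n_runs = 1L,
                         seed = 5L)
  expect_equal(nrow(rep1$folds), 3L)
  expect_true(all(rep1$folds$auroc >= 0 & rep1$folds$auroc <= 1))
  expect_true(rep1$grand_auroc > 0.9)  # fully penetrant planted signal
  rep2 <- cross_validate(sim$dataset, efc_cfg, efs_cfg, k = 3L, n_runs = 1L,
                         seed = 5L)
  expect_identical(rep1$folds, rep2$folds)
})

test_that("shuffled labels give chance-level cross-validated auROC", {
  withr::with_seed(81L, {
    null_ds <- dna_dataset(replicate(45L, rand_seq(40L)),
                           replicate(45L, rand_seq(40L)))
  })
  efc_cfg <- efc_config(pop_size_initial = 60L, generations = 6L,
                        pop_size_floor = 30L, hof_top_k = 8L,
                        hof_seed_m = 10L, hof_capacity = 30L, seed = 1L)
  efs_cfg <- efs_config(pop_size = 40L, generations = 12L, seed = 1L)
  rep0 <- cross_validate(null_ds, efc_cfg, efs_cfg, k = 3L, n_runs = 1L,
                         seed = 6L)
  expect_true(rep0$grand_auroc >= 0.3 && rep0$grand_auroc <= 0.7)
})
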