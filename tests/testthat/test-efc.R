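test_that("filter fitness counts class-conditional occurrence", {
  ds <- toy_carrier_dataset(carriers_pos = 8L, carriers_neg = 3L)
  feat <- ft_matches("ACGTACGT")
  # independent count: scan the raw strings
  P_f <- sum(grepl("ACGTACGT", ds$sequences[ds$labels == "positive"], fixed = TRUE))
  N_f <- sum(grepl("ACGTACGT", ds$sequences[ds$labels == "negative"], fixed = TRUE))
  expect_equal(P_f, 8L)
  expect_equal(N_f, 3L)
  expect_equal(surrogate_fitness(feat, ds), (P_f - N_f) / 10)
  expect_equal(surrogate_fitness(feat, ds), 0.5)
})

test_that("fitness floors at zero and saturates at one", {
  ds <- toy_carrier_dataset(carriers_pos = 10L, carriers_neg = 0L)
  expect_equal(surrogate_fitness(ft_matches("ACGTACGT"), ds), 1)
  # tautological feature present everywhere: P_f = N_f -> 0
  expect_equal(surrogate_fitness(ft_matches("N"), ds), 0)
  # anti-feature more common in negatives -> clamped to 0
  ds2 <- toy_carrier_dataset(carriers_pos = 1L, carriers_neg = 9L)
  expect_equal(surrogate_fitness(ft_matches("ACGTACGT"), ds2), 0)
})

test_that("fitness ignores sequence order and feature-free negatives", {
  ds <- toy_carrier_dataset()
  feat <- ft_matches("ACGTACGT")
  f0 <- surrogate_fitness(feat, ds)
  perm <- sample(seq_along(ds$sequences))
  ds_perm <- ds
  ds_perm$sequences <- ds$sequences[perm]
  ds_perm$labels <- ds$labels[perm]
  expect_equal(surrogate_fitness(feat, ds_perm), f0)
  # duplicating a negative that lacks the feature leaves fitness unchanged
  ds_dup <- ds
  non_carrier <- which(ds$labels == "negative" &
                         !grepl("ACGTACGT", ds$sequences, fixed = TRUE))[1L]
  ds_dup$sequences <- c(ds$sequences, ds$sequences[non_carrier])
  ds_dup$labels <- factor(c(as.character(ds$labels), "negative"),
                          levels = levels(ds$labels))
  expect_equal(surrogate_fitness(feat, ds_dup), f0)
})

test_that("initialization fills the population within caps, reproducibly", {
  cfg <- efc_config(pop_size_initial = 60L, init_depth_range = c(2L, 4L),
                    seed = 5L)
  pop <- evomotif:::with_seed(5L, init_population(cfg, 40L))
  expect_length(pop, 60L)
  depths <- sapply(pop, tree_depth)
  expect_true(all(depths >= 2L & depths <= cfg$depth_cap))
  expect_true(all(sapply(pop, tree_size) <= cfg$size_cap))
  pop2 <- evomotif:::with_seed(5L, init_population(cfg, 40L))
  expect_identical(lapply(pop, serialize_feature),
                   lapply(pop2, serialize_feature))
  # all node variants reachable in a moderately sized population
  ops <- unique(unlist(lapply(pop, function(t)
    regmatches(serialize_feature(t),
               gregexpr("\\((matches[a-z-]*|and|or|not|corr)", serialize_feature(t))))))
  expect_true(length(ops) >= 5L)
})

test_that("restricted-alphabet populations contain no degenerate symbols", {
  cfg <- efc_config(pop_size_initial = 40L, alphabet_mode = "acgt", seed = 2L)
  pop <- evomotif:::with_seed(2L, init_population(cfg, 30L))
  sers <- sapply(pop, serialize_feature)
  all_motifs <- unlist(regmatches(sers, gregexpr("[GATCRYMKSWHBVDN]{2,}", sers)))
  expect_true(all(strsplit(paste(all_motifs, collapse = ""), "")[[1L]] %in%
                    c("A", "C", "G", "T")))
})

test_that("mutation respects caps, length bounds and clamping", {
  cfg <- efc_config(motif_len_range = c(2L, 5L), depth_cap = 4L,
                    init_depth_range = c(2L, 4L), size_cap = 10L, seed = 1L)
  withr::with_seed(11L, {
    t <- ft_matches_at("CG", 0L)
    for (i in 1:200) {
      t2 <- mutate_tree(t, cfg, 20L)
      expect_true(tree_depth(t2) <= cfg$depth_cap)
      expect_true(tree_size(t2) <= cfg$size_cap)
      for (m in evomotif:::collect_motif_nodes(t2)) {
        expect_true(nchar(m$motif) >= 2L && nchar(m$motif) <= 5L)
        if (m$op == "matches_at")
          expect_true(m$position >= 0L && m$position < 20L)
      }
    }
    # a deep tree at the cap never exceeds it
    deep <- ft_not(ft_not(ft_not(ft_matches("ACG"))))
    for (i in 1:100) {
      expect_true(tree_depth(mutate_tree(deep, cfg, 20L)) <= cfg$depth_cap)
    }
  })
})

test_that("crossover swaps compatible material and respects caps", {
  cfg <- efc_config(depth_cap = 5L, size_cap = 12L, seed = 1L)
  withr::with_seed(21L, {
    a <- ft_and(ft_matches("GGTAA"), ft_matches("CCTGG"))
    b <- ft_or(ft_matches_at("TTTT", 3L), ft_not(ft_matches("AAA")))
    for (i in 1:100) {
      off <- crossover_trees(a, b, cfg, 20L)
      for (o in off) {
        expect_true(tree_depth(o) <= cfg$depth_cap)
        expect_true(tree_size(o) <= cfg$size_cap)
        expect_s3_class(o, "feature_node")
        # offspring parse back (structural validity)
        expect_identical(serialize_feature(parse_feature(serialize_feature(o))),
                         serialize_feature(o))
      }
    }
  })
})

test_that("the population follows the implosion schedule exactly", {
  cfg <- efc_config(pop_size_initial = 100L, implosion_rate = 0.05,
                    pop_size_floor = 50L, generations = 25L, seed = 1L)
  sched <- evomotif:::implosion_schedule(cfg)
  expect_identical(sched[1:5], c(100L, 95L, 90L, 86L, 81L))
  expect_true(all(sched >= 50L))
  expect_identical(sched,
                   pmax(50L, as.integer(round(100 * 0.95^(0:24)))))
  # and the realized run matches the schedule
  sim <- planted_benchmark(n_pos = 40L, n_neg = 40L, seed = 9L)
  cfg2 <- efc_config(pop_size_initial = 60L, implosion_rate = 0.1,
                     pop_size_floor = 20L, generations = 8L,
                     hof_top_k = 5L, hof_seed_m = 10L, hof_capacity = 30L,
                     seed = 3L)
  hof <- efc_evolve(sim$dataset, cfg2)
  expect_identical(hof$log$pop_size, evomotif:::implosion_schedule(cfg2))
})

test_that("the hall of fame is deduplicated, sorted, capped, monotone", {
  sim <- planted_benchmark(n_pos = 60L, n_neg = 60L, seed = 13L)
  cfg <- efc_config(pop_size_initial = 80L, generations = 10L,
                    pop_size_floor = 30L, hof_top_k = 10L, hof_seed_m = 15L,
                    hof_capacity = 40L, seed = 4L)
  hof <- efc_evolve(sim$dataset, cfg)
  keys <- sapply(hof$trees, serialize_feature)
  expect_identical(keys, hof$keys)
  expect_false(any(duplicated(keys)))
  expect_true(length(hof$trees) <= 40L)
  expect_true(all(diff(hof$fitness) <= 0))
  # archived fitness values are exact: recompute independently
  for (i in sample(seq_along(hof$trees), 5L)) {
    expect_equal(hof$fitness[i], surrogate_fitness(hof$trees[[i]], sim$dataset))
  }
})

test_that("identical seeds reproduce the run; different seeds differ", {
  sim <- planted_benchmark(n_pos = 40L, n_neg = 40L, seed = 17L)
  cfg <- efc_config(pop_size_initial = 50L, generations = 5L,
                    pop_size_floor = 20L, hof_top_k = 5L, hof_seed_m = 10L,
                    hof_capacity = 25L, seed = 6L)
  h1 <- efc_evolve(sim$dataset, cfg)
  h2 <- efc_evolve(sim$dataset, cfg)
  expect_identical(h1$keys, h2$keys)
  expect_identical(h1$fitness, h2$fitness)
  cfg$seed <- 7L
  h3 <- efc_evolve(sim$dataset, cfg)
  expect_false(identical(h1$keys, h3$keys))
})

test_that("a dataset without positives is refused before generation 0", {
  ds <- toy_carrier_dataset()
  ds$labels[] <- "negative"
  expect_error(efc_evolve(ds, efc_config(pop_size_initial = 10L,
                                         generations = 2L, seed = 1L)),
               "no positive")
})
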