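test_that("IUPAC symbol expansion matches the code table", {
  expect_setequal(expand_iupac("R"), c("G", "A"))
  expect_setequal(expand_iupac("Y"), c("T", "C"))
  expect_setequal(expand_iupac("N"), c("G", "A", "T", "C"))
  expect_identical(expand_iupac("G"), "G")
  # base symbols are singletons; 2-fold and 3-fold symbols have the right size
  sizes <- sapply(iupac_alphabet(), function(s) length(expand_iupac(s)))
  expect_identical(unname(sizes[c("A", "C", "G", "T")]), rep(1L, 4L))
  expect_identical(unname(sizes[c("R", "Y", "M", "K", "S", "W")]), rep(2L, 6L))
  expect_identical(unname(sizes[c("H", "B", "V", "D")]), rep(3L, 4L))
  expect_error(expand_iupac("X"), "unknown symbol")
})

test_that("the restricted alphabet refuses degenerate symbols", {
  acgt <- iupac_alphabet("acgt")
  expect_error(expand_iupac("R", acgt), "unknown symbol")
  expect_error(ft_matches("AR", acgt), "outside the active alphabet")
  expect_silent(ft_matches("ACGT", acgt))
})

test_that("motif occurrences report all overlapping starts", {
  expect_identical(motif_occurrences("CG", "CGCG"), c(0L, 2L))
  expect_identical(motif_occurrences("RY", "GT"), 0L)
  expect_identical(motif_occurrences("AAAA", "ACG"), integer(0))
  expect_identical(motif_occurrences("AA", "AAAA"), c(0L, 1L, 2L))
})

test_that("positional, shift and region operators follow their contracts", {
  expect_true(evaluate_feature(ft_matches_at("CG", 1L), "ACGT"))
  expect_false(evaluate_feature(ft_matches_at("CG", 0L), "ACGT"))
  expect_true(evaluate_feature(ft_matches_shift("GT", 0L, 2L), "ACGT"))
  expect_false(evaluate_feature(ft_matches_shift("GT", 0L, 1L), "ACGT"))
  expect_true(evaluate_feature(
    ft_and(ft_matches("GAT"), ft_not(ft_matches("CCC"))), "GGATG"))
  # region semantics on an anchored window: TAAT planted at anchor -16,
  # searched in the anchor-relative region [-18, -14) of a 40 nt window
  # with the anchor at offset 20
  win <- paste0(rand_seq(4L), "TAAT", rand_seq(32L))
  expect_true(evaluate_feature(ft_matches_region("TAAT", 20L - 18L, 4L), win))
})

test_that("match counts are defined only for motif-rooted features", {
  expect_equal(match_count(ft_matches("CG"), "CGCG"), 2L)
  expect_true(match_count(ft_matches_at("CG", 0L), "CGCG") %in% c(0L, 1L))
  expect_equal(match_count(ft_matches_region("AA", 0L, 3L), "AAAA"), 3L)
  expect_error(match_count(ft_and(ft_matches("A"), ft_matches("C")), "ACGT"),
               "motif-rooted")
})

test_that("serialization round-trips and parses the documented dialect", {
  f <- parse_feature("(and (matches CCTGG) (matches GAGGC))")
  expect_identical(f$op, "and")
  expect_identical(f$left$motif, "CCTGG")
  expect_identical(serialize_feature(f), "(and (matches CCTGG) (matches GAGGC))")

  withr::with_seed(99L, {
    for (i in 1:50) {
      t <- rand_tree_for_oracle(sample(1:4, 1L), 30L)
      expect_identical(parse_feature(serialize_feature(t)),
                       t, label = serialize_feature(t))
    }
  })
})

test_that("parse errors carry a position", {
  expect_error(parse_feature("(and (matches"), "unexpected end of input")
  expect_error(parse_feature("(frobnicate A)"), "unknown operator")
  expect_error(parse_feature("(matches CG) junk"), "trailing input")
  expect_error(parse_feature("(matches-at CG x)"), "expected an integer")
})

test_that("feature files round-trip with comments and fitness annotations", {
  feats <- list(ft_matches("GGTAAG"), ft_matches_shift("CCTGG", 10L, 2L))
  path <- withr::local_tempfile(fileext = ".features")
  write_features(feats, path, fitness = c(0.9, 0.5))
  back <- read_features(path)
  expect_identical(lapply(back, serialize_feature),
                   lapply(feats, serialize_feature))
})

test_that("vectorize produces labeled 0/1 or count matrices", {
  ds <- toy_carrier_dataset()
  carrier <- ft_matches("ACGTACGT")
  fm <- vectorize(ds, list(carrier, ft_not(carrier)))
  expect_true(all(fm$x %in% c(0L, 1L)))
  expect_equal(fm$x[, 1L], 1L - fm$x[, 2L], ignore_attr = TRUE)
  expect_identical(fm$labels, ds$labels)

  fmc <- vectorize(ds, list(ft_matches("A")), mode = "count")
  expect_true(all(fmc$x >= 0L))
  expect_error(vectorize(ds, list(ft_not(carrier)), mode = "count"),
               "motif-rooted")
  expect_error(vectorize(ds, list()), "non-empty")
})

test_that("vectorized evaluation agrees with the brute-force string oracle", {
  withr::with_seed(1234L, {
    for (i in 1:200) {
      tree <- rand_tree_for_oracle(sample(1:4, 1L), 25L)
      s <- rand_seq(25L)
      expect_identical(evaluate_feature(tree, s), oracle_eval(tree, s),
                       label = paste(serialize_feature(tree), s))
    }
  })
})

test_that("shift and region generalize the exact-position operator", {
  withr::with_seed(555L, {
    for (i in 1:100) {
      m <- rand_motif_for_oracle()
      p <- sample(0:19, 1L)
      s <- rand_seq(24L)
      if (evaluate_feature(ft_matches_at(m, p), s)) {
        for (sh in c(0L, 1L, 3L)) {
          expect_true(evaluate_feature(ft_matches_shift(m, p, sh), s))
        }
        expect_true(evaluate_feature(ft_matches_region(m, p, 1L), s))
        expect_true(evaluate_feature(ft_matches(m), s))
      }
    }
  })
})

test_that("boolean combinations satisfy De Morgan on random inputs", {
  withr::with_seed(777L, {
    for (i in 1:100) {
      a <- rand_tree_for_oracle(2L, 20L)
      b <- rand_tree_for_oracle(2L, 20L)
      s <- rand_seq(20L)
      expect_identical(
        evaluate_feature(ft_not(ft_and(a, b)), s),
        evaluate_feature(ft_or(ft_not(a), ft_not(b)), s))
    }
  })
})

test_that("correlational co-occurrence is ordered and gap-bounded", {
  f <- ft_corr(ft_matches("AA"), ft_matches("TT"), 2L)
  expect_true(evaluate_feature(f, "AATTGGGGGG"))   # gap 0
  expect_true(evaluate_feature(f, "AACGTTGGGG"))   # gap 2
  expect_false(evaluate_feature(f, "AACGGTTGGG"))  # gap 3 > shift
  expect_false(evaluate_feature(f, "TTGGGGGGAA"))  # wrong order
  # non-motif child degrades to conjunction
  g <- ft_corr(ft_not(ft_matches("CC")), ft_matches("TT"), 0L)
  expect_true(evaluate_feature(g, "TTGGGGGGAA"))
  expect_false(evaluate_feature(g, "CCTTGGGGGG"))
})
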