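# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except temp files the tests write.

write_temp_fasta <- function(records, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (nm in names(records)) {
    s <- records[[nm]]
    if (!is.null(wrap)) {
      s <- substring(s, seq(1L, nchar(s), wrap),
                     pmin(seq(1L, nchar(s), wrap) + wrap - 1L, nchar(s)))
    }
    lines <- c(lines, paste0(">", nm), s)
  }
  writeLines(lines, path)
  path
}

# A tiny dataset where a known motif is carried by an exact number of
# sequences per class, so counting-based values can be asserted.
toy_carrier_dataset <- function(motif = "ACGTACGT", n_pos = 10L, n_neg = 10L,
                                carriers_pos = 8L, carriers_neg = 3L,
                                window = 20L, seed = 404L) {
  stopifnot(nchar(motif) <= window)
  base_seq <- function() {
    repeat {
      s <- rand_seq(window)
      if (!grepl(motif, s, fixed = TRUE)) return(s)
    }
  }
  with_plant <- function() {
    s <- base_seq()
    at <- sample(0:(window - nchar(motif)), 1L)
    paste0(substr(s, 1L, at), motif, substr(s, at + nchar(motif) + 1L, window))
  }
  withr::with_seed(seed, {
    pos <- c(replicate(carriers_pos, with_plant()),
             replicate(n_pos - carriers_pos, base_seq()))
    neg <- c(replicate(carriers_neg, with_plant()),
             replicate(n_neg - carriers_neg, base_seq()))
    dna_dataset(pos, neg)
  })
}

# The planted-motif benchmark conditions used by the recovery and
# selection-parsimony checks: GGTAAG at locus 30 +/- 2 nt in 60 nt windows.
planted_benchmark <- function(n_pos = 500L, n_neg = 500L, p_neg = 0.05,
                              seed = 1L) {
  generate_dataset(plant_spec(
    window_length = 60L, n_pos = n_pos, n_neg = n_neg,
    plants = list(plant("GGTAAG", 30L, jitter = 2L,
                        prob_in_positive = 0.9, prob_in_negative = p_neg)),
    seed = seed))
}

# Desk-scale EA configurations used throughout the suite.
desk_efc <- function(seed) {
  efc_config(pop_size_initial = 300L, generations = 30L,
             pop_size_floor = 100L, implosion_rate = 0.05, size_cap = 25L,
             hof_top_k = 15L, hof_seed_m = 30L, hof_capacity = 100L,
             seed = seed)
}

desk_efs <- function(seed) {
  efs_config(pop_size = 100L, generations = 40L, seed = seed)
}

# 12-column benchmark for subset selection: 3 relevant nearly independent
# features, 6 redundant copies, 3 pure-noise columns.
subset_benchmark <- function(n = 200L, seed = 2024L) {
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), each = n / 2L)
    flip <- function(v, p) ifelse(runif(n) < p, 1L - v, v)
    relevant <- sapply(1:3, function(i) flip(y, 0.12))
    redundant <- sapply(1:6, function(i) flip(relevant[, (i - 1L) %% 3L + 1L], 0.05))
    noise <- sapply(1:3, function(i) rbinom(n, 1L, 0.5))
    x <- cbind(relevant, redundant, noise)
    colnames(x) <- paste0("f", 1:12)
    list(x = x, labels = y)
  })
}
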