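# Synthetic benchmark generator: fixed-length windows over an i.i.d.
# background composition, with class-conditionally planted IUPAC motifs
# (exact, degenerate, positionally jittered, and co-occurring pairs), plus
# ground-truth bookkeeping so every downstream stage can be validated
# against known signal.

#' Specification of a synthetic planted-motif dataset
#'
#' Describes the benchmark structure the generator emulates: equal-length
#' windows drawn from a background nucleotide distribution, into which
#' signals are planted with class-dependent probabilities. A plant is an
#' IUPAC motif written at `locus + U(-jitter, jitter)` (or anywhere, when
#' `locus = "anywhere"`), with each degenerate symbol resolved uniformly
#' over its base set. A co-occurrence plant writes two motifs in 5'-to-3'
#' order separated by a gap drawn uniformly from `gap_range`.
#'
#' @param window_length Window length in nt.
#' @param n_pos,n_neg Class sizes.
#' @param background Named probability vector over `A`, `C`, `G`, `T`.
#' @param plants List of plants from [plant()].
#' @param co_plants List of co-occurrence plants from [co_plant()].
#' @param anchor_offset Optional 0-based anchor within the window.
#' @param seed Integer seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(window_length, n_pos, n_neg,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       plants = list(), co_plants = list(),
                       anchor_offset = NULL, seed = 1L) {
  stopifnot(window_length >= 1L, n_pos >= 1L, n_neg >= 1L,
            setequal(names(background), c("A", "C", "G", "T")),
            all(background >= 0), sum(background) > 0)
  background <- background[c("A", "C", "G", "T")] / sum(background)
  for (p in plants) {
    if (!identical(p$locus, "anywhere") &&
        p$locus + nchar(p$motif) > window_length)
      stop("plant '", p$motif, "' at locus ", p$locus,
           " does not fit the window", call. = FALSE)
  }
  structure(list(window_length = as.integer(window_length),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 background = background, plants = plants,
                 co_plants = co_plants, anchor_offset = anchor_offset,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Planted-signal descriptors
#'
#' @param motif IUPAC motif to plant; degenerate symbols are resolved
#'   uniformly at insertion time.
#' @param locus 0-based expected start, or `"anywhere"`.
#' @param jitter Maximum absolute positional offset from the locus, in nt.
#' @param prob_in_positive,prob_in_negative Insertion probabilities per
#'   class; discriminative plants have `prob_in_positive >
#'   prob_in_negative`.
#' @return A plant descriptor for [plant_spec()].
#' @export
plant <- function(motif, locus, jitter = 0L, prob_in_positive = 1,
                  prob_in_negative = 0) {
  check_motif(motif)
  stopifnot(prob_in_positive >= 0, prob_in_positive <= 1,
            prob_in_negative >= 0, prob_in_negative <= 1, jitter >= 0L)
  list(motif = motif, locus = locus, jitter = as.integer(jitter),
       prob_in_positive = prob_in_positive,
       prob_in_negative = prob_in_negative)
}

#' @rdname plant
#' @param motif_a,motif_b The 5' and 3' motifs of a co-occurring pair.
#' @param gap_range Length-2 integer vector, inclusive bounds on the gap
#'   between the end of `motif_a` and the start of `motif_b`.
#' @export
co_plant <- function(motif_a, motif_b, gap_range, prob_in_positive = 1,
                     prob_in_negative = 0) {
  check_motif(motif_a); check_motif(motif_b)
  stopifnot(length(gap_range) == 2L, gap_range[1L] >= 0L,
            gap_range[2L] >= gap_range[1L])
  list(motif_a = motif_a, motif_b = motif_b,
       gap_range = as.integer(gap_range),
       prob_in_positive = prob_in_positive,
       prob_in_negative = prob_in_negative)
}

resolve_iupac <- function(motif) {
  syms <- strsplit(motif, "", fixed = TRUE)[[1L]]
  paste(vapply(syms, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1L)), collapse = "")
}

#' Generate a labeled dataset with planted signals
#'
#' Background bases are drawn i.i.d. from the spec composition; plants
#' overwrite (never insert into) the window so all sequences stay
#' equal-length. Overlapping plants within one sequence are resolved
#' left-to-right in spec order: a later plant colliding with an earlier one
#' is skipped and counted. Deterministic given `spec$seed`.
#'
#' @param spec A [plant_spec()].
#' @return List with `dataset` (a `dna_dataset`), `truth` (data frame of
#'   realized insertions: `plant`, `seq`, `class`, `start`), and
#'   `n_collisions`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  L <- spec$window_length
  n <- spec$n_pos + spec$n_neg
  is_pos <- rep(c(TRUE, FALSE), c(spec$n_pos, spec$n_neg))
  truth <- list()
  with_seed(spec$seed, {
    chars <- matrix(sample(BASE_SYMBOLS, n * L, replace = TRUE,
                           prob = spec$background),
                    nrow = n, ncol = L)
    occupied <- matrix(FALSE, nrow = n, ncol = L)
    n_coll <- 0L
    write_motif <- function(i, concrete, start0) {
      span <- (start0 + 1L):(start0 + nchar(concrete))
      if (any(occupied[i, span])) return(FALSE)
      chars[i, span] <<- strsplit(concrete, "", fixed = TRUE)[[1L]]
      occupied[i, span] <<- TRUE
      TRUE
    }
    for (pi in seq_along(spec$plants)) {
      p <- spec$plants[[pi]]
      k <- nchar(p$motif)
      for (i in seq_len(n)) {
        pr <- if (is_pos[i]) p$prob_in_positive else p$prob_in_negative
        if (stats::runif(1L) >= pr) next
        start0 <- if (identical(p$locus, "anywhere")) {
          sample.int(L - k + 1L, 1L) - 1L
        } else {
          clamp(p$locus + sample(seq(-p$jitter, p$jitter), 1L), 0L, L - k)
        }
        if (write_motif(i, resolve_iupac(p$motif), start0)) {
          truth[[length(truth) + 1L]] <- data.frame(
            plant = paste0("plant", pi), seq = i,
            class = if (is_pos[i]) "positive" else "negative",
            start = start0)
        } else n_coll <- n_coll + 1L
      }
    }
    for (ci in seq_along(spec$co_plants)) {
      p <- spec$co_plants[[ci]]
      ka <- nchar(p$motif_a); kb <- nchar(p$motif_b)
      for (i in seq_len(n)) {
        pr <- if (is_pos[i]) p$prob_in_positive else p$prob_in_negative
        if (stats::runif(1L) >= pr) next
        gap <- sample(seq(p$gap_range[1L], p$gap_range[2L]), 1L)
        total <- ka + gap + kb
        if (total > L) stop("co-occurrence plant does not fit the window",
                            call. = FALSE)
        a0 <- sample.int(L - total + 1L, 1L) - 1L
        b0 <- a0 + ka + gap
        ok_a <- write_motif(i, resolve_iupac(p$motif_a), a0)
        ok_b <- if (ok_a) write_motif(i, resolve_iupac(p$motif_b), b0) else FALSE
        if (ok_a && ok_b) {
          truth[[length(truth) + 1L]] <- data.frame(
            plant = paste0("co_plant", ci), seq = i,
            class = if (is_pos[i]) "positive" else "negative", start = a0)
        } else n_coll <- n_coll + 1L
      }
    }
    seqs <- apply(chars, 1L, paste, collapse = "")
    ds <- dna_dataset(seqs[is_pos], seqs[!is_pos],
                      anchor_offset = spec$anchor_offset)
    truth_df <- if (length(truth) > 0L) do.call(rbind, truth)
    else data.frame(plant = character(0), seq = integer(0),
                    class = character(0), start = integer(0))
    list(dataset = ds, truth = truth_df, n_collisions = n_coll)
  })
}

# ---- ground-truth analysis --------------------------------------------------

# Do two IUPAC symbols share at least one base?
symbols_compatible <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
}

# Best number of compatible aligned symbol pairs between a feature motif and
# a planted motif over all ungapped alignments; also reports the feature
# start offset (relative to the plant start) achieving it.
motif_overlap <- function(feature_motif, planted_motif) {
  f <- strsplit(feature_motif, "", fixed = TRUE)[[1L]]
  p <- strsplit(planted_motif, "", fixed = TRUE)[[1L]]
  best <- 0L; best_off <- 0L
  for (off in seq(-(length(f) - 1L), length(p) - 1L)) {
    n_comp <- 0L
    for (i in seq_along(f)) {
      j <- i + off
      if (j >= 1L && j <= length(p) && symbols_compatible(f[i], p[j]))
        n_comp <- n_comp + 1L
    }
    if (n_comp > best) { best <- n_comp; best_off <- off }
  }
  list(overlap = best, offset = best_off)
}

collect_motif_nodes <- function(node, negated = FALSE) {
  if (is_motif_node(node)) {
    if (negated) return(list())
    return(list(node))
  }
  switch(node$op,
    not = collect_motif_nodes(node$child, !negated),
    c(collect_motif_nodes(node$left, negated),
      collect_motif_nodes(node$right, negated)))
}

#' Check whether a hall of fame recovered a planted motif
#'
#' A planted signal counts as recovered when some archived feature (i) has
#' fitness at least `min_fitness`, and (ii) contains a non-negated motif
#' node whose motif aligns to the planted motif with at least `min_overlap`
#' compatible symbols (IUPAC base sets intersecting position-wise), at an
#' alignment whose implied window position is consistent with the planted
#' locus whenever the node carries a positional constraint.
#'
#' @param hof A `hall_of_fame` from [efc_evolve()].
#' @param motif The planted IUPAC motif.
#' @param locus 0-based planted locus (ignored if the plant was
#'   `"anywhere"`: pass `NULL`).
#' @param jitter Planted jitter in nt.
#' @param min_fitness,min_overlap Recovery thresholds.
#' @return `TRUE`/`FALSE`.
#' @export
hof_recovers_plant <- function(hof, motif, locus = NULL, jitter = 0L,
                               min_fitness = 0.7, min_overlap = 4L) {
  stopifnot(inherits(hof, "hall_of_fame"))
  for (i in seq_along(hof$trees)) {
    if (hof$fitness[i] < min_fitness) next
    for (node in collect_motif_nodes(hof$trees[[i]])) {
      ov <- motif_overlap(node$motif, motif)
      if (ov$overlap < min_overlap) next
      if (is.null(locus) || node$op == "matches") return(TRUE)
      # implied 0-based start of the feature motif in the window
      implied <- locus + ov$offset
      starts <- qualifying_cols(node, W = 10000L) - 1L
      if (any(starts >= implied - jitter & starts <= implied + jitter))
        return(TRUE)
    }
  }
  FALSE
}
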