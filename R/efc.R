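# Feature construction by genetic programming: a population of feature
# trees evolves under a class-occurrence filter fitness, with an imploding
# population schedule, typed mutation/crossover, hard bloat caps with
# parsimony tie-breaking, and a hall-of-fame archive.

#' Configuration for the feature-construction GP
#'
#' All run parameters of the feature-construction stage. The population
#' starts at `pop_size_initial` and implodes by `implosion_rate` per
#' generation, never below `pop_size_floor`. Each generation contributes its
#' `hof_top_k` fittest features to the hall of fame, which in turn seeds the
#' next generation with `hof_seed_m` randomly drawn archive members; the
#' remainder of the next generation is bred from tournament-selected parents
#' by crossover (probability `p_crossover`) or mutation (`p_mutation`).
#' Bloat is controlled by hard `depth_cap`/`size_cap` limits enforced at
#' birth plus parsimony tie-breaking (smaller tree wins equal fitness) in
#' selection and archive ranking.
#'
#' @param pop_size_initial Initial population size.
#' @param generations Number of generations.
#' @param implosion_rate Per-generation fractional shrinkage of the
#'   population.
#' @param pop_size_floor Lower bound on population size.
#' @param init_depth_range Length-2 integer vector, depth levels for ramped
#'   half-and-half initialization.
#' @param depth_cap,size_cap Hard limits on tree depth and node count.
#' @param motif_len_range Length-2 integer vector, allowed motif lengths in
#'   nt.
#' @param shift_max Largest shift generated for shift/correlational nodes.
#' @param region_len_max Largest region length generated for region nodes.
#' @param p_crossover,p_mutation Reproduction operator probabilities
#'   (summing to at most 1; the remainder is plain copying).
#' @param hof_top_k Features archived per generation.
#' @param hof_seed_m Archive features injected into each new generation.
#' @param hof_capacity Maximum archive size.
#' @param tournament_size Tournament size for parent selection.
#' @param alphabet_mode `"iupac"` or `"acgt"` (see [iupac_alphabet()]).
#' @param seed Integer seed; a run is fully determined by it.
#' @return An `efc_config` list.
#' @export
efc_config <- function(pop_size_initial = 500L, generations = 30L,
                       implosion_rate = 0.05, pop_size_floor = 100L,
                       init_depth_range = c(2L, 5L), depth_cap = 8L,
                       size_cap = 40L, motif_len_range = c(2L, 8L),
                       shift_max = 5L, region_len_max = 12L,
                       p_crossover = 0.8, p_mutation = 0.2,
                       hof_top_k = 25L, hof_seed_m = 50L,
                       hof_capacity = 200L, tournament_size = 3L,
                       alphabet_mode = c("iupac", "acgt"), seed = 1L) {
  alphabet_mode <- match.arg(alphabet_mode)
  cfg <- list(pop_size_initial = as.integer(pop_size_initial),
              generations = as.integer(generations),
              implosion_rate = implosion_rate,
              pop_size_floor = as.integer(pop_size_floor),
              init_depth_range = as.integer(init_depth_range),
              depth_cap = as.integer(depth_cap),
              size_cap = as.integer(size_cap),
              motif_len_range = as.integer(motif_len_range),
              shift_max = as.integer(shift_max),
              region_len_max = as.integer(region_len_max),
              p_crossover = p_crossover, p_mutation = p_mutation,
              hof_top_k = as.integer(hof_top_k),
              hof_seed_m = as.integer(hof_seed_m),
              hof_capacity = as.integer(hof_capacity),
              tournament_size = as.integer(tournament_size),
              alphabet_mode = alphabet_mode, seed = as.integer(seed))
  stopifnot(cfg$pop_size_initial > 0L, cfg$generations > 0L,
            cfg$implosion_rate >= 0, cfg$implosion_rate < 1,
            cfg$pop_size_floor > 0L,
            length(cfg$init_depth_range) == 2L,
            cfg$init_depth_range[1L] >= 1L,
            diff(cfg$init_depth_range) >= 0L,
            cfg$depth_cap >= cfg$init_depth_range[2L],
            cfg$size_cap > 0L,
            length(cfg$motif_len_range) == 2L,
            cfg$motif_len_range[1L] >= 1L,
            diff(cfg$motif_len_range) >= 0L,
            cfg$p_crossover >= 0, cfg$p_mutation >= 0,
            cfg$p_crossover + cfg$p_mutation <= 1,
            cfg$hof_top_k > 0L, cfg$hof_seed_m > 0L, cfg$hof_capacity > 0L,
            cfg$tournament_size > 0L)
  structure(cfg, class = "efc_config")
}

#' Filter fitness of a single feature
#'
#' Counts class-conditional occurrence: with `P_f` positives and `N_f`
#' negatives in which the feature evaluates true, and `P` total positives,
#' the fitness is `max(0, (P_f - N_f) / P)`. The score tracks occurrence in
#' positives (negatives need not share any signal), penalizes features
#' equally present in both classes down to the floor of 0, and is
#' precision-oriented on unbalanced data. No classifier is trained.
#'
#' @param tree A `feature_node`.
#' @param dataset A `dna_dataset` with at least one positive.
#' @return Fitness in `[0, 1]`.
#' @export
surrogate_fitness <- function(tree, dataset) {
  stopifnot(inherits(dataset, "dna_dataset"))
  pos <- dataset$labels == "positive"
  if (!any(pos)) stop("dataset has no positive sequences", call. = FALSE)
  hits <- evaluate_feature(tree, dataset)
  fitness_from_hits(hits, pos)
}

fitness_from_hits <- function(hits, pos) {
  P_f <- sum(hits & pos)
  N_f <- sum(hits & !pos)
  max(0, (P_f - N_f) / sum(pos))
}

# ---- random tree generation -------------------------------------------------

# Degenerate symbols are generated less often than concrete bases so that
# random motifs start informative; evolution is free to degenerate them.
random_symbol <- function(alphabet) {
  if (attr(alphabet, "mode") == "acgt") return(sample(BASE_SYMBOLS, 1L))
  if (stats::runif(1L) < 0.75) sample(BASE_SYMBOLS, 1L)
  else sample(setdiff(IUPAC_SYMBOLS, BASE_SYMBOLS), 1L)
}

random_motif <- function(cfg, alphabet) {
  len <- sample(cfg$motif_len_range[1L]:cfg$motif_len_range[2L], 1L)
  paste(vapply(seq_len(len), function(i) random_symbol(alphabet),
               character(1L)), collapse = "")
}

random_leaf <- function(cfg, window_length, alphabet) {
  m <- random_motif(cfg, alphabet)
  switch(sample(MOTIF_OPS, 1L),
    matches = ft_matches(m, alphabet),
    matches_at = ft_matches_at(m, sample.int(window_length, 1L) - 1L, alphabet),
    matches_shift = ft_matches_shift(m, sample.int(window_length, 1L) - 1L,
                                     sample.int(cfg$shift_max + 1L, 1L) - 1L,
                                     alphabet),
    matches_region = ft_matches_region(m, sample.int(window_length, 1L) - 1L,
                                       sample.int(cfg$region_len_max, 1L),
                                       alphabet))
}

# Grow or full tree of at most `depth` levels; `full` forces internal nodes
# until the target depth, `grow` may close early (but never at the root when
# depth > 1, so initialization respects the ramped depth levels).
random_tree <- function(cfg, window_length, alphabet, depth,
                        full = FALSE, at_root = TRUE) {
  make_leaf <- depth <= 1L ||
    (!full && !at_root && stats::runif(1L) < 0.3)
  if (make_leaf) return(random_leaf(cfg, window_length, alphabet))
  op <- sample(BOOL_OPS, 1L)
  sub <- function() random_tree(cfg, window_length, alphabet, depth - 1L,
                                full = full, at_root = FALSE)
  switch(op,
    and = ft_and(sub(), sub()),
    or = ft_or(sub(), sub()),
    not = ft_not(sub()),
    corr = ft_corr(sub(), sub(), sample.int(cfg$shift_max + 1L, 1L) - 1L))
}

#' Initialize a GP population
#'
#' Ramped half-and-half: depth levels cycle over `init_depth_range`, half
#' the trees full-shaped and half grow-shaped at each level. Duplicate trees
#' (by serialization) are regenerated with bounded retries. Runs in the
#' caller's RNG stream.
#'
#' @param config An [efc_config()].
#' @param window_length Window length of the target dataset, in nt.
#' @return List of `pop_size_initial` feature nodes.
#' @export
init_population <- function(config, window_length) {
  alphabet <- iupac_alphabet(config$alphabet_mode)
  depths <- rep_len(seq(config$init_depth_range[1L],
                        config$init_depth_range[2L]),
                    config$pop_size_initial)
  seen <- new.env(parent = emptyenv())
  lapply(seq_len(config$pop_size_initial), function(i) {
    full <- i %% 2L == 0L
    for (try in 1:20) {
      t <- random_tree(config, window_length, alphabet, depths[i], full = full)
      if (tree_depth(t) <= config$depth_cap && tree_size(t) <= config$size_cap) {
        key <- serialize_feature(t)
        if (is.null(seen[[key]]) || try == 20L) {
          seen[[key]] <- TRUE
          return(t)
        }
      }
    }
    t
  })
}

# ---- tree surgery -----------------------------------------------------------

# Flatten a tree into a list of paths; a path is an integer-free character
# vector of child slots from the root ("left"/"right"/"child").
node_paths <- function(node, prefix = character(0)) {
  out <- list(prefix)
  for (slot in intersect(c("left", "right", "child"), names(node))) {
    out <- c(out, node_paths(node[[slot]], c(prefix, slot)))
  }
  out
}

get_path <- function(node, path) {
  for (s in path) node <- node[[s]]
  node
}

set_path <- function(node, path, value) {
  if (length(path) == 0L) return(value)
  node[[path[1L]]] <- set_path(node[[path[1L]]], path[-1L], value)
  node
}

clamp <- function(x, lo, hi) max(lo, min(hi, x))

within_caps <- function(tree, cfg) {
  tree_depth(tree) <= cfg$depth_cap && tree_size(tree) <= cfg$size_cap
}

#' Mutate a feature tree
#'
#' One node is chosen uniformly; one applicable variant is then applied with
#' equal probability among: (1) motif edit — substitute, insert or delete a
#' single symbol, keeping the motif length within `motif_len_range`; (2)
#' integer jitter — a position, shift or region bound perturbed by a uniform
#' offset in 1..5 of either sign, clamped into the window; (3) operator swap
#' — a boolean operator replaced by another of the same arity; (4) subtree
#' replacement by a freshly grown subtree. An offspring that violates the
#' depth or size caps is re-drawn a bounded number of times, after which the
#' parent is returned unchanged. Runs in the caller's RNG stream.
#'
#' @param tree A `feature_node`.
#' @param config An [efc_config()].
#' @param window_length Window length in nt.
#' @return A `feature_node` respecting the caps.
#' @export
mutate_tree <- function(tree, config, window_length) {
  alphabet <- iupac_alphabet(config$alphabet_mode)
  for (try in 1:10) {
    out <- mutate_once(tree, config, window_length, alphabet)
    if (within_caps(out, config)) return(out)
  }
  tree
}

mutate_once <- function(tree, cfg, window_length, alphabet) {
  paths <- node_paths(tree)
  path <- paths[[sample.int(length(paths), 1L)]]
  node <- get_path(tree, path)
  variants <- character(0)
  if (is_motif_node(node)) {
    variants <- c(variants, "motif_edit")
    if (node$op != "matches") variants <- c(variants, "int_jitter")
  } else {
    if (node$op %in% c("and", "or", "corr"))
      variants <- c(variants, "op_swap")
    if (node$op == "corr") variants <- c(variants, "int_jitter")
  }
  variants <- c(variants, "subtree")
  new_node <- switch(sample(variants, 1L),
    motif_edit = mutate_motif(node, cfg, alphabet),
    int_jitter = jitter_ints(node, cfg, window_length),
    op_swap = swap_op(node, cfg),
    subtree = random_tree(cfg, window_length, alphabet,
                          depth = sample.int(max(1L, cfg$depth_cap - length(path)), 1L),
                          at_root = FALSE))
  set_path(tree, path, new_node)
}

mutate_motif <- function(node, cfg, alphabet) {
  syms <- strsplit(node$motif, "", fixed = TRUE)[[1L]]
  len <- length(syms)
  edits <- "substitute"
  if (len < cfg$motif_len_range[2L]) edits <- c(edits, "insert")
  if (len > cfg$motif_len_range[1L]) edits <- c(edits, "delete")
  edit <- sample(edits, 1L)
  if (edit == "substitute") {
    i <- sample.int(len, 1L)
    syms[i] <- random_symbol(alphabet)
  } else if (edit == "insert") {
    i <- sample.int(len + 1L, 1L)
    syms <- append(syms, random_symbol(alphabet), after = i - 1L)
  } else {
    syms <- syms[-sample.int(len, 1L)]
  }
  node$motif <- paste(syms, collapse = "")
  node
}

jitter_ints <- function(node, cfg, window_length) {
  delta <- sample.int(5L, 1L) * sample(c(-1L, 1L), 1L)
  fields <- switch(node$op,
    matches_at = "position",
    matches_shift = c("position", "shift"),
    matches_region = c("region_start", "region_length"),
    corr = "shift")
  f <- if (length(fields) == 1L) fields else sample(fields, 1L)
  lo <- if (f %in% c("position", "region_start")) 0L
        else if (f == "region_length") 1L else 0L
  hi <- switch(f, position = window_length - 1L,
               region_start = window_length - 1L,
               region_length = window_length,
               shift = max(cfg$shift_max, window_length %/% 2L))
  node[[f]] <- as.integer(clamp(node[[f]] + delta, lo, hi))
  node
}

swap_op <- function(node, cfg) {
  alt <- setdiff(c("and", "or", "corr"), node$op)
  new_op <- sample(alt, 1L)
  out <- if (new_op == "corr")
    ft_corr(node$left, node$right,
            if (!is.null(node$shift)) node$shift
            else sample.int(cfg$shift_max + 1L, 1L) - 1L)
  else if (new_op == "and") ft_and(node$left, node$right)
  else ft_or(node$left, node$right)
  out
}

#' Cross two feature trees
#'
#' Exchanges type-compatible material: boolean subtrees, whole motifs, or
#' same-role integer arguments (position with position, shift with shift,
#' region bounds with region bounds), the crossover kind drawn uniformly
#' among those available in both parents. Offspring violating the caps are
#' re-drawn a bounded number of times, then fall back to their parent. Runs
#' in the caller's RNG stream.
#'
#' @param a,b Parent `feature_node`s.
#' @param config An [efc_config()].
#' @param window_length Window length in nt.
#' @return List of two offspring `feature_node`s.
#' @export
crossover_trees <- function(a, b, config, window_length) {
  for (try in 1:10) {
    off <- crossover_once(a, b)
    ok1 <- within_caps(off[[1L]], config)
    ok2 <- within_caps(off[[2L]], config)
    if (ok1 && ok2) return(off)
  }
  list(a, b)
}

# Integer roles present in a node, as "op:field" strings for role matching.
int_roles <- function(node) {
  switch(node$op,
    matches_at = "position",
    matches_shift = c("position", "shift"),
    matches_region = c("region_start", "region_length"),
    corr = "shift",
    character(0))
}

crossover_once <- function(a, b) {
  pa <- node_paths(a); pb <- node_paths(b)
  kinds <- "subtree"
  motif_a <- Filter(function(p) is_motif_node(get_path(a, p)), pa)
  motif_b <- Filter(function(p) is_motif_node(get_path(b, p)), pb)
  if (length(motif_a) > 0L && length(motif_b) > 0L) kinds <- c(kinds, "motif")
  roles_a <- unique(unlist(lapply(pa, function(p) int_roles(get_path(a, p)))))
  roles_b <- unique(unlist(lapply(pb, function(p) int_roles(get_path(b, p)))))
  shared_roles <- intersect(roles_a, roles_b)
  if (length(shared_roles) > 0L) kinds <- c(kinds, "integer")
  kind <- sample(kinds, 1L)
  if (kind == "subtree") {
    qa <- pa[[sample.int(length(pa), 1L)]]
    qb <- pb[[sample.int(length(pb), 1L)]]
    sub_a <- get_path(a, qa); sub_b <- get_path(b, qb)
    list(set_path(a, qa, sub_b), set_path(b, qb, sub_a))
  } else if (kind == "motif") {
    qa <- motif_a[[sample.int(length(motif_a), 1L)]]
    qb <- motif_b[[sample.int(length(motif_b), 1L)]]
    na <- get_path(a, qa); nb <- get_path(b, qb)
    ma <- na$motif; na$motif <- nb$motif; nb$motif <- ma
    list(set_path(a, qa, na), set_path(b, qb, nb))
  } else {
    role <- if (length(shared_roles) == 1L) shared_roles
            else sample(shared_roles, 1L)
    ca <- Filter(function(p) role %in% int_roles(get_path(a, p)), pa)
    cb <- Filter(function(p) role %in% int_roles(get_path(b, p)), pb)
    qa <- ca[[sample.int(length(ca), 1L)]]
    qb <- cb[[sample.int(length(cb), 1L)]]
    na <- get_path(a, qa); nb <- get_path(b, qb)
    va <- na[[role]]; na[[role]] <- nb[[role]]; nb[[role]] <- va
    list(set_path(a, qa, na), set_path(b, qb, nb))
  }
}

# ---- hall of fame -----------------------------------------------------------

hof_new <- function(capacity) {
  structure(list(trees = list(), fitness = numeric(0), keys = character(0),
                 sizes = integer(0), capacity = as.integer(capacity),
                 log = NULL),
            class = "hall_of_fame")
}

# Ranking: fitness desc, then smaller tree (parsimony), then lexicographic key.
hof_order <- function(hof) {
  order(-hof$fitness, hof$sizes, hof$keys, method = "radix")
}

hof_insert <- function(hof, trees, fitness) {
  keys <- vapply(trees, serialize_feature, character(1L))
  keep <- !duplicated(keys) & !(keys %in% hof$keys)
  if (any(keep)) {
    hof$trees <- c(hof$trees, trees[keep])
    hof$fitness <- c(hof$fitness, fitness[keep])
    hof$keys <- c(hof$keys, keys[keep])
    hof$sizes <- c(hof$sizes, vapply(trees[keep], tree_size, integer(1L)))
  }
  o <- hof_order(hof)
  if (length(o) > hof$capacity) o <- o[seq_len(hof$capacity)]
  hof$trees <- hof$trees[o]
  hof$fitness <- hof$fitness[o]
  hof$keys <- hof$keys[o]
  hof$sizes <- hof$sizes[o]
  hof
}

#' @export
print.hall_of_fame <- function(x, ...) {
  cat("<hall_of_fame> ", length(x$trees), " features (capacity ",
      x$capacity, ")\n", sep = "")
  n <- min(5L, length(x$trees))
  for (i in seq_len(n))
    cat(sprintf("  %.3f  %s\n", x$fitness[i], x$keys[i]))
  if (length(x$trees) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.hall_of_fame <- function(x) length(x$trees)

# ---- the evolutionary loop --------------------------------------------------

# Implosion schedule: population size at generation g (0-based).
implosion_schedule <- function(config) {
  g <- seq_len(config$generations) - 1L
  pmax(config$pop_size_floor,
       as.integer(round(config$pop_size_initial *
                          (1 - config$implosion_rate)^g)))
}

#' Evolve a hall of fame of discriminative features
#'
#' Runs the GP over `config$generations` generations. Each generation the
#' whole population is scored with [surrogate_fitness()], the `hof_top_k`
#' fittest individuals enter the hall of fame (deduplicated by
#' serialization; ties broken toward smaller trees), and the next,
#' implosion-shrunk generation is assembled from `hof_seed_m` archive
#' members plus offspring of tournament-selected parents. The archive's best
#' fitness is non-decreasing across generations, every individual respects
#' the depth and size caps, and identical seeds give identical results.
#'
#' @param dataset A `dna_dataset` with at least one positive sequence.
#' @param config An [efc_config()].
#' @param verbose Print one log line per generation.
#' @param keep_populations Also return every generation's population (as
#'   lists of trees) in a `populations` element; intended for auditing the
#'   engine's invariants, off by default.
#' @return A `hall_of_fame` with elements `trees`, `fitness` (sorted
#'   descending), and `log` (per-generation data frame: `gen`, `pop_size`,
#'   `best_fitness`, `mean_fitness`, `hof_size`).
#' @export
efc_evolve <- function(dataset, config = efc_config(), verbose = FALSE,
                       keep_populations = FALSE) {
  stopifnot(inherits(dataset, "dna_dataset"))
  pos <- dataset$labels == "positive"
  if (!any(pos)) stop("dataset has no positive sequences", call. = FALSE)
  E <- encode_sequences(dataset$sequences)
  W <- dataset$window_length
  sched <- implosion_schedule(config)
  fit_cache <- new.env(parent = emptyenv())
  hof <- hof_new(config$hof_capacity)
  log_rows <- vector("list", config$generations)
  populations <- if (keep_populations) vector("list", config$generations)

  score_pop <- function(pop) {
    occ_cache <- new.env(parent = emptyenv())
    vapply(pop, function(t) {
      key <- serialize_feature(t)
      f <- fit_cache[[key]]
      if (is.null(f)) {
        f <- fitness_from_hits(eval_node(t, E, occ_cache), pos)
        fit_cache[[key]] <- f
      }
      f
    }, numeric(1L))
  }

  with_seed(config$seed, {
    pop <- init_population(config, W)
    for (g in seq_len(config$generations)) {
      pop <- pop[seq_len(min(length(pop), sched[g]))]
      if (keep_populations) populations[[g]] <- pop
      fit <- score_pop(pop)
      top <- order(-fit, vapply(pop, tree_size, integer(1L)),
                   method = "radix")[seq_len(min(config$hof_top_k,
                                                 length(pop)))]
      hof <- hof_insert(hof, pop[top], fit[top])
      log_rows[[g]] <- data.frame(gen = g - 1L, pop_size = length(pop),
                                  best_fitness = max(fit),
                                  mean_fitness = mean(fit),
                                  hof_size = length(hof$trees))
      if (verbose)
        message(sprintf("gen %3d  pop %4d  best %.3f  mean %.3f  hof %d",
                        g - 1L, length(pop), max(fit), mean(fit),
                        length(hof$trees)))
      if (g == config$generations) break
      n_next <- sched[g + 1L]
      sizes <- vapply(pop, tree_size, integer(1L))
      select_parent <- function() {
        cand <- sample.int(length(pop), min(config$tournament_size,
                                            length(pop)))
        best <- cand[order(-fit[cand], sizes[cand])[1L]]
        pop[[best]]
      }
      n_seed <- min(config$hof_seed_m, length(hof$trees), n_next)
      nxt <- if (n_seed > 0L)
        hof$trees[sample.int(length(hof$trees), n_seed)] else list()
      while (length(nxt) < n_next) {
        u <- stats::runif(1L)
        if (u < config$p_crossover) {
          off <- crossover_trees(select_parent(), select_parent(), config, W)
          nxt <- c(nxt, off)
        } else if (u < config$p_crossover + config$p_mutation) {
          nxt <- c(nxt, list(mutate_tree(select_parent(), config, W)))
        } else {
          nxt <- c(nxt, list(select_parent()))
        }
      }
      pop <- nxt[seq_len(n_next)]
    }
  })
  hof$log <- do.call(rbind, log_rows)
  if (keep_populations) hof$populations <- populations
  hof
}
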