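# End-to-end orchestration: one JSON-configurable pipeline running
# feature construction, subset selection, classifier training and
# evaluation with stage-scoped seeds derived from a single master seed.

#' Assemble a pipeline configuration
#'
#' Collects the stage configurations into one serializable document. Stage
#' seeds are derived from `seed` (as a hash of the master seed and the
#' stage name) so that adding a stage never perturbs the random streams of
#' earlier stages.
#'
#' @param efc Arguments for [efc_config()] as a named list.
#' @param efs Arguments for [efs_config()] as a named list.
#' @param alphabet_mode `"iupac"` or `"acgt"`; forwarded to the EFC stage.
#' @param vector_mode `"occurrence"` or `"count"` for [vectorize()].
#' @param nb_mode `"bernoulli"` or `"kde"` for [nb_train()].
#' @param cv_folds,cv_runs If `cv_folds >= 2`, [cross_validate()] is run as
#'   the evaluation stage with this many folds and replicate runs.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(efc = list(), efs = list(),
                       alphabet_mode = c("iupac", "acgt"),
                       vector_mode = c("occurrence", "count"),
                       nb_mode = c("bernoulli", "kde"),
                       cv_folds = 0L, cv_runs = 1L, seed = 1L) {
  alphabet_mode <- match.arg(alphabet_mode)
  check_known <- function(args, fn, what) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0L)
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  check_known(efc, efc_config, "efc")
  check_known(efs, efs_config, "efs")
  efc$alphabet_mode <- alphabet_mode
  structure(list(efc = efc, efs = efs, alphabet_mode = alphabet_mode,
                 vector_mode = match.arg(vector_mode),
                 nb_mode = match.arg(nb_mode),
                 cv_folds = as.integer(cv_folds),
                 cv_runs = as.integer(cv_runs),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys anywhere in the document are rejected rather than silently
#' ignored.
#'
#' @param path Path to a JSON file whose keys mirror the [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(doc), names(formals(run_config)))
  if (length(bad) > 0L)
    stop("unknown config key(s) in '", path, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, doc)
}

#' Run the full pipeline on a labeled dataset
#'
#' Stages, in order: feature construction ([efc_evolve()]), subset
#' selection ([efs_select()]), naive Bayes training on the selected
#' features, and evaluation (training-set auROC/auPRC, plus
#' [cross_validate()] when `config$cv_folds >= 2`). When `out_dir` is
#' given, each stage writes its artifact there: `hof.features` (+ fitness),
#' `efc_log.tsv`, `selected.features`, `model.json`, and `report.json`.
#'
#' @param config A [run_config()].
#' @param dataset A `dna_dataset`, or `NULL` to load from `pos_path` /
#'   `neg_path`.
#' @param pos_path,neg_path FASTA paths used when `dataset` is `NULL`.
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Forwarded to the stage functions.
#' @return List with `hof`, `selection`, `model`, and `report`.
#' @export
run_pipeline <- function(config, dataset = NULL, pos_path = NULL,
                         neg_path = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    if (is.null(pos_path) || is.null(neg_path))
      stop("either `dataset` or both FASTA paths are required", call. = FALSE)
    dataset <- load_dataset(pos_path, neg_path)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  efc_cfg <- do.call(efc_config, c(config$efc,
                                   list(seed = derive_seed(config$seed, "efc"))))
  efs_cfg <- do.call(efs_config, c(config$efs,
                                   list(seed = derive_seed(config$seed, "efs"))))

  hof <- efc_evolve(dataset, efc_cfg, verbose = verbose)
  sel <- efs_select(hof, dataset, efs_cfg, verbose = verbose)
  feats <- if (length(sel$features) > 0L) sel$features else hof$trees[1L]
  fm <- vectorize(dataset, feats, mode = config$vector_mode)
  model <- nb_train(fm, mode = config$nb_mode)
  train_scores <- nb_score(model, fm)
  report <- list(
    n_sequences = length(dataset$sequences),
    window_length = dataset$window_length,
    hof_size = length(hof$trees),
    hof_best_fitness = max(hof$fitness),
    n_selected = length(feats),
    merit = sel$merit,
    train_auroc = auroc(train_scores, dataset$labels),
    train_auprc = auprc(train_scores, dataset$labels))
  if (config$cv_folds >= 2L) {
    cv <- cross_validate(dataset, efc_cfg, efs_cfg, k = config$cv_folds,
                         n_runs = config$cv_runs,
                         seed = derive_seed(config$seed, "cv"),
                         nb_mode = config$nb_mode)
    report$cv_auroc <- cv$grand_auroc
    report$cv_auprc <- cv$grand_auprc
  }

  if (!is.null(out_dir)) {
    write_features(hof$trees, file.path(out_dir, "hof.features"),
                   fitness = hof$fitness)
    utils::write.table(hof$log, file.path(out_dir, "efc_log.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_features(feats, file.path(out_dir, "selected.features"))
    jsonlite::write_json(nb_model_to_list(model),
                         file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(hof = hof, selection = sel, model = model, report = report)
}

nb_model_to_list <- function(model) {
  if (model$mode == "bernoulli") {
    list(mode = model$mode, priors = as.list(model$priors),
         theta_neg = unname(model$theta[, "neg"]),
         theta_pos = unname(model$theta[, "pos"]))
  } else {
    list(mode = model$mode, priors = as.list(model$priors),
         kde = lapply(model$kde, function(cl)
           lapply(cl, function(k) list(values = k$values, bw = k$bw))))
  }
}

#' Write a synthetic dataset to FASTA files with a truth record
#'
#' @param sim Result of [generate_dataset()].
#' @param pos_path,neg_path Output FASTA paths.
#' @param truth_path Optional JSON path for the ground-truth plant record.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, pos_path, neg_path, truth_path = NULL) {
  ds <- sim$dataset
  pos <- ds$sequences[ds$labels == "positive"]
  neg <- ds$sequences[ds$labels == "negative"]
  write_fasta <- function(seqs, prefix, path) {
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- paste0(prefix, seq_along(seqs))
    Biostrings::writeXStringSet(set, path, width = 80L)
  }
  write_fasta(pos, "pos_", pos_path)
  write_fasta(neg, "neg_", neg_path)
  if (!is.null(truth_path))
    jsonlite::write_json(list(truth = sim$truth,
                              n_collisions = sim$n_collisions),
                         truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(pos_path, neg_path, truth_path))
}
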