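# End-to-end experiment orchestration: split, feature assembly, training,
# held-out evaluation, and between-experiment comparison.

#' Experiment configuration
#'
#' @param dataset Either a directory of recording bundles or an in-memory
#'   named list of `aligned_recording`s (e.g. from [simulate_cohort()]).
#' @param granularity Stage granularity: 5, 3 or 2.
#' @param combo Modality combination: "act", "act_hrv", "act_hrv_rrv",
#'   "act_hrv_edrrv".
#' @param algorithm Model family (see [search_spec()]).
#' @param budget Hyperparameter search budget.
#' @param k_folds Embedded CV folds (capped at the number of training
#'   participants).
#' @param train_fraction Participant-level train fraction (default 0.8).
#' @param sequence_minutes Window length for sequence models.
#' @param epochs Training epochs for sequence models.
#' @param seed Master seed for every stochastic step.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(dataset, granularity = 5,
                              combo = "act_hrv_rrv", algorithm = "gboost",
                              budget = NULL, k_folds = 5,
                              train_fraction = 0.8,
                              sequence_minutes = 10, epochs = 10, seed = 1) {
  if (!granularity %in% c(5, 3, 2)) stopf("granularity must be 5, 3 or 2")
  structure(list(dataset = dataset, granularity = granularity,
                 combo = normalize_combo(combo), algorithm = algorithm,
                 budget = budget, k_folds = k_folds,
                 train_fraction = train_fraction,
                 sequence_minutes = sequence_minutes, epochs = epochs,
                 seed = seed),
            class = "experiment_config")
}

load_cohort <- function(dataset) {
  if (is.character(dataset)) {
    dirs <- list.dirs(dataset, recursive = FALSE)
    recs <- lapply(dirs, read_recording_bundle)
    names(recs) <- vapply(recs, `[[`, "", "participant_id")
    recs
  } else dataset
}

ensure_edr <- function(rec) {
  if (!is.null(rec$edr)) return(rec)
  if (is.null(rec$ecg))
    stopf("combination act_hrv_edrrv requires an ECG or EDR signal for %s",
          rec$participant_id)
  beats <- detect_r_peaks(rec$ecg)
  ann <- detect_troughs(rec$ecg, beats$r_times)
  rec$edr <- edr_to_signal(extract_edr(ann))
  rec
}

cohort_features <- function(recs, cfg, target) {
  out <- lapply(recs, function(rec) {
    if (cfg$combo == "act_hrv_edrrv") rec <- ensure_edr(rec)
    assemble_features(rec, cfg$combo, target = target,
                      granularity = cfg$granularity)
  })
  list(values = do.call(rbind, lapply(out, function(p) p$features$values)),
       labels = factor(unlist(lapply(out, function(p) as.character(p$labels))),
                       levels = stage_levels(cfg$granularity)),
       ids = unlist(lapply(names(out), function(id)
         rep(id, length(out[[id]]$labels)))))
}

#' Run one end-to-end sleep-staging experiment
#'
#' Participant-level split, modality feature assembly, leakage-safe model
#' fitting on the training participants, prediction on held-out
#' participants, and per-participant metric reporting.  Test participants
#' are never touched before final evaluation; all randomness derives from
#' the config seed.
#'
#' @param cfg An `experiment_config`.
#' @return A result bundle: `model`, `results` (per-participant metric
#'   table and summary), `confusion` (pooled test confusion matrix),
#'   `predictions`, `split`, `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  recs <- load_cohort(cfg$dataset)
  if (cfg$combo == "act_hrv_edrrv") {
    no_sig <- vapply(recs, function(r) is.null(r$edr) && is.null(r$ecg),
                     TRUE)
    if (any(no_sig))
      stopf("combination act_hrv_edrrv requires ECG/EDR; missing for: %s",
            paste(names(recs)[no_sig], collapse = ", "))
  }
  sp <- split_participants(names(recs), cfg$train_fraction, cfg$seed)
  is_seq <- cfg$algorithm %in% c("lstm", "rnn")
  target <- if (is_seq) "dl" else "ml"
  train_feat <- cohort_features(recs[sp$train], cfg, target)
  if (is_seq) {
    inner <- split_participants(sp$train, 0.8, derive_seed(cfg$seed, 2))
    tr_rows <- train_feat$ids %in% inner$train
    tr <- make_sequences(train_feat$values[tr_rows, , drop = FALSE],
                         train_feat$labels[tr_rows],
                         train_feat$ids[tr_rows], cfg$sequence_minutes)
    va <- make_sequences(train_feat$values[!tr_rows, , drop = FALSE],
                         train_feat$labels[!tr_rows],
                         train_feat$ids[!tr_rows], cfg$sequence_minutes,
                         norm_stats = tr$norm_stats)
    model <- fit_sequence_model(tr, va, epochs = cfg$epochs,
                                seed = cfg$seed)
  } else {
    spec <- search_spec(cfg$algorithm, budget = cfg$budget, seed = cfg$seed,
                        k_folds = min(cfg$k_folds %||% 5,
                                      length(sp$train)))
    model <- fit_ml(train_feat$values, train_feat$labels, train_feat$ids,
                    spec)
  }
  test_feat <- cohort_features(recs[sp$test], cfg, target)
  pred <- if (is_seq) {
    seqs <- make_sequences(test_feat$values, test_feat$labels,
                           test_feat$ids, cfg$sequence_minutes,
                           norm_stats = model$preproc)
    predict(model, seqs)
  } else predict(model, test_feat$values)
  classes <- stage_levels(cfg$granularity)
  res <- per_participant(as.character(test_feat$labels),
                         as.character(pred), test_feat$ids, classes)
  structure(list(model = model, results = res,
                 confusion = confusion(as.character(test_feat$labels),
                                       as.character(pred), classes),
                 predictions = data.frame(participant_id = test_feat$ids,
                                          truth = as.character(test_feat$labels),
                                          predicted = as.character(pred)),
                 split = sp, config = cfg),
            class = "experiment_result")
}

#' Compare experiment results by per-participant MCC
#'
#' Pairwise two-sided rank-sum tests on per-participant MCC with
#' Bonferroni adjustment over the declared family.  Bundles must share the
#' same granularity and test participants.
#'
#' @param bundles Named list of `experiment_result`s.
#' @param family_size Bonferroni family size (default: number of pairs).
#' @return Data frame with one row per pair: U statistic, raw and adjusted
#'   p, significance stars.
#' @export
compare_experiments <- function(bundles, family_size = NULL) {
  stopifnot(length(bundles) >= 2)
  grans <- vapply(bundles, function(b) b$config$granularity, 0)
  if (length(unique(grans)) != 1)
    stopf("bundles differ in granularity: %s",
          paste(unique(grans), collapse = ", "))
  tests <- lapply(bundles, function(b) sort(b$results$table$participant_id))
  if (!all(vapply(tests, identical, TRUE, tests[[1]])))
    stopf("bundles were evaluated on different test participants")
  pairs <- utils::combn(names(bundles), 2, simplify = FALSE)
  if (is.null(family_size)) family_size <- length(pairs)
  rows <- lapply(pairs, function(p) {
    a <- bundles[[p[1]]]$results$table$mcc
    b <- bundles[[p[2]]]$results$table$mcc
    cr <- compare_conditions(a, b, family_size)
    data.frame(condition_a = p[1], condition_b = p[2],
               median_a = median(a), median_b = median(b),
               U = cr$statistic, p_raw = cr$p_raw,
               p_adjusted = cr$p_adjusted, stars = cr$stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
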