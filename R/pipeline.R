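#' Configuration for a full three-strategy experiment
#'
#' Bundles every stage's options: synthetic-corpus generation (or
#' externally supplied data), preprocessing, embedding, timeline assembly,
#' the LSTM and gradient-boosted-tree models, and evaluation. All
#' randomness flows from `seed`: stage seeds are derived as fixed offsets,
#' and the synthetic generator's own seed is overridden with `seed`.
#'
#' @param synth A [synth_config()] describing the synthetic corpus (used
#'   when no external corpus is passed to [run_experiment()]).
#' @param min_count Rare-word threshold for preprocessing.
#' @param embed_dim,embed_window,embed_epochs Skip-gram hyperparameters.
#' @param horizon_days Label horizon.
#' @param max_len Fixed sequence length for truncation/padding.
#' @param weak_threshold_hi,weak_threshold_lo Weak-label score thresholds:
#'   the high threshold defines the high-specificity preset (weak #1), the
#'   low one the high-sensitivity preset (weak #2).
#' @param train_frac Patient-level training fraction of the manual cohort.
#' @param lstm An [lstm_config()]; its `input_dim` is forced to
#'   `embed_dim` and its seed is derived from `seed`.
#' @param gbt_nrounds Boosting rounds for the baseline.
#' @param n_boot Bootstrap resamples for the evaluation report.
#' @param strategies Subset of `c("traditional", "weak1", "weak2")`.
#' @param models Subset of `c("lstm", "gbt")`.
#' @param seed Master integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(), min_count = 50L,
                              embed_dim = 300L, embed_window = 30L,
                              embed_epochs = 30L, horizon_days = 365L,
                              max_len = 800L, weak_threshold_hi = 0.9,
                              weak_threshold_lo = 0.5, train_frac = 0.75,
                              lstm = lstm_config(), gbt_nrounds = 100L,
                              n_boot = 1000L,
                              strategies = c("traditional", "weak1", "weak2"),
                              models = c("lstm", "gbt"), seed = 1L) {
  stopifnot(inherits(synth, "synth_config"), inherits(lstm, "lstm_config"),
            all(strategies %in% c("traditional", "weak1", "weak2")),
            all(models %in% c("lstm", "gbt")),
            weak_threshold_hi >= weak_threshold_lo)
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

#' Scaled-down demonstration configuration
#'
#' A compact configuration for running the full three-strategy comparison
#' on a desktop CPU in minutes: a 2,000-patient synthetic cohort with a
#' dense but shortened visit stream (about 8 notes per year over roughly
#' 2.5 years of follow-up, so temporal aggregation still has material to
#' work with), 32-dimensional embeddings, and a reduced network (16 and 8
#' LSTM units, 12 epochs). The recurrence signal keeps the reference
#' shape: 15% recurrence, signal strength 0.5 ramping over the 540 days
#' before recurrence.
#'
#' @param seed Master seed.
#' @param n_patients Cohort size.
#' @param signal_strength Maximum signal-token mixing probability; set 0
#'   for a no-signal null run.
#' @param manual_fraction Fraction of manually labelled patients.
#' @return An `experiment_config`.
#' @export
demo_experiment_config <- function(seed = 1L, n_patients = 2000L,
                                   signal_strength = 0.5,
                                   manual_fraction = 0.08) {
  experiment_config(
    synth = synth_config(
      n_patients = n_patients, recurrence_fraction = 0.15,
      follow_up_mean = 2.5, follow_up_sd = 0.8,
      visits_per_year_mean = 8, visits_per_year_sd = 2,
      note_length_mean = 20, note_length_sd = 6,
      background_vocab = 800L, signal_vocab = 60L,
      signal_ramp_days = 540L, signal_strength = signal_strength,
      manual_fraction = manual_fraction, seed = seed
    ),
    min_count = 50L, embed_dim = 32L, embed_window = 5L, embed_epochs = 3L,
    max_len = 48L,
    lstm = lstm_config(input_dim = 32L, layer1_units = 16L,
                       layer2_units = 8L, epochs = 12L),
    gbt_nrounds = 80L, n_boot = 200L, seed = seed
  )
}

# Split a vectorized note table into per-patient timelines.
build_timelines <- function(note_dt, V, outcomes) {
  oc <- data.table::as.data.table(outcomes)
  ids <- unique(note_dt$patient_id)
  idx_by_pat <- split(seq_len(nrow(note_dt)), note_dt$patient_id)
  lapply(ids, function(p) {
    idx <- idx_by_pat[[as.character(p)]]
    o <- oc[oc$patient_id == p]
    patient_timeline(
      patient_id = p,
      note_id = note_dt$note_id[idx],
      date = note_dt$timestamp[idx],
      vectors = V[idx, , drop = FALSE],
      recurrence_date = if (nrow(o)) o$recurrence_date[1] else as.Date(NA),
      label_source = if (nrow(o)) o$label_source[1] else "manual"
    )
  })
}

#' Run the full three-strategy experiment
#'
#' Executes the whole workflow on one corpus: preprocessing, skip-gram
#' embedding (trained on the pooled corpus), frozen training-corpus idf,
#' note vectorization, patient-level train/test split of the manually
#' curated cohort, supervision-set assembly under each strategy (weak
#' recurrence dates imputed from the thresholded weak-label scores), LSTM
#' and gradient-boosted baseline training, and note-level evaluation on
#' the same fixed test cohort with post-recurrence notes excluded.
#'
#' @param config An [experiment_config()].
#' @param corpus Optional pre-generated [generate_corpus()] result; when
#'   `NULL` a corpus is generated from `config$synth` with the master seed.
#' @return An `experiment_result`: list with `report` (one row per
#'   strategy x model: AUROC, sensitivity, specificity and bootstrap
#'   standard errors), `positives` (training positive-note counts per
#'   strategy), `details` (per strategy/model test scores and labels),
#'   `test_ids` and `seeds`.
#' @export
run_experiment <- function(config, corpus = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- list(synth = config$seed, embed = config$seed + 101L,
                split = config$seed + 202L, lstm = config$seed + 303L,
                gbt = config$seed + 404L, boot = config$seed + 505L)
  if (is.null(corpus)) {
    sc <- config$synth
    sc$seed <- seeds$synth
    corpus <- generate_corpus(sc)
  }

  prep <- preprocess_corpus(
    corpus$notes, lexicon = corpus$lexicon, stopwords = corpus$stopwords,
    headings = corpus$headings, legal_phrases = corpus$legal_phrases,
    names_list = corpus$names_list, min_count = config$min_count
  )
  note_dt <- prep$notes

  space <- train_skipgram(
    note_dt$tokens, dim = config$embed_dim, window = config$embed_window,
    epochs = config$embed_epochs, seed = seeds$embed
  )

  outcomes <- data.table::as.data.table(corpus$outcomes)
  manual_ids <- outcomes$patient_id[outcomes$label_source == "manual"]
  weak_ids <- outcomes$patient_id[outcomes$label_source == "weak"]
  sp <- split_cohort(manual_ids, train_frac = config$train_frac,
                     seed = seeds$split)

  train_note_rows <- !(note_dt$patient_id %in% sp$test)
  idf <- compute_idf(build_vocabulary(note_dt$tokens[train_note_rows]))
  V <- vectorize_corpus(note_dt$tokens, space, idf)

  manual_oc <- outcomes[outcomes$label_source == "manual"]
  tl_manual <- build_timelines(note_dt[note_dt$patient_id %in% manual_ids],
                               V[note_dt$patient_id %in% manual_ids, ,
                                 drop = FALSE], manual_oc)
  names(tl_manual) <- vapply(tl_manual, `[[`, character(1), "patient_id")
  tl_train_manual <- tl_manual[as.character(sp$train)]
  tl_test <- lapply(tl_manual[as.character(sp$test)], filter_test_notes)
  tl_test <- tl_test[vapply(tl_test, function(t) length(t$date) > 0,
                            logical(1))]

  weak_note_dt <- note_dt[note_dt$patient_id %in% weak_ids]
  weak_V <- V[note_dt$patient_id %in% weak_ids, , drop = FALSE]
  weak_tl_for <- function(threshold) {
    if (nrow(weak_note_dt) == 0L) return(list())
    wl <- threshold_weak_labels(corpus$weak_scores, threshold)
    imp <- impute_recurrence_dates(weak_note_dt, wl)
    imp$label_source <- "weak"
    build_timelines(weak_note_dt, weak_V, imp)
  }

  # labelled test note pool (post-recurrence notes already excluded;
  # sequences truncated to max_len exactly as in training)
  test_batch <- build_sequence_batch(tl_test, max_len = config$max_len,
                                     horizon_days = config$horizon_days)
  tf <- list(
    labels = unlist(lapply(seq_along(tl_test), function(i)
      test_batch$y[seq_len(test_batch$n_real[i]), i])),
    pids = unlist(lapply(seq_along(tl_test), function(i)
      rep(test_batch$patient_ids[i], test_batch$n_real[i])))
  )

  report <- list(); details <- list(); positives <- c()
  for (strategy in config$strategies) {
    tl_weak <- switch(strategy,
      traditional = list(),
      weak1 = weak_tl_for(config$weak_threshold_hi),
      weak2 = weak_tl_for(config$weak_threshold_lo)
    )
    sup <- assemble_supervision(tl_train_manual, tl_weak, strategy,
                                test_ids = sp$test)
    batch <- build_sequence_batch(sup, max_len = config$max_len,
                                  horizon_days = config$horizon_days)
    cw <- inverse_class_weights(batch$y)
    batch$w <- matrix(ifelse(batch$y == 2L, 0, cw[batch$y + 1L]),
                      nrow = nrow(batch$y))
    positives[strategy] <- sum(batch$y == 1L)

    for (mdl in config$models) {
      if (mdl == "lstm") {
        cfg_l <- config$lstm
        cfg_l$input_dim <- config$embed_dim
        cfg_l$seed <- seeds$lstm
        model <- build_lstm(cfg_l)
        model <- train_lstm(model, batch)
        P <- predict_lstm(model, test_batch)
        sc <- unlist(lapply(seq_along(tl_test), function(i)
          P[2L, seq_len(test_batch$n_real[i]), i]))
      } else {
        # same note pool as the sequence model: first max_len notes each
        Xtr <- do.call(rbind, lapply(sup$timelines, function(t)
          utils::head(t$vectors, config$max_len)))
        ytr <- unlist(lapply(sup$timelines, function(t)
          utils::head(assign_labels(t, config$horizon_days),
                      config$max_len)))
        model <- train_gbt_baseline(Xtr, ytr, nrounds = config$gbt_nrounds,
                                    seed = seeds$gbt)
        Xte <- do.call(rbind, lapply(seq_along(tl_test), function(i)
          tl_test[[i]]$vectors[seq_len(test_batch$n_real[i]), ,
                               drop = FALSE]))
        sc <- predict_gbt(model, Xte)
      }
      ev <- evaluate_predictions(sc, tf$labels, tf$pids,
                                 n_boot = config$n_boot, seed = seeds$boot)
      report[[paste(strategy, mdl, sep = ".")]] <- data.table::data.table(
        strategy = strategy, model = mdl, auroc = ev$auroc,
        auroc_se = ev$auroc_se, sensitivity = ev$sensitivity,
        sens_se = ev$sens_se, specificity = ev$specificity,
        spec_se = ev$spec_se, threshold = ev$threshold,
        n_test_notes = ev$n_notes, n_test_patients = ev$n_patients
      )
      details[[paste(strategy, mdl, sep = ".")]] <-
        list(scores = sc, labels = tf$labels, pids = tf$pids,
             threshold = ev$threshold)
    }
  }

  structure(list(
    report = data.table::rbindlist(report),
    positives = positives, details = details,
    test_ids = sp$test, test_timelines = tl_test, seeds = seeds
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Three-strategy recurrence prediction experiment\n")
  print(x$report)
  invisible(x)
}

#' Patient-level k-fold cross-validation of the LSTM
#'
#' Splits training timelines into k patient-level folds, trains the LSTM
#' on k-1 folds and computes note-level AUROC on the held-out fold. Used
#' for hyperparameter checking; the final model is trained on the full
#' training set.
#'
#' @param timelines List of labelled `patient_timeline`s.
#' @param k Number of folds (default 5).
#' @param lstm An [lstm_config()].
#' @param max_len,horizon_days Sequence assembly options.
#' @param seed Integer seed for fold assignment.
#' @return Numeric vector of per-fold AUROCs (NA when a fold lacks both
#'   classes).
#' @export
cross_validate <- function(timelines, k = 5L, lstm = lstm_config(),
                           max_len = 800L, horizon_days = 365L, seed = 1L) {
  n <- length(timelines)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than patients")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  vapply(seq_len(k), function(f) {
    tr <- timelines[fold != f]
    te <- timelines[fold == f]
    batch <- build_sequence_batch(tr, max_len = max_len,
                                  horizon_days = horizon_days)
    cw <- tryCatch(inverse_class_weights(batch$y), error = function(e) NULL)
    if (is.null(cw)) return(NA_real_)
    batch$w <- matrix(ifelse(batch$y == 2L, 0, cw[batch$y + 1L]),
                      nrow = nrow(batch$y))
    model <- train_lstm(build_lstm(lstm), batch)
    teb <- build_sequence_batch(te, max_len = max_len,
                                horizon_days = horizon_days)
    P <- predict_lstm(model, teb)
    sc <- unlist(lapply(seq_along(te), function(i)
      P[2L, seq_len(teb$n_real[i]), i]))
    lab <- unlist(lapply(te, assign_labels, horizon_days = horizon_days))
    if (length(unique(lab)) < 2L) return(NA_real_)
    roc_auc(sc, lab)
  }, numeric(1))
}
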