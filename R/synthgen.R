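#' Configuration for the synthetic note-corpus generator
#'
#' The generator emulates the statistical shape of a longitudinal
#' breast-cancer note corpus: multi-year follow-up with visit streams of
#' tens-to-hundreds of notes per patient (defaults: mean 7.46 years of
#' follow-up and about 17 notes per year, i.e. roughly 126 notes per
#' patient), a minority recurrence class, Zipf-distributed background
#' vocabulary, and a noisy escalating recurrence signal: the expected
#' signal-token rate rises linearly over `signal_ramp_days` before the
#' recurrence date, but each note's realised rate is scaled by
#' heavy-tailed multiplicative (gamma) noise. A single note is therefore
#' an unreliable readout of disease state — healthy patients emit
#' occasional alarming notes and sick patients bland ones — while the
#' recent-history average is far sharper, so one-year-ahead prediction is
#' learnable and rewards temporal context. A small
#' fraction of tokens are lexicon-mappable surface variants, digit runs,
#' stopwords, section headings and proper names so the preprocessing stage
#' is genuinely exercised.
#'
#' @param n_patients Number of patients.
#' @param recurrence_fraction Fraction with a distant recurrence.
#' @param follow_up_mean,follow_up_sd Follow-up duration in years.
#' @param visits_per_year_mean,visits_per_year_sd Note (visit) rate; visit
#'   dates follow a renewal process with exponential inter-visit gaps.
#' @param note_length_mean,note_length_sd Tokens per note.
#' @param background_vocab,signal_vocab Vocabulary sizes.
#' @param zipf_s Zipf exponent of the background token distribution.
#' @param signal_ramp_days Window before recurrence over which the
#'   expected signal-token rate rises linearly from the background rate.
#' @param signal_strength Maximum increase in the expected signal-token
#'   mixing rate (reached at and after the recurrence date).
#' @param signal_background Baseline expected signal-token mixing rate in
#'   every note, so signal terms exist corpus-wide and healthy patients
#'   produce occasional false alarms.
#' @param signal_noise_shape Shape of the mean-one gamma noise that
#'   multiplies each note's expected signal rate; smaller values give
#'   heavier-tailed, less reliable single notes.
#' @param stopword_fraction,lexicon_fraction,digit_fraction Emission rates
#'   of stopwords, mappable surface variants and digit tokens.
#' @param manual_fraction Fraction of patients with manually curated
#'   (ground-truth) outcome labels; the rest are weak-label patients.
#' @param weak_sensitivity,weak_specificity Per-note operating
#'   characteristics of the simulated weak-label extractor at the 0.5
#'   score threshold.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 2000L, recurrence_fraction = 0.15,
                         follow_up_mean = 7.46, follow_up_sd = 5.48,
                         visits_per_year_mean = 17, visits_per_year_sd = 6,
                         note_length_mean = 60, note_length_sd = 20,
                         background_vocab = 5000L, signal_vocab = 200L,
                         zipf_s = 1.1, signal_ramp_days = 540L,
                         signal_strength = 0.5, signal_background = 0.05,
                         signal_noise_shape = 0.7,
                         stopword_fraction = 0.2, lexicon_fraction = 0.05,
                         digit_fraction = 0.02, manual_fraction = 0.1,
                         weak_sensitivity = 0.9, weak_specificity = 0.997,
                         seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(
    n_patients >= 1, recurrence_fraction >= 0, recurrence_fraction < 1,
    follow_up_mean > 0, visits_per_year_mean > 0, note_length_mean > 0,
    background_vocab > 0, signal_vocab > 0,
    signal_strength >= 0, signal_strength <= 1,
    signal_background >= 0, signal_ramp_days > 0,
    signal_noise_shape > 0,
    manual_fraction > 0, manual_fraction <= 1,
    weak_sensitivity > 0, weak_sensitivity <= 1,
    weak_specificity > 0, weak_specificity <= 1
  ))
  structure(cfg, class = "synth_config")
}

# truncated-normal draw by rejection-free clamping
rtnorm <- function(n, mean, sd, lower) pmax(rnorm(n, mean, sd), lower)

#' Generate a synthetic note corpus with ground truth
#'
#' Simulates patients, visit streams, raw note texts and outcomes under a
#' [synth_config()]. Returns everything the pipeline consumes: raw notes,
#' patient outcomes (with manual/weak source flags), per-note weak-label
#' scores from [corrupt_labels()], ground-truth note statuses, and the
#' word lists and lexicon used to compose the texts.
#'
#' @param config A `synth_config`.
#' @return A list with `notes` (raw note table), `outcomes`,
#'   `weak_scores` (named numeric), `truth` (per-note table with
#'   `days_to_recurrence` and the post-recurrence indicator), `lexicon`,
#'   `stopwords`, `headings`, `legal_phrases`, `names_list`, `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (cfg$visits_per_year_mean <= 0) stop("visit rate must be positive")

  stop_words <- c("the", "and", "of", "was", "with", "for", "is", "on",
                  "in", "no", "to", "at")
  headings <- c("impression", "findings", "history", "assessment")
  names_list <- c("smith", "jones", "garcia", "nguyen")
  legal_phrases <- c("electronically signed by", "not for redistribution")

  n_map <- 100L
  map_base <- sprintf("term%03d", seq_len(n_map))
  lexicon <- setNames(
    rep(toupper(map_base), each = 2L),
    paste0(rep(map_base, each = 2L), c("a", "b"))
  )
  bg_vocab <- sprintf("bkg%05d", seq_len(cfg$background_vocab))
  sig_vocab <- sprintf("sig%04d", seq_len(cfg$signal_vocab))
  zipf_p <- (1 / seq_len(cfg$background_vocab)^cfg$zipf_s)
  zipf_p <- zipf_p / sum(zipf_p)

  with_seed(cfg$seed, {
    n <- cfg$n_patients
    pid <- sprintf("P%05d", seq_len(n))
    fu_years <- rtnorm(n, cfg$follow_up_mean, cfg$follow_up_sd, 1)
    rate <- rtnorm(n, cfg$visits_per_year_mean, cfg$visits_per_year_sd, 0.5)
    origin <- as.Date("2008-01-01")

    n_rec <- round(n * cfg$recurrence_fraction)
    rec_flag <- logical(n)
    if (n_rec > 0) rec_flag[sample.int(n, n_rec)] <- TRUE

    # manual subset stratified by recurrence status so both the manual and
    # weak cohorts carry the configured recurrence mix
    resample <- function(x, size) x[sample.int(length(x), size)]
    n_manual <- max(2L, round(n * cfg$manual_fraction))
    manual_flag <- logical(n)
    if (n_manual >= n) {
      manual_flag[] <- TRUE
    } else {
      man_rec <- resample(which(rec_flag),
                          min(sum(rec_flag),
                              round(n_manual * cfg$recurrence_fraction)))
      man_non <- resample(which(!rec_flag),
                          min(sum(!rec_flag), n_manual - length(man_rec)))
      manual_flag[c(man_rec, man_non)] <- TRUE
    }

    notes_list <- vector("list", n)
    rec_date <- rep(as.Date(NA), n)
    for (i in seq_len(n)) {
      fu_days <- fu_years[i] * 365.25
      gaps <- stats::rexp(ceiling(rate[i] * fu_years[i] * 3) + 10,
                          rate = rate[i] / 365.25)
      days <- cumsum(gaps)
      days <- days[days <= fu_days]
      if (length(days) == 0L) days <- stats::runif(1, 1, fu_days)
      dates <- origin + round(days)
      m <- length(dates)
      if (rec_flag[i]) {
        u <- stats::runif(1, 0.35, 0.9)
        rd <- min(dates) + round(u * as.numeric(max(dates) - min(dates)))
        rec_date[i] <- max(rd, min(dates)) # recurrence never precedes notes
      }
      lens <- pmax(5L, round(rnorm(m, cfg$note_length_mean,
                                   cfg$note_length_sd)))
      texts <- character(m)
      for (j in seq_len(m)) {
        L <- lens[j]
        ramp <- if (rec_flag[i]) {
          dd <- as.numeric(rec_date[i] - dates[j])
          if (dd <= 0) 1 else max(0, 1 - dd / cfg$signal_ramp_days)
        } else 0
        noise <- stats::rgamma(1, shape = cfg$signal_noise_shape,
                               rate = cfg$signal_noise_shape)
        p_sig <- min(0.9, (cfg$signal_background +
                             cfg$signal_strength * ramp) * noise)
        kind <- sample(c("sig", "stop", "map", "digit", "name", "bkg"), L,
                       replace = TRUE,
                       prob = c(p_sig, cfg$stopword_fraction,
                                cfg$lexicon_fraction, cfg$digit_fraction,
                                0.005,
                                max(1e-9, 1 - p_sig - cfg$stopword_fraction -
                                      cfg$lexicon_fraction -
                                      cfg$digit_fraction - 0.005)))
        tok <- character(L)
        nb <- sum(kind == "bkg")
        if (nb) tok[kind == "bkg"] <- sample(bg_vocab, nb, TRUE, zipf_p)
        ns <- sum(kind == "sig")
        if (ns) tok[kind == "sig"] <- sample(sig_vocab, ns, TRUE)
        nw <- sum(kind == "stop")
        if (nw) tok[kind == "stop"] <- sample(stop_words, nw, TRUE)
        nm <- sum(kind == "map")
        if (nm) tok[kind == "map"] <- sample(names(lexicon), nm, TRUE)
        nd <- sum(kind == "digit")
        if (nd) tok[kind == "digit"] <- as.character(sample.int(3000, nd, TRUE))
        nn <- sum(kind == "name")
        if (nn) {
          nmup <- sample(names_list, nn, TRUE)
          tok[kind == "name"] <- paste0(toupper(substr(nmup, 1, 1)),
                                        substr(nmup, 2, nchar(nmup)))
        }
        body <- paste(tok, collapse = " ")
        texts[j] <- paste0(
          sample(headings, 1), ": ", body, ". ",
          sample(legal_phrases, 1), "."
        )
      }
      notes_list[[i]] <- data.table::data.table(
        patient_id = pid[i],
        note_id = sprintf("%s_N%04d", pid[i], seq_len(m)),
        timestamp = dates, text = texts
      )
    }
    notes <- data.table::rbindlist(notes_list)

    outcomes <- data.table::data.table(
      patient_id = pid,
      recurrence_date = rec_date,
      label_source = ifelse(manual_flag, "manual", "weak")
    )

    truth <- notes[, .(patient_id, note_id, timestamp)]
    truth[, recurrence_date := rec_date[match(patient_id, pid)]]
    truth[, days_to_recurrence := as.integer(recurrence_date - timestamp)]
    truth[, post_recurrence := as.integer(!is.na(recurrence_date) &
                                            timestamp >= recurrence_date)]
    truth[, label_1y := as.integer(!is.na(recurrence_date) &
                                     recurrence_date <= timestamp + 365L)]

    weak_scores <- corrupt_labels(
      setNames(truth$post_recurrence, truth$note_id),
      sensitivity = cfg$weak_sensitivity,
      specificity = cfg$weak_specificity,
      seed = cfg$seed + 1L
    )

    list(notes = as_note_table(notes), outcomes = outcomes,
         weak_scores = weak_scores, truth = truth[],
         lexicon = lexicon, stopwords = stop_words, headings = headings,
         legal_phrases = legal_phrases, names_list = names_list,
         config = cfg)
  })
}

#' Corrupt true binary note labels into weak probabilistic scores
#'
#' Emulates an imperfect NLP extractor: a truly positive note receives a
#' score in (0.5, 1] with probability `sensitivity` (else in [0, 0.5)),
#' and a truly negative note a score in [0, 0.5) with probability
#' `specificity` (else in (0.5, 1]). Thresholding the scores at 0.5 then
#' reproduces the configured sensitivity/specificity in expectation, while
#' other thresholds trade the two off, so a single score table supports
#' both the high-specificity and high-sensitivity weak-label presets.
#'
#' @param true_labels Named integer 0/1 vector (names = note ids).
#' @param sensitivity,specificity Target rates in (0, 1].
#' @param seed Integer seed.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
corrupt_labels <- function(true_labels, sensitivity, specificity, seed = 1L) {
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1,
            all(true_labels %in% c(0L, 1L)))
  n <- length(true_labels)
  with_seed(seed, {
    correct <- runif(n) < ifelse(true_labels == 1L, sensitivity, specificity)
    hi <- (true_labels == 1L) == correct # score lands above 0.5
    u <- runif(n)
    score <- ifelse(hi, 0.5 + 0.5 * pmax(u, 1e-12), 0.5 * u * 0.9999)
    setNames(score, names(true_labels))
  })
}

#' Write a synthetic dataset to disk in the standard input formats
#'
#' Emits the same file formats the real-data readers consume (JSONL notes,
#' CSV outcomes and weak scores, TSV lexicon, plain-text word lists) so
#' synthetic and real inputs are interchangeable.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_notes_jsonl(corpus$notes, file.path(dir, "notes.jsonl"))
  write_outcomes_csv(corpus$outcomes, file.path(dir, "outcomes.csv"))
  write_scores_csv(corpus$weak_scores, file.path(dir, "weak_scores.csv"))
  write_lexicon_tsv(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  write_wordlist(corpus$stopwords, file.path(dir, "stopwords.txt"))
  write_wordlist(corpus$headings, file.path(dir, "headings.txt"))
  write_wordlist(corpus$legal_phrases, file.path(dir, "legal_phrases.txt"))
  write_wordlist(corpus$names_list, file.path(dir, "names.txt"))
  invisible(dir)
}
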