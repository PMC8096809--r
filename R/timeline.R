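#' Construct a patient timeline of note vectors
#'
#' Bundles a patient's chronologically ordered note vectors with their
#' outcome. Notes are stably sorted by (timestamp, note_id) so same-day
#' ordering is deterministic.
#'
#' @param patient_id Patient identifier.
#' @param note_id Character vector of note ids.
#' @param date Vector of note dates (coercible to `Date`).
#' @param vectors Numeric matrix, one row per note.
#' @param recurrence_date A `Date` or `NA` for no recurrence.
#' @param label_source `"manual"` or `"weak"`.
#' @return A `patient_timeline` object.
#' @export
patient_timeline <- function(patient_id, note_id, date, vectors,
                             recurrence_date = as.Date(NA),
                             label_source = "manual") {
  date <- as.Date(date)
  vectors <- as.matrix(vectors)
  stopifnot(length(note_id) == length(date), nrow(vectors) == length(date),
            label_source %in% c("manual", "weak"))
  ord <- order(date, note_id, method = "radix")
  recurrence_date <- as.Date(recurrence_date)
  if (!is.na(recurrence_date) && length(date) > 0 &&
      recurrence_date < min(date))
    stop("recurrence_date precedes the first note date")
  structure(
    list(patient_id = patient_id, note_id = as.character(note_id)[ord],
         date = date[ord], vectors = vectors[ord, , drop = FALSE],
         recurrence_date = recurrence_date, label_source = label_source),
    class = "patient_timeline"
  )
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat("Patient", x$patient_id, "-", length(x$date), "notes",
      if (!is.na(x$recurrence_date))
        paste("(recurrence", format(x$recurrence_date), ")")
      else "(no recurrence)", "\n")
  invisible(x)
}

#' One-year-ahead recurrence labels for a timeline
#'
#' Labels each note with the patient's recurrence status one horizon ahead
#' of the note date: label 1 iff a recurrence date exists and falls on or
#' before `note date + horizon_days` (inclusive boundary; notes on or after
#' the recurrence date are therefore also 1), else 0. Padding labels are
#' added later by [truncate_pad()].
#'
#' @param timeline A `patient_timeline`.
#' @param horizon_days Prediction horizon in days (default 365).
#' @return Integer vector of 0/1 labels, one per note.
#' @export
assign_labels <- function(timeline, horizon_days = 365L) {
  stopifnot(inherits(timeline, "patient_timeline"))
  if (is.unsorted(timeline$date)) stop("timeline notes are not sorted")
  if (is.na(timeline$recurrence_date))
    return(integer(length(timeline$date)))
  as.integer(timeline$recurrence_date <= timeline$date + horizon_days)
}

#' Truncate or right-pad a labelled sequence to fixed length
#'
#' Sequences longer than `max_len` keep their first `max_len` notes;
#' shorter ones are right-padded with zero vectors, the pad class label 2,
#' and sample weight 0. Real positions receive the class weight of their
#' label.
#'
#' @param vectors Numeric matrix of note vectors (rows = notes).
#' @param labels Integer 0/1 labels aligned to the rows.
#' @param max_len Fixed output length (default 800).
#' @param class_weights Length-2 numeric: weights for classes 0 and 1 at
#'   real positions (default unit weights).
#' @return List with `X` (`max_len` x dim matrix), `y` (length `max_len`,
#'   classes 0/1/2), `w` (sample weights) and `n_real`.
#' @export
truncate_pad <- function(vectors, labels, max_len = 800L,
                         class_weights = c(1, 1)) {
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) == length(labels), all(labels %in% c(0L, 1L)),
            length(class_weights) == 2L)
  if (max_len < 1L) stop("max_len must be at least 1")
  n <- min(nrow(vectors), max_len)
  X <- matrix(0, nrow = max_len, ncol = ncol(vectors))
  y <- rep(2L, max_len)
  w <- numeric(max_len)
  if (n > 0L) {
    X[seq_len(n), ] <- vectors[seq_len(n), , drop = FALSE]
    y[seq_len(n)] <- labels[seq_len(n)]
    w[seq_len(n)] <- class_weights[labels[seq_len(n)] + 1L]
  }
  list(X = X, y = y, w = w, n_real = n)
}

#' Threshold probabilistic weak-label scores
#'
#' Converts per-note scores from the upstream NLP recurrence extractor to
#' binary note labels: 1 iff `score >= threshold`. The high-specificity
#' preset uses the higher threshold (few, confident positives) and the
#' high-sensitivity preset the lower one (more positives).
#'
#' @param scores Named numeric vector of scores in `[0, 1]`.
#' @param threshold A value in `[0, 1]`.
#' @return Named integer vector of 0/1 labels.
#' @export
threshold_weak_labels <- function(scores, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("weak-label scores must lie in [0, 1]")
  setNames(as.integer(scores >= threshold), names(scores))
}

#' Impute recurrence dates from weak note labels
#'
#' For weakly labelled patients, the patient's imputed recurrence date is
#' the date of their first weak-positive note (no positive note means no
#' recurrence). One-year-ahead labels are then derived exactly as for
#' manually curated patients.
#'
#' @param note_table data.table with `patient_id`, `note_id`, `timestamp`.
#' @param weak_labels Named integer 0/1 vector (names = note ids).
#' @return data.table with `patient_id` and imputed `recurrence_date`
#'   (`NA` when never positive).
#' @export
impute_recurrence_dates <- function(note_table, weak_labels) {
  dt <- data.table::as.data.table(note_table)
  dt[, weak := weak_labels[as.character(note_id)]]
  dt[is.na(weak), weak := 0L]
  dt[, .(recurrence_date = if (any(weak == 1L))
    min(timestamp[weak == 1L]) else as.Date(NA)), by = patient_id]
}

#' Patient-level train/test split
#'
#' Deterministically splits patient ids into a training and a test set at
#' the patient (not note) level.
#'
#' @param patient_ids Character/atomic vector of patient ids.
#' @param train_frac Fraction of patients assigned to training
#'   (default 0.75; the training size is `floor(n * train_frac)`).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_cohort <- function(patient_ids, train_frac = 0.75, seed = 1L) {
  ids <- sort(unique(patient_ids))
  if (length(ids) < 2L) stop("need at least 2 patients to split")
  n_train <- floor(length(ids) * train_frac)
  perm <- with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[-seq_len(n_train)]))
}

#' Assemble a supervision strategy training set
#'
#' Builds the training cohort for one of the three supervision strategies:
#' `traditional` uses only manually curated timelines; `weak1` and `weak2`
#' add the weakly labelled timelines (the caller supplies timelines whose
#' recurrence dates were imputed under the strategy's weak-label
#' threshold). Test-cohort patients must never appear.
#'
#' @param manual_timelines List of manual-source `patient_timeline`s.
#' @param weak_timelines List of weak-source `patient_timeline`s.
#' @param strategy One of `"traditional"`, `"weak1"`, `"weak2"`.
#' @param test_ids Patient ids held out for testing; overlap is an error.
#' @return A `supervision_set`: list with `strategy` and `timelines`.
#' @export
assemble_supervision <- function(manual_timelines, weak_timelines = list(),
                                 strategy = c("traditional", "weak1", "weak2"),
                                 test_ids = character()) {
  strategy <- match.arg(strategy)
  man_ids <- vapply(manual_timelines, `[[`, character(1), "patient_id")
  weak_ids <- vapply(weak_timelines, function(t) as.character(t$patient_id),
                     character(1))
  if (length(intersect(man_ids, weak_ids)))
    stop("manual and weak patient id sets overlap")
  if (length(intersect(c(man_ids, weak_ids), as.character(test_ids))))
    stop("training timelines overlap the test cohort")
  tl <- if (strategy == "traditional") manual_timelines
        else c(manual_timelines, weak_timelines)
  structure(list(strategy = strategy, timelines = tl),
            class = "supervision_set")
}

#' @export
print.supervision_set <- function(x, ...) {
  cat("Supervision set [", x$strategy, "]: ", length(x$timelines),
      " patient timelines\n", sep = "")
  invisible(x)
}

#' Build a fixed-shape sequence batch from timelines
#'
#' Applies [assign_labels()] and [truncate_pad()] to every timeline and
#' stacks the results into dense arrays suitable for the LSTM trainer.
#'
#' @param timelines List of `patient_timeline`s (or a `supervision_set`).
#' @param max_len Fixed sequence length.
#' @param horizon_days Label horizon in days.
#' @param class_weights Length-2 weights for real classes 0/1.
#' @return A `sequence_batch`: list with `X` (dim x max_len x n array),
#'   `y` (max_len x n integer matrix), `w` (max_len x n weights),
#'   `n_real`, `patient_ids`.
#' @export
build_sequence_batch <- function(timelines, max_len = 800L,
                                 horizon_days = 365L,
                                 class_weights = c(1, 1)) {
  if (inherits(timelines, "supervision_set")) timelines <- timelines$timelines
  n <- length(timelines)
  stopifnot(n > 0L)
  d <- ncol(timelines[[1]]$vectors)
  X <- array(0, dim = c(d, max_len, n))
  y <- matrix(2L, nrow = max_len, ncol = n)
  w <- matrix(0, nrow = max_len, ncol = n)
  n_real <- integer(n)
  for (i in seq_len(n)) {
    tl <- timelines[[i]]
    lab <- assign_labels(tl, horizon_days)
    tp <- truncate_pad(tl$vectors, lab, max_len, class_weights)
    X[, , i] <- t(tp$X)
    y[, i] <- tp$y
    w[, i] <- tp$w
    n_real[i] <- tp$n_real
  }
  structure(
    list(X = X, y = y, w = w, n_real = n_real,
         patient_ids = vapply(timelines, function(t) as.character(t$patient_id),
                              character(1))),
    class = "sequence_batch"
  )
}
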