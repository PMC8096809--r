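#' Exclude post-recurrence notes from a test timeline
#'
#' Removes every note dated strictly after the recurrence date so that test
#' metrics measure prediction rather than detection; notes dated exactly on
#' the recurrence date are kept, and non-recurrent patients are untouched.
#'
#' @param timeline A `patient_timeline`.
#' @return The filtered `patient_timeline`.
#' @export
filter_test_notes <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  if (is.na(timeline$recurrence_date)) return(timeline)
  keep <- timeline$date <= timeline$recurrence_date
  timeline$note_id <- timeline$note_id[keep]
  timeline$date <- timeline$date[keep]
  timeline$vectors <- timeline$vectors[keep, , drop = FALSE]
  timeline
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the probability
#' that a random positive scores above a random negative, with ties
#' counted 1/2. Equivalent to the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric prediction scores.
#' @param labels Integer/logical 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks handle ties at 1/2
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Optimal ROC operating point (Youden's J)
#'
#' Scans thresholds at the midpoints between consecutive distinct scores
#' (plus the two infinite extremes) and returns the threshold maximising
#' sensitivity + specificity - 1, with a prediction rule of
#' "positive iff score >= threshold". Ties are broken toward higher
#' specificity, then toward the higher threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Integer/logical 0/1 labels; both classes must be present.
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
optimal_operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1L) / np
    spec <- sum(!pred & labels == 0L) / nn
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && th > best$threshold)))) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec,
                   j = j)
    }
  }
  best
}

#' Patient-level bootstrap uncertainty for note-level metrics
#'
#' Resamples patients (not notes) with replacement to respect
#' within-patient correlation, recomputes AUROC and, at a fixed threshold,
#' sensitivity and specificity on each resample, and reports the standard
#' deviation across resamples as the plus/minus value. Resamples with a
#' single class are dropped.
#'
#' @param scores,labels Note-level scores and 0/1 labels.
#' @param patient_ids Patient id of each note.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param threshold Operating threshold for sensitivity/specificity; if
#'   `NULL`, the full-sample optimal operating point is used.
#' @return List with `auroc_se`, `sens_se`, `spec_se`, `threshold`,
#'   `n_boot_used`.
#' @export
bootstrap_metrics <- function(scores, labels, patient_ids, n_boot = 1000L,
                              seed = 1L, threshold = NULL) {
  labels <- as.integer(labels)
  stopifnot(n_boot >= 2L,
            length(scores) == length(labels),
            length(scores) == length(patient_ids))
  if (is.null(threshold))
    threshold <- optimal_operating_point(scores, labels)$threshold
  ids <- unique(patient_ids)
  by_pat <- split(seq_along(scores), patient_ids)
  stats_mat <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = 3L)
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(by_pat[as.character(take)], use.names = FALSE)
      lb <- labels[idx]
      if (length(unique(lb)) < 2L) next
      sc <- scores[idx]
      pred <- sc >= threshold
      out[b, 1] <- roc_auc(sc, lb)
      out[b, 2] <- sum(pred & lb == 1L) / sum(lb == 1L)
      out[b, 3] <- sum(!pred & lb == 0L) / sum(lb == 0L)
    }
    out
  })
  ok <- stats::complete.cases(stats_mat)
  list(
    auroc_se = stats::sd(stats_mat[ok, 1]),
    sens_se = stats::sd(stats_mat[ok, 2]),
    spec_se = stats::sd(stats_mat[ok, 3]),
    threshold = threshold, n_boot_used = sum(ok)
  )
}

#' Full note-level evaluation report
#'
#' Combines [roc_auc()], [optimal_operating_point()] and
#' [bootstrap_metrics()] into one report.
#'
#' @inheritParams bootstrap_metrics
#' @return An `eval_report` list: `auroc`, `threshold`, `sensitivity`,
#'   `specificity`, their `*_se` bootstrap values, `n_notes`, `n_patients`.
#' @export
evaluate_predictions <- function(scores, labels, patient_ids,
                                 n_boot = 1000L, seed = 1L) {
  auroc <- roc_auc(scores, labels)
  op <- optimal_operating_point(scores, labels)
  bs <- bootstrap_metrics(scores, labels, patient_ids, n_boot, seed,
                          threshold = op$threshold)
  structure(list(
    auroc = auroc, threshold = op$threshold,
    sensitivity = op$sensitivity, specificity = op$specificity,
    auroc_se = bs$auroc_se, sens_se = bs$sens_se, spec_se = bs$spec_se,
    n_notes = length(scores), n_patients = length(unique(patient_ids))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f +/- %.3f | sens %.2f +/- %.2f | spec %.2f +/- %.2f (threshold %.3f; %d notes, %d patients)\n",
    x$auroc, x$auroc_se, x$sensitivity, x$sens_se, x$specificity, x$spec_se,
    x$threshold, x$n_notes, x$n_patients
  ))
  invisible(x)
}

#' Prediction intervals: how far in advance recurrence is flagged
#'
#' For each recurrence-positive test patient, finds the earliest note whose
#' predicted recurrence probability exceeds the operating threshold and
#' reports the number of days between that note and the confirmed
#' recurrence date (`NA` when the threshold is never exceeded). Counts are
#' binned in 100-day bins starting at 0.
#'
#' @param timelines List of (post-recurrence-filtered) test
#'   `patient_timeline`s.
#' @param probabilities List of per-note probability vectors aligned to the
#'   timelines' notes.
#' @param threshold Operating threshold (exceedance is strict).
#' @return List with `intervals` (data.table: patient_id, days_in_advance)
#'   and `histogram` (named counts per 100-day bin).
#' @export
prediction_intervals <- function(timelines, probabilities, threshold) {
  stopifnot(length(timelines) == length(probabilities))
  rows <- list()
  for (i in seq_along(timelines)) {
    tl <- timelines[[i]]
    if (is.na(tl$recurrence_date)) next
    p <- probabilities[[i]]
    stopifnot(length(p) == length(tl$date))
    hit <- which(p > threshold)
    days <- if (length(hit)) as.integer(tl$recurrence_date - tl$date[hit[1]])
            else NA_integer_
    rows[[length(rows) + 1L]] <- data.table::data.table(
      patient_id = as.character(tl$patient_id), days_in_advance = days
    )
  }
  intervals <- if (length(rows)) data.table::rbindlist(rows)
               else data.table::data.table(patient_id = character(),
                                           days_in_advance = integer())
  d <- intervals$days_in_advance
  d <- d[!is.na(d)]
  histogram <- if (length(d)) {
    breaks <- seq(0, (max(d) %/% 100 + 1) * 100, by = 100)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
    setNames(h$counts, paste0("[", head(breaks, -1), ",", breaks[-1], ")"))
  } else setNames(integer(0), character(0))
  list(intervals = intervals, histogram = histogram)
}

#' Two-dimensional embedding diagnostics
#'
#' Projects word or note vectors to 2-D with t-distributed stochastic
#' neighbour embedding for visual inspection of cluster structure
#' (similar terms, or recurrence vs non-recurrence notes at a chosen label
#' horizon). Optionally writes a scatter plot to file.
#'
#' @param X Numeric matrix (rows = points).
#' @param labels Optional vector colouring the points.
#' @param seed Integer seed (coordinates are reproducible given the seed).
#' @param perplexity t-SNE perplexity.
#' @param n_iter Gradient-descent iterations.
#' @param file Optional PNG path for the plot artifact.
#' @return A n x 2 matrix of coordinates (invisibly when plotting).
#' @export
embedding_diagnostics <- function(X, labels = NULL, seed = 1L,
                                  perplexity = 15, n_iter = 400,
                                  file = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  Y <- tsne_project(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    col <- if (is.null(labels)) "grey30"
           else as.integer(factor(labels)) + 1L
    graphics::plot(Y, col = col, pch = 19, cex = 0.7,
                   xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "Embedding projection")
  }
  Y
}
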