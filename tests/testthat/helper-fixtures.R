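# Small in-code fixtures shared across test files.

# A tiny embedding space with known vectors.
toy_space <- function(vecs) {
  structure(list(dim = ncol(vecs), vectors = vecs),
            class = "embedding_space")
}

toy_idf <- function(idf, n_notes = 10L) {
  structure(list(idf = idf, n_notes = n_notes), class = "idf_table")
}

# A timeline with evenly spaced notes and random vectors.
toy_timeline <- function(n_notes, dim = 4L, start = as.Date("2010-01-01"),
                         gap_days = 30L, recurrence_date = as.Date(NA),
                         patient_id = "P1", label_source = "manual",
                         seed = 1L) {
  dates <- start + gap_days * (seq_len(n_notes) - 1L)
  V <- with_seed(seed, matrix(rnorm(n_notes * dim), n_notes, dim))
  patient_timeline(
    patient_id = patient_id,
    note_id = sprintf("%s_N%03d", patient_id, seq_len(n_notes)),
    date = dates, vectors = V, recurrence_date = recurrence_date,
    label_source = label_source
  )
}

with_seed <- oncorecur:::with_seed

# Brute-force AUROC over all positive-negative pairs (ties at 1/2);
# independent of the rank-based implementation.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force operating point: enumerate candidate thresholds (midpoints
# plus infinities), maximise Youden's J, break ties toward higher
# specificity then higher threshold.
brute_operating_point <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  rows <- lapply(cand, function(th) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    c(th = th, sens = sens, spec = spec, j = sens + spec - 1)
  })
  m <- do.call(rbind, rows)
  m <- m[order(-m[, "j"], -m[, "spec"], -m[, "th"]), , drop = FALSE]
  list(threshold = m[1, "th"], sensitivity = m[1, "sens"],
       specificity = m[1, "spec"], j = m[1, "j"])
}

# Brute-force per-occurrence note vector: sum idf(w) * V_w over every
# token occurrence, divided by the number of in-vocabulary occurrences.
brute_note_vector <- function(tokens, space, idf) {
  keep <- tokens[tokens %in% rownames(space$vectors) &
                   tokens %in% names(idf$idf)]
  if (length(keep) == 0) return(numeric(space$dim))
  acc <- numeric(space$dim)
  for (w in keep) acc <- acc + idf$idf[[w]] * space$vectors[w, ]
  acc / length(keep)
}
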