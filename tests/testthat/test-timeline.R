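test_that("assign_labels marks notes within one horizon of recurrence", {
  tl <- toy_timeline(3)
  expect_identical(assign_labels(tl), c(0L, 0L, 0L))

  mk <- function(note_date, rec) patient_timeline(
    "P1", "N1", as.Date(note_date), matrix(0, 1, 2),
    recurrence_date = as.Date(rec)
  )
  expect_identical(assign_labels(mk("2010-01-01", "2010-06-01")), 1L) # 151 d
  expect_identical(assign_labels(mk("2010-01-01", "2011-06-01")), 0L) # 516 d
  expect_identical(assign_labels(mk("2011-06-01", "2011-06-01")), 1L)
  # exactly 365 days out is positive (inclusive boundary)
  expect_identical(assign_labels(mk("2010-01-01", "2011-01-01")), 1L)
  expect_identical(assign_labels(mk("2010-01-01", "2011-01-02")), 0L)
})

test_that("notes after recurrence keep label 1 and dates sort stably", {
  tl <- patient_timeline(
    "P1", c("b", "a", "c"),
    as.Date(c("2011-02-01", "2011-02-01", "2010-01-01")),
    matrix(1:6, 3, 2), recurrence_date = as.Date("2010-06-01")
  )
  expect_identical(tl$note_id, c("c", "a", "b")) # date then note_id
  expect_identical(assign_labels(tl), c(1L, 1L, 1L))
  expect_error(patient_timeline("P", "N", as.Date("2012-01-01"),
                                matrix(0, 1, 2),
                                recurrence_date = as.Date("2010-01-01")),
               "precedes")
})

test_that("horizon monotonicity holds on randomised timelines", {
  with_seed(21, {
    for (i in 1:300) {
      n <- sample(1:12, 1)
      dates <- as.Date("2010-01-01") + sort(sample(0:2000, n))
      rec <- if (runif(1) < 0.7) dates[1] + sample(0:2500, 1) else as.Date(NA)
      tl <- patient_timeline("P", sprintf("N%02d", 1:n), dates,
                             matrix(0, n, 2), recurrence_date = rec)
      l1 <- assign_labels(tl, horizon_days = 365L)
      l2 <- assign_labels(tl, horizon_days = 730L)
      expect_true(all(l2 >= l1)) # widening the horizon never clears a 1
      if (is.na(rec)) expect_true(all(l1 == 0L))
    }
  })
})

test_that("truncate_pad pads with zero vectors, class 2 and weight 0", {
  V <- matrix(1:6, 3, 2)
  tp <- truncate_pad(V, c(0L, 1L, 0L), max_len = 5L)
  expect_identical(dim(tp$X), c(5L, 2L))
  expect_equal(tp$X[4:5, ], matrix(0, 2, 2))
  expect_identical(tp$y, c(0L, 1L, 0L, 2L, 2L))
  expect_equal(tp$w, c(1, 1, 1, 0, 0))
  expect_identical(tp$n_real, 3L)
  expect_error(truncate_pad(V, c(0L, 1L, 0L), max_len = 0L), "max_len")
})

test_that("long sequences keep their first max_len notes", {
  V <- matrix(seq_len(12 * 2), 12, 2)
  tp <- truncate_pad(V, rep(0L, 12), max_len = 10L)
  expect_equal(tp$X, V[1:10, ])
  expect_identical(tp$n_real, 10L)
  # exact length passes through unchanged
  tp2 <- truncate_pad(V, rep(0L, 12), max_len = 12L)
  expect_equal(tp2$X, V)
  expect_identical(sum(tp2$y == 2L), 0L)
})

test_that("truncate_pad round-trips and conserves weight mass", {
  with_seed(13, {
    for (i in 1:50) {
      n <- sample(1:15, 1)
      V <- matrix(rnorm(n * 3), n, 3)
      lab <- sample(0:1, n, replace = TRUE)
      tp <- truncate_pad(V, lab, max_len = 12L)
      k <- min(n, 12L)
      expect_equal(tp$X[seq_len(k), , drop = FALSE],
                   V[seq_len(k), , drop = FALSE])
      expect_identical(tp$y[seq_len(k)], lab[seq_len(k)])
      # unit class weights: total weight equals number of real positions
      expect_equal(sum(tp$w), k)
      expect_true(all(tp$y[tp$w == 0] == 2L | seq_len(12L)[tp$w == 0] > n))
    }
  })
})

test_that("weak-label thresholding is monotone and validates inputs", {
  sc <- c(a = 0.3, b = 0.7)
  expect_identical(threshold_weak_labels(sc, 0), c(a = 1L, b = 1L))
  expect_identical(threshold_weak_labels(sc, 1), c(a = 0L, b = 0L))
  expect_identical(threshold_weak_labels(sc, 0.5), c(a = 0L, b = 1L))
  expect_error(threshold_weak_labels(c(a = 1.2), 0.5), "\\[0, 1\\]")
  with_seed(2, {
    s <- setNames(runif(200), paste0("n", 1:200))
    thr <- sort(runif(5))
    pos <- vapply(thr, function(t) sum(threshold_weak_labels(s, t)),
                  integer(1))
    expect_true(all(diff(pos) <= 0)) # lower threshold, never fewer positives
  })
})

test_that("imputed recurrence dates use the first weak-positive note", {
  notes <- data.table::data.table(
    patient_id = c("A", "A", "A", "B"),
    note_id = c("n1", "n2", "n3", "n4"),
    timestamp = as.Date(c("2010-01-01", "2010-06-01", "2010-09-01",
                          "2011-01-01"))
  )
  wl <- c(n1 = 0L, n2 = 1L, n3 = 1L, n4 = 0L)
  imp <- impute_recurrence_dates(notes, wl)
  expect_identical(imp$recurrence_date[imp$patient_id == "A"],
                   as.Date("2010-06-01"))
  expect_true(is.na(imp$recurrence_date[imp$patient_id == "B"]))
})

test_that("split_cohort is patient-level, deterministic and sized correctly", {
  ids <- sprintf("P%03d", 1:894)
  sp <- split_cohort(ids, 0.75, seed = 4)
  expect_length(sp$train, 670L)
  expect_length(sp$test, 224L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(split_cohort(ids, 0.75, seed = 4), sp)
  sp4 <- split_cohort(sprintf("Q%d", 1:4), 0.75, seed = 1)
  expect_length(sp4$train, 3L)
  expect_length(sp4$test, 1L)
})

test_that("assemble_supervision builds the right cohorts and guards leakage", {
  man <- lapply(1:10, function(i) toy_timeline(3, patient_id = paste0("M", i)))
  weak <- lapply(1:90, function(i)
    toy_timeline(2, patient_id = paste0("W", i), label_source = "weak"))
  expect_length(assemble_supervision(man, weak, "traditional")$timelines, 10L)
  expect_length(assemble_supervision(man, weak, "weak2")$timelines, 100L)
  expect_error(assemble_supervision(man, weak, "weak1", test_ids = "M3"),
               "test")
  expect_error(assemble_supervision(man, man, "weak1"), "overlap")
})

test_that("weak2 never has fewer positive note labels than weak1", {
  with_seed(31, {
    for (i in 1:20) {
      s <- setNames(runif(300), paste0("n", 1:300))
      lo <- threshold_weak_labels(s, 0.4)
      hi <- threshold_weak_labels(s, 0.8)
      expect_gte(sum(lo), sum(hi))
    }
  })
})

test_that("sequence batches stack timelines with aligned labels", {
  tls <- list(
    toy_timeline(3, dim = 4, recurrence_date = as.Date("2010-04-01")),
    toy_timeline(6, dim = 4, patient_id = "P2")
  )
  b <- build_sequence_batch(tls, max_len = 5L)
  expect_identical(dim(b$X), c(4L, 5L, 2L))
  expect_identical(b$n_real, c(3L, 5L))
  expect_identical(b$y[, 2], rep(0L, 5))
  expect_identical(b$y[4:5, 1], c(2L, 2L))
  expect_identical(b$patient_ids, c("P1", "P2"))
})
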