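test_that("roc_auc matches hand-counted concordance", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc equals brute-force pairwise concordance with ties", {
  with_seed(41, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
      lab <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      expect_identical(roc_auc(sc, lab), brute_auc(sc, lab))
    }
  })
})

test_that("roc_auc is reversal-symmetric and monotone-invariant", {
  with_seed(42, {
    for (i in 1:25) {
      sc <- runif(20)
      lab <- c(0L, 1L, sample(0:1, 18, replace = TRUE))
      expect_equal(roc_auc(sc, lab) + roc_auc(-sc, lab), 1, tolerance = 1e-12)
      expect_equal(roc_auc(exp(3 * sc), lab), roc_auc(sc, lab),
                   tolerance = 1e-12)
    }
  })
})

test_that("optimal operating point maximises Youden's J with stated tie-breaks", {
  op <- optimal_operating_point(c(1, 2, 3, 10), c(0, 0, 1, 1))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$j, 1)
  # degenerate two-point case
  op2 <- optimal_operating_point(c(0.2, 0.9), c(0, 1))
  expect_equal(op2$j, 1)
  # brute-force agreement on random tied data
  with_seed(43, {
    for (i in 1:60) {
      n <- sample(4:25, 1)
      sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      lab <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      got <- optimal_operating_point(sc, lab)
      want <- brute_operating_point(sc, lab)
      expect_equal(got$j, unname(want$j), tolerance = 1e-12)
      expect_equal(got$sensitivity, unname(want$sensitivity))
      expect_equal(got$specificity, unname(want$specificity))
      expect_true(got$j <= 1 + 1e-12)
    }
  })
})

test_that("roc_auc agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  with_seed(44, {
    for (i in 1:10) {
      sc <- runif(40)
      lab <- c(0L, 1L, sample(0:1, 38, replace = TRUE))
      ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
    }
  })
})

test_that("post-recurrence notes are excluded strictly after the date", {
  tl <- patient_timeline(
    "P1", c("n1", "n2", "n3"),
    as.Date(c("2010-12-01", "2011-01-01", "2011-02-01")),
    matrix(1:6, 3, 2), recurrence_date = as.Date("2011-01-01")
  )
  f <- filter_test_notes(tl)
  expect_identical(f$note_id, c("n1", "n2")) # on-date note retained
  tl2 <- toy_timeline(5)
  expect_identical(filter_test_notes(tl2)$note_id, tl2$note_id)
})

test_that("bootstrap intervals are reproducible and shrink with cohort size", {
  mk <- function(npat, seed) with_seed(seed, {
    pid <- rep(sprintf("P%03d", 1:npat), each = 6)
    lab <- rep(rep(0:1, npat / 2), each = 6)
    sc <- pmin(1, pmax(0, lab * 0.4 + runif(npat * 6, 0, 0.6)))
    list(sc = sc, lab = lab, pid = pid)
  })
  d <- mk(40, 1)
  b1 <- bootstrap_metrics(d$sc, d$lab, d$pid, n_boot = 150, seed = 9)
  b2 <- bootstrap_metrics(d$sc, d$lab, d$pid, n_boot = 150, seed = 9)
  expect_identical(b1, b2)
  d16 <- mk(640, 2)
  b16 <- bootstrap_metrics(d16$sc, d16$lab, d16$pid, n_boot = 150, seed = 9)
  expect_lt(b16$auroc_se, b1$auroc_se) # roughly 1/sqrt(n) shrinkage
  # near-degenerate scores give near-zero AUROC spread
  lab <- rep(0:1, each = 30)
  sc <- c(rep(0.1, 30), rep(0.9, 30))
  b0 <- bootstrap_metrics(sc, lab, rep(sprintf("Q%02d", 1:20), 3),
                          n_boot = 20, seed = 3)
  expect_equal(b0$auroc_se, 0)
})

test_that("evaluate_predictions assembles a coherent report", {
  with_seed(45, {
    pid <- rep(sprintf("P%02d", 1:30), each = 5)
    lab <- rep(sample(0:1, 30, replace = TRUE, prob = c(.6, .4)), each = 5)
    sc <- pmin(1, pmax(0, lab * 0.3 + runif(150, 0, 0.7)))
    r <- evaluate_predictions(sc, lab, pid, n_boot = 30, seed = 1)
    expect_s3_class(r, "eval_report")
    expect_true(r$auroc >= 0 && r$auroc <= 1)
    expect_identical(r$n_notes, 150L)
    expect_identical(r$n_patients, 30L)
    op <- optimal_operating_point(sc, lab)
    expect_identical(r$sensitivity, op$sensitivity)
    expect_identical(r$specificity, op$specificity)
  })
})

test_that("prediction intervals report days in advance and 100-day bins", {
  dates <- as.Date("2010-01-01") + c(0, 100, 200, 300)
  tl <- patient_timeline("P1", sprintf("n%d", 1:4), dates,
                         matrix(0, 4, 2),
                         recurrence_date = as.Date("2010-01-01") + 330)
  # crosses threshold first at the second note: 330 - 100 = 230 days ahead
  pi1 <- prediction_intervals(list(tl), list(c(0.1, 0.8, 0.9, 0.9)), 0.5)
  expect_identical(pi1$intervals$days_in_advance, 230L)
  expect_identical(unname(pi1$histogram[["[200,300)"]]), 1L)
  # never crosses
  pi2 <- prediction_intervals(list(tl), list(rep(0.1, 4)), 0.5)
  expect_true(is.na(pi2$intervals$days_in_advance))
  # first exceedance on the recurrence date itself
  tl3 <- patient_timeline("P2", "m1", as.Date("2012-05-05"),
                          matrix(0, 1, 2),
                          recurrence_date = as.Date("2012-05-05"))
  pi3 <- prediction_intervals(list(tl3), list(0.9), 0.5)
  expect_identical(pi3$intervals$days_in_advance, 0L)
  # non-recurrent patients contribute no rows
  pi4 <- prediction_intervals(list(toy_timeline(3)), list(rep(0.9, 3)), 0.5)
  expect_identical(nrow(pi4$intervals), 0L)
})

test_that("intervals are nonnegative after post-recurrence filtering", {
  with_seed(46, {
    for (i in 1:20) {
      n <- sample(3:10, 1)
      dates <- as.Date("2010-01-01") + sort(sample(0:900, n))
      tl <- patient_timeline("P", sprintf("n%d", 1:n), dates,
                             matrix(0, n, 2),
                             recurrence_date = dates[1] + sample(0:900, 1))
      tf <- filter_test_notes(tl)
      if (length(tf$date) == 0) next
      p <- runif(length(tf$date))
      pi <- prediction_intervals(list(tf), list(p), 0.5)
      d <- pi$intervals$days_in_advance
      expect_true(all(is.na(d) | d >= 0))
    }
  })
})

test_that("t-SNE diagnostics produce reproducible 2-D coordinates", {
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  Y1 <- embedding_diagnostics(X, seed = 5, n_iter = 150)
  expect_identical(dim(Y1), c(40L, 2L))
  Y2 <- embedding_diagnostics(X, seed = 5, n_iter = 150)
  expect_identical(Y1, Y2)
  # two identical points end nearer each other than a distant outlier
  Z <- rbind(c(0, 0), c(0, 0), c(50, 50))
  Yz <- tsne_project(Z, perplexity = 1, n_iter = 150, seed = 2)
  d12 <- sqrt(sum((Yz[1, ] - Yz[2, ])^2))
  d13 <- sqrt(sum((Yz[1, ] - Yz[3, ])^2))
  expect_lt(d12, d13)
  # plot artifact is written when a file is requested
  f <- tempfile(fileext = ".png")
  embedding_diagnostics(X, labels = rep(1:2, each = 20), seed = 1,
                        n_iter = 50, file = f)
  expect_true(file.exists(f))
})
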