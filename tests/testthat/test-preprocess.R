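test_that("clean_text lowercases, strips punctuation and spells numbers", {
  expect_identical(clean_text(""), character(0))
  expect_identical(clean_text(NA_character_), character(0))
  expect_identical(clean_text("Mass—2 cm!!"), c("mass", "two", "cm"))
  expect_identical(clean_text("IMPRESSION:   No change."),
                   c("impression", "no", "change"))
  expect_identical(clean_text("2.5 cm"), c("two", "point", "five", "cm"))
  expect_identical(clean_text("her2 status"), c("her", "two", "status"))
  # no token may contain whitespace, punctuation or digits
  toks <- clean_text("A 12-mm mass; T2 lesion? 3/2015, 40%...")
  expect_false(any(grepl("[^a-z]", toks)))
})

test_that("number spelling covers units, tens, scales and decimals", {
  expect_identical(number_to_words("0"), "zero")
  expect_identical(number_to_words("15"), "fifteen")
  expect_identical(number_to_words("25"), "twenty five")
  expect_identical(number_to_words("105"), "one hundred five")
  expect_identical(number_to_words("2015"), "two thousand fifteen")
  expect_identical(number_to_words("1000000"), "one million")
  expect_identical(clean_text("3.75"),
                   c("three", "point", "seven", "five"))
})

test_that("clean_text is idempotent", {
  texts <- c(
    "Pt seen 3/2015; Mass—2.5cm!! IMPRESSION: stable.",
    "Follow up in 6 weeks (per Dr. Smith).",
    "No evidence of disease. T2N0M0, grade 3."
  )
  for (t in texts) {
    once <- clean_text(t)
    twice <- clean_text(paste(once, collapse = " "))
    expect_identical(twice, once)
  }
})

test_that("build_vocabulary counts terms and document frequency exactly", {
  v <- build_vocabulary(list(c("a", "a", "b"), "b"))
  expect_identical(v$term_count, c(a = 2L, b = 2L))
  expect_identical(v$doc_freq, c(a = 1L, b = 2L))
  expect_identical(v$n_notes, 2L)

  v1 <- build_vocabulary(list(character(0)))
  expect_length(v1$term_count, 0L)
  expect_identical(v1$n_notes, 1L)

  expect_identical(build_vocabulary(list("x"))$doc_freq, c(x = 1L))
  expect_error(build_vocabulary(list()), "non-empty")
})

test_that("remove_unwanted applies heading, stopword, count and phrase rules", {
  vocab <- build_vocabulary(list(rep("mass", 60), rep("impression", 60),
                                 "rare_token"))
  expect_identical(
    remove_unwanted(c("impression", "mass"), vocab,
                    headings = "impression", min_count = 1L),
    "mass"
  )
  expect_identical(
    remove_unwanted("rare_token", vocab, min_count = 50L),
    character(0)
  )
  # identity case: no lists, no threshold
  toks <- c("impression", "mass", "rare_token")
  expect_identical(remove_unwanted(toks, vocab, min_count = 0L), toks)
  # phrase removal drops the full consecutive run only
  vocab2 <- build_vocabulary(list(c("electronically", "signed", "by",
                                    "mass", "signed")))
  expect_identical(
    remove_unwanted(c("electronically", "signed", "by", "mass", "signed"),
                    vocab2, legal_phrases = "electronically signed by",
                    min_count = 0L),
    c("mass", "signed")
  )
  expect_error(remove_unwanted(c("a"), NULL), "vocabulary")
})

test_that("raising min_count never lengthens the output", {
  with_seed(7, {
    for (i in 1:20) {
      toks <- sample(letters[1:6], 30, replace = TRUE)
      vocab <- build_vocabulary(list(toks))
      lens <- vapply(c(0L, 2L, 5L, 10L), function(mc)
        length(remove_unwanted(toks, vocab, min_count = mc)), integer(1))
      expect_true(all(diff(lens) <= 0))
    }
  })
})

test_that("apply_lexicon maps many-to-one and passes unknowns through", {
  lex <- c(brother = "FAM", mother = "FAM", cancer = "CA",
           lesion = "CA", oncology = "CA")
  expect_identical(apply_lexicon("brother", lex), "FAM")
  expect_identical(apply_lexicon(c("cancer", "lesion"), lex), c("CA", "CA"))
  expect_identical(apply_lexicon("mass", character()), "mass")
  expect_length(apply_lexicon(c("cancer", "mass", "mother"), lex), 3L)
})

test_that("proper nouns are detected on raw text, not sentence-initially", {
  pn <- detect_proper_nouns("The patient saw Dr Smith today. Stable mass.")
  expect_true("smith" %in% pn)
  expect_false("the" %in% pn)
  expect_false("stable" %in% pn) # sentence-initial capital
  expect_true("jones" %in% detect_proper_nouns("x", known_names = "Jones"))
})

test_that("the full preprocessing cascade yields only retained or mapped tokens", {
  notes <- data.frame(
    patient_id = "P1",
    note_id = sprintf("N%02d", 1:6),
    timestamp = as.Date("2015-01-01") + 1:6,
    text = c(
      "IMPRESSION: stable mass seen with cancer cells.",
      "The mass is 2 cm. Electronically signed by Dr Smith.",
      "Known lesion; mass stable. The brother was present.",
      "Mass and lesion stable, cancer unchanged.",
      "FINDINGS: mass. The cancer is stable.",
      "Stable mass; no cancer progression."
    ),
    stringsAsFactors = FALSE
  )
  lex <- c(cancer = "CA", lesion = "CA", brother = "FAM")
  prep <- preprocess_corpus(
    notes, lexicon = lex, stopwords = c("the", "is", "and", "no", "was"),
    headings = c("impression", "findings"),
    legal_phrases = "electronically signed by",
    names_list = "Smith", min_count = 2L
  )
  out_tokens <- unique(unlist(prep$notes$tokens))
  allowed <- union(unname(lex),
                   names(prep$vocab$term_count[prep$vocab$term_count >= 2L]))
  expect_true(all(out_tokens %in% allowed))
  expect_false("impression" %in% out_tokens)
  expect_false("smith" %in% out_tokens)
  expect_true("CA" %in% out_tokens)
})

test_that("note tables enforce unique ids and parseable dates", {
  bad <- data.frame(patient_id = "P", note_id = c("a", "a"),
                    timestamp = c("2010-01-01", "2010-01-02"),
                    text = c("x", "y"))
  expect_error(oncorecur:::as_note_table(bad), "unique")
  bad2 <- data.frame(patient_id = "P", note_id = c("a", "b"),
                     timestamp = c("2010-01-01", "not-a-date"),
                     text = c("x", "y"))
  expect_error(oncorecur:::as_note_table(bad2), "timestamp")
})
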