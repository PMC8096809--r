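#' Clean raw note text into a normalised token stream
#'
#' Applies the standard cleaning cascade for clinical free text: digit runs
#' are spelled out as cardinal words (decimals split on the point), the text
#' is lowercased, all punctuation and residual non-letter characters are
#' replaced by whitespace, and the result is tokenised on whitespace. The
#' operation is idempotent: re-cleaning the joined token stream returns the
#' same tokens.
#'
#' @param text A single character string (possibly empty or `NA`).
#' @return A character vector of lowercase, punctuation- and digit-free
#'   tokens; empty input yields `character(0)`.
#' @seealso [clean_corpus()] for the vectorised form, [remove_unwanted()],
#'   [apply_lexicon()].
#' @examples
#' clean_text("Mass - 2 cm, no change since 3/2015.")
#' @export
clean_text <- function(text) {
  stopifnot(length(text) <= 1L)
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  clean_corpus(text)[[1]]
}

#' Clean a vector of note texts
#'
#' Vectorised [clean_text()]: one token vector per input string.
#'
#' @param texts Character vector of raw note texts.
#' @return A list of token character vectors, one per input.
#' @export
clean_corpus <- function(texts) {
  stopifnot(is.character(texts))
  x <- texts
  x[is.na(x)] <- ""
  x <- spell_numbers(x)
  x <- tolower(x)
  x <- gsub("[^a-z]+", " ", x)
  toks <- strsplit(trimws(x), " +")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Detect probable proper nouns in raw text
#'
#' Capitalisation evidence is destroyed by lowercasing, so proper nouns are
#' detected on the raw text: a token is flagged when it is capitalised with a
#' lowercase continuation and does not start a sentence (i.e. it is not the
#' first token and the preceding token does not end in `.`, `!`, `?` or `:`).
#' A supplied name list is always included.
#'
#' @param text A single raw note string.
#' @param known_names Optional character vector of known names (any case).
#' @return Lowercased unique character vector of detected proper-noun tokens.
#' @export
detect_proper_nouns <- function(text, known_names = character()) {
  out <- tolower(known_names)
  if (length(text) == 1L && !is.na(text) && nzchar(text)) {
    toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
    if (length(toks) > 1L) {
      cap <- grepl("^[A-Z][a-z]+$", gsub("[[:punct:]]+$", "", toks))
      sent_init <- c(TRUE, grepl("[.!?:]$", toks[-length(toks)]))
      hit <- toks[cap & !sent_init]
      out <- c(out, tolower(gsub("[[:punct:]]+", "", hit)))
    }
  }
  unique(out[nzchar(out)])
}

#' Corpus vocabulary statistics
#'
#' Counts total occurrences and note-level document frequency for every
#' token in a corpus of cleaned notes. These counts are the denominators of
#' the tf-idf weighting and drive the rare-word filter, so they must be
#' computed on the full (unfiltered) training corpus.
#'
#' @param corpus A list of token character vectors, one per note.
#' @return An object of class `vocab_stats`: a list with named integer
#'   vectors `term_count` and `doc_freq`, and scalar `n_notes`.
#' @examples
#' build_vocabulary(list(c("a", "a", "b"), "b"))
#' @export
build_vocabulary <- function(corpus) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of token vectors")
  all_tok <- unlist(corpus, use.names = FALSE)
  if (length(all_tok) == 0L) {
    tc <- df <- integer(0)
  } else {
    tc_tab <- table(all_tok)
    tc <- setNames(as.integer(tc_tab), names(tc_tab))
    per_note <- lapply(corpus, unique)
    df_tab <- table(unlist(per_note, use.names = FALSE))
    df <- setNames(as.integer(df_tab), names(df_tab))
    df <- df[names(tc)]
  }
  structure(
    list(term_count = tc, doc_freq = df, n_notes = length(corpus)),
    class = "vocab_stats"
  )
}

#' @export
print.vocab_stats <- function(x, ...) {
  cat(
    "Vocabulary statistics:", length(x$term_count), "tokens over",
    x$n_notes, "notes\n"
  )
  invisible(x)
}

#' Remove unwanted tokens from a cleaned note
#'
#' Filters a cleaned token stream against corpus-level vocabulary statistics
#' and curated word lists: general stopwords, section-heading terms
#' (e.g. "impression", "findings"), medico-legal boilerplate phrases,
#' proper nouns, and tokens occurring fewer than `min_count` times in the
#' training corpus. Token order is preserved. Phrases are matched as
#' consecutive token runs.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param vocab A [build_vocabulary()] result for the full training corpus;
#'   required so the rare-word filter is corpus-aware.
#' @param stopwords,headings,proper_nouns Character vectors of single tokens
#'   to drop (lowercase).
#' @param legal_phrases Character vector of multi-word phrases to drop; each
#'   phrase is cleaned with the same rules as the notes before matching.
#' @param min_count Minimum corpus occurrence count a token needs to be
#'   retained (default 50). Tokens absent from `vocab` count as 0.
#' @return The filtered token vector.
#' @export
remove_unwanted <- function(tokens, vocab, stopwords = character(),
                            headings = character(),
                            legal_phrases = character(),
                            proper_nouns = character(),
                            min_count = 50L) {
  if (missing(vocab) || is.null(vocab))
    stop("vocabulary statistics are required: rare-word filtering is corpus-aware")
  stopifnot(inherits(vocab, "vocab_stats"))
  if (length(tokens) == 0L) return(character(0))

  keep <- rep(TRUE, length(tokens))
  # phrase removal: drop every token of a matching consecutive run
  for (ph in legal_phrases) {
    pt <- clean_text(ph)
    np <- length(pt)
    if (np == 0L || np > length(tokens)) next
    for (s in seq_len(length(tokens) - np + 1L)) {
      if (all(tokens[s:(s + np - 1L)] == pt)) keep[s:(s + np - 1L)] <- FALSE
    }
  }
  drop_single <- tokens %in% c(stopwords, headings, proper_nouns)
  cnt <- vocab$term_count[tokens]
  cnt[is.na(cnt)] <- 0L
  keep <- keep & !drop_single & cnt >= min_count
  tokens[keep]
}

#' Map surface terms to controlled vocabulary tokens
#'
#' Replaces each token by its controlled form under a many-to-one term
#' lexicon (CLEVER-style, e.g. "brother" -> "FAM", "cancer" -> "CA").
#' Unmapped tokens pass through unchanged; length is preserved.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon A named character vector: `names()` are surface terms,
#'   values are controlled tokens. May be empty.
#' @return Character vector of the same length.
#' @export
apply_lexicon <- function(tokens, lexicon = character()) {
  if (length(tokens) == 0L || length(lexicon) == 0L) return(tokens)
  stopifnot(!is.null(names(lexicon)))
  idx <- match(tokens, names(lexicon))
  hit <- !is.na(idx)
  tokens[hit] <- unname(lexicon[idx[hit]])
  tokens
}

#' Preprocess a note corpus end to end
#'
#' Runs the full cleaning cascade over a raw note table: text cleaning,
#' proper-noun detection on the raw text, corpus vocabulary construction,
#' unwanted-term removal, and lexicon mapping (in that order; the rare-word
#' threshold is applied before mapping, so mapped controlled tokens are
#' always retained). When `vocab` is supplied (e.g. frozen from a training
#' corpus) it is reused instead of being recomputed, preventing test-time
#' vocabulary leakage.
#'
#' @param notes A data.frame/data.table with columns `patient_id`,
#'   `note_id`, `timestamp` (coercible to `Date`), `text`.
#' @param lexicon Named character vector (see [apply_lexicon()]).
#' @param stopwords,headings,legal_phrases,names_list Word/phrase lists.
#' @param min_count Rare-word threshold (see [remove_unwanted()]).
#' @param vocab Optional frozen [build_vocabulary()] result.
#' @return A list with `notes` (a data.table with a `tokens` list-column of
#'   cleaned, filtered, mapped tokens) and `vocab` (the vocabulary used).
#' @export
preprocess_corpus <- function(notes, lexicon = character(),
                              stopwords = character(),
                              headings = character(),
                              legal_phrases = character(),
                              names_list = character(),
                              min_count = 50L, vocab = NULL) {
  notes <- as_note_table(notes)
  cleaned <- clean_corpus(notes$text)
  if (is.null(vocab)) vocab <- build_vocabulary(cleaned)
  out <- vector("list", length(cleaned))
  for (i in seq_along(cleaned)) {
    pn <- detect_proper_nouns(notes$text[i], names_list)
    toks <- remove_unwanted(
      cleaned[[i]], vocab,
      stopwords = stopwords, headings = headings,
      legal_phrases = legal_phrases, proper_nouns = pn,
      min_count = min_count
    )
    out[[i]] <- apply_lexicon(toks, lexicon)
  }
  res <- data.table::copy(notes)
  res[, text := NULL]
  res[, tokens := out]
  list(notes = res, vocab = vocab)
}

# Validate and normalise a raw note table; enforces unique note ids and
# parseable timestamps, and sorts stably by (patient, timestamp, note_id).
as_note_table <- function(notes) {
  notes <- data.table::as.data.table(notes)
  need <- c("patient_id", "note_id", "timestamp", "text")
  miss <- setdiff(need, names(notes))
  if (length(miss)) stop("note table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(notes$note_id)) stop("note_id values must be unique")
  ts <- tryCatch(as.Date(notes$timestamp), error = function(e) as.Date(NA))
  if (anyNA(ts)) stop("unparseable timestamp values in note table")
  notes[, timestamp := ts]
  data.table::setorder(notes, patient_id, timestamp, note_id)
  notes[]
}
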