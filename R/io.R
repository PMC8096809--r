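#' Read and write note corpora as JSON-lines
#'
#' One JSON object per line with keys `patient_id`, `note_id`, `timestamp`
#' (ISO-8601 date) and `text`.
#'
#' @param path File path.
#' @param notes A data.frame/data.table of notes.
#' @return `read_notes_jsonl` returns a data.table sorted by
#'   (patient, timestamp, note_id).
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  dt <- data.table::rbindlist(recs)
  as_note_table(dt)
}

#' @rdname read_notes_jsonl
#' @export
write_notes_jsonl <- function(notes, path) {
  notes <- as_note_table(notes)
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(
      patient_id = notes$patient_id[i],
      note_id = notes$note_id[i],
      timestamp = format(notes$timestamp[i], "%Y-%m-%d"),
      text = notes$text[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write the patient outcome table
#'
#' CSV with columns `patient_id`, `recurrence_date` (ISO date or empty for
#' none) and `label_source` (`manual` or `weak`).
#'
#' @param path File path.
#' @param outcomes A data.frame/data.table of outcomes.
#' @export
read_outcomes_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "recurrence_date"))
  dt[, recurrence_date := as.Date(ifelse(nzchar(recurrence_date),
                                         recurrence_date, NA_character_))]
  stopifnot(all(dt$label_source %in% c("manual", "weak")))
  dt[]
}

#' @rdname read_outcomes_csv
#' @export
write_outcomes_csv <- function(outcomes, path) {
  dt <- data.table::as.data.table(outcomes)
  out <- data.table::data.table(
    patient_id = dt$patient_id,
    recurrence_date = ifelse(is.na(dt$recurrence_date), "",
                             format(as.Date(dt$recurrence_date), "%Y-%m-%d")),
    label_source = dt$label_source
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read and write per-note weak-label scores
#'
#' CSV with columns `note_id` and `score` (a probability in `[0, 1]`).
#'
#' @param path File path.
#' @param scores Either a named numeric vector (names are note ids) or a
#'   data.frame with `note_id` and `score`.
#' @return `read_scores_csv` returns a named numeric vector.
#' @export
read_scores_csv <- function(path) {
  dt <- data.table::fread(path)
  setNames(dt$score, as.character(dt$note_id))
}

#' @rdname read_scores_csv
#' @export
write_scores_csv <- function(scores, path) {
  if (is.numeric(scores)) {
    dt <- data.table::data.table(note_id = names(scores),
                                 score = unname(scores))
  } else {
    dt <- data.table::as.data.table(scores)[, c("note_id", "score")]
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a term lexicon from two-column TSV
#'
#' Column 1 is the surface term, column 2 the controlled token.
#'
#' @param path File path.
#' @param lexicon Named character vector (names = surface terms).
#' @return A named character vector usable by [apply_lexicon()].
#' @export
read_lexicon_tsv <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("surface", "controlled"))
  setNames(dt$controlled, dt$surface)
}

#' @rdname read_lexicon_tsv
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  writeLines(paste(names(lexicon), unname(lexicon), sep = "\t"), path)
  invisible(path)
}

#' Read or write a one-entry-per-line word list
#'
#' @param path File path.
#' @param words Character vector.
#' @export
read_wordlist <- function(path) {
  w <- readLines(path, encoding = "UTF-8")
  w[nzchar(trimws(w))]
}

#' @rdname read_wordlist
#' @export
write_wordlist <- function(words, path) {
  writeLines(words, path, useBytes = TRUE)
  invisible(path)
}
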