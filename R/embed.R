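#' Train a skip-gram word embedding on a cleaned corpus
#'
#' Learns dense token vectors with the skip-gram / negative-sampling
#' objective over the preprocessed note corpus. Training is single-threaded
#' and bitwise reproducible given `seed`. Hyperparameters default to the
#' standard word2vec settings apart from the stated vector size and window.
#'
#' @param corpus List of token character vectors (cleaned notes).
#' @param dim Embedding dimension (default 300).
#' @param window Maximum context window; the effective window per position
#'   is sampled uniformly from 1..window (default 30).
#' @param epochs Training passes over the corpus (default 30).
#' @param seed Integer RNG seed.
#' @param negative Number of negative samples per context pair.
#' @param learning_rate Initial learning rate (linearly decayed).
#' @param sample Frequent-word subsampling threshold.
#' @param min_count Drop tokens rarer than this before training; the
#'   corpus is normally already frequency-filtered upstream, so default 1.
#' @return An `embedding_space` object: list with `dim` and `vectors`
#'   (a vocabulary-by-dim numeric matrix with token rownames).
#' @export
train_skipgram <- function(corpus, dim = 300L, window = 30L, epochs = 30L,
                           seed = 1L, negative = 5L, learning_rate = 0.025,
                           sample = 1e-3, min_count = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of token vectors")
  all_tok <- unlist(corpus, use.names = FALSE)
  if (length(all_tok) == 0L) stop("corpus contains no tokens")
  tab <- table(all_tok)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) stop("no token satisfies min_count")
  vocab <- names(tab)
  counts <- as.numeric(tab)
  sents <- lapply(corpus, function(toks) {
    ids <- match(toks, vocab) - 1L
    ids[!is.na(ids)]
  })
  sents <- sents[vapply(sents, length, integer(1)) > 0L]
  E <- cpp_sgns_train(
    sents, counts, as.integer(dim), as.integer(window), as.integer(epochs),
    as.integer(negative), learning_rate, sample, as.integer(seed)
  )
  rownames(E) <- vocab
  structure(list(dim = as.integer(dim), vectors = E),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("Embedding space:", nrow(x$vectors), "tokens x", x$dim, "dimensions\n")
  invisible(x)
}

#' Nearest terms by cosine similarity
#'
#' Ranks vocabulary terms by cosine similarity to a query term's vector,
#' excluding the query itself. Ties are broken lexicographically.
#'
#' @param space An `embedding_space`.
#' @param term Query token (must be in the vocabulary).
#' @param k Number of neighbours to return.
#' @return Character vector of `k` terms in decreasing similarity.
#' @export
nearest_terms <- function(space, term, k = 10L) {
  stopifnot(inherits(space, "embedding_space"), k >= 1L)
  E <- space$vectors
  if (!term %in% rownames(E)) stop("unknown term: ", term)
  if (k > nrow(E) - 1L) stop("k exceeds vocabulary size minus one")
  v <- E[term, ]
  nv <- sqrt(sum(v^2))
  norms <- sqrt(rowSums(E^2))
  sims <- as.numeric(E %*% v) / (norms * nv)
  sims[norms == 0 | nv == 0] <- -Inf
  sims[rownames(E) == term] <- -Inf
  ord <- order(-sims, rownames(E))
  rownames(E)[ord][seq_len(k)]
}

#' Inverse document frequency table
#'
#' Computes `idf(t) = log(N / df(t))` (natural log) from corpus vocabulary
#' statistics; terms present in every note get idf exactly 0.
#'
#' @param vocab A [build_vocabulary()] result.
#' @return An `idf_table`: list with named numeric `idf` and `n_notes`.
#' @export
compute_idf <- function(vocab) {
  stopifnot(inherits(vocab, "vocab_stats"))
  if (vocab$n_notes == 0L) stop("empty corpus: N = 0")
  if (length(vocab$doc_freq) && any(vocab$doc_freq <= 0L))
    stop("document frequency must be positive for every stored token")
  idf <- log(vocab$n_notes / as.numeric(vocab$doc_freq))
  names(idf) <- names(vocab$doc_freq)
  structure(list(idf = idf, n_notes = vocab$n_notes), class = "idf_table")
}

#' tf-idf weighted note vector
#'
#' Embeds one note as the tf-idf weighted average of its word vectors:
#' \deqn{V_{note} = \frac{1}{N} \sum_{w \in unique(note)} tf(w)\, idf(w)\, V_w}
#' where `tf` is the within-note occurrence count and `N` the total token
#' count of the preprocessed note. Summing tf*idf over unique words is
#' algebraically identical to summing idf per occurrence. Tokens absent from
#' the embedding vocabulary (or without an idf entry) are skipped and
#' excluded from `N`; an empty note yields the zero vector.
#'
#' @param tokens Character vector: the note's cleaned tokens.
#' @param space An `embedding_space`.
#' @param idf An `idf_table` frozen from the same training corpus.
#' @return Numeric vector of length `space$dim`.
#' @export
vectorize_note <- function(tokens, space, idf) {
  stopifnot(inherits(space, "embedding_space"), inherits(idf, "idf_table"))
  E <- space$vectors
  keep <- tokens[tokens %in% rownames(E) & tokens %in% names(idf$idf)]
  if (length(keep) == 0L) return(numeric(space$dim))
  tf <- table(keep)
  w <- as.numeric(tf) * idf$idf[names(tf)]
  v <- as.numeric(crossprod(E[names(tf), , drop = FALSE], w))
  if (length(v) != space$dim) stop("embedding dimension mismatch")
  v / length(keep)
}

#' Vectorize a whole corpus of cleaned notes
#'
#' Sparse-matrix implementation of [vectorize_note()] over many notes at
#' once; results are identical to the per-note form.
#'
#' @param token_list List of token character vectors.
#' @param space An `embedding_space`.
#' @param idf An `idf_table`.
#' @return A numeric matrix with one row per note and `space$dim` columns.
#' @export
vectorize_corpus <- function(token_list, space, idf) {
  stopifnot(inherits(space, "embedding_space"), inherits(idf, "idf_table"))
  E <- space$vectors
  vocab <- intersect(rownames(E), names(idf$idf))
  n <- length(token_list)
  out <- matrix(0, nrow = n, ncol = space$dim)
  lens <- vapply(token_list, length, integer(1))
  ii <- rep.int(seq_len(n), lens)
  jj <- match(unlist(token_list, use.names = FALSE), vocab)
  ok <- !is.na(jj)
  if (!any(ok)) return(out)
  TF <- Matrix::sparseMatrix(
    i = ii[ok], j = jj[ok], x = 1,
    dims = c(n, length(vocab))
  )
  Nw <- Matrix::rowSums(TF)
  W <- TF %*% Matrix::Diagonal(x = idf$idf[vocab])
  V <- as.matrix(W %*% E[vocab, , drop = FALSE])
  nz <- Nw > 0
  V[nz, ] <- V[nz, , drop = FALSE] / Nw[nz]
  V
}

#' Write / read an embedding space in word2vec text format
#'
#' The format is a header line "vocab_size dim" followed by one line per
#' token: the token then its coordinates, space-separated.
#'
#' @param space An `embedding_space`.
#' @param path File path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   returns an `embedding_space`.
#' @export
write_embeddings <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  E <- space$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(E), ncol(E)), con)
  body <- paste(
    rownames(E),
    apply(E, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                          scientific = FALSE),
                                   collapse = " "))
  )
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  E <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  stopifnot(nrow(E) == hdr[1], ncol(E) == hdr[2])
  rownames(E) <- vocab
  structure(list(dim = hdr[2], vectors = E), class = "embedding_space")
}

#' Write / read an idf table as two-column TSV
#'
#' @param idf An `idf_table`.
#' @param path File path.
#' @export
write_idf <- function(idf, path) {
  stopifnot(inherits(idf, "idf_table"))
  lines <- c(
    paste0("#n_notes\t", idf$n_notes),
    "token\tidf",
    paste(names(idf$idf),
          format(unname(idf$idf), digits = 17, trim = TRUE,
                 scientific = FALSE),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_idf
#' @export
read_idf <- function(path) {
  first <- readLines(path, n = 1L)
  n_notes <- as.integer(strsplit(first, "\t")[[1]][2])
  dt <- data.table::fread(path, sep = "\t", skip = 1L)
  structure(list(idf = setNames(dt$idf, dt$token), n_notes = n_notes),
            class = "idf_table")
}
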