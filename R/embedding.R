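#' Train a skip-gram word/phrase embedding over a normalized corpus
#'
#' Fits a skip-gram-with-negative-sampling embedding (the word2vec model) on a
#' tokenized corpus. Training is single-threaded and fully deterministic: two
#' runs with the same corpus and seed produce bitwise-identical matrices,
#' which the downstream centroid geometry and the test suite rely on.
#'
#' The vocabulary is every token occurring at least `min_count` times, ordered
#' by descending frequency (ties broken alphabetically). Multi-word diagnoses
#' should be merged with [apply_phrases()] *before* training so that each
#' phrase receives its own vector.
#'
#' @param corpus A list of character vectors (one tokenized document per
#'   element), or a character vector of space-separated documents.
#' @param dim Embedding dimensionality (default 300).
#' @param window Maximum context window half-width in words (default 5); the
#'   effective window per position is uniformly reduced, as in word2vec.
#' @param epochs Passes over the corpus (default 5).
#' @param min_count Minimum token frequency for vocabulary inclusion
#'   (default 5).
#' @param negative Number of negative samples per positive pair (default 5).
#' @param learning_rate Initial learning rate, decayed linearly (default
#'   0.025).
#' @param seed Integer seed for the trainer's internal RNG.
#' @return An `embedding_space`: token-by-`dim` real matrix plus vocabulary.
#' @examples
#' docs <- rep(list(c("amotio", "retinae", "op")), 20)
#' sp <- train_embedding(docs, dim = 8, min_count = 1, seed = 1)
#' glance(sp)
#' @export
train_embedding <- function(corpus, dim = 300, window = 5, epochs = 5,
                            min_count = 5, negative = 5,
                            learning_rate = 0.025, seed = 1L) {
  if (is.character(corpus)) corpus <- strsplit(corpus, "\\s+")
  stopifnot(is.list(corpus))
  corpus <- lapply(corpus, as.character)
  if (length(corpus) == 0 || sum(lengths(corpus)) == 0) {
    abort("Corpus is empty.", class = "icdvec_config_error")
  }
  if (dim < 2 || window < 1 || epochs < 1 || min_count < 1 || negative < 0) {
    abort("Invalid training configuration.", class = "icdvec_config_error")
  }
  freq <- table(unlist(corpus, use.names = FALSE))
  freq <- freq[freq >= min_count]
  if (length(freq) == 0) {
    abort("No token reaches `min_count`; vocabulary is empty.",
          class = "icdvec_config_error")
  }
  ord <- order(-as.integer(freq), names(freq))
  vocab <- names(freq)[ord]
  counts <- as.integer(freq)[ord]

  ids <- lapply(corpus, function(toks) {
    m <- match(toks, vocab)
    as.integer(m[!is.na(m)]) - 1L
  })
  mat <- sgns_train_cpp(ids, counts, as.integer(dim), as.integer(window),
                        as.integer(epochs), as.integer(negative),
                        learning_rate, as.integer(seed))
  rownames(mat) <- vocab
  new_embedding_space(mat, counts = counts)
}

new_embedding_space <- function(mat, counts = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) {
    abort("Vocabulary entries must be unique.", class = "icdvec_format_error")
  }
  if (!all(is.finite(mat))) {
    abort("Embedding matrix contains non-finite values.",
          class = "icdvec_format_error")
  }
  structure(
    list(vectors = mat, dim = ncol(mat), counts = counts),
    class = "embedding_space"
  )
}

#' Construct an embedding space from a plain matrix
#'
#' Mainly useful in tests and examples, where a small hand-made space is
#' easier to reason about than a trained one.
#'
#' @param mat Numeric matrix with one row per token; row names are the
#'   vocabulary.
#' @return An `embedding_space`.
#' @export
embedding_space <- function(mat) new_embedding_space(mat)

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d tokens x %d dims>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Vocabulary of an embedding space or centroid index
#' @param x An `embedding_space` or `centroid_index`.
#' @return Character vector of tokens (or ICD codes).
#' @export
vocabulary <- function(x) UseMethod("vocabulary")

#' @export
vocabulary.embedding_space <- function(x) rownames(x$vectors)

#' Look up one token's vector
#'
#' Unknown tokens are an expected, non-exceptional outcome (the vocabulary is
#' whatever the corpus provided), so this returns `NULL` rather than raising.
#'
#' @param space An `embedding_space`.
#' @param token A single token (already normalized; the vocabulary is
#'   lowercase by construction, so case variants are out-of-vocabulary).
#' @return Numeric vector of length `space$dim`, or `NULL` if out of
#'   vocabulary.
#' @export
word_vector <- function(space, token) {
  stopifnot(inherits(space, "embedding_space"), length(token) == 1)
  i <- match(token, rownames(space$vectors))
  if (is.na(i)) return(NULL)
  space$vectors[i, ]
}

#' Average token vectors column-wise
#'
#' Collects the rows of every in-vocabulary token (out-of-vocabulary tokens
#' are skipped and counted), appends any `extra` rows, and returns their
#' unweighted column-wise mean — the sequence representation used both for
#' queries and for thesaurus annotations. Vectors are averaged raw, without
#' length-normalization.
#'
#' @param space An `embedding_space`.
#' @param tokens Character vector of normalized tokens.
#' @param extra Optional numeric matrix (rows of dimension `space$dim`)
#'   appended to the vector array before averaging, e.g. detected phrase
#'   vectors.
#' @return Numeric vector with attributes `n_contributing` (rows averaged)
#'   and `n_oov` (word tokens skipped), or `NULL` if no row was collected.
#' @export
embed_tokens <- function(space, tokens, extra = NULL) {
  stopifnot(inherits(space, "embedding_space"))
  ids <- match(tokens, rownames(space$vectors))
  n_oov <- sum(is.na(ids))
  rows <- space$vectors[ids[!is.na(ids)], , drop = FALSE]
  if (!is.null(extra)) {
    extra <- rbind(extra)
    if (ncol(extra) != space$dim) {
      abort(sprintf("`extra` has dimension %d; space has %d.",
                    ncol(extra), space$dim),
            class = "icdvec_dimension_error")
    }
    rows <- rbind(rows, extra)
  }
  if (nrow(rows) == 0) return(NULL)
  v <- colMeans(rows)
  names(v) <- NULL
  attr(v, "n_contributing") <- nrow(rows)
  attr(v, "n_oov") <- n_oov
  v
}

#' Write / read word vectors in word2vec text format
#'
#' The text format of the original word2vec tool (`-binary 0`): a header line
#' `"<count> <dim>"` followed by one `token v1 ... v_dim` line per vocabulary
#' entry. Values are written with 9 significant digits, so a round trip
#' reproduces the matrix to well under `1e-6`.
#'
#' @param space An `embedding_space`.
#' @param path File path.
#' @return `write_word2vec` returns `path` invisibly; `read_word2vec` returns
#'   an `embedding_space`.
#' @export
write_word2vec <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  mat <- space$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i],
          paste(sprintf("%.9g", mat[i, ]), collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) {
    abort("Empty vector file (line 1): missing header.",
          class = "icdvec_format_error")
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  d <- suppressWarnings(as.integer(hdr[2]))
  if (length(hdr) != 2 || is.na(n) || is.na(d) || n < 1 || d < 1) {
    abort("Malformed header (line 1): expected '<count> <dim>'.",
          class = "icdvec_format_error")
  }
  if (length(lines) - 1 != n) {
    abort(sprintf(
      "Header declares %d rows but file has %d (last line %d).",
      n, length(lines) - 1, length(lines)
    ), class = "icdvec_format_error")
  }
  mat <- matrix(NA_real_, nrow = n, ncol = d)
  toks <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      abort(sprintf("Malformed row at line %d: expected %d fields, got %d.",
                    i + 1, d + 1, length(parts)),
            class = "icdvec_format_error")
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) {
      abort(sprintf("Non-numeric value at line %d.", i + 1),
            class = "icdvec_format_error")
    }
    toks[i] <- parts[1]
    mat[i, ] <- vals
  }
  rownames(mat) <- toks
  new_embedding_space(mat)
}

#' @exportS3Method generics::glance
glance.embedding_space <- function(x, ...) {
  tibble::tibble(n_tokens = nrow(x$vectors), dim = x$dim)
}
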