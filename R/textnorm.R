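#' Normalize German clinical text into a token stream
#'
#' Applies the five normalization rules used throughout the pipeline, in this
#' order: transliterate German umlauts and sharp s (`ä`→`ae`, `ö`→`oe`,
#' `ü`→`ue`, `ß`→`ss`, independent of case), lowercase everything, treat every
#' remaining non-alphanumeric character as a token separator, drop pure-integer
#' tokens whose value exceeds 10 (a `Visus 20` measurement carries no
#' diagnostic meaning, a `Grad 3` does), and optionally split compound words.
#' The same function normalizes corpus documents, thesaurus annotations and
#' inference queries, so all three live in one token space.
#'
#' Tokens that mix digits and letters (e.g. `"h40"`) are kept whole; the
#' number rule applies only to pure integers, by strict comparison, so `"10"`
#' survives and `"11"` does not.
#'
#' @param x Character vector of raw texts (one document per element), UTF-8.
#' @param split_compounds If `TRUE`, attempt to split out-of-vocabulary
#'   compound tokens via `splitter` (see [compound_splitter()]).
#' @param splitter A function `function(token) -> character()` returning the
#'   token's parts, or `NULL` to leave the token unchanged. Only consulted
#'   when `split_compounds` is `TRUE`.
#' @return A list of character vectors, one token vector per input element.
#' @examples
#' normalize_text("Sekundärglaukom")
#' normalize_text("Visus 20 rechts, Grad 3")
#' @export
normalize_text <- function(x, split_compounds = FALSE, splitter = NULL) {
  if (length(x) == 0) return(list())
  if (!is.character(x)) abort("`x` must be a character vector.")
  bad <- !validUTF8(x)
  if (any(bad)) {
    abort(
      sprintf("Input is not valid UTF-8 (element %d).", which(bad)[1]),
      class = "icdvec_encoding_error"
    )
  }
  out <- lapply(x, normalize_one)
  if (split_compounds && !is.null(splitter)) {
    out <- lapply(out, function(toks) {
      if (length(toks) == 0) return(toks)
      unlist(lapply(toks, function(t) {
        parts <- splitter(t)
        if (is.null(parts) || length(parts) == 0) t else parts
      }), use.names = FALSE)
    })
  }
  out
}

umlaut_map <- c(
  "ä" = "ae", "ö" = "oe", "ü" = "ue",
  "Ä" = "ae", "Ö" = "oe", "Ü" = "ue",
  "ß" = "ss"
)

normalize_one <- function(s) {
  s <- stringr::str_replace_all(s, umlaut_map)
  s <- tolower(s)
  toks <- strsplit(gsub("[^a-z0-9]+", " ", s), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(character())
  pure_int <- grepl("^[0-9]+$", toks)
  drop <- pure_int & suppressWarnings(as.numeric(toks)) > 10
  toks[!drop]
}

#' Default compound-splitting strategy
#'
#' German clinical prose is rich in ad-hoc compounds
#' (`"Hornhautdekompensation"`). This builds a splitter that greedily breaks a
#' single out-of-vocabulary token into two known vocabulary words, each at
#' least `min_part` characters long, preferring the longest left part. Tokens
#' already in the vocabulary, or with no admissible split, pass through
#' unchanged. Returned function is suitable for the `splitter` argument of
#' [normalize_text()].
#'
#' @param vocabulary Character vector of known (normalized) word forms.
#' @param min_part Minimum length of each part; default 4.
#' @return A function mapping one token to its parts (length 1 or 2).
#' @export
compound_splitter <- function(vocabulary, min_part = 4) {
  vocab <- unique(vocabulary)
  force(min_part)
  function(token) {
    n <- nchar(token)
    if (token %in% vocab || n < 2 * min_part) return(token)
    for (i in seq(n - min_part, min_part)) {
      left <- substr(token, 1, i)
      right <- substr(token, i + 1, n)
      if (left %in% vocab && right %in% vocab) return(c(left, right))
    }
    token
  }
}

#' Construct a phrase lexicon
#'
#' A phrase lexicon is the set of multi-word terms that are merged into single
#' underscore-joined tokens, so that multi-word diagnoses
#' (`"amotio retinae"` → `"amotio_retinae"`) receive their own embedding
#' vectors.
#'
#' @param phrases A list of character vectors (each a normalized word tuple of
#'   length >= 2), or a character vector of space-separated phrases which will
#'   be normalized first.
#' @return An object of class `phrase_lexicon`.
#' @examples
#' phrase_lexicon(c("Amotio retinae", "cataracta senilis"))
#' @export
phrase_lexicon <- function(phrases = list()) {
  if (is.character(phrases)) phrases <- normalize_text(phrases)
  stopifnot(is.list(phrases))
  phrases <- phrases[lengths(phrases) >= 2]
  keys <- vapply(phrases, paste, "", collapse = " ")
  phrases <- phrases[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  tokens <- vapply(phrases, paste, "", collapse = "_")
  map <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) assign(keys[i], tokens[i], envir = map)
  structure(
    list(
      phrases = phrases,
      tokens = tokens,
      map = map,
      lengths = sort(unique(lengths(phrases)), decreasing = TRUE),
      first_words = unique(vapply(phrases, `[`, "", 1))
    ),
    class = "phrase_lexicon"
  )
}

#' @export
print.phrase_lexicon <- function(x, ...) {
  cat(sprintf("<phrase_lexicon: %d phrases>\n", length(x$phrases)))
  if (length(x$tokens)) {
    shown <- head(x$tokens, 5)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$tokens) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.phrase_lexicon <- function(x) length(x$phrases)

#' Read a phrase lexicon from a file
#'
#' One multi-word phrase per line, words whitespace-separated; `#`-prefixed
#' comment lines and blank lines are ignored. Each line is normalized with
#' [normalize_text()]; lines yielding fewer than two tokens are skipped with a
#' warning; duplicates collapse.
#'
#' @param path Path to a UTF-8 phrase file.
#' @return A `phrase_lexicon`.
#' @export
read_phrases <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- normalize_text(lines)
  short <- lengths(toks) < 2
  if (any(short)) {
    warn(sprintf("Skipped %d phrase line(s) with fewer than 2 tokens.",
                 sum(short)))
  }
  phrase_lexicon(toks[!short])
}

#' Merge known multi-word phrases in a token sequence
#'
#' Greedy longest-match, left to right, non-overlapping: at each position the
#' longest lexicon phrase matching the upcoming tokens is replaced by its
#' underscore-merged token; everything else passes through unchanged. With an
#' empty lexicon this is the identity.
#'
#' @param tokens Character vector of normalized tokens.
#' @param lexicon A `phrase_lexicon`, or `NULL` for the identity.
#' @return Character vector of tokens with phrases merged.
#' @examples
#' lex <- phrase_lexicon(list(c("amotio", "retinae")))
#' apply_phrases(c("rhegmatogene", "amotio", "retinae"), lex)
#' @export
apply_phrases <- function(tokens, lexicon = NULL) {
  if (is.null(lexicon) || length(lexicon$phrases) == 0) return(tokens)
  n <- length(tokens)
  if (n < 2 || !any(tokens %in% lexicon$first_words)) return(tokens)
  out <- character(n)
  k <- 0L
  i <- 1L
  lens <- lexicon$lengths
  while (i <= n) {
    merged <- NULL
    for (L in lens) {
      if (i + L - 1L > n) next
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      hit <- get0(key, envir = lexicon$map, inherits = FALSE)
      if (!is.null(hit)) {
        merged <- hit
        i <- i + L
        break
      }
    }
    k <- k + 1L
    if (is.null(merged)) {
      out[k] <- tokens[i]
      i <- i + 1L
    } else {
      out[k] <- merged
    }
  }
  out[seq_len(k)]
}

#' Find which lexicon phrases occur in a token sequence
#'
#' Runs the same greedy longest-match scan as [apply_phrases()] but returns
#' the merged tokens of the phrases detected (possibly with repeats, in order
#' of occurrence) instead of rewriting the sequence. Used at query time, where
#' the phrase vector augments rather than replaces the word vectors.
#'
#' @inheritParams apply_phrases
#' @return Character vector of merged phrase tokens found (may be empty).
#' @export
detect_phrases <- function(tokens, lexicon = NULL) {
  if (is.null(lexicon) || length(lexicon$phrases) == 0) return(character())
  merged <- apply_phrases(tokens, lexicon)
  merged[grepl("_", merged, fixed = TRUE)]
}
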