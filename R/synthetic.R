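#' Configuration of a synthetic clinical world
#'
#' Describes a self-contained artificial corpus-plus-thesaurus world with
#' controllable semantic structure, standing in for a private clinical
#' corpus. Each of `n_codes` ICD-like codes owns a disjoint signature
#' vocabulary of `words_per_code` pseudowords; `query_words_per_code` of
#' them are held out for gold queries only (paraphrase words that never
#' appear in the thesaurus), the rest form the annotation pool. Every
#' document is assigned one code and draws each token from that code's
#' signature distribution with probability `alpha`, otherwise from a
#' background distribution over the whole vocabulary (all signatures plus
#' `n_shared_fillers` shared filler words). `alpha = 1` gives perfectly
#' separated sublanguages; `alpha = 0` removes every code/token association,
#' so nearest-centroid retrieval of held-out queries can only succeed at
#' chance level.
#'
#' @param n_codes Number of ICD-like codes (>= 2; default 20).
#' @param words_per_code Signature pseudowords per code (default 12).
#' @param query_words_per_code Signature words held out for queries
#'   (default 4; must be >= `annotation_len` and leave at least
#'   `annotation_len` annotation words).
#' @param n_shared_fillers Shared filler pseudowords (default 60).
#' @param alpha Probability that a document token comes from the document
#'   code's signature rather than the background (default 0.8).
#' @param n_docs Number of corpus documents (default 2000).
#' @param doc_len Tokens per document before phrase injection (default 40).
#' @param annotations_per_code Thesaurus annotations per code (default 5).
#' @param annotation_len Words per annotation and per query (default 3).
#' @param n_phrases Number of codes that get a two-word collocation phrase
#'   (default 5; requires `annotation_len >= 2` when positive).
#' @param n_queries Gold paraphrase queries (default 100).
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @return A `world_config` list.
#' @export
world_config <- function(n_codes = 20, words_per_code = 12,
                         query_words_per_code = 4, n_shared_fillers = 60,
                         alpha = 0.8, n_docs = 2000, doc_len = 40,
                         annotations_per_code = 5, annotation_len = 3,
                         n_phrases = 5, n_queries = 100, seed = 1L) {
  cfg <- list(
    n_codes = as.integer(n_codes),
    words_per_code = as.integer(words_per_code),
    query_words_per_code = as.integer(query_words_per_code),
    n_shared_fillers = as.integer(n_shared_fillers),
    alpha = as.numeric(alpha),
    n_docs = as.integer(n_docs),
    doc_len = as.integer(doc_len),
    annotations_per_code = as.integer(annotations_per_code),
    annotation_len = as.integer(annotation_len),
    n_phrases = as.integer(n_phrases),
    n_queries = as.integer(n_queries),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_codes", "words_per_code", "query_words_per_code",
                  "n_shared_fillers", "n_docs", "doc_len",
                  "annotations_per_code", "annotation_len", "n_queries")]
  if (any(vapply(counts, function(v) is.na(v) || v < 1, TRUE))) {
    abort("All world counts must be >= 1.", class = "icdvec_config_error")
  }
  if (cfg$n_codes < 2) {
    abort("Need at least 2 codes.", class = "icdvec_config_error")
  }
  if (is.na(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "icdvec_config_error")
  }
  if (cfg$words_per_code - cfg$query_words_per_code < cfg$annotation_len) {
    abort("Annotation pool too small: need words_per_code - query_words_per_code >= annotation_len.",
          class = "icdvec_config_error")
  }
  if (cfg$query_words_per_code < cfg$annotation_len) {
    abort("Query pool too small: need query_words_per_code >= annotation_len.",
          class = "icdvec_config_error")
  }
  if (cfg$n_phrases > cfg$n_codes) {
    abort("`n_phrases` cannot exceed `n_codes`.",
          class = "icdvec_config_error")
  }
  if (cfg$n_phrases > 0 && cfg$annotation_len < 2) {
    abort("Phrases need `annotation_len` >= 2.",
          class = "icdvec_config_error")
  }
  structure(cfg, class = "world_config")
}

# CVCV pseudowords over a reduced consonant set; any token containing an
# excluded letter (q, w, x, y, ...) is guaranteed out of vocabulary, which
# inject_oov() exploits.
make_pseudowords <- function(n, n_syllables = 3) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  words <- character(0)
  while (length(words) < n) {
    batch <- vapply(seq_len(2 * (n - length(words))), function(i) {
      paste0(paste0(sample(consonants, n_syllables, replace = TRUE),
                    sample(vowels, n_syllables, replace = TRUE)),
             collapse = "")
    }, "")
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

make_codes <- function(n_codes) {
  n_groups <- max(3L, ceiling(n_codes / 6))
  letters_pool <- sample(LETTERS, min(length(LETTERS), n_groups),
                         replace = FALSE)
  groups <- character(0)
  while (length(groups) < n_groups) {
    g <- paste0(sample(letters_pool, 1),
                sprintf("%02d", sample(0:99, 1)))
    groups <- unique(c(groups, g))
  }
  groups <- groups[seq_len(n_groups)]
  codes <- character(n_codes)
  sub_idx <- integer(n_groups)
  for (i in seq_len(n_codes)) {
    g <- ((i - 1) %% n_groups) + 1
    codes[i] <- paste0(groups[g], ".", sub_idx[g])
    sub_idx[g] <- sub_idx[g] + 1
  }
  codes
}

#' Generate a synthetic world
#'
#' Builds the full set of artifacts the pipeline consumes: a tokenized
#' corpus whose vocabulary clusters by code, a phrase lexicon of injected
#' two-word collocations, a thesaurus of several annotations per code, and
#' gold-labelled paraphrase queries whose words are held out from the
#' thesaurus. Deterministic given `config$seed`.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` with fields `corpus` (list of token vectors),
#'   `lexicon`, `thesaurus` (tibble `code`, `annotation`), `gold` (tibble
#'   `query`, `true_code`), `code_vocab` (per-code word sets) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  codes <- sort(make_codes(cfg$n_codes))
  n_sig <- cfg$n_codes * cfg$words_per_code
  words <- make_pseudowords(n_sig + cfg$n_shared_fillers)
  signatures <- split(words[seq_len(n_sig)],
                      rep(seq_len(cfg$n_codes), each = cfg$words_per_code))
  names(signatures) <- codes
  fillers <- words[n_sig + seq_len(cfg$n_shared_fillers)]
  n_ann_pool <- cfg$words_per_code - cfg$query_words_per_code
  ann_pool <- lapply(signatures, function(w) w[seq_len(n_ann_pool)])
  query_pool <- lapply(signatures, function(w) w[n_ann_pool + seq_len(cfg$query_words_per_code)])

  # per-code signature multinomial (mild Dirichlet tilt, not uniform)
  sig_prob <- lapply(signatures, function(w) {
    g <- rgamma(length(w), shape = 2)
    g / sum(g)
  })
  background <- c(unlist(signatures, use.names = FALSE), fillers)

  # two-word collocations from the annotation pools of the first n_phrases codes
  phrase_codes <- codes[seq_len(cfg$n_phrases)]
  phrase_words <- lapply(phrase_codes, function(cd) ann_pool[[cd]][1:2])
  names(phrase_words) <- phrase_codes
  lexicon <- phrase_lexicon(phrase_words)

  doc_codes <- codes[sample.int(cfg$n_codes, cfg$n_docs, replace = TRUE)]
  corpus <- lapply(doc_codes, function(cd) {
    from_sig <- runif(cfg$doc_len) < cfg$alpha
    toks <- character(cfg$doc_len)
    n_s <- sum(from_sig)
    if (n_s > 0) {
      toks[from_sig] <- sample(signatures[[cd]], n_s, replace = TRUE,
                               prob = sig_prob[[cd]])
    }
    if (n_s < cfg$doc_len) {
      toks[!from_sig] <- sample(background, cfg$doc_len - n_s,
                                replace = TRUE)
    }
    pw <- phrase_words[[cd]]
    if (!is.null(pw)) {
      # inject the collocation: after some occurrences of its first word,
      # insert the second
      hit <- toks == pw[1] & runif(length(toks)) < 0.5
      if (any(hit)) {
        pieces <- as.list(toks)
        pieces[hit] <- lapply(pieces[hit], c, pw[2])
        toks <- unlist(pieces, use.names = FALSE)
      }
    }
    toks
  })

  sample_annotation <- function(pool) {
    paste(sample(pool, cfg$annotation_len), collapse = " ")
  }
  thesaurus <- purrr::map_dfr(codes, function(cd) {
    pool <- ann_pool[[cd]]
    anns <- character(0)
    guard <- 0
    while (length(anns) < cfg$annotations_per_code) {
      guard <- guard + 1
      if (guard > 1000 * cfg$annotations_per_code) {
        abort("Cannot draw enough distinct annotations; enlarge the annotation pool.",
              class = "icdvec_config_error")
      }
      anns <- unique(c(anns, sample_annotation(pool)))
    }
    if (cd %in% phrase_codes) {
      pw <- phrase_words[[cd]]
      rest <- setdiff(pool, pw)
      tail_words <- if (cfg$annotation_len > 2) {
        sample(rest, min(cfg$annotation_len - 2, length(rest)))
      } else {
        character(0)
      }
      anns[1] <- paste(c(pw, tail_words), collapse = " ")
      anns <- unique(anns)
      while (length(anns) < cfg$annotations_per_code) {
        anns <- unique(c(anns, sample_annotation(pool)))
      }
    }
    tibble::tibble(code = cd, annotation = anns[seq_len(cfg$annotations_per_code)])
  })

  gold_codes <- codes[sample.int(cfg$n_codes, cfg$n_queries, replace = TRUE)]
  gold <- tibble::tibble(
    query = vapply(gold_codes, function(cd) {
      paste(sample(query_pool[[cd]], cfg$annotation_len), collapse = " ")
    }, "", USE.NAMES = FALSE),
    true_code = gold_codes
  )

  structure(
    list(
      corpus = corpus,
      lexicon = lexicon,
      thesaurus = thesaurus,
      gold = gold,
      code_vocab = list(signature = signatures, annotation_pool = ann_pool,
                        query_pool = query_pool, fillers = fillers),
      config = cfg
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_world: %d docs, %d codes (%d groups), %d annotations, %d gold queries, alpha = %.2f>\n",
    length(x$corpus), cfg$n_codes,
    length(unique(icd_group(x$thesaurus$code))),
    nrow(x$thesaurus), nrow(x$gold), cfg$alpha
  ))
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Emits `corpus.txt` (one space-joined document per line), `phrases.txt`,
#' `thesaurus.tsv`, `queries.txt` and `gold.tsv` into `dir`, the file dialects
#' the rest of the package reads.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(vapply(world$corpus, paste, "", collapse = " "),
             file.path(dir, "corpus.txt"), useBytes = TRUE)
  writeLines(vapply(world$lexicon$phrases, paste, "", collapse = " "),
             file.path(dir, "phrases.txt"), useBytes = TRUE)
  writeLines(sprintf("%s\t%s", world$thesaurus$code,
                     world$thesaurus$annotation),
             file.path(dir, "thesaurus.tsv"), useBytes = TRUE)
  writeLines(world$gold$query, file.path(dir, "queries.txt"),
             useBytes = TRUE)
  writeLines(sprintf("%s\t%s", world$gold$query, world$gold$true_code),
             file.path(dir, "gold.tsv"), useBytes = TRUE)
  invisible(dir)
}

#' Replace query words with unseen pseudowords
#'
#' Emulates cross-site out-of-vocabulary degradation: per query, a fraction
#' `fraction` of its words (rounded up) is replaced by tokens containing the
#' letter `x`, which the pseudoword alphabet excludes, so the replacements
#' are out of vocabulary by construction. At `fraction = 1` every word is
#' replaced and no query can produce a vector.
#'
#' @param queries Character vector of queries.
#' @param fraction Fraction of words to replace, in `[0, 1]`.
#' @param seed Seed controlling which words are hit.
#' @return Character vector of corrupted queries.
#' @export
inject_oov <- function(queries, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  withr::with_seed(as.integer(seed), {
    counter <- 0L
    vapply(queries, function(q) {
      w <- strsplit(q, "\\s+")[[1]]
      k <- ceiling(fraction * length(w))
      if (k > 0) {
        at <- sample.int(length(w), k)
        counter <<- counter + k
        w[at] <- sprintf("xx%06d", counter - rev(seq_len(k)) + 1L)
      }
      paste(w, collapse = " ")
    }, "", USE.NAMES = FALSE)
  })
}

#' Run the whole pipeline on a synthetic world
#'
#' Trains the embedding on the world's corpus (phrases merged first), places
#' centroids from its thesaurus, infers codes for the gold queries, and
#' scores the predictions at both correctness levels.
#'
#' @param world A `synthetic_world`.
#' @param dim,window,epochs,min_count,negative,learning_rate,seed Passed to
#'   [train_embedding()].
#' @param max_distance,phrase_mode Passed to [infer_codes()].
#' @param min_group_n Passed to [summarize_eval()].
#' @return An `eval_report`; the prediction and record tibbles ride along as
#'   attributes `predictions` and `records`, and the trained space and index
#'   as `space` and `index`.
#' @export
run_end_to_end <- function(world, dim = 50, window = 5, epochs = 5,
                           min_count = 5, negative = 5,
                           learning_rate = 0.025, seed = 1L,
                           max_distance = 2,
                           phrase_mode = c("augment", "replace"),
                           min_group_n = 3) {
  stopifnot(inherits(world, "synthetic_world"))
  phrase_mode <- match.arg(phrase_mode)
  corpus <- lapply(world$corpus, apply_phrases, lexicon = world$lexicon)
  space <- train_embedding(corpus, dim = dim, window = window,
                           epochs = epochs, min_count = min_count,
                           negative = negative,
                           learning_rate = learning_rate, seed = seed)
  index <- build_centroids(world$thesaurus, space, world$lexicon,
                           phrase_mode = phrase_mode)
  preds <- infer_codes(world$gold$query, index, space, world$lexicon,
                       max_distance = max_distance,
                       phrase_mode = phrase_mode)
  records <- score_predictions(preds, world$gold)
  report <- summarize_eval(records, min_group_n = min_group_n)
  attr(report, "predictions") <- preds
  attr(report, "records") <- records
  attr(report, "space") <- space
  attr(report, "index") <- index
  report
}
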