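# Small in-code fixtures shared across test files.

# A hand-made 2-d space where every vector is easy to reason about.
tiny_space <- function() {
  m <- rbind(
    amotio         = c(1, 0),
    retinae        = c(0, 1),
    amotio_retinae = c(1, 1),
    katarakt       = c(-1, 0),
    glaukom        = c(0.6, 0.8)
  )
  embedding_space(m)
}

tiny_lexicon <- function() phrase_lexicon(list(c("amotio", "retinae")))

# Random embedding space over a synthetic vocabulary.
random_space <- function(n_tokens, dim, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_tokens * dim), n_tokens, dim)
    rownames(m) <- sprintf("tok%03d", seq_len(n_tokens))
    embedding_space(m)
  })
}

# Random centroid index with valid ICD-like codes.
random_index <- function(n_codes, dim, seed = 1) {
  withr::with_seed(seed, {
    codes <- sprintf("%s%02d.%d", sample(LETTERS, n_codes, replace = TRUE),
                     sample(0:99, n_codes, replace = TRUE),
                     sample(0:9, n_codes, replace = TRUE))
    codes <- make.unique_codes(codes, n_codes)
    m <- matrix(rnorm(n_codes * dim), n_codes, dim)
    rownames(m) <- codes
    centroid_index(m)
  })
}

make.unique_codes <- function(codes, n) {
  i <- 0
  while (anyDuplicated(codes)) {
    i <- i + 1
    dup <- duplicated(codes)
    codes[dup] <- sprintf("%s%02d.%d", sample(LETTERS, sum(dup), TRUE),
                          sample(0:99, sum(dup), TRUE),
                          sample(0:9, sum(dup), TRUE))
    if (i > 100) stop("could not draw unique codes")
  }
  codes[seq_len(n)]
}

# Independent brute-force nearest-centroid oracle: plain loop over all
# centroids with pairwise cosine_distance, ties to the smallest code.
brute_force_nearest <- function(v, index) {
  codes <- rownames(index$vectors)
  d <- vapply(seq_along(codes),
              function(i) cosine_distance(v, index$vectors[i, ]), 0.0)
  best <- min(d)
  cand <- sort(codes[d <= best])
  list(code = cand[1], distance = best)
}

# A small world + trained pipeline, reused by several files. Cached per
# session so the expensive training runs once.
small_world_cfg <- function(alpha = 1, seed = 1, ...) {
  world_config(
    n_codes = 8, words_per_code = 10, query_words_per_code = 3,
    n_shared_fillers = 20, alpha = alpha, n_docs = 400, doc_len = 30,
    annotations_per_code = 3, annotation_len = 3, n_phrases = 2,
    n_queries = 40, seed = seed, ...
  )
}

.pipeline_cache <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (is.null(.pipeline_cache$p)) {
    w <- generate_world(small_world_cfg())
    rep <- run_end_to_end(w, dim = 30, seed = 1)
    .pipeline_cache$p <- list(world = w, report = rep,
                              space = attr(rep, "space"),
                              index = attr(rep, "index"),
                              predictions = attr(rep, "predictions"))
  }
  .pipeline_cache$p
}
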