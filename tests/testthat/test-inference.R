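test_that("cosine distance matches its closed form on canonical pairs", {
  expect_equal(cosine_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  # symmetry and scale invariance
  u <- c(0.3, -1.2, 2.5)
  v <- c(1.1, 0.4, -0.2)
  expect_equal(cosine_distance(u, v), cosine_distance(v, u))
  expect_equal(cosine_distance(7.5 * u, v), cosine_distance(u, v))
  expect_error(cosine_distance(c(0, 0, 0), v),
               class = "icdvec_degenerate_vector_error")
  expect_error(cosine_distance(u, c(1, 2)),
               class = "icdvec_dimension_error")
})

test_that("query embedding augments word vectors with the phrase vector", {
  sp <- tiny_space()
  lex <- tiny_lexicon()
  # both words and the phrase contribute one row each
  v <- embed_query(sp, lex, "amotio retinae")
  expect_equal(as.numeric(v), colMeans(rbind(c(1, 0), c(0, 1), c(1, 1))))
  expect_equal(attr(v, "n_contributing"), 3)
  # single in-vocabulary word: identity
  expect_equal(as.numeric(embed_query(sp, NULL, "Glaukom")), c(0.6, 0.8))
  # replace mode keeps only the merged token
  expect_equal(as.numeric(embed_query(sp, lex, "amotio retinae",
                                      phrase_mode = "replace")),
               c(1, 1))
  # fully OOV query yields the no-vector signal
  expect_null(embed_query(sp, lex, "voellig unbekannt"))
  expect_null(embed_query(sp, lex, ""))
})

test_that("inference returns the nearest centroid with exact self-retrieval", {
  sp <- tiny_space()
  lex <- tiny_lexicon()
  th <- tibble::tibble(
    code = c("H33.0", "H25.0"),
    annotation = c("amotio retinae", "katarakt")
  )
  idx <- build_centroids(th, sp, lex)
  out <- infer_codes(c("Amotio retinae!", "KATARAKT"), idx, sp, lex)
  expect_equal(out$code, c("H33.0", "H25.0"))
  expect_lt(max(out$distance), 1e-9)
  expect_true(all(out$accepted))
})

test_that("inference agrees with the exhaustive brute-force oracle", {
  sp <- random_space(60, 10, seed = 21)
  idx <- random_index(50, 10, seed = 22)
  withr::with_seed(23, {
    queries <- vapply(1:100, function(i) {
      paste(sample(vocabulary(sp), sample(1:5, 1), replace = TRUE),
            collapse = " ")
    }, "")
  })
  out <- infer_codes(queries, idx, sp)
  for (i in seq_along(queries)) {
    v <- embed_query(sp, NULL, queries[i])
    oracle <- brute_force_nearest(as.numeric(v), idx)
    expect_identical(out$code[i], oracle$code)
    expect_equal(out$distance[i], oracle$distance, tolerance = 1e-12)
  }
})

test_that("equidistant centroids resolve to the lexicographically smallest code", {
  sp <- embedding_space(matrix(c(1, 0), 1, 2, dimnames = list("q")))
  m <- rbind("Z99.9" = c(1, 0), "A10.0" = c(2, 0), "B20.1" = c(0, 1))
  idx <- centroid_index(m)
  out <- infer_codes("q", idx, sp)
  expect_equal(out$code, "A10.0")
  expect_equal(out$distance, 0)
})

test_that("rescaling all centroids changes no predicted code", {
  sp <- random_space(40, 8, seed = 31)
  idx <- random_index(25, 8, seed = 32)
  idx_scaled <- centroid_index(idx$vectors * 1000,
                               n_annotations = idx$n_annotations)
  withr::with_seed(33, {
    queries <- vapply(1:50, function(i) {
      paste(sample(vocabulary(sp), 3), collapse = " ")
    }, "")
  })
  expect_identical(infer_codes(queries, idx, sp)$code,
                   infer_codes(queries, idx_scaled, sp)$code)
})

test_that("acceptance is monotone in the threshold and distances stay in range", {
  p <- small_pipeline()
  preds <- infer_codes(p$world$gold$query, p$index, p$space, p$world$lexicon)
  expect_true(all(preds$distance >= 0 & preds$distance <= 2, na.rm = TRUE))
  thresholds <- c(2, 1, 0.5, 0.1, 0.01, 0)
  accepted <- lapply(thresholds, function(th) {
    out <- infer_codes(p$world$gold$query, p$index, p$space, p$world$lexicon,
                       max_distance = th)
    which(out$accepted)
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(accepted[[i]] %in% accepted[[i - 1]]))
  }
})

test_that("no-vector queries are rejected with NA code and counted OOV", {
  p <- small_pipeline()
  out <- infer_codes(c("xx1 xx2", p$world$gold$query[1]), p$index, p$space,
                     p$world$lexicon)
  expect_true(is.na(out$code[1]))
  expect_true(is.na(out$distance[1]))
  expect_false(out$accepted[1])
  expect_equal(out$n_oov[1], 2L)
  expect_false(is.na(out$code[2]))
})

test_that("batch inference preserves order and permutes with its input", {
  p <- small_pipeline()
  q <- p$world$gold$query[1:10]
  out <- infer_codes(q, p$index, p$space, p$world$lexicon)
  expect_equal(out$query, q)
  perm <- c(7, 2, 9, 1, 10, 3, 5, 8, 4, 6)
  out_perm <- infer_codes(q[perm], p$index, p$space, p$world$lexicon)
  expect_equal(out_perm$code, out$code[perm])
  expect_equal(out_perm$distance, out$distance[perm])
  # empty input, empty frame with stable schema
  out0 <- infer_codes(character(), p$index, p$space)
  expect_equal(nrow(out0), 0)
  expect_named(out0, c("query", "code", "distance", "accepted", "n_oov"))
})

test_that("inference validates its configuration", {
  sp <- tiny_space()
  idx3 <- centroid_index(matrix(1:6, 2, 3,
                                dimnames = list(c("A10.0", "B20.0"))))
  expect_error(infer_codes("amotio", idx3, sp),
               class = "icdvec_dimension_error")
  idx2 <- centroid_index(rbind("A10.0" = c(1, 0)))
  expect_error(infer_codes("amotio", idx2, sp, max_distance = 3),
               class = "icdvec_config_error")
})

test_that("predictions write to the documented TSV dialect", {
  p <- small_pipeline()
  preds <- infer_codes(c(p$world$gold$query[1], "xx1"), p$index, p$space,
                       p$world$lexicon)
  f <- withr::local_tempfile()
  write_predictions(preds, f)
  lines <- readLines(f)
  expect_equal(lines[1], "query\tcode\tcosine_distance\taccepted\tn_oov")
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 5))
  expect_equal(fields[[2]][2], "")  # empty code for the no-vector query
})
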