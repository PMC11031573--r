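#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`, in `[0, 2]`: 0 for identical direction, 1 for orthogonal,
#' 2 for opposite. Symmetric and invariant to positive rescaling of either
#' argument.
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return A number in `[0, 2]`.
#' @examples
#' cosine_distance(c(3, 4), c(3, 4))
#' cosine_distance(c(1, 0), c(0, 1))
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) {
    abort(sprintf("Dimension mismatch: %d vs %d.", length(u), length(v)),
          class = "icdvec_dimension_error")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("Cosine distance is undefined for a zero vector.",
          class = "icdvec_degenerate_vector_error")
  }
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

#' Embed a free-text diagnosis query
#'
#' Normalizes the query, scans it for lexicon phrases, and averages the
#' resulting vector array column-wise. In `"augment"` mode (the default) the
#' array holds one row per in-vocabulary word token *plus* one additional row
#' for every detected phrase whose merged token is in vocabulary — the phrase
#' vector is concatenated to the array before averaging, it does not replace
#' its constituent words. In `"replace"` mode phrases are merged first and
#' only the rewritten tokens are embedded.
#'
#' @param space An `embedding_space`.
#' @param lexicon A `phrase_lexicon` or `NULL`.
#' @param text A single query string (raw text; normalization is applied
#'   here).
#' @param phrase_mode `"augment"` (default) or `"replace"`.
#' @param split_compounds,splitter Passed to [normalize_text()].
#' @return Numeric query vector with attributes `n_contributing` and `n_oov`,
#'   or `NULL` when nothing in the query is in vocabulary.
#' @export
embed_query <- function(space, lexicon = NULL, text,
                        phrase_mode = c("augment", "replace"),
                        split_compounds = FALSE, splitter = NULL) {
  phrase_mode <- match.arg(phrase_mode)
  stopifnot(length(text) == 1)
  toks <- normalize_text(text, split_compounds = split_compounds,
                         splitter = splitter)[[1]]
  if (length(toks) == 0) return(NULL)
  if (phrase_mode == "replace") {
    return(embed_tokens(space, apply_phrases(toks, lexicon)))
  }
  phr <- detect_phrases(toks, lexicon)
  extra <- NULL
  if (length(phr) > 0) {
    ids <- match(phr, rownames(space$vectors))
    ids <- ids[!is.na(ids)]
    if (length(ids) > 0) extra <- space$vectors[ids, , drop = FALSE]
  }
  embed_tokens(space, toks, extra = extra)
}

#' Infer ICD-10 codes for free-text diagnosis queries
#'
#' For each query, embeds the text with [embed_query()] and returns the code
#' of the nearest centroid under cosine distance, scanning the whole index
#' exhaustively. Equidistant centroids are resolved in favor of the
#' lexicographically smallest code. A prediction is `accepted` when its
#' distance does not exceed `max_distance`; the default of 2 accepts
#' everything, so rejection must be opted into. Queries with no in-vocabulary
#' content get an `NA` code and are never accepted.
#'
#' @param queries Character vector of raw query texts.
#' @param index A `centroid_index`.
#' @param space The `embedding_space` the index was built against.
#' @param lexicon Optional `phrase_lexicon`.
#' @param max_distance Cosine-distance acceptance threshold in `[0, 2]`
#'   (default 2).
#' @param phrase_mode Passed to [embed_query()].
#' @param verbose If `TRUE`, print a one-line batch summary.
#' @return A tibble with one row per query: `query`, `code`, `distance`,
#'   `accepted`, `n_oov`.
#' @examples
#' sp <- embedding_space(matrix(c(1, 0, 0, 1), 2, 2,
#'                              dimnames = list(c("katarakt", "glaukom"))))
#' idx <- centroid_index(matrix(c(1, 0, 0, 1), 2, 2,
#'                              dimnames = list(c("H25.0", "H40.1"))))
#' infer_codes(c("Katarakt", "Glaukom"), idx, sp)
#' @export
infer_codes <- function(queries, index, space, lexicon = NULL,
                        max_distance = 2, phrase_mode = c("augment", "replace"),
                        verbose = FALSE) {
  phrase_mode <- match.arg(phrase_mode)
  stopifnot(inherits(index, "centroid_index"),
            inherits(space, "embedding_space"))
  if (nrow(index$vectors) == 0) {
    abort("Centroid index is empty.", class = "icdvec_config_error")
  }
  if (index$dim != space$dim) {
    abort(sprintf("Index dimension %d does not match space dimension %d.",
                  index$dim, space$dim),
          class = "icdvec_dimension_error")
  }
  if (!(max_distance >= 0 && max_distance <= 2)) {
    abort("`max_distance` must lie in [0, 2].", class = "icdvec_config_error")
  }
  C <- index$vectors
  Cn <- C / sqrt(rowSums(C^2))
  codes <- rownames(C)

  one <- function(q) {
    v <- embed_query(space, lexicon, q, phrase_mode = phrase_mode)
    n_oov <- if (is.null(v)) {
      length(normalize_text(q)[[1]])
    } else {
      attr(v, "n_oov")
    }
    if (is.null(v) || sqrt(sum(v^2)) == 0) {
      return(tibble::tibble(query = q, code = NA_character_,
                            distance = NA_real_, accepted = FALSE,
                            n_oov = as.integer(n_oov)))
    }
    d <- 1 - as.numeric(Cn %*% v) / sqrt(sum(v^2))
    d <- pmin(pmax(d, 0), 2)
    j <- which.min(d)   # codes sorted ascending: ties pick the smallest code
    tibble::tibble(query = q, code = codes[j], distance = d[j],
                   accepted = d[j] <= max_distance,
                   n_oov = as.integer(n_oov))
  }
  out <- purrr::map_dfr(as.character(queries), one)
  if (length(queries) == 0) {
    out <- tibble::tibble(query = character(), code = character(),
                          distance = double(), accepted = logical(),
                          n_oov = integer())
  }
  if (verbose) {
    inform(sprintf(
      "infer_codes: %d queries, %d accepted, %d without vector, mean distance %.4f",
      nrow(out), sum(out$accepted), sum(is.na(out$code)),
      mean(out$distance, na.rm = TRUE)
    ))
  }
  out
}

#' Write predictions to a TSV file
#'
#' Columns `query`, `code`, `cosine_distance`, `accepted`, `n_oov`; the code
#' and distance fields are empty for queries that produced no vector.
#'
#' @param predictions Tibble from [infer_codes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(is.data.frame(predictions))
  lines <- sprintf(
    "%s\t%s\t%s\t%s\t%d",
    predictions$query,
    ifelse(is.na(predictions$code), "", predictions$code),
    ifelse(is.na(predictions$distance), "",
           sprintf("%.6f", predictions$distance)),
    ifelse(predictions$accepted, "true", "false"),
    predictions$n_oov
  )
  writeLines(c("query\tcode\tcosine_distance\taccepted\tn_oov", lines),
             path, useBytes = TRUE)
  invisible(path)
}
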