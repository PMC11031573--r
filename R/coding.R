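icd_pattern <- "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$"

#' Validate ICD-10(-GM) style codes
#'
#' A valid code is an uppercase letter, two digits, and an optional
#' subcategory of one to four alphanumerics after a dot — terminal letters are
#' allowed (`"H34.8Z"`), as ICD-10-GM uses them.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @export
is_valid_icd <- function(code) {
  !is.na(code) & grepl(icd_pattern, code)
}

#' Superordinate disease group of an ICD-10 code
#'
#' The 3-character ICD-10 category (e.g. `"H33"` for every retinal-detachment
#' code), the unit at which lenient "correct" scoring and the per-group
#' accuracy table operate.
#'
#' @param code Character vector of valid ICD-10 codes.
#' @return Character vector of 3-character group codes.
#' @examples
#' icd_group(c("H34.8Z", "H40.5", "I10"))
#' @export
icd_group <- function(code) {
  bad <- !is_valid_icd(code)
  if (any(bad)) {
    abort(sprintf("Invalid ICD-10 code: '%s'.", code[which(bad)[1]]),
          class = "icdvec_validation_error")
  }
  substr(code, 1, 3)
}

#' Read an ICD-10 thesaurus from a two-column TSV file
#'
#' Each line is `code<TAB>annotation`, UTF-8; `#`-prefixed comment lines and
#' blank lines are ignored. Codes are validated against the ICD-10-GM pattern
#' and invalid lines are skipped with a warning. Duplicates are removed after
#' normalizing the annotation, so case or punctuation variants of the same
#' (annotation, code) pair collapse to one entry.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `code` and `annotation`; attribute
#'   `n_skipped` counts the dropped invalid lines.
#' @export
read_thesaurus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  has_tab <- grepl("\t", lines, fixed = TRUE)
  code <- sub("\t.*$", "", lines)
  annotation <- sub("^[^\t]*\t", "", lines)
  annotation <- sub("\t.*$", "", annotation)
  ok <- has_tab & is_valid_icd(trimws(code)) & nzchar(trimws(annotation))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d thesaurus line(s) with invalid code or format.",
                 n_skipped))
  }
  tb <- tibble::tibble(
    code = trimws(code[ok]),
    annotation = trimws(annotation[ok])
  )
  if (nrow(tb) == 0) {
    abort("Thesaurus contains no valid entries.",
          class = "icdvec_empty_thesaurus_error")
  }
  key <- paste(
    tb$code,
    vapply(normalize_text(tb$annotation), paste, "", collapse = " ")
  )
  tb <- tb[!duplicated(key), ]
  attr(tb, "n_skipped") <- n_skipped
  tb
}

#' Place one centroid per ICD-10 code in the embedding space
#'
#' Every thesaurus annotation is normalized, phrase-scanned and embedded
#' through the same path as an inference query ([embed_query()]); the
#' centroid of a code is the unweighted mean of its embeddable annotation
#' vectors. These centroids are the targets of the nearest-neighbor search.
#' Codes whose annotations are all out of vocabulary get no centroid and are
#' dropped with a warning. Centroids are stored sorted by code, which also
#' fixes the deterministic tie-break of [infer_codes()].
#'
#' @param thesaurus A data frame with columns `code` and `annotation`
#'   (e.g. from [read_thesaurus()] or a [generate_world()] thesaurus).
#' @param space An `embedding_space` built from the same normalization
#'   pipeline.
#' @param lexicon Optional `phrase_lexicon` used when embedding annotations.
#' @param phrase_mode How detected phrases enter the vector array; see
#'   [embed_query()].
#' @return A `centroid_index`: code-by-dim matrix plus per-code annotation
#'   counts.
#' @export
build_centroids <- function(thesaurus, space, lexicon = NULL,
                            phrase_mode = c("augment", "replace")) {
  phrase_mode <- match.arg(phrase_mode)
  stopifnot(is.data.frame(thesaurus),
            all(c("code", "annotation") %in% names(thesaurus)),
            inherits(space, "embedding_space"))
  bad <- !is_valid_icd(thesaurus$code)
  if (any(bad)) {
    abort(sprintf("Invalid ICD-10 code in thesaurus: '%s'.",
                  thesaurus$code[which(bad)[1]]),
          class = "icdvec_validation_error")
  }
  vecs <- lapply(thesaurus$annotation, function(a) {
    embed_query(space, lexicon, a, phrase_mode = phrase_mode)
  })
  ok <- !vapply(vecs, is.null, TRUE)
  dropped <- unique(thesaurus$code[!ok][!thesaurus$code[!ok] %in%
                                          thesaurus$code[ok]])
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d code(s) had no embeddable annotation and were dropped: %s%s",
      length(dropped), paste(head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else ""
    ))
  }
  if (!any(ok)) {
    abort("No thesaurus annotation could be embedded.",
          class = "icdvec_config_error")
  }
  codes <- sort(unique(thesaurus$code[ok]))
  mat <- matrix(0, nrow = length(codes), ncol = space$dim,
                dimnames = list(codes, NULL))
  n_ann <- integer(length(codes))
  names(n_ann) <- codes
  for (i in seq_along(codes)) {
    rows <- do.call(rbind, vecs[ok & thesaurus$code == codes[i]])
    mat[i, ] <- colMeans(rows)
    n_ann[i] <- nrow(rows)
  }
  new_centroid_index(mat, n_ann)
}

new_centroid_index <- function(mat, n_annotations) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            length(n_annotations) == nrow(mat))
  if (!all(is.finite(mat))) {
    abort("Centroid matrix contains non-finite values.",
          class = "icdvec_format_error")
  }
  if (any(n_annotations < 1)) {
    abort("Every stored centroid needs n_annotations >= 1.",
          class = "icdvec_format_error")
  }
  ord <- order(rownames(mat))
  structure(
    list(vectors = mat[ord, , drop = FALSE],
         n_annotations = n_annotations[ord],
         dim = ncol(mat)),
    class = "centroid_index"
  )
}

#' Construct a centroid index from a plain matrix
#'
#' For tests, examples and loading persisted indexes; [build_centroids()] is
#' the normal constructor.
#'
#' @param mat Numeric code-by-dim matrix with ICD codes as row names.
#' @param n_annotations Integer vector: annotations contributing per code
#'   (default 1 each).
#' @return A `centroid_index`.
#' @export
centroid_index <- function(mat, n_annotations = rep(1L, nrow(mat))) {
  names(n_annotations) <- rownames(mat)
  new_centroid_index(mat, n_annotations)
}

#' @export
print.centroid_index <- function(x, ...) {
  cat(sprintf("<centroid_index: %d ICD-10 codes x %d dims>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @export
vocabulary.centroid_index <- function(x) rownames(x$vectors)

#' @exportS3Method generics::tidy
tidy.centroid_index <- function(x, ...) {
  tibble::tibble(
    code = rownames(x$vectors),
    group = icd_group(rownames(x$vectors)),
    n_annotations = as.integer(x$n_annotations)
  )
}

#' @exportS3Method generics::glance
glance.centroid_index <- function(x, ...) {
  tibble::tibble(
    n_codes = nrow(x$vectors),
    n_groups = length(unique(icd_group(rownames(x$vectors)))),
    dim = x$dim
  )
}

#' Persist / load a centroid index
#'
#' Uses the word2vec text format with ICD codes as row labels, plus a sidecar
#' TSV `<path>.meta.tsv` holding the per-code annotation counts.
#'
#' @param index A `centroid_index`.
#' @param path File path for the vector file.
#' @return `write_centroids` returns `path` invisibly; `read_centroids`
#'   returns a `centroid_index`.
#' @export
write_centroids <- function(index, path) {
  stopifnot(inherits(index, "centroid_index"))
  write_word2vec(new_embedding_space(index$vectors), path)
  meta <- sprintf("%s\t%d", rownames(index$vectors), index$n_annotations)
  writeLines(c("code\tn_annotations", meta), paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  sp <- read_word2vec(path)
  meta_path <- paste0(path, ".meta.tsv")
  n_ann <- rep(1L, nrow(sp$vectors))
  names(n_ann) <- rownames(sp$vectors)
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, header = TRUE,
                              stringsAsFactors = FALSE)
    n_ann[meta$code] <- as.integer(meta$n_annotations)
  }
  new_centroid_index(sp$vectors, n_ann)
}

#' Convert an Alpha-ID-style pipe-delimited catalog to the thesaurus TSV
#'
#' National diagnosis catalogs distribute as pipe-delimited tables with
#' several metadata columns around the ICD code and the natural-language
#' term. This converter extracts two columns into the `code<TAB>annotation`
#' dialect that [read_thesaurus()] consumes. It is a deliberately thin
#' adapter: field positions vary between catalog releases, so they are
#' arguments, and rows without a valid ICD code in the chosen field (e.g.
#' unencodable terms) are dropped silently.
#'
#' @param path Pipe-delimited input file, UTF-8.
#' @param out_path Output TSV path.
#' @param code_field 1-based index of the ICD-10 code column (default 3).
#' @param text_field 1-based index of the annotation text column; default
#'   `NULL` takes the last column.
#' @return `out_path`, invisibly; attribute `n_converted` carries the row
#'   count.
#' @export
alpha_id_to_tsv <- function(path, out_path, code_field = 3,
                            text_field = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "|", fixed = TRUE)
  rows <- purrr::map_chr(parts, function(p) {
    tf <- if (is.null(text_field)) length(p) else text_field
    if (length(p) < max(code_field, tf)) return(NA_character_)
    code <- trimws(p[[code_field]])
    text <- trimws(p[[tf]])
    if (!is_valid_icd(code) || !nzchar(text)) return(NA_character_)
    paste0(code, "\t", text)
  })
  rows <- rows[!is.na(rows)]
  writeLines(rows, out_path, useBytes = TRUE)
  res <- out_path
  attr(res, "n_converted") <- length(rows)
  invisible(res)
}
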