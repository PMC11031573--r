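#' Read gold labels from a TSV file
#'
#' Each line is `query<TAB>true_code`. Codes are validated; a malformed line
#' is an error naming the line number, because silently dropping gold labels
#' would bias every rate computed downstream.
#'
#' @param path Path to the gold TSV.
#' @return Tibble with columns `query`, `true_code`.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    abort("Gold file contains no records.", class = "icdvec_empty_input_error")
  }
  has_tab <- grepl("\t", lines, fixed = TRUE)
  query <- sub("\t.*$", "", lines)
  code <- trimws(sub("^[^\t]*\t", "", lines))
  bad <- !has_tab | !is_valid_icd(code)
  if (any(bad)) {
    abort(sprintf("Malformed gold line %d: '%s'.",
                  lineno[which(bad)[1]], lines[which(bad)[1]]),
          class = "icdvec_format_error")
  }
  tibble::tibble(query = query, true_code = code)
}

#' Score predictions against gold codes at both correctness levels
#'
#' Two grades per record: `cc` ("completely correct") is an exact string
#' match between the accepted predicted code and the gold code; `c`
#' ("correct") only requires agreement of the 3-character superordinate
#' disease group, so e.g. a rhegmatogenous retinal detachment coded as a
#' serous one (H33.0 vs H33.2) is `c` but not `cc`. Rejected or no-vector
#' predictions score `FALSE` on both.
#'
#' @param predictions Tibble from [infer_codes()] (needs `query`, `code`,
#'   `accepted`).
#' @param gold Tibble with `query` and `true_code`, aligned row-by-row with
#'   `predictions`.
#' @return Tibble of evaluation records: `query`, `predicted`, `gold`, `cc`,
#'   `c`.
#' @export
score_predictions <- function(predictions, gold) {
  stopifnot(is.data.frame(predictions), is.data.frame(gold))
  if (nrow(predictions) != nrow(gold)) {
    abort("`predictions` and `gold` must have the same number of rows.",
          class = "icdvec_config_error")
  }
  if (!all(predictions$query == gold$query)) {
    abort("`predictions` and `gold` are not aligned on `query`.",
          class = "icdvec_config_error")
  }
  bad <- !is_valid_icd(gold$true_code)
  if (any(bad)) {
    abort(sprintf("Invalid gold code '%s'.", gold$true_code[which(bad)[1]]),
          class = "icdvec_validation_error")
  }
  predicted <- ifelse(predictions$accepted, predictions$code, NA_character_)
  usable <- !is.na(predicted)
  cc <- usable & predicted == gold$true_code
  cc[is.na(cc)] <- FALSE
  c_lvl <- cc
  c_lvl[usable] <- substr(predicted[usable], 1, 3) ==
    icd_group(gold$true_code)[usable]
  tibble::tibble(
    query = gold$query,
    predicted = predicted,
    gold = gold$true_code,
    cc = cc,
    c = c_lvl
  )
}

#' Summarize evaluation records into a two-level accuracy report
#'
#' Overall CC ("completely correct", exact code) and C ("correct",
#' 3-character group) rates as percentages of all records, plus a per-group
#' CC-accuracy table keyed by the gold code's group. Groups occurring
#' `min_group_n` times or fewer are excluded from the table (default 3,
#' i.e. a group needs more than three gold occurrences to be reported);
#' their records still count toward the overall rates. Rows are sorted by
#' CC accuracy, descending, then group.
#'
#' @param records Tibble from [score_predictions()].
#' @param min_group_n Exclusion threshold: per-group rows require
#'   `n > min_group_n`.
#' @return An `eval_report` with fields `n`, `cc_rate`, `c_rate`,
#'   `per_group`, `min_group_n`.
#' @export
summarize_eval <- function(records, min_group_n = 3) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    abort("No evaluation records.", class = "icdvec_empty_input_error")
  }
  stopifnot(all(c("gold", "cc", "c") %in% names(records)))
  per_group <- records |>
    dplyr::mutate(group = icd_group(.data$gold)) |>
    dplyr::summarise(
      n = dplyr::n(),
      cc_accuracy = 100 * mean(.data$cc),
      .by = "group"
    ) |>
    dplyr::filter(.data$n > min_group_n) |>
    dplyr::arrange(dplyr::desc(.data$cc_accuracy), .data$group)
  structure(
    list(
      n = nrow(records),
      cc_rate = 100 * mean(records$cc),
      c_rate = 100 * mean(records$c),
      per_group = per_group,
      min_group_n = min_group_n
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n = %d>\n", x$n))
  cat(sprintf("  completely correct (CC): %.1f%%\n", x$cc_rate))
  cat(sprintf("  correct at group level (C): %.1f%%\n", x$c_rate))
  cat(sprintf("  per-group table: %d groups (each with n > %d)\n",
              nrow(x$per_group), x$min_group_n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$per_group

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    cc_rate = x$cc_rate,
    c_rate = x$c_rate,
    n_groups = nrow(x$per_group),
    min_group_n = x$min_group_n
  )
}

#' Write / read an evaluation report as TSV
#'
#' The body mirrors the per-group accuracy table (columns `group`, `n`,
#' `cc_accuracy`); the overall figures travel in `#key value` header comments
#' so that a read round-trips the whole report.
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @return `write_eval_report` returns `path` invisibly; `read_eval_report`
#'   returns an `eval_report`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  hdr <- c(
    sprintf("#n %d", report$n),
    sprintf("#cc_rate %.10g", report$cc_rate),
    sprintf("#c_rate %.10g", report$c_rate),
    sprintf("#min_group_n %d", report$min_group_n),
    "group\tn\tcc_accuracy"
  )
  body <- sprintf("%s\t%d\t%.10g", report$per_group$group,
                  report$per_group$n, report$per_group$cc_accuracy)
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, " "))]
    if (length(hit) != 1) {
      abort(sprintf("Report is missing '#%s' header.", key),
            class = "icdvec_format_error")
    }
    as.numeric(sub(paste0("^#", key, " "), "", hit))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[-1]  # column header
  per_group <- if (length(body) == 0) {
    tibble::tibble(group = character(), n = integer(),
                   cc_accuracy = double())
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      abort("Malformed report row.", class = "icdvec_format_error")
    }
    tibble::tibble(
      group = vapply(parts, `[`, "", 1),
      n = as.integer(vapply(parts, `[`, "", 2)),
      cc_accuracy = as.numeric(vapply(parts, `[`, "", 3))
    )
  }
  structure(
    list(
      n = as.integer(get_meta("n")),
      cc_rate = get_meta("cc_rate"),
      c_rate = get_meta("c_rate"),
      per_group = per_group,
      min_group_n = as.integer(get_meta("min_group_n"))
    ),
    class = "eval_report"
  )
}
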