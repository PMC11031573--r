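mk_preds <- function(codes, accepted = TRUE) {
  tibble::tibble(
    query = sprintf("q%d", seq_along(codes)),
    code = codes,
    distance = ifelse(is.na(codes), NA_real_, 0.1),
    accepted = accepted & !is.na(codes),
    n_oov = 0L
  )
}

mk_gold <- function(codes) {
  tibble::tibble(query = sprintf("q%d", seq_along(codes)), true_code = codes)
}

test_that("scoring distinguishes exact-code from group-level correctness", {
  preds <- mk_preds(c("H33.0", "H40.5", NA, "H25.0"))
  gold <- mk_gold(c("H33.2", "H40.5", "H25.0", "I10"))
  rec <- score_predictions(preds, gold)
  # retinal detachment example: same H33 group, different subcode
  expect_equal(rec$cc, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(rec$c, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("rejected predictions score false at both levels", {
  preds <- mk_preds(c("H33.0", "H33.0"), accepted = c(TRUE, FALSE))
  gold <- mk_gold(c("H33.0", "H33.0"))
  rec <- score_predictions(preds, gold)
  expect_equal(rec$cc, c(TRUE, FALSE))
  expect_equal(rec$c, c(TRUE, FALSE))
  expect_true(is.na(rec$predicted[2]))
})

test_that("cc implies c on every record, fuzzed over random prediction pairs", {
  withr::with_seed(14, {
    codes <- c("H33.0", "H33.2", "H40.5", "H25.0", "I10", NA)
    for (i in 1:30) {
      n <- sample(2:12, 1)
      preds <- mk_preds(sample(codes, n, replace = TRUE),
                        accepted = sample(c(TRUE, FALSE), n, replace = TRUE))
      gold <- mk_gold(sample(codes[!is.na(codes)], n, replace = TRUE))
      rec <- score_predictions(preds, gold)
      expect_true(all(rec$c[rec$cc]))
      rep <- summarize_eval(rec)
      expect_lte(rep$cc_rate, rep$c_rate)
      expect_gte(rep$cc_rate, 0)
      expect_lte(rep$c_rate, 100)
    }
  })
})

test_that("summary rates are percentages over all records", {
  rec <- score_predictions(mk_preds(rep("H33.0", 4)),
                           mk_gold(c("H33.0", "H33.0", "H33.2", "I10")))
  rep <- summarize_eval(rec, min_group_n = 0)
  expect_equal(rep$n, 4)
  expect_equal(rep$cc_rate, 50)
  expect_equal(rep$c_rate, 75)
  # all-correct batch
  rep2 <- summarize_eval(score_predictions(mk_preds(rep("H40.5", 10)),
                                           mk_gold(rep("H40.5", 10))))
  expect_equal(rep2$cc_rate, 100)
  expect_equal(rep2$c_rate, 100)
})

test_that("rates are invariant under record permutation", {
  withr::with_seed(5, {
    rec <- score_predictions(
      mk_preds(sample(c("H33.0", "H40.5"), 20, replace = TRUE)),
      mk_gold(sample(c("H33.0", "H40.5"), 20, replace = TRUE))
    )
    rep1 <- summarize_eval(rec)
    rep2 <- summarize_eval(rec[sample(nrow(rec)), ])
    expect_equal(rep1$cc_rate, rep2$cc_rate)
    expect_equal(rep1$c_rate, rep2$c_rate)
  })
})

test_that("groups at or below the exclusion threshold are absent from the table", {
  # H33 occurs 4 times, H40 exactly 3 times, I10 once
  gold_codes <- c(rep("H33.0", 4), rep("H40.5", 3), "I10")
  rec <- score_predictions(mk_preds(gold_codes), mk_gold(gold_codes))
  rep <- summarize_eval(rec, min_group_n = 3)
  expect_equal(rep$per_group$group, "H33")
  # excluded records still count toward the overall rates
  expect_equal(rep$n, 8)
  expect_lte(sum(rep$per_group$n), rep$n)
  # threshold is configurable
  rep0 <- summarize_eval(rec, min_group_n = 0)
  expect_setequal(rep0$per_group$group, c("H33", "H40", "I10"))
})

test_that("per-group rows sort by accuracy then group", {
  preds <- mk_preds(c(rep("H33.0", 4), rep("H40.5", 4), rep("H25.0", 4)))
  gold <- mk_gold(c(rep("H33.0", 4), rep("H40.5", 2), rep("H40.1", 2),
                    rep("H25.0", 4)))
  rep <- summarize_eval(score_predictions(preds, gold))
  expect_equal(rep$per_group$group, c("H25", "H33", "H40"))
  expect_equal(rep$per_group$cc_accuracy, c(100, 100, 50))
})

test_that("summarize rejects empty input and misaligned frames error", {
  expect_error(summarize_eval(mk_preds(character())[0, ]),
               class = "icdvec_empty_input_error")
  expect_error(score_predictions(mk_preds("H33.0"), mk_gold(c("H33.0", "I10"))),
               class = "icdvec_config_error")
})

test_that("gold files parse, validate codes, and name bad lines", {
  f <- withr::local_tempfile(lines = c("Amotio\tH33.0", "Katarakt\tH25.1"))
  g <- read_gold(f)
  expect_equal(nrow(g), 2)
  expect_equal(g$true_code, c("H33.0", "H25.1"))

  f2 <- withr::local_tempfile(lines = c("Amotio\tH33.0", "Katarakt\tBAD"))
  expect_error(read_gold(f2), "line 2", class = "icdvec_format_error")

  f3 <- withr::local_tempfile(lines = character())
  expect_error(read_gold(f3), class = "icdvec_empty_input_error")
})

test_that("evaluation reports round-trip through TSV", {
  rec <- score_predictions(
    mk_preds(c(rep("H33.0", 5), rep("H40.5", 5))),
    mk_gold(c(rep("H33.0", 4), "H33.2", rep("H40.5", 5)))
  )
  rep <- summarize_eval(rec)
  f <- withr::local_tempfile()
  write_eval_report(rep, f)
  rep2 <- read_eval_report(f)
  expect_equal(rep2$n, rep$n)
  expect_equal(rep2$cc_rate, rep$cc_rate)
  expect_equal(rep2$c_rate, rep$c_rate)
  expect_equal(rep2$min_group_n, rep$min_group_n)
  expect_equal(as.data.frame(rep2$per_group), as.data.frame(rep$per_group))
})

test_that("tidy, glance and autoplot expose the report", {
  rec <- score_predictions(mk_preds(rep("H33.0", 5)), mk_gold(rep("H33.0", 5)))
  rep <- summarize_eval(rec)
  expect_named(glance(rep), c("n", "cc_rate", "c_rate", "n_groups",
                              "min_group_n"))
  expect_identical(tidy(rep), rep$per_group)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
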