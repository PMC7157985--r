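stage1 <- confusion_counts(50084, 6022, 161478, 67217)
stage2 <- confusion_counts(85838, 11291, 222938, 82994)

test_that("outcome classification follows the display-by-condition taxonomy", {
  modeled <- c("I25.101", "I10 06")
  expect_identical(classify_outcome("I25.101", "I25.101", modeled), "TP")
  expect_identical(classify_outcome("I25.101", "I10 06", modeled), "FP")
  expect_identical(classify_outcome(NA, "I10 06", modeled), "FN")
  expect_identical(classify_outcome(NA, "Z51.005", modeled), "TN")
})

test_that("audit tabulation matches an independent per-record tally", {
  corpus <- generate_corpus(corpus_spec(n_codes = 60, n_records = 500,
                                        coverage = 0.5, ambiguity_rate = 0.1,
                                        seed = 77))
  run <- code_batch(compile_rulebase(corpus$rulebase), corpus$records,
                    clock = function() "t0")
  cc <- tabulate_outcomes(run, modeled = corpus$modeled)
  emitted <- run$assignments$code[match(corpus$records$record_id,
                                        run$assignments$record_id)]
  ref <- naive_tally(emitted, corpus$records$gold_code, corpus$modeled)
  expect_identical(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn), ref)
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, nrow(corpus$records))

  bad <- corpus$records
  bad$gold_code[3] <- NA
  expect_error(tabulate_outcomes(run, bad, corpus$modeled), "R000003")
})

test_that("published two-stage confusion counts yield the reported metrics", {
  expect_identical(precision(stage1), 89.27)
  expect_identical(recall(stage1), 23.67)
  expect_identical(f_measure(precision(stage1), recall(stage1)), 37.42)
  expect_identical(accuracy(stage1), 41.19)

  expect_identical(precision(stage2), 88.38)
  expect_identical(accuracy(stage2), 41.89)
  # stage-2 recall derived from the counts themselves
  expect_identical(recall(stage2), 27.80)
  # and F satisfies the harmonic-mean identity on those counts
  expect_identical(f_measure(precision(stage2), recall(stage2)),
                   round(2 * 88.38 * 27.80 / (88.38 + 27.80) * 100) / 100)
})

test_that("degenerate counts give explicit undefined markers, not 0 or 100", {
  expect_true(is.na(precision(confusion_counts(0, 0, 5, 5))))
  expect_true(is.na(recall(confusion_counts(0, 3, 0, 2))))
  expect_true(is.na(f_measure(NA_real_, 50)))
  expect_true(is.na(f_measure(0, 50)))
  m <- metrics_report(confusion_counts(0, 0, 5, 5))
  expect_true(is.na(m$precision_pct))
  expect_identical(m$accuracy_pct, 50)
})

test_that("simple symmetric counts give 50 percent everywhere", {
  m <- metrics_report(confusion_counts(1, 1, 1, 1))
  expect_identical(c(m$precision_pct, m$recall_pct, m$f_pct, m$accuracy_pct),
                   c(50, 50, 50, 50))
  expect_identical(accuracy(confusion_counts(0, 0, 0, 5)), 100)
})

test_that("F is a weighted harmonic mean: equals endpoints' mean behaviour", {
  # harmonic mean of equals is that value
  expect_identical(f_measure(50, 50), 50)
  # monotone in alpha between r (alpha -> 0) and p (alpha -> 1) when p > r
  p <- 89.27; r <- 23.67
  grid <- seq(0.01, 0.99, by = 0.01)
  f <- vapply(grid, function(a) f_measure(p, r, a, digits = NA), numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f > r & f < p))
})

test_that("metric monotonicity: TPs help, FPs hurt", {
  withr::with_seed(5, {
    for (i in 1:50) {
      cc <- confusion_counts(sample(0:500, 1) + 1, sample(0:500, 1),
                             sample(0:500, 1), sample(0:500, 1))
      plus_tp <- confusion_counts(cc$tp + 1, cc$fp, cc$fn, cc$tn)
      plus_fp <- confusion_counts(cc$tp, cc$fp + 1, cc$fn, cc$tn)
      expect_gte(precision(plus_tp, NA), precision(cc, NA))
      expect_gte(recall(plus_tp, NA), recall(cc, NA))
      expect_gte(accuracy(plus_tp, NA), accuracy(cc, NA))
      expect_lte(precision(plus_fp, NA), precision(cc, NA))
      expect_lte(accuracy(plus_fp, NA), accuracy(cc, NA))
    }
  })
})

test_that("frequency ranking counts, orders and tie-breaks deterministically", {
  codes <- c(rep("I25.101", 3), "A09.901")
  ft <- code_frequency(codes, 2)
  expect_identical(ft$code, c("I25.101", "A09.901"))
  expect_identical(ft$count, c(3L, 1L))
  expect_identical(ft$rank, 1:2)

  # equal counts -> lexicographic order
  ft <- code_frequency(c("B01.001", "A02.002", "C03.003"))
  expect_identical(ft$code, c("A02.002", "B01.001", "C03.003"))

  expect_identical(nrow(code_frequency(character(0))), 0L)

  withr::with_seed(8, {
    codes <- sample(sprintf("A%02d.%03d", 0:30, 0:30), 5000, replace = TRUE)
    ft <- code_frequency(codes)
    ref <- table(codes)
    expect_identical(sum(ft$count), length(codes))
    expect_true(all(diff(ft$count) <= 0))
    for (j in seq_len(nrow(ft))) {
      expect_identical(ft$count[j], as.integer(ref[[ft$code[j]]]))
    }
  })
})

test_that("chapter summary conserves occurrences and categories", {
  cs <- cluster_summary(c("I25.101", "I10 06", "K22.902"))
  expect_identical(cs$cluster, c("I", "K"))
  expect_identical(cs$n_categories, c(2L, 1L))
  expect_identical(cs$n_codes, c(2L, 1L))
  expect_identical(nrow(cluster_summary(character(0))), 0L)
  expect_error(cluster_summary(c("I25.101", "bogus")), "bogus")

  corpus <- generate_corpus(corpus_spec(n_codes = 80, n_records = 600,
                                        coverage = 0.4, seed = 31,
                                        ambiguity_rate = 0))
  cs <- cluster_summary(corpus$records$gold_code)
  expect_identical(sum(cs$n_codes), nrow(corpus$records))
  expect_identical(sum(cs$n_categories),
                   length(unique(corpus$records$gold_code)))
})

test_that("failure breakdown reports mismatch, loss and per-group repeats", {
  # two groups; one group receives the same code twice
  rb <- rulebase(c("I10 06", "E11.901"), c("hyper", "diab"))
  crb <- compile_rulebase(rb)
  records <- data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    description = c("hyper", "hyper", "diab", "unknown thing"),
    gold_code = c("I10 06", "I10 06", "I10 06", "E11.901"),
    group_id = c("g1", "g1", "g2", "g2"),
    stringsAsFactors = FALSE)
  run <- code_batch(crb, records, clock = function() "t0")
  fb <- failure_breakdown(run, modeled = rb$code)
  # r3 assigned E11.901 vs gold I10 06 -> 1 mismatch; r4 unmatched with
  # modeled gold -> 1 loss; r1+r2 same code in g1 -> 1 repeat
  expect_identical(fb$repeated, 1L)
  expect_identical(fb$mismatch, 1L)
  expect_identical(fb$loss, 1L)
  cc <- tabulate_outcomes(run, modeled = rb$code)
  expect_identical(fb$mismatch, cc$fp)
  expect_identical(fb$loss, cc$fn)

  none <- failure_breakdown(
    code_batch(crb, records[c(1, 3), c("record_id", "description",
                                       "gold_code")],
               clock = function() "t0"),
    modeled = rb$code)
  expect_identical(none$repeated, 0L)
})

test_that("evaluation report JSON carries counts, metrics and analytics", {
  tf <- withr::local_tempfile(fileext = ".json")
  m <- metrics_report(stage1)
  write_evaluation_report(m, tf,
                          frequency = code_frequency(c("A00.001", "A00.001")),
                          clusters = cluster_summary(c("A00.001")))
  got <- jsonlite::fromJSON(tf)
  expect_identical(got$metrics$precision, "89.27")
  expect_identical(got$counts$tp, 50084L)
  expect_identical(got$frequency_table$count, 2L)
})
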