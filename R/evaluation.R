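#' Confusion counts for a coding audit
#'
#' The audit taxonomy crosses whether the system automatically displayed
#' a code against whether the record's true code was modelable at all:
#' TP = correct automatic code; FP = wrong automatic code; FN = no
#' automatic code although the gold code is in the modeled set; TN = no
#' automatic code and the gold code is outside the modeled set (correct
#' absence — the system was never given a rule for it).
#'
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @return object of class `icd_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(length(counts) == 4L, !anyNA(counts), all(counts >= 0),
            all(counts == floor(counts)))
  structure(as.list(counts), class = "icd_confusion")
}

#' @export
print.icd_confusion <- function(x, ...) {
  cat(sprintf("<icd_confusion> TP %d  FP %d  FN %d  TN %d  (total %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Classify one record's coding outcome
#'
#' @param emitted the automatically assigned code, or `NA` when the
#'   system emitted nothing (no match / ambiguous).
#' @param gold the record's true code.
#' @param modeled character vector of codes the rule base models.
#' @return one of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
classify_outcome <- function(emitted, gold, modeled) {
  stopifnot(length(gold) == 1L, !is.na(gold))
  if (!is.na(emitted)) {
    if (emitted == gold) "TP" else "FP"
  } else {
    if (gold %in% modeled) "FN" else "TN"
  }
}

#' Audit a coding run against gold codes
#'
#' @param run an [code_batch()] result.
#' @param records data frame with `record_id` and `gold_code` for every
#'   processed record (defaults to the batch stored on the run).
#' @param modeled modeled-code set; defaults to the union of codes the
#'   run could have assigned is not stored, so pass the rule base codes.
#' @return an `icd_confusion`; tp+fp+fn+tn equals the number of records.
#' @export
tabulate_outcomes <- function(run, records = run$records, modeled) {
  stopifnot(inherits(run, "icd_coding_run"), is.data.frame(records),
            all(c("record_id", "gold_code") %in% names(records)))
  missing_gold <- records$record_id[is.na(records$gold_code)]
  if (length(missing_gold)) {
    stop(sprintf("record(s) lacking a gold code: %s",
                 paste(utils::head(missing_gold, 5L), collapse = ", ")),
         call. = FALSE)
  }
  emitted <- run$assignments$code[match(records$record_id,
                                        run$assignments$record_id)]
  lab <- vapply(seq_len(nrow(records)), function(i)
    classify_outcome(emitted[i], records$gold_code[i], modeled), character(1))
  confusion_counts(sum(lab == "TP"), sum(lab == "FP"),
                   sum(lab == "FN"), sum(lab == "TN"))
}

# exact half-up rounding of the rational (100 * num / den) to `digits`
# decimals; num, den integer-valued doubles (exact below 2^53)
pct_rational <- function(num, den, digits = 2L) {
  if (den == 0) return(NA_real_)
  if (is.na(digits)) return(100 * num / den)
  s <- 10^digits
  # floor((100*s*num/den) + 1/2) via integer arithmetic, exact below 2^53
  q <- (200 * s * num + den) %/% (2 * den)
  q / s
}

round_half_up <- function(x, digits = 2L) {
  if (is.na(digits)) return(x)
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Precision, recall, F-measure and accuracy of a coding audit
#'
#' All four are percentages in \[0, 100\]. Precision is
#' `100*TP/(TP+FP)`, recall `100*TP/(TP+FN)`, accuracy
#' `100*(TP+TN)/(TP+FP+FN+TN)`. The F-measure is the weighted harmonic
#' mean of precision and recall,
#' `1 / (alpha/P + (1-alpha)/R)` (on proportions), which at the default
#' `alpha = 0.5` reduces to the familiar `2PR/(P+R)`.
#'
#' Count-based metrics are computed on exact rationals and rounded
#' half-up to `digits` decimals only at reporting; pass `digits = NA` for
#' the full-precision value. A zero denominator yields `NA` — an
#' explicit undefined-metric marker, never silently 0 or 100.
#'
#' @param cc an `icd_confusion`.
#' @param digits decimal places for half-up rounding (default 2,
#'   `NA` = no rounding).
#' @return a percentage, or `NA_real_` when undefined.
#' @examples
#' cc <- confusion_counts(50084, 6022, 161478, 67217)
#' precision(cc)  # 89.27
#' recall(cc)     # 23.67
#' @export
precision <- function(cc, digits = 2L) {
  stopifnot(inherits(cc, "icd_confusion"))
  pct_rational(cc$tp, cc$tp + cc$fp, digits)
}

#' @rdname precision
#' @export
recall <- function(cc, digits = 2L) {
  stopifnot(inherits(cc, "icd_confusion"))
  pct_rational(cc$tp, cc$tp + cc$fn, digits)
}

#' @rdname precision
#' @export
accuracy <- function(cc, digits = 2L) {
  stopifnot(inherits(cc, "icd_confusion"))
  pct_rational(cc$tp + cc$tn, cc$tp + cc$fp + cc$fn + cc$tn, digits)
}

#' @rdname precision
#' @param p,r precision and recall percentages (typically already rounded
#'   to report precision).
#' @param alpha harmonic-mean weight on precision, in (0, 1); 0.5 weighs
#'   precision and recall equally.
#' @export
f_measure <- function(p, r, alpha = 0.5, digits = 2L) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.na(p) || is.na(r) || p <= 0 || r <= 0) return(NA_real_)
  f <- (p * r) / (alpha * r + (1 - alpha) * p)
  round_half_up(f, digits)
}

#' Full metrics report
#'
#' Composes precision, recall, F-measure and accuracy. The F-measure is
#' computed from the rounded precision and recall, matching how coding
#' reports are usually tabulated; undefined metrics propagate as `NA`.
#'
#' @inheritParams precision
#' @inheritParams f_measure
#' @return object of class `icd_metrics`: list with the four rounded
#'   percentages (`precision_pct`, `recall_pct`, `f_pct`,
#'   `accuracy_pct`), their full-precision counterparts (`*_full`),
#'   `alpha`, and the input `counts`.
#' @export
metrics_report <- function(cc, alpha = 0.5, digits = 2L) {
  stopifnot(inherits(cc, "icd_confusion"))
  p <- precision(cc, digits)
  r <- recall(cc, digits)
  structure(
    list(precision_pct = p, recall_pct = r,
         f_pct = f_measure(p, r, alpha, digits),
         accuracy_pct = accuracy(cc, digits),
         precision_full = precision(cc, NA), recall_full = recall(cc, NA),
         f_full = f_measure(precision(cc, NA), recall(cc, NA), alpha, NA),
         accuracy_full = accuracy(cc, NA),
         alpha = alpha, counts = cc),
    class = "icd_metrics")
}

#' @export
print.icd_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("<icd_metrics> P %s  R %s  F %s  A %s  (alpha %.2f)\n",
              fmt(x$precision_pct), fmt(x$recall_pct), fmt(x$f_pct),
              fmt(x$accuracy_pct), x$alpha))
  invisible(x)
}

#' Code frequency ranking
#'
#' Ranks codes by occurrence count (rank 1 = most frequent); ties are
#' broken by lexicographic code order so the ranking is deterministic.
#'
#' @param codes character vector (multiset) of code occurrences.
#' @param top_n number of top entries to keep (default: all).
#' @return data frame `code`, `count`, `rank` with counts non-increasing.
#' @export
code_frequency <- function(codes, top_n = Inf) {
  stopifnot(top_n >= 1)
  if (length(codes) == 0L) {
    return(data.frame(code = character(0), count = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(codes)
  ord <- order(-as.integer(tab), names(tab))
  k <- min(length(tab), top_n)
  out <- data.frame(code = names(tab)[ord][seq_len(k)],
                    count = as.integer(tab)[ord][seq_len(k)],
                    rank = seq_len(k), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-chapter (cluster) code summary
#'
#' Groups code occurrences by ICD-10 chapter — the leading letter A--Z —
#' and reports, per chapter, the number of distinct code categories and
#' the total number of occurrences.
#'
#' @param codes character vector (multiset) of syntactically valid codes.
#' @return data frame `cluster`, `n_categories`, `n_codes`, sorted by
#'   chapter letter. Column sums conserve the input: `sum(n_codes)`
#'   equals `length(codes)` and `sum(n_categories)` the number of
#'   distinct codes.
#' @export
cluster_summary <- function(codes) {
  if (length(codes) == 0L) {
    return(data.frame(cluster = character(0), n_categories = integer(0),
                      n_codes = integer(0), stringsAsFactors = FALSE))
  }
  assert_valid_codes(codes)
  cl <- substr(codes, 1L, 1L)
  clusters <- sort(unique(cl))
  out <- data.frame(
    cluster = clusters,
    n_categories = vapply(clusters, function(k)
      length(unique(codes[cl == k])), integer(1)),
    n_codes = vapply(clusters, function(k) sum(cl == k), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Failure breakdown of an audited run
#'
#' The audit step hands three kinds of failed codes back to the rule
#' maintainers: mismatch codes (wrong automatic code, the audit's FP
#' count), loss codes (missing automatic code whose gold code was
#' modeled, the FN count), and repeated codes — the same code assigned
#' more than once within one patient group, which single-record matching
#' cannot see but the per-patient audit can.
#'
#' @inheritParams tabulate_outcomes
#' @return object of class `icd_failures`: list with counts `repeated`,
#'   `mismatch`, `loss`.
#' @export
failure_breakdown <- function(run, records = run$records, modeled) {
  cc <- tabulate_outcomes(run, records, modeled)
  repeated <- 0L
  grp <- records$group_id[match(run$assignments$record_id, records$record_id)]
  has_grp <- !is.na(grp)
  if (any(has_grp)) {
    key <- paste(grp[has_grp], run$assignments$code[has_grp], sep = "\r")
    repeated <- sum(table(key) > 1L)
  }
  structure(list(repeated = repeated, mismatch = cc$fp, loss = cc$fn),
            class = "icd_failures")
}

#' @export
print.icd_failures <- function(x, ...) {
  cat(sprintf("<icd_failures> repeated %d  mismatch %d  loss %d\n",
              x$repeated, x$mismatch, x$loss))
  invisible(x)
}

#' Write a JSON evaluation report
#'
#' @param metrics an `icd_metrics`.
#' @param path output path.
#' @param failures optional `icd_failures`.
#' @param frequency optional [code_frequency()] table.
#' @param clusters optional [cluster_summary()] table.
#' @return invisibly, `path`.
#' @export
write_evaluation_report <- function(metrics, path, failures = NULL,
                                    frequency = NULL, clusters = NULL) {
  stopifnot(inherits(metrics, "icd_metrics"))
  fmt2 <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  body <- list(
    counts = list(tp = metrics$counts$tp, fp = metrics$counts$fp,
                  fn = metrics$counts$fn, tn = metrics$counts$tn),
    alpha = metrics$alpha,
    metrics = list(
      precision = fmt2(metrics$precision_pct), recall = fmt2(metrics$recall_pct),
      f_measure = fmt2(metrics$f_pct), accuracy = fmt2(metrics$accuracy_pct)),
    metrics_full = list(
      precision = metrics$precision_full, recall = metrics$recall_full,
      f_measure = metrics$f_full, accuracy = metrics$accuracy_full))
  if (!is.null(failures)) {
    body$failure_breakdown <- list(repeated = failures$repeated,
                                   mismatch = failures$mismatch,
                                   loss = failures$loss)
  }
  if (!is.null(frequency)) body$frequency_table <- frequency
  if (!is.null(clusters)) body$cluster_summary <- clusters
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
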