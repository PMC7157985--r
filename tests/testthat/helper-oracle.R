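# Independent oracles used across tests.

# naive all-rules scan: per-record loop over every rule with scalar
# regexpr(), no shared state with the package's batch matcher
naive_match <- function(rb, text, config = normalization_config(),
                        anchored = FALSE) {
  norm <- normalize_description(text, config)
  hits <- character(0)
  for (i in seq_len(nrow(rb))) {
    pat <- rb$pattern[i]
    if (anchored) pat <- sprintf("^(?:%s)$", pat)
    if (regexpr(pat, norm, perl = TRUE)[[1L]] > 0L) hits <- c(hits, rb$code[i])
  }
  hits <- sort(hits)
  list(status = if (length(hits) == 1L) "unique"
                else if (length(hits) == 0L) "no_match" else "ambiguous",
       candidates = hits)
}

# second-pass per-record outcome tally, independent of tabulate_outcomes()
naive_tally <- function(emitted, gold, modeled) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(gold)) {
    if (!is.na(emitted[i])) {
      if (emitted[i] == gold[i]) tp <- tp + 1L else fp <- fp + 1L
    } else if (gold[i] %in% modeled) fn <- fn + 1L else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small hand-built rule base reused by several files
toy_rulebase <- function() {
  rulebase(
    code = c("I10 06", "E11.901", "A09.901"),
    pattern = c("hypertension( grade (I|II|III))?", "type 2 diabetes",
                "^(acute )?gastroenteritis$"),
    canonical_label = c("hypertension grade III", "type 2 diabetes",
                        "acute gastroenteritis"))
}

# per-record match status of a coding run, aligned to `ids`
run_statuses <- function(run, ids) {
  ifelse(ids %in% run$assignments$record_id, "unique",
         run$failure_log$reason[match(ids, run$failure_log$record_id)])
}
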