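#' Read a batch of diagnosis records
#'
#' Record files are UTF-8, tab-delimited, with a header naming
#' `record_id` and `description` and optionally `gold_code` and
#' `group_id` (patient/admission grouping). `#` comment lines and blank
#' lines are skipped.
#'
#' @param path file path.
#' @return data frame with columns `record_id`, `description`,
#'   `gold_code`, `group_id` (the optional columns are `NA` when absent
#'   from the file).
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    return(data.frame(record_id = character(0), description = character(0),
                      gold_code = character(0), group_id = character(0),
                      stringsAsFactors = FALSE))
  }
  header <- trimws(strsplit(lines[[keep[1L]]], "\t", fixed = TRUE)[[1L]])
  if (!all(c("record_id", "description") %in% header)) {
    stop("record file header must name 'record_id' and 'description'",
         call. = FALSE)
  }
  body <- keep[-1L]
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  col <- function(name) {
    i <- match(name, header)
    if (is.na(i)) return(rep(NA_character_, length(body)))
    out <- vapply(fields, function(f) if (i <= length(f)) f[[i]] else "",
                  character(1))
    out[!nzchar(out)] <- NA_character_
    out
  }
  data.frame(record_id = col("record_id"), description = col("description"),
             gold_code = col("gold_code"), group_id = col("group_id"),
             stringsAsFactors = FALSE)
}

#' @rdname read_records
#' @param records a record data frame.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  na2empty <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- c("record_id\tdescription\tgold_code\tgroup_id",
             sprintf("%s\t%s\t%s\t%s",
                     na2empty(records$record_id), na2empty(records$description),
                     na2empty(records$gold_code), na2empty(records$group_id)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Match one description against a compiled rule base
#'
#' The description is normalized with the rule base's own normalization
#' config and tested against every rule. Exactly one matching code is a
#' unique assignment; zero is a `no_match`; two or more is `ambiguous`
#' (no tie-breaking is ever applied — multi-rule hits are audit work, not
#' guesses).
#'
#' @param crb an [compile_rulebase()] result.
#' @param text one free-text description.
#' @return list with `status` (`"unique"`, `"no_match"` or
#'   `"ambiguous"`), `assigned_code` (the code when unique, else `NA`),
#'   and `candidates` (all matching codes in code order).
#' @examples
#' rb <- rulebase(c("I10 06", "E11.901"),
#'                c("hypertension( grade (I|II|III))?", "type 2 diabetes"))
#' crb <- compile_rulebase(rb)
#' match_description(crb, "Hypertension grade III")
#' @export
match_description <- function(crb, text) {
  stopifnot(inherits(crb, "icd_compiled_rulebase"), length(text) == 1L)
  norm <- normalize_description(text, crb$config)
  hit <- vapply(crb$patterns, function(p) grepl(p, norm, perl = TRUE),
                logical(1), USE.NAMES = FALSE)
  candidates <- sort(crb$codes[hit])
  status <- if (length(candidates) == 1L) "unique"
            else if (length(candidates) == 0L) "no_match"
            else "ambiguous"
  list(status = status,
       assigned_code = if (status == "unique") candidates else NA_character_,
       candidates = candidates)
}

#' Batch automatic coding
#'
#' Runs the automatic-coding pass over a batch: every record is matched
#' independently; unique matches become assignments and coding-log
#' entries, no-match and ambiguous records become failure-log entries
#' with their candidate sets. Assignments and failures partition the
#' batch exactly.
#'
#' @param crb a compiled rule base.
#' @param records data frame with `record_id` (unique) and `description`
#'   columns; `gold_code`/`group_id` are carried through untouched.
#' @param clock zero-argument function returning the timestamp string to
#'   stamp coding-log entries with. Defaults to the wall clock; inject a
#'   constant for reproducible logs.
#' @return an object of class `icd_coding_run`: list with `assignments`
#'   (data frame `record_id`, `code`), `coding_log` (`record_id`, `code`,
#'   `ts`), `failure_log` (`record_id`, `reason`, `candidates` list
#'   column, `ts`), and `records` (the input batch).
#' @export
code_batch <- function(crb, records, clock = NULL) {
  stopifnot(inherits(crb, "icd_compiled_rulebase"), is.data.frame(records),
            all(c("record_id", "description") %in% names(records)))
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup)) {
    stop(sprintf("duplicate record_id in batch: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (is.null(clock)) clock <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  n <- nrow(records)
  norm <- normalize_description(records$description, crb$config)
  if (any(!nzchar(norm))) {
    stop(sprintf("description empty after normalization for record(s): %s",
                 paste(records$record_id[!nzchar(norm)], collapse = ", ")),
         call. = FALSE)
  }
  # rule-major pass: one vectorized grepl per pattern over the whole batch
  nhit <- integer(n)
  unique_code <- rep(NA_character_, n)
  cand <- vector("list", n)
  for (j in seq_along(crb$patterns)) {
    hit <- grepl(crb$patterns[[j]], norm, perl = TRUE)
    idx <- which(hit)
    nhit[idx] <- nhit[idx] + 1L
    unique_code[idx] <- crb$codes[[j]]
    for (i in idx) cand[[i]] <- c(cand[[i]], crb$codes[[j]])
  }
  ts <- clock()
  assigned <- which(nhit == 1L)
  failed <- which(nhit != 1L)
  assignments <- data.frame(record_id = records$record_id[assigned],
                            code = unique_code[assigned],
                            stringsAsFactors = FALSE)
  coding_log <- data.frame(record_id = assignments$record_id,
                           code = assignments$code,
                           ts = rep_len(ts, nrow(assignments)),
                           stringsAsFactors = FALSE)
  failure_log <- data.frame(
    record_id = records$record_id[failed],
    reason = ifelse(nhit[failed] == 0L, "no_match", "ambiguous"),
    ts = rep_len(ts, length(failed)),
    stringsAsFactors = FALSE)
  failure_log$candidates <- lapply(cand[failed], function(x)
    if (is.null(x)) character(0) else sort(x))
  structure(list(assignments = assignments, coding_log = coding_log,
                 failure_log = failure_log, records = records,
                 fingerprint = crb$fingerprint),
            class = "icd_coding_run")
}

#' @export
print.icd_coding_run <- function(x, ...) {
  cat(sprintf("<icd_coding_run> %d record(s): %d assigned, %d failed (%d no_match, %d ambiguous)\n",
              nrow(x$records), nrow(x$assignments), nrow(x$failure_log),
              sum(x$failure_log$reason == "no_match"),
              sum(x$failure_log$reason == "ambiguous")))
  invisible(x)
}

jsonl_lines <- function(rows) {
  vapply(rows, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null")),
    character(1))
}

#' Write coding-run artifacts
#'
#' Writes `assignments.tsv` (record_id, code), `coding_log.jsonl` and
#' `failure_log.jsonl` (one JSON object per line, stable field names
#' `record_id`, `code`/`reason`, `candidates`, `ts`) into `dir`.
#'
#' @param run an `icd_coding_run`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_coding_run <- function(run, dir) {
  stopifnot(inherits(run, "icd_coding_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_assign <- file.path(dir, "assignments.tsv")
  writeLines(c("record_id\tcode",
               sprintf("%s\t%s", run$assignments$record_id,
                       run$assignments$code)),
             p_assign)
  p_log <- file.path(dir, "coding_log.jsonl")
  rows <- lapply(seq_len(nrow(run$coding_log)), function(i)
    list(record_id = run$coding_log$record_id[i],
         code = run$coding_log$code[i],
         ts = run$coding_log$ts[i]))
  writeLines(jsonl_lines(rows), p_log)
  p_fail <- file.path(dir, "failure_log.jsonl")
  rows <- lapply(seq_len(nrow(run$failure_log)), function(i)
    list(record_id = run$failure_log$record_id[i],
         reason = run$failure_log$reason[i],
         candidates = run$failure_log$candidates[[i]],
         ts = run$failure_log$ts[i]))
  writeLines(jsonl_lines(rows), p_fail)
  invisible(c(p_assign, p_log, p_fail))
}
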