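#' Specify a synthetic coding corpus
#'
#' The generator emulates the structure of a hospital discharge-diagnosis
#' stream: a Zipf-skewed universe of code categories (high-frequency
#' codes concentrated in the top ranks), a rule base covering only the
#' most frequent fraction of codes (rules are built for high-frequency
#' categories first), descriptions that vary by synonym substitution,
#' optional qualifier tokens and spacing/width/case noise, and an
#' injectable rate of ambiguous records whose text matches a second rule.
#' Surface vocabulary is synthetic token strings, deliberately
#' language-neutral.
#'
#' @param n_codes number of code categories in the universe (default 500,
#'   the size of a high-frequency modeling set).
#' @param zipf_exponent Zipf exponent `s >= 0` of the frequency skew;
#'   rank-`k` weight is proportional to `k^-s`. 0 gives uniform weights;
#'   the default 1 reproduces the heavy concentration of occurrences in
#'   the top ~100 ranks seen in hospital code-frequency data.
#' @param n_records number of diagnosis records to generate.
#' @param coverage fraction in \[0, 1\] of codes given rules, selected
#'   from the most frequent downward.
#' @param ambiguity_rate fraction in \[0, 1\] of rule-covered records
#'   whose description is made to also match a second rule.
#' @param p_synonym probability a record uses the synonym surface form of
#'   its diagnosis rather than the primary one.
#' @param p_optional probability a record carries the optional qualifier
#'   token ("chronic ") its rule treats as optional.
#' @param p_noise probability a record's surface text gets spacing,
#'   full-width or letter-case noise (all undone by normalization).
#' @param records_per_group records per patient group (`group_id`);
#'   discharge records average about 6 diagnoses per patient. 0 disables
#'   grouping.
#' @param seed integer seed; all sampling is routed through it.
#' @return object of class `icd_corpus_spec`.
#' @export
corpus_spec <- function(n_codes = 500L, zipf_exponent = 1, n_records = 5000L,
                        coverage = 0.5, ambiguity_rate = 0.02,
                        p_synonym = 0.3, p_optional = 0.3, p_noise = 0.2,
                        records_per_group = 6L, seed = 1L) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_codes) && n_codes >= 1 && n_codes == floor(n_codes) &&
        n_codes <= 9999, "n_codes must be an integer in [1, 9999]")
  chk(is.numeric(zipf_exponent) && zipf_exponent >= 0,
      "zipf_exponent must be >= 0")
  chk(is.numeric(n_records) && n_records >= 1 && n_records == floor(n_records),
      "n_records must be a positive integer")
  for (f in c("coverage", "ambiguity_rate", "p_synonym", "p_optional",
              "p_noise")) {
    v <- get(f)
    chk(is.numeric(v) && v >= 0 && v <= 1, sprintf("%s must be in [0, 1]", f))
  }
  chk(is.numeric(records_per_group) && records_per_group >= 0,
      "records_per_group must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1L && !is.na(seed),
      "seed must be a single integer")
  if (length(problems)) {
    stop(paste(c("invalid corpus spec:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(n_codes = as.integer(n_codes),
                 zipf_exponent = zipf_exponent,
                 n_records = as.integer(n_records), coverage = coverage,
                 ambiguity_rate = ambiguity_rate, p_synonym = p_synonym,
                 p_optional = p_optional, p_noise = p_noise,
                 records_per_group = as.integer(records_per_group),
                 seed = as.integer(seed)),
            class = "icd_corpus_spec")
}

# universe body shared by generate_code_universe() and generate_corpus();
# caller owns the RNG state
universe_impl <- function(spec) {
  n <- spec$n_codes
  codes <- character(0)
  while (length(codes) < n) {
    need <- n - length(codes)
    letter <- sample(LETTERS, 2L * need + 8L, replace = TRUE)
    num <- sprintf("%02d", sample(0:99, length(letter), replace = TRUE))
    sub <- sprintf("%03d", sample(0:999, length(letter), replace = TRUE))
    ext <- stats::runif(length(letter)) < 0.1  # ~10% national extension style
    cand <- ifelse(ext,
                   paste0(letter, num, " ", sprintf("%02d", sample(0:99, length(letter), replace = TRUE))),
                   paste0(letter, num, ".", sub))
    codes <- unique(c(codes, cand))[seq_len(min(n, length(unique(c(codes, cand)))))]
  }
  rank <- seq_len(n)
  w <- rank^(-spec$zipf_exponent)
  data.frame(code = codes, rank = rank, weight = w / sum(w),
             stringsAsFactors = FALSE)
}

#' Generate the weighted code universe
#'
#' @param spec a [corpus_spec()].
#' @return data frame `code`, `rank`, `weight` with `n_codes` distinct,
#'   syntactically valid codes and normalized Zipf weights (rank 1 most
#'   frequent). Deterministic under the spec's seed.
#' @export
generate_code_universe <- function(spec) {
  stopifnot(inherits(spec, "icd_corpus_spec"))
  withr::with_seed(spec$seed, universe_impl(spec))
}

noise_impl <- function(text) {
  kind <- sample(3L, 1L)
  if (kind == 1L) {
    # widen one internal space
    sub(" ", "   ", text, fixed = TRUE)
  } else if (kind == 2L) {
    # upper-case a random prefix
    k <- sample(nchar(text), 1L)
    paste0(toupper(substr(text, 1L, k)), substr(text, k + 1L, nchar(text)))
  } else {
    # full-width the first character and pad the ends
    first <- utf8ToInt(substr(text, 1L, 1L))
    wide <- if (first >= 0x21 && first <= 0x7E) intToUtf8(first + 0xFEE0)
            else substr(text, 1L, 1L)
    paste0(" ", wide, substr(text, 2L, nchar(text)), " ")
  }
}

#' Generate a gold-labelled synthetic corpus
#'
#' Each code gets a unique fixed-width token pair (primary + synonym);
#' covered codes get the rule
#' `"(chronic )?(<primary>|<synonym>) disorder"`, whose construct set
#' stays inside the guaranteed dialect. Record descriptions are built
#' from their gold code's tokens, so by construction an in-coverage,
#' non-ambiguous record matches exactly its own rule, an
#' ambiguity-injected record (its text gains a second rule's token
#' phrase) matches at least two rules, and an out-of-coverage record
#' matches none.
#'
#' @param spec a [corpus_spec()].
#' @return object of class `icd_corpus`: list with `records` (data frame
#'   `record_id`, `description`, `gold_code`, `group_id`), `rulebase`
#'   (an `icd_rulebase` for the covered codes), `modeled` (covered code
#'   set), `truth` (data frame `record_id`, `status` with the expected
#'   match status per record), `universe`, and the `spec`.
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_codes = 20, n_records = 50,
#'                                       coverage = 1, ambiguity_rate = 0))
#' table(corpus$truth$status)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "icd_corpus_spec"))
  n_cov <- as.integer(round(spec$coverage * spec$n_codes))
  if (spec$ambiguity_rate > 0 && n_cov < 2L) {
    stop("ambiguity_rate > 0 needs at least 2 covered codes", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    universe <- universe_impl(spec)
    n <- spec$n_records
    tok_a <- sprintf("c%04da", universe$rank)
    tok_b <- sprintf("c%04db", universe$rank)
    covered <- universe$rank <= n_cov
    rb <- rulebase(
      code = universe$code[covered],
      pattern = sprintf("(chronic )?(%s|%s) disorder",
                        tok_a[covered], tok_b[covered]),
      canonical_label = sprintf("%s disorder", tok_a[covered]),
      note = rep("synthetic", n_cov))

    gold_idx <- sample(spec$n_codes, n, replace = TRUE,
                       prob = universe$weight)
    use_syn <- stats::runif(n) < spec$p_synonym
    use_opt <- stats::runif(n) < spec$p_optional
    core <- paste0(ifelse(use_opt, "chronic ", ""),
                   ifelse(use_syn, tok_b[gold_idx], tok_a[gold_idx]),
                   " disorder")
    is_cov <- covered[gold_idx]
    ambig <- is_cov & stats::runif(n) < spec$ambiguity_rate
    if (any(ambig)) {
      cov_ranks <- which(covered)
      for (i in which(ambig)) {
        pool <- setdiff(cov_ranks, gold_idx[i])
        other <- pool[sample.int(length(pool), 1L)]
        core[i] <- paste0(core[i], " ", tok_a[other], " disorder")
      }
    }
    noisy <- stats::runif(n) < spec$p_noise
    desc <- core
    for (i in which(noisy)) desc[i] <- noise_impl(desc[i])

    status <- ifelse(!is_cov, "no_match", ifelse(ambig, "ambiguous", "unique"))
    group_id <- if (spec$records_per_group > 0L) {
      sprintf("G%05d", ceiling(seq_len(n) / spec$records_per_group))
    } else rep(NA_character_, n)
    records <- data.frame(record_id = sprintf("R%06d", seq_len(n)),
                          description = desc,
                          gold_code = universe$code[gold_idx],
                          group_id = group_id, stringsAsFactors = FALSE)
    structure(list(records = records, rulebase = rb,
                   modeled = universe$code[covered],
                   truth = data.frame(record_id = records$record_id,
                                      status = status,
                                      stringsAsFactors = FALSE),
                   universe = universe, spec = spec),
              class = "icd_corpus")
  })
}

#' @export
print.icd_corpus <- function(x, ...) {
  cat(sprintf("<icd_corpus> %d record(s), %d/%d code(s) covered, statuses: %s\n",
              nrow(x$records), length(x$modeled), nrow(x$universe),
              paste(sprintf("%s=%d", names(table(x$truth$status)),
                            as.integer(table(x$truth$status))),
                    collapse = " ")))
  invisible(x)
}

#' Write corpus artifacts
#'
#' Writes `records.tsv`, `rules.tsv` and a `truth.jsonl` sidecar (one
#' `{"record_id": ..., "status": ..., "gold_code": ...}` object per
#' line) into `dir`.
#'
#' @param corpus an `icd_corpus`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "icd_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_rec <- file.path(dir, "records.tsv")
  write_records(corpus$records, p_rec)
  p_rules <- file.path(dir, "rules.tsv")
  write_rulebase(corpus$rulebase, p_rules)
  p_truth <- file.path(dir, "truth.jsonl")
  rows <- lapply(seq_len(nrow(corpus$truth)), function(i)
    list(record_id = corpus$truth$record_id[i],
         status = corpus$truth$status[i],
         gold_code = corpus$records$gold_code[i]))
  writeLines(jsonl_lines(rows), p_truth)
  invisible(c(p_rec, p_rules, p_truth))
}
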