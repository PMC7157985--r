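#' Construct a rule base of description models
#'
#' A rule base binds one regular expression — the "description model"
#' covering all clinician phrasings of one diagnosis — to exactly one
#' diagnosis code. Matching later uses unanchored (substring) search by
#' default, so a pattern without `^`/`$` may match anywhere in a
#' description.
#'
#' @param code character vector of diagnosis codes.
#' @param pattern character vector of regular-expression sources, same
#'   length as `code`.
#' @param canonical_label optional human-readable description per rule.
#' @param note optional free-text provenance per rule.
#' @param dialect_version tag recording the regex dialect the patterns
#'   were written for.
#' @return an object of class `icd_rulebase`: a data frame with columns
#'   `code`, `pattern`, `canonical_label`, `note`, in input order.
#' @seealso [read_rulebase()], [validate_rulebase()], [compile_rulebase()]
#' @examples
#' rb <- rulebase(code = c("I10 06", "E11.901"),
#'                pattern = c("hypertension( grade (I|II|III))?",
#'                            "type 2 diabetes"))
#' validate_rulebase(rb)
#' @export
rulebase <- function(code, pattern,
                     canonical_label = rep("", length(code)),
                     note = rep("", length(code)),
                     dialect_version = "pcre-1") {
  code <- as.character(code)
  pattern <- as.character(pattern)
  canonical_label <- as.character(canonical_label)
  note <- as.character(note)
  n <- length(code)
  stopifnot(length(pattern) == n, length(canonical_label) == n,
            length(note) == n)
  rules <- data.frame(code = code, pattern = pattern,
                      canonical_label = canonical_label, note = note,
                      stringsAsFactors = FALSE)
  structure(rules, class = c("icd_rulebase", "data.frame"),
            dialect_version = dialect_version)
}

#' @export
print.icd_rulebase <- function(x, ...) {
  cat(sprintf("<icd_rulebase> %d rule(s), dialect %s\n",
              nrow(x), attr(x, "dialect_version")))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read / write a rule file
#'
#' Rule files are UTF-8, tab-delimited, with a required header line naming
#' at least `code` and `pattern` (optionally `canonical_label` and
#' `note`). Blank lines and lines starting with `#` are skipped. Field
#' order follows the header.
#'
#' @param path file path (or a connection) to read from / write to.
#' @return `read_rulebase()`: an `icd_rulebase` preserving file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("code\tpattern", "A09.901\t^(acute )?gastroenteritis$"), tf)
#' read_rulebase(tf)
#' @export
read_rulebase <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_rulebase(lines)
}

#' @rdname read_rulebase
#' @param lines character vector of raw rule-file lines.
#' @export
parse_rulebase <- function(lines) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    return(rulebase(character(0), character(0)))
  }
  header <- strsplit(lines[[keep[1L]]], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (!all(c("code", "pattern") %in% header)) {
    stop("rule file header must name 'code' and 'pattern' columns",
         call. = FALSE)
  }
  body <- keep[-1L]
  n <- length(body)
  get_col <- function(fields, name, default = "") {
    i <- match(name, header)
    if (is.na(i) || i > length(fields)) default else fields[[i]]
  }
  code <- pattern <- label <- note <- character(n)
  for (j in seq_len(n)) {
    lineno <- body[[j]]
    fields <- strsplit(lines[[lineno]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop(sprintf("malformed rule line %d: expected >= 2 tab-delimited fields",
                   lineno), call. = FALSE)
    }
    code[j] <- trimws(get_col(fields, "code"))
    pattern[j] <- get_col(fields, "pattern")
    if (!nzchar(code[j]) || !nzchar(pattern[j])) {
      stop(sprintf("malformed rule line %d: empty code or pattern", lineno),
           call. = FALSE)
    }
    label[j] <- get_col(fields, "canonical_label")
    note[j] <- get_col(fields, "note")
  }
  rulebase(code, pattern, label, note)
}

#' @rdname read_rulebase
#' @param rb an `icd_rulebase`.
#' @export
write_rulebase <- function(rb, path) {
  stopifnot(inherits(rb, "icd_rulebase"))
  lines <- c("code\tpattern\tcanonical_label\tnote",
             sprintf("%s\t%s\t%s\t%s",
                     rb$code, rb$pattern, rb$canonical_label, rb$note))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Table-1 construct set: ^ $ * . | ? grouping and plain literals are the
# guaranteed dialect; these PCRE metacharacters fall outside it.
.dialect_extras <- "[+{}\\[\\]\\\\]"

pattern_compiles <- function(pattern) {
  ok <- TRUE
  tryCatch(regexpr(pattern, "", perl = TRUE),
           error = function(e) ok <<- FALSE,
           warning = function(w) ok <<- FALSE)
  ok
}

#' Validate a rule base
#'
#' Checks the one-regexp-per-code discipline (duplicate codes are
#' errors), that every pattern compiles, and that every code is
#' syntactically valid. Patterns using regex constructs outside the
#' guaranteed set `{^, $, *, ., |, ?, grouping, literals}` compile but
#' get a portability warning, since behaviour of richer constructs is
#' dialect-dependent.
#'
#' @param rb an `icd_rulebase`.
#' @return an object of class `icd_validation`: a list with data frames
#'   `errors` and `warnings`, each with columns `position`, `kind`,
#'   `message`. The rule base is compilable iff `errors` is empty.
#' @export
validate_rulebase <- function(rb) {
  stopifnot(inherits(rb, "icd_rulebase"))
  err <- list()
  wrn <- list()
  add <- function(store, position, kind, message) {
    store[[length(store) + 1L]] <- data.frame(
      position = position, kind = kind, message = message,
      stringsAsFactors = FALSE)
    store
  }
  dup <- duplicated(rb$code)
  for (i in which(dup)) {
    err <- add(err, i, "duplicate_code",
               sprintf("code '%s' already bound to an earlier rule", rb$code[i]))
  }
  for (i in seq_len(nrow(rb))) {
    if (!is_valid_code(rb$code[i])) {
      err <- add(err, i, "code_syntax",
                 sprintf("'%s' is not a valid diagnosis code", rb$code[i]))
    }
    if (!nzchar(rb$pattern[i])) {
      err <- add(err, i, "empty_pattern", "pattern is empty")
    } else if (!pattern_compiles(rb$pattern[i])) {
      err <- add(err, i, "bad_pattern",
                 sprintf("pattern '%s' does not compile", rb$pattern[i]))
    } else if (grepl(.dialect_extras, rb$pattern[i], perl = TRUE)) {
      wrn <- add(wrn, i, "dialect",
                 sprintf("pattern '%s' uses constructs outside the guaranteed set",
                         rb$pattern[i]))
    }
  }
  empty <- data.frame(position = integer(0), kind = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  structure(
    list(errors = if (length(err)) do.call(rbind, err) else empty,
         warnings = if (length(wrn)) do.call(rbind, wrn) else empty),
    class = "icd_validation")
}

#' @export
print.icd_validation <- function(x, ...) {
  cat(sprintf("<icd_validation> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print.data.frame(x$errors, row.names = FALSE)
  if (nrow(x$warnings)) print.data.frame(x$warnings, row.names = FALSE)
  invisible(x)
}

#' @rdname validate_rulebase
#' @param v an `icd_validation` report.
#' @export
is_valid_rulebase <- function(v) {
  stopifnot(inherits(v, "icd_validation"))
  nrow(v$errors) == 0L
}

#' Resolve description/code pairs by coder majority
#'
#' During rule building, historical data yields (description, code) pairs
#' each supported by some number of coder agreements. When one
#' description maps to several codes, the code with strictly greatest
#' total support wins; descriptions whose top support is tied are routed
#' to an unresolved queue for manual handling rather than guessed at.
#'
#' @param pairs data frame with columns `description`, `code`, `support`
#'   (positive integer counts; repeated (description, code) rows are
#'   summed).
#' @return list with `mapping` (data frame `description`, `code`,
#'   `support`) and `unresolved` (character vector of descriptions whose
#'   top support was tied). Every input description appears in exactly
#'   one of the two.
#' @export
majority_resolve <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("description", "code", "support") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(list(mapping = data.frame(description = character(0),
                                     code = character(0),
                                     support = numeric(0),
                                     stringsAsFactors = FALSE),
                unresolved = character(0)))
  }
  if (any(pairs$support < 1)) {
    stop("support counts must be >= 1", call. = FALSE)
  }
  agg <- stats::aggregate(support ~ description + code, data = pairs, FUN = sum)
  split_by_desc <- split(agg, agg$description)
  mapping <- list()
  unresolved <- character(0)
  for (d in names(split_by_desc)) {
    g <- split_by_desc[[d]]
    top <- max(g$support)
    winners <- g[g$support == top, , drop = FALSE]
    if (nrow(winners) == 1L) {
      mapping[[length(mapping) + 1L]] <- winners
    } else {
      unresolved <- c(unresolved, d)
    }
  }
  mapping <- if (length(mapping)) do.call(rbind, mapping) else
    agg[0, , drop = FALSE]
  rownames(mapping) <- NULL
  list(mapping = mapping[, c("description", "code", "support")],
       unresolved = unresolved)
}

#' Compile a rule base for matching
#'
#' Rejects a rule base that fails [validate_rulebase()], precompiles each
#' pattern (anchoring it fully when `anchored = TRUE`), normalizes
#' canonical labels with `config`, and self-checks each rule: a rule
#' whose own canonical label does not match its pattern under search
#' semantics gets a `self_match` warning attached — usually a sign the
#' pattern drifted from the diagnosis it models.
#'
#' @param rb an `icd_rulebase` with no validation errors.
#' @param config a [normalization_config()] applied to labels at compile
#'   time and to descriptions at match time.
#' @param anchored if `TRUE`, patterns must match the whole normalized
#'   description (each is wrapped as `^(?:pattern)$`); the default
#'   `FALSE` keeps unanchored substring-search semantics, mirroring SQL
#'   `REGEXP_LIKE` containment.
#' @return an object of class `icd_compiled_rulebase` with elements
#'   `codes`, `patterns` (match-ready), `labels`, `config`,
#'   `fingerprint`, `anchored`, and a `warnings` data frame.
#' @export
compile_rulebase <- function(rb, config = normalization_config(),
                             anchored = FALSE) {
  stopifnot(inherits(rb, "icd_rulebase"),
            inherits(config, "icd_norm_config"),
            is.logical(anchored), length(anchored) == 1L)
  v <- validate_rulebase(rb)
  if (!is_valid_rulebase(v)) {
    stop(sprintf("cannot compile an invalid rule base: %s",
                 paste(sprintf("[rule %d] %s", v$errors$position,
                               v$errors$message), collapse = "; ")),
         call. = FALSE)
  }
  patterns <- rb$pattern
  if (anchored) patterns <- sprintf("^(?:%s)$", patterns)
  labels <- normalize_description(rb$canonical_label, config)
  warn <- data.frame(position = integer(0), kind = character(0),
                     message = character(0), stringsAsFactors = FALSE)
  has_label <- nzchar(labels)
  for (i in which(has_label)) {
    if (!grepl(patterns[i], labels[i], perl = TRUE)) {
      warn <- rbind(warn, data.frame(
        position = i, kind = "self_match",
        message = sprintf("canonical label '%s' does not match its own pattern",
                          rb$canonical_label[i]),
        stringsAsFactors = FALSE))
    }
  }
  structure(
    list(codes = rb$code, patterns = patterns, labels = labels,
         config = config, fingerprint = normalization_fingerprint(config),
         anchored = anchored, warnings = warn,
         dialect_version = attr(rb, "dialect_version")),
    class = "icd_compiled_rulebase")
}

#' @export
print.icd_compiled_rulebase <- function(x, ...) {
  cat(sprintf("<icd_compiled_rulebase> %d code(s), %s, %d compile warning(s)\n",
              length(x$codes),
              if (x$anchored) "anchored" else "substring search",
              nrow(x$warnings)))
  invisible(x)
}
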