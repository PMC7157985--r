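#' Diagnosis code syntax
#'
#' ICD-10 codes are one uppercase chapter letter, two digits, an optional
#' "." subdivision of 1--4 alphanumerics, and an optional national
#' extension: a single space followed by two digits (the CCD dialect used
#' in Chinese hospitals, e.g. `"I10 06"` or `"F09 01"`).
#'
#' @param code character vector of candidate codes.
#' @return `is_valid_code()`: logical vector. `code_cluster()`: the chapter
#'   letter (first character) of each code, `NA` for invalid codes.
#' @examples
#' is_valid_code(c("I25.101", "I10 06", "25I.101"))
#' code_cluster("K22.902")
#' @export
is_valid_code <- function(code) {
  if (length(code) == 0L) return(logical(0))
  !is.na(code) & grepl(.code_syntax, code)
}

.code_syntax <- "^[A-Z][0-9]{2}(\\.[A-Za-z0-9]{1,4})?( [0-9]{2})?$"

#' @rdname is_valid_code
#' @export
code_cluster <- function(code) {
  out <- substr(code, 1L, 1L)
  out[!is_valid_code(code)] <- NA_character_
  out
}

# stop() with the offending codes listed, used by several entry points
assert_valid_codes <- function(code, what = "code") {
  bad <- unique(code[!is_valid_code(code)])
  if (length(bad)) {
    stop(sprintf("invalid %s syntax: %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(code)
}
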