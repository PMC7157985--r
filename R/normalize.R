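#' Text normalization configuration
#'
#' Diagnosis descriptions arrive with inconsistent spacing, full-width
#' (CJK keyboard) punctuation and mixed Latin case. Normalization is
#' applied to descriptions before matching and to rule canonical labels at
#' compile time, so both sides of the comparison see the same surface
#' form.
#'
#' Folding order is fixed: width fold, then Latin case fold, then
#' punctuation stripping, then whitespace collapse (plus trimming). The
#' composite is idempotent: normalizing an already-normalized string is a
#' no-op.
#'
#' @param collapse_whitespace collapse runs of whitespace to a single
#'   space and trim the ends. Default `TRUE`.
#' @param width_fold map full-width ASCII variants (U+FF01--U+FF5E) and
#'   the ideographic space (U+3000) to their half-width equivalents.
#'   Default `TRUE`.
#' @param case_fold fold Latin letters A--Z to lower case. Default `TRUE`.
#' @param strip_chars character vector of single characters to delete
#'   (punctuation, typically). Default: none.
#' @return an object of class `icd_norm_config`.
#' @examples
#' cfg <- normalization_config()
#' normalize_description("  Abdominal   Pain ", cfg)
#' @export
normalization_config <- function(collapse_whitespace = TRUE,
                                 width_fold = TRUE,
                                 case_fold = TRUE,
                                 strip_chars = character()) {
  stopifnot(is.logical(collapse_whitespace), length(collapse_whitespace) == 1L,
            is.logical(width_fold), length(width_fold) == 1L,
            is.logical(case_fold), length(case_fold) == 1L,
            is.character(strip_chars))
  structure(
    list(collapse_whitespace = collapse_whitespace,
         width_fold = width_fold,
         case_fold = case_fold,
         strip_chars = strip_chars),
    class = "icd_norm_config"
  )
}

# full-width block U+FF01..U+FF5E maps 1:1 onto ASCII 0x21..0x7E
.fullwidth_from <- intToUtf8(c(0x3000, 0xFF01:0xFF5E))
.fullwidth_to <- intToUtf8(c(0x20, 0x21:0x7E))

#' Normalize a diagnosis description
#'
#' @param text character vector of free-text descriptions (UTF-8).
#' @param config a [normalization_config()].
#' @return character vector of normalized text, same length as `text`.
#' @export
normalize_description <- function(text, config = normalization_config()) {
  stopifnot(inherits(config, "icd_norm_config"))
  if (length(text) == 0L) return(character(0))
  x <- enc2utf8(as.character(text))
  if (config$width_fold) {
    x <- chartr(.fullwidth_from, .fullwidth_to, x)
  }
  if (config$case_fold) {
    x <- chartr(paste(LETTERS, collapse = ""),
                paste(letters, collapse = ""), x)
  }
  if (length(config$strip_chars)) {
    cls <- paste0("[", gsub("([][\\\\^-])", "\\\\\\1",
                            paste(config$strip_chars, collapse = "")), "]")
    x <- gsub(cls, "", x, perl = TRUE)
  }
  if (config$collapse_whitespace) {
    x <- trimws(gsub("[[:space:]]+", " ", x, perl = TRUE))
  }
  x
}

# single stable string identifying a normalization config, recorded on
# compiled rule bases so a run can assert it matches the compile-time config
normalization_fingerprint <- function(config) {
  stopifnot(inherits(config, "icd_norm_config"))
  paste0("ws=", as.integer(config$collapse_whitespace),
         ";width=", as.integer(config$width_fold),
         ";case=", as.integer(config$case_fold),
         ";strip=", paste(sort(config$strip_chars), collapse = ""))
}
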