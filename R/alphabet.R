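#' Symbol alphabet for a random number generation task
#'
#' An alphabet is the ordered finite set of symbols a subject may produce.
#' The default is the nine digit tokens `"1"` to `"9"`, the standard range in
#' random number generation tasks. Symbols are opaque tokens compared only by
#' equality — nothing in the package does arithmetic on them, so alphabets of
#' letters work unchanged.
#'
#' @param symbols Character vector (or vector coercible to character) of
#'   distinct, non-empty tokens. Tokens may not contain whitespace, because the
#'   on-disk manifest format separates symbols by spaces.
#' @return An object of class `rngt_alphabet`: a character vector of symbols.
#' @examples
#' rngt_alphabet()
#' rngt_alphabet(letters[1:4])
#' @export
rngt_alphabet <- function(symbols = as.character(1:9)) {
  if (inherits(symbols, "rngt_alphabet")) return(symbols)
  symbols <- as.character(symbols)
  if (length(symbols) == 0) stop("alphabet must be non-empty", call. = FALSE)
  if (anyNA(symbols) || any(!nzchar(symbols))) {
    stop("alphabet symbols must be non-missing, non-empty tokens", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be distinct; duplicated: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[[:space:]]", symbols))) {
    stop("alphabet symbols may not contain whitespace", call. = FALSE)
  }
  structure(symbols, class = "rngt_alphabet")
}

#' @export
print.rngt_alphabet <- function(x, ...) {
  cat("<rngt_alphabet> ", paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}
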