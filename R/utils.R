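## shared small helpers

BASES <- c("A", "C", "G", "T")

## reverse-complement of a plain character vector of sequences
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of single-base character vector (keeps N)
comp_base <- function(b) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[b])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Render an efficiency as a percentage
#'
#' Formats an editing efficiency in `[0, 1]` as a percentage with two
#' decimals, e.g. `0.0543` becomes `"5.43%"`.
#' @param x numeric vector of fractions
#' @return character vector
#' @export
format_percent <- function(x) sprintf("%.2f%%", 100 * x)
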