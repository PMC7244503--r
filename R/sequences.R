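#' Sequence utilities
#'
#' Minimal 5'->3' character-string helpers used throughout the package.
#' Only the DNA alphabet ACGT is supported.
#'
#' @param x character vector of DNA sequences (5'->3')
#' @return character vector
#' @name sequence-utils
NULL

#' @rdname sequence-utils
#' @export
dna_complement <- function(x) chartr("ACGT", "TGCA", toupper(x))

#' @rdname sequence-utils
#' @export
dna_reverse <- function(x) {
  vapply(strsplit(toupper(x), ""), function(s) paste(rev(s), collapse = ""), "")
}

#' @rdname sequence-utils
#' @export
dna_reverse_complement <- function(x) dna_reverse(dna_complement(x))

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", toupper(x))
  if (any(bad)) {
    sym <- unique(unlist(strsplit(gsub("[ACGT]", "", toupper(x[bad])), "")))
    stop(sprintf(
      "unsupported base symbol(s) %s in %s; only A, C, G, T are supported",
      paste(sQuote(sym), collapse = ", "), what
    ), call. = FALSE)
  }
  toupper(x)
}

.is_wc_pair <- function(top, bottom) dna_complement(top) == bottom
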