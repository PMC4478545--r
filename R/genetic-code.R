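#' The standard nuclear genetic code
#'
#' Returns the mapping from each of the 64 codons (3-mers over A/C/G/T) to an
#' amino-acid letter, with `*` for the three stop codons (TAA, TAG, TGA).
#' The default is taken from [Biostrings::GENETIC_CODE].
#'
#' @return A named character vector of length 64; names are codons, values are
#'   single amino-acid letters.
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  structure(as.character(code), names = names(code))
}

# Validate a user-supplied genetic code: 64 codons, every amino acid reachable.
validate_genetic_code <- function(code) {
  if (!is.character(code) || length(code) != 64L || is.null(names(code))) {
    agam_abort("a genetic code must be a named character vector of 64 codons", "invalid_param")
  }
  all_codons <- all_codons()
  if (!setequal(names(code), all_codons)) {
    agam_abort("genetic code must cover exactly the 64 ACGT codons", "invalid_param")
  }
  if (any(nchar(code) != 1L)) {
    agam_abort("genetic code values must be single amino-acid letters", "invalid_param")
  }
  invisible(code[all_codons])
}

#' All 64 codons
#'
#' @return Character vector of the 64 codons in lexicographic order.
#' @export
all_codons <- function() {
  b <- DNA_ALPHABET
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

#' Synonymous codons of an amino acid
#'
#' @param aa Single amino-acid letter (or `"*"` for stop).
#' @param code Genetic code, as from [standard_genetic_code()].
#' @return Character vector of the codons translating to `aa`.
#' @export
synonymous_codons <- function(aa, code = standard_genetic_code()) {
  names(code)[code == aa]
}
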