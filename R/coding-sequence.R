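#' Construct a coding sequence
#'
#' A coding sequence (CDS) is an in-frame open reading frame: its length is a
#' positive multiple of 3, it uses only A/C/G/T, and it carries no internal
#' stop codon. A single terminal stop codon is permitted.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string. Lowercase input is uppercased with a warning;
#'   ambiguity codes are rejected.
#' @param code Genetic code used to check for internal stops.
#' @return An object of class `coding_sequence` with elements `id` and
#'   `sequence`.
#' @examples
#' cds <- coding_sequence("demo", "ATGGCTTGGTAA")
#' translate_cds(cds)
#' @export
coding_sequence <- function(id, sequence, code = standard_genetic_code()) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    agam_abort("id must be a non-empty string", "invalid_cds")
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    agam_abort(sprintf("[%s] sequence must be a single string", id), "invalid_cds")
  }
  if (grepl("[a-z]", sequence)) {
    agam_warn(sprintf("[%s] lowercase sequence uppercased", id), "lowercase_input")
    sequence <- toupper(sequence)
  }
  if (grepl("[^ACGT]", sequence)) {
    agam_abort(sprintf("[%s] sequence contains characters outside A/C/G/T", id), "invalid_cds")
  }
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    agam_abort(sprintf("[%s] length %d is not a positive multiple of 3", id, n), "invalid_cds")
  }
  codons <- split_codons(sequence)
  aa <- code[codons]
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop < length(codons)]
  if (length(internal_stop) > 0) {
    agam_abort(
      sprintf("[%s] internal stop codon at codon %d", id, internal_stop[1]),
      "invalid_cds"
    )
  }
  structure(list(id = id, sequence = sequence), class = "coding_sequence")
}

as_coding_sequence <- function(x, id = "cds") {
  if (inherits(x, "coding_sequence")) return(x)
  coding_sequence(id, x)
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf(
    "<coding_sequence> %s: %d nt (%d codons)\n",
    x$id, nchar(x$sequence), nchar(x$sequence) %/% 3L
  ))
  invisible(x)
}

#' Translate a coding sequence
#'
#' @param cds A [coding_sequence()] (or a plain DNA string).
#' @param code Genetic code.
#' @return Protein string, one letter per codon, terminal stop rendered `*`.
#' @export
translate_cds <- function(cds, code = standard_genetic_code()) {
  cds <- as_coding_sequence(cds)
  codons <- split_codons(cds$sequence)
  aa <- code[codons]
  if (anyNA(aa)) {
    agam_abort(sprintf("[%s] unknown codon in sequence", cds$id), "invalid_cds")
  }
  paste0(aa, collapse = "")
}
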