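# Internal helpers shared across modules.

# Signal a classed condition so callers (and tests) can dispatch on the
# domain error name rather than on message text.
agam_abort <- function(msg, class, data = list()) {
  cond <- structure(
    c(list(message = msg, call = sys.call(-1)), data),
    class = c(paste0("agam_", class), "agam_error", "error", "condition")
  )
  stop(cond)
}

agam_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("agam_", class), "agam_warning")))
}

# Run code under a temporary RNG state; never perturbs the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    agam_abort("seed must be a single integer", "invalid_param")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

DNA_ALPHABET <- c("A", "C", "G", "T")

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    agam_abort(sprintf("%s must be a single character string", what), "invalid_param")
  }
  if (grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    agam_abort(
      sprintf("%s contains non-ACGT characters: %s", what, paste(bad, collapse = ", ")),
      "invalid_param"
    )
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x A character string over A/C/G/T.
#' @return The reverse complement, as a character string.
#' @examples
#' revcomp("GGTCTC")
#' @export
revcomp <- function(x) {
  assert_dna(x)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# IUPAC nucleotide code -> regular expression character class.
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_MAP))
  if (length(unknown) > 0) {
    agam_abort(
      sprintf("motif contains non-IUPAC characters: %s", paste(unique(unknown), collapse = ", ")),
      "invalid_param"
    )
  }
  paste0(IUPAC_MAP[chars], collapse = "")
}

# All start positions (1-based) of a fixed-length motif (IUPAC allowed) on a
# string; overlapping matches included.
motif_starts <- function(seq, motif, fixed = TRUE) {
  if (nchar(seq) < nchar(motif) || nchar(motif) == 0L) return(integer(0))
  pat <- if (fixed) motif else iupac_to_regex(motif)
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# A 4-nt overhang label is palindromic when it equals its own reverse
# complement (self-ligation risk).
is_palindromic <- function(label) {
  nchar(label) %% 2 == 0 && identical(label, revcomp(label))
}

# Split a codon string into consecutive triplets.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
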