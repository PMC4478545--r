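#' Construct a DNA molecule
#'
#' A double-stranded DNA molecule represented by its top strand (5'->3'),
#' linear or circular, optionally carrying named features. Coordinates are
#' 1-based inclusive on the top strand (GenBank convention); features on a
#' circular molecule may wrap the origin (`start > end`).
#'
#' @param id Identifier.
#' @param sequence Top-strand DNA string (A/C/G/T).
#' @param topology `"linear"` or `"circular"`.
#' @param features A data frame with columns `name`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), or `NULL`.
#' @return An object of class `dna_molecule`.
#' @examples
#' dna_molecule("demo", "ACGTACGT", features = data.frame(
#'   name = "site", start = 3, end = 6, strand = "+"
#' ))
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"), features = NULL) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    agam_abort("id must be a non-empty string", "invalid_param")
  }
  sequence <- toupper(sequence)
  assert_dna(sequence, what = sprintf("[%s] sequence", id))
  features <- normalize_features(features, nchar(sequence), topology, id)
  structure(
    list(id = id, sequence = sequence, topology = topology, features = features),
    class = "dna_molecule"
  )
}

empty_features <- function() {
  data.frame(
    name = character(0), start = integer(0), end = integer(0),
    strand = character(0), stringsAsFactors = FALSE
  )
}

normalize_features <- function(features, len, topology, id) {
  if (is.null(features) || nrow(features) == 0) return(empty_features())
  req <- c("name", "start", "end", "strand")
  if (!all(req %in% names(features))) {
    agam_abort(sprintf("[%s] features need columns %s", id, paste(req, collapse = ", ")), "invalid_param")
  }
  features <- features[req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1L | features$end < 1L | features$start > len | features$end > len)) {
    agam_abort(sprintf("[%s] feature coordinates outside 1..%d", id, len), "invalid_param")
  }
  if (topology == "linear" && any(features$end < features$start)) {
    agam_abort(sprintf("[%s] wrapped feature on a linear molecule", id), "invalid_param")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    agam_abort(sprintf("[%s] feature strand must be '+' or '-'", id), "invalid_param")
  }
  rownames(features) <- NULL
  features
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf(
    "<dna_molecule> %s: %d bp, %s, %d feature(s)\n",
    x$id, nchar(x$sequence), x$topology, nrow(x$features)
  ))
  if (nrow(x$features) > 0) print.data.frame(x$features, row.names = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA molecule
#'
#' @param mol A [dna_molecule()].
#' @return A `dna_molecule` with complemented top strand and mirrored features.
#' @export
revcomp_molecule <- function(mol) {
  len <- nchar(mol$sequence)
  feats <- mol$features
  if (nrow(feats) > 0) {
    new_start <- len - feats$end + 1L
    new_end <- len - feats$start + 1L
    feats$start <- new_start
    feats$end <- new_end
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  dna_molecule(mol$id, revcomp(mol$sequence), mol$topology, feats)
}

# Rotate a circular molecule so that 1-based position `origin` becomes
# position 1; features are remapped.
rotate_molecule <- function(mol, origin) {
  if (mol$topology != "circular") agam_abort("can only rotate a circular molecule", "invalid_param")
  len <- nchar(mol$sequence)
  origin <- ((origin - 1L) %% len) + 1L
  if (origin == 1L) return(mol)
  seq <- paste0(substr(mol$sequence, origin, len), substr(mol$sequence, 1L, origin - 1L))
  feats <- mol$features
  if (nrow(feats) > 0) {
    shift <- function(p) ((p - origin) %% len) + 1L
    feats$start <- shift(feats$start)
    feats$end <- shift(feats$end)
  }
  dna_molecule(mol$id, seq, "circular", feats)
}

# Subsequence of the top strand honouring circular wrap-around.
subseq_circ <- function(seq, start, end) {
  len <- nchar(seq)
  start <- ((start - 1L) %% len) + 1L
  end <- ((end - 1L) %% len) + 1L
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, len), substr(seq, 1L, end))
  }
}

# Features fully contained in top-strand window [from, to] (no wrap), shifted
# to window coordinates. Features crossing a cut are dropped.
features_in_window <- function(features, from, to) {
  if (is.null(features) || nrow(features) == 0) return(empty_features())
  keep <- features$start >= from & features$end <= to & features$start <= features$end
  out <- features[keep, , drop = FALSE]
  out$start <- out$start - from + 1L
  out$end <- out$end - from + 1L
  rownames(out) <- NULL
  out
}

shift_features <- function(features, offset) {
  if (nrow(features) == 0) return(features)
  features$start <- features$start + offset
  features$end <- features$end + offset
  features
}
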