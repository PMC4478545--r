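#' Count codon usage over a set of coding sequences
#'
#' Accumulates per-codon counts over all input sequences. Counts are invariant
#' under permutation of the input set, and the total equals the summed codon
#' lengths of the inputs.
#'
#' @param cds_set A list of [coding_sequence()] objects (or a named character
#'   vector / list of DNA strings, which are validated as coding sequences).
#' @param code Genetic code used for validation.
#' @return An object of class `codon_count_table`: a list with `counts` (named
#'   integer vector over the 64 codons), `total_codons`, and `source_ids`.
#' @examples
#' ct <- count_codons(list(coding_sequence("a", "ATGGCTGCTTAA")))
#' ct$counts[c("ATG", "GCT", "TAA")]
#' @export
count_codons <- function(cds_set, code = standard_genetic_code()) {
  if (is.character(cds_set)) cds_set <- as.list(cds_set)
  if (!is.list(cds_set)) {
    agam_abort("cds_set must be a list of coding sequences", "invalid_cds")
  }
  counts <- structure(integer(64L), names = all_codons())
  ids <- character(0)
  for (i in seq_along(cds_set)) {
    x <- cds_set[[i]]
    id <- if (inherits(x, "coding_sequence")) x$id else (names(cds_set)[i] %||% sprintf("seq%d", i))
    if (is.null(id) || !nzchar(id)) id <- sprintf("seq%d", i)
    cds <- tryCatch(
      as_coding_sequence(x, id = id),
      agam_invalid_cds = function(e) {
        agam_abort(sprintf("invalid coding sequence '%s': %s", id, conditionMessage(e)), "invalid_cds")
      }
    )
    tab <- table(split_codons(cds$sequence))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    ids <- c(ids, cds$id)
  }
  structure(
    list(counts = counts, total_codons = sum(counts), source_ids = ids),
    class = "codon_count_table"
  )
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(sprintf(
    "<codon_count_table> %d codons from %d sequence(s)\n",
    x$total_codons, length(x$source_ids)
  ))
  invisible(x)
}

#' Build a codon frequency table from codon counts
#'
#' For every codon the table records its amino acid, raw count, frequency
#' among the synonymous codons of that amino acid (`freq_within_aa`), and
#' occurrences per 1000 codons (`per_1000`). Amino acids with zero total count
#' carry `freq_within_aa = NA` ("undefined"); the penalty scorer treats their
#' codons as rare.
#'
#' @param counts A `codon_count_table` from [count_codons()], or a named
#'   integer vector of per-codon counts.
#' @param code Genetic code.
#' @return A `codon_frequency_table`: a data frame with columns `codon`, `aa`,
#'   `count`, `freq_within_aa`, `per_1000`, plus attributes `total_codons` and
#'   `source_ids`.
#' @examples
#' ct <- count_codons(list(coding_sequence("a", "ATGGCTGCTTAA")))
#' ft <- build_frequency_table(ct)
#' subset(ft, count > 0)
#' @export
build_frequency_table <- function(counts, code = standard_genetic_code()) {
  if (inherits(counts, "codon_count_table")) {
    src <- counts$source_ids
    counts <- counts$counts
  } else {
    src <- character(0)
  }
  full <- structure(integer(64L), names = all_codons())
  if (is.null(names(counts))) {
    agam_abort("counts must be named by codon", "invalid_param")
  }
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) agam_abort("codon counts must be non-negative", "invalid_param")
  total <- sum(full)
  if (total == 0L) agam_abort("cannot build a frequency table from zero codons", "empty_table")

  codon <- all_codons()
  aa <- unname(code[codon])
  aa_totals <- tapply(full, aa, sum)
  denom <- as.numeric(aa_totals[aa])
  freq <- ifelse(denom > 0, full / denom, NA_real_)
  tab <- data.frame(
    codon = codon,
    aa = aa,
    count = as.integer(full),
    freq_within_aa = as.numeric(freq),
    per_1000 = 1000 * full / total,
    stringsAsFactors = FALSE
  )
  new_codon_frequency_table(tab, total_codons = total, source_ids = src)
}

new_codon_frequency_table <- function(df, total_codons = NA_real_, source_ids = character(0)) {
  rownames(df) <- df$codon
  structure(
    df,
    total_codons = total_codons,
    source_ids = source_ids,
    class = c("codon_frequency_table", "data.frame")
  )
}

#' Construct a codon frequency table from explicit frequencies
#'
#' Used for toy tables and for tables transcribed from printed sources, where
#' within-amino-acid frequencies are given directly and counts may be missing.
#'
#' @param codon Character vector of codons.
#' @param freq_within_aa Frequencies within each codon's amino acid.
#' @param count Optional integer counts (default `NA`).
#' @param per_1000 Optional per-1000 frequencies; computed from counts when
#'   counts are available and `per_1000` is missing.
#' @param code Genetic code (supplies the amino-acid column).
#' @param tol Tolerance on per-amino-acid frequency sums (default `0.02`,
#'   accommodating printed rounding).
#' @return A `codon_frequency_table` covering all 64 codons; codons not listed
#'   get count 0 and `freq_within_aa` 0 when their amino acid is represented,
#'   `NA` otherwise.
#' @export
codon_frequency_table <- function(codon, freq_within_aa, count = NA_integer_,
                                  per_1000 = NULL, code = standard_genetic_code(),
                                  tol = 0.02) {
  codon <- toupper(codon)
  if (anyDuplicated(codon)) agam_abort("duplicated codon rows", "invalid_param")
  if (!all(codon %in% all_codons())) {
    agam_abort("unknown codon in table", "invalid_param")
  }
  count <- rep_len(as.numeric(count), length(codon))
  all64 <- all_codons()
  aa <- unname(code[all64])
  freq <- structure(rep(NA_real_, 64L), names = all64)
  cnt <- structure(rep(NA_real_, 64L), names = all64)
  freq[codon] <- freq_within_aa
  cnt[codon] <- count
  # amino acids with at least one listed codon: unlisted synonyms get 0
  listed_aa <- unique(unname(code[codon]))
  fill <- is.na(freq) & aa %in% listed_aa
  freq[fill] <- 0
  for (a in listed_aa) {
    s <- sum(freq[aa == a])
    if (abs(s - 1) > tol) {
      agam_abort(
        sprintf("frequencies for amino acid '%s' sum to %.4f (tolerance %.3g)", a, s, tol),
        "invalid_param"
      )
    }
  }
  total <- if (all(!is.na(cnt[codon]))) sum(cnt[codon]) else NA_real_
  p1000 <- structure(rep(NA_real_, 64L), names = all64)
  if (!is.null(per_1000)) {
    p1000[codon] <- per_1000
  } else if (!is.na(total) && total > 0) {
    p1000 <- ifelse(is.na(cnt), NA_real_, 1000 * cnt / total)
  }
  tab <- data.frame(
    codon = all64, aa = aa, count = as.numeric(cnt),
    freq_within_aa = as.numeric(freq), per_1000 = as.numeric(p1000),
    stringsAsFactors = FALSE
  )
  new_codon_frequency_table(tab, total_codons = total)
}

#' @export
print.codon_frequency_table <- function(x, ...) {
  tot <- attr(x, "total_codons")
  cat(sprintf(
    "<codon_frequency_table> 64 codons%s\n",
    if (!is.na(tot)) sprintf(", %s total codons", format(tot, big.mark = ",")) else ""
  ))
  print.data.frame(utils::head(x[x$count > 0 | !is.na(x$freq_within_aa), ], 10), row.names = FALSE)
  cat("...\n")
  invisible(x)
}

# round half away from zero, matching integer indices reported for the score
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Translation penalty index of a coding sequence
#'
#' Scores how hostile a coding sequence is to the codon preferences of a
#' reference table. Every codon whose within-amino-acid frequency in the
#' reference table is strictly below `threshold` counts as a rare codon; with
#' the default unit weight, the index is the number of rare codons normalised
#' per 1000 codons, so that sequences of different lengths are comparable.
#'
#' Codons of an amino acid absent from the reference table score as rare (a
#' warning is emitted): usage that was never observed cannot be endorsed.
#'
#' @param cds A [coding_sequence()] or DNA string.
#' @param table A `codon_frequency_table`.
#' @param threshold Rarity threshold on `freq_within_aa`, strict (default
#'   `0.10`); codons at exactly the threshold are not penalised.
#' @param exclude_stop If `TRUE`, a terminal stop codon is excluded from both
#'   the codon count and the rare-codon scan.
#' @param weight Per-rare-codon penalty weight: either a single number or a
#'   function of the rare codon's `freq_within_aa` returning its penalty
#'   (configuration hook; default unit weight).
#' @param code Genetic code.
#' @return A `penalty_report`: list with `sequence_id`, `n_codons`,
#'   `threshold`, `rare_hits` (data frame: `position`, `codon`, `aa`,
#'   `freq_within_aa`), `raw_penalty`, `penalty_index`, and
#'   `penalty_index_rounded` (half away from zero).
#' @examples
#' toy <- codon_frequency_table(
#'   codon = c("CTG", "CTC", "CTT", "TTA", "TTG", "CTA", "ATG"),
#'   freq_within_aa = c(0.50, 0.30, 0.12, 0.05, 0.02, 0.01, 1.0)
#' )
#' rep <- penalty_index("ATGCTGCTGTTACTACTCCTTCTGCTCATG", toy)
#' rep$penalty_index
#' @export
penalty_index <- function(cds, table, threshold = 0.10, exclude_stop = FALSE,
                          weight = 1, code = standard_genetic_code()) {
  cds <- as_coding_sequence(cds)
  if (!inherits(table, "codon_frequency_table")) {
    agam_abort("table must be a codon_frequency_table", "invalid_param")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    agam_abort("threshold must lie strictly between 0 and 1", "invalid_param")
  }
  codons <- split_codons(cds$sequence)
  if (exclude_stop && length(codons) > 0 && code[codons[length(codons)]] == "*") {
    codons <- codons[-length(codons)]
  }
  n <- length(codons)
  freq <- table$freq_within_aa[match(codons, table$codon)]
  aa <- unname(code[codons])
  undefined <- is.na(freq)
  if (any(undefined)) {
    agam_warn(
      sprintf(
        "[%s] amino acid(s) %s absent from reference table; their codons scored as rare",
        cds$id, paste(unique(aa[undefined]), collapse = ", ")
      ),
      "unscored_amino_acid"
    )
  }
  rare <- undefined | (freq < threshold)
  hits <- data.frame(
    position = which(rare),
    codon = codons[rare],
    aa = aa[rare],
    freq_within_aa = freq[rare],
    stringsAsFactors = FALSE
  )
  w <- if (is.function(weight)) {
    vapply(ifelse(is.na(hits$freq_within_aa), 0, hits$freq_within_aa), weight, numeric(1))
  } else {
    rep_len(weight, nrow(hits))
  }
  raw <- sum(w)
  idx <- if (n > 0) raw * 1000 / n else 0
  structure(
    list(
      sequence_id = cds$id,
      n_codons = n,
      threshold = threshold,
      rare_hits = hits,
      raw_penalty = raw,
      penalty_index = idx,
      penalty_index_rounded = as.integer(round_half_away(idx))
    ),
    class = "penalty_report"
  )
}

#' @export
print.penalty_report <- function(x, ...) {
  cat(sprintf(
    "<penalty_report> %s: %d codons, %d rare (< %.2g), penalty index %.2f (~%d per 1000)\n",
    x$sequence_id, x$n_codons, nrow(x$rare_hits), x$threshold,
    x$penalty_index, x$penalty_index_rounded
  ))
  invisible(x)
}

#' The packaged A. gambiae-style reference codon usage table
#'
#' Loads the codon preference table shipped with the package. The table is a
#' synthetic stand-in emulating codon preference in a small set of medium to
#' highly expressed *Anopheles gambiae* genes (9 coding sequences, 10,160
#' codons in total): GC-ending codons are preferred and Leu TTA and Arg
#' AGA/AGG are rare. It is generated, not transcribed from published counts,
#' and is intended for scoring demonstrations and tests; substitute your own
#' table (see [read_codon_table()]) for production optimization.
#'
#' @return A `codon_frequency_table`.
#' @export
agam_reference_table <- function() {
  path <- system.file("extdata", "gambiae_reference_table_synthetic.tsv",
    package = "agamtools", mustWork = TRUE
  )
  read_codon_table(path)
}
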