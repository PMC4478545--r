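#' Optimization settings for codon rewriting
#'
#' @param strategy One of `"most_frequent"` (every codon replaced by its amino
#'   acid's most frequent synonym), `"weighted_sampling"` (synonyms sampled in
#'   proportion to their reference frequency, restricted to synonyms at or
#'   above `threshold` so the penalty index can never increase), or
#'   `"threshold_swap"` (only codons rarer than `threshold` are replaced, by
#'   the most frequent synonym).
#' @param seed Integer seed, used only by `weighted_sampling`.
#' @param forbidden_motifs Character vector of DNA motifs (each >= 4 nt) that
#'   must not occur in the output on either strand. The GoldenGate workflow
#'   passes `c("GGTCTC", "GAGACC")` so optimized inserts stay BsaI-free.
#' @param threshold Rarity threshold (default 0.10).
#' @return An `optimization_spec` list.
#' @export
optimization_spec <- function(strategy = c("most_frequent", "weighted_sampling", "threshold_swap"),
                              seed = 1L, forbidden_motifs = character(0),
                              threshold = 0.10) {
  strategy <- match.arg(strategy)
  forbidden_motifs <- toupper(forbidden_motifs)
  if (length(forbidden_motifs) > 0) {
    if (any(nchar(forbidden_motifs) < 4L)) {
      agam_abort("forbidden motifs must each be at least 4 nt", "invalid_param")
    }
    lapply(forbidden_motifs, assert_dna, what = "forbidden motif")
  }
  structure(
    list(
      strategy = strategy, seed = as.integer(seed),
      forbidden_motifs = forbidden_motifs, threshold = threshold
    ),
    class = "optimization_spec"
  )
}

# For one amino acid, the synonym choices ranked by descending reference
# frequency (ties broken alphabetically for determinism). Amino acids absent
# from the table fall back to a uniform choice over their synonyms (warning).
synonym_choices <- function(aa, table, code) {
  syn <- synonymous_codons(aa, code)
  freq <- table$freq_within_aa[match(syn, table$codon)]
  if (all(is.na(freq))) {
    agam_warn(
      sprintf("amino acid '%s' absent from table; uniform synonymous choice", aa),
      "unscored_amino_acid"
    )
    freq <- rep(1 / length(syn), length(syn))
  }
  freq[is.na(freq)] <- 0
  ord <- order(-freq, syn)
  list(codons = syn[ord], freq = freq[ord])
}

# Choose an output codon per position under the given strategy.
pick_codons <- function(codons, aa, table, spec, code) {
  choices <- lapply(
    stats::setNames(unique(aa), unique(aa)),
    synonym_choices, table = table, code = code
  )
  out <- character(length(codons))
  for (i in seq_along(codons)) {
    ch <- choices[[aa[i]]]
    out[i] <- switch(spec$strategy,
      most_frequent = ch$codons[1],
      threshold_swap = {
        f <- table$freq_within_aa[match(codons[i], table$codon)]
        if (is.na(f) || f < spec$threshold) ch$codons[1] else codons[i]
      },
      weighted_sampling = {
        keep <- ch$freq >= spec$threshold
        if (!any(keep)) {
          ch$codons[1]
        } else if (sum(keep) == 1L) {
          ch$codons[keep]
        } else {
          sample(ch$codons[keep], 1L, prob = ch$freq[keep])
        }
      }
    )
  }
  out
}

# Positions (1-based) of every forbidden-motif occurrence on either strand.
forbidden_windows <- function(seq, motifs) {
  out <- list()
  for (m in motifs) {
    for (pat in unique(c(m, revcomp(m)))) {
      st <- motif_starts(seq, pat)
      if (length(st)) out[[length(out) + 1L]] <- cbind(start = st, end = st + nchar(pat) - 1L)
    }
  }
  if (length(out) == 0) {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  } else {
    do.call(rbind, out)
  }
}

# Greedy left-to-right motif breaking: for the left-most forbidden window, try
# synonymous alternatives (descending frequency) at each overlapped mutable
# codon until the window disappears; repeat. Heuristic, documented as such.
break_motifs <- function(codons, aa, mutable, table, spec, code) {
  if (length(spec$forbidden_motifs) == 0) return(codons)
  choices <- lapply(
    stats::setNames(unique(aa), unique(aa)),
    synonym_choices, table = table, code = code
  )
  for (iter in seq_len(10L * length(codons) + 10L)) {
    seq <- paste0(codons, collapse = "")
    win <- forbidden_windows(seq, spec$forbidden_motifs)
    if (nrow(win) == 0) return(codons)
    win <- win[order(win[, "start"]), , drop = FALSE]
    w <- win[1, ]
    cod_idx <- unique(((w["start"] - 1L) %/% 3L):((w["end"] - 1L) %/% 3L)) + 1L
    cod_idx <- cod_idx[cod_idx >= 1 & cod_idx <= length(codons) & mutable[pmin(cod_idx, length(mutable))]]
    fixed <- TRUE
    for (j in cod_idx) {
      alts <- setdiff(choices[[aa[j]]]$codons, codons[j])
      done <- FALSE
      for (alt in alts) {
        trial <- codons
        trial[j] <- alt
        tw <- forbidden_windows(paste0(trial, collapse = ""), spec$forbidden_motifs)
        still <- nrow(tw) > 0 && any(tw[, "start"] <= w["end"] & tw[, "end"] >= w["start"])
        if (!still) {
          codons <- trial
          done <- TRUE
          break
        }
      }
      if (done) {
        fixed <- FALSE
        break
      }
    }
    if (fixed) {
      agam_abort(
        sprintf(
          "cannot remove forbidden motif at nucleotide %d: no synonymous substitution breaks it",
          w["start"]
        ),
        "motif_conflict",
        data = list(position = unname(w["start"]))
      )
    }
  }
  agam_abort("motif avoidance did not converge", "motif_conflict")
}

#' Rewrite a coding sequence toward a reference codon usage
#'
#' Produces a synonymous recoding of `cds` under the chosen strategy, always
#' preserving the encoded protein. The input's terminal stop codon, when
#' present, is kept verbatim. Forbidden motifs (both strands) are removed by a
#' greedy left-to-right substitution pass; if some motif cannot be broken by
#' any synonymous substitution a `motif_conflict` error is raised.
#'
#' @param cds A [coding_sequence()] or DNA string.
#' @param table Reference `codon_frequency_table`.
#' @param spec An [optimization_spec()].
#' @param code Genetic code.
#' @return An `optimization_result`: list with `cds` (the optimized
#'   [coding_sequence()]), `before` and `after` ([penalty_index()] reports at
#'   `spec$threshold`).
#' @examples
#' toy <- codon_frequency_table(
#'   codon = c("CTG", "CTC", "CTT", "TTA", "TTG", "CTA", "ATG"),
#'   freq_within_aa = c(0.50, 0.30, 0.12, 0.05, 0.02, 0.01, 1.0)
#' )
#' res <- optimize_cds("ATGTTACTA", toy, optimization_spec("most_frequent"))
#' res$cds$sequence
#' @export
optimize_cds <- function(cds, table, spec = optimization_spec(), code = standard_genetic_code()) {
  cds <- as_coding_sequence(cds)
  if (!inherits(table, "codon_frequency_table")) {
    agam_abort("table must be a codon_frequency_table", "invalid_param")
  }
  codons <- split_codons(cds$sequence)
  aa <- unname(code[codons])
  mutable <- rep(TRUE, length(codons))
  if (aa[length(aa)] == "*") mutable[length(mutable)] <- FALSE # stop kept verbatim

  new_codons <- codons
  idx <- which(mutable)
  picked <- with_seed(spec$seed, pick_codons(codons[idx], aa[idx], table, spec, code))
  new_codons[idx] <- picked
  new_codons <- break_motifs(new_codons, aa, mutable, table, spec, code)

  out <- coding_sequence(paste0(cds$id, "_opt"), paste0(new_codons, collapse = ""), code)
  stopifnot(identical(translate_cds(out, code), translate_cds(cds, code)))
  before <- suppressWarnings(penalty_index(cds, table, threshold = spec$threshold, code = code))
  after <- suppressWarnings(penalty_index(out, table, threshold = spec$threshold, code = code))
  structure(list(cds = out, before = before, after = after), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> %s: penalty index %.1f -> %.1f (threshold %.2g)\n",
    x$before$sequence_id, x$before$penalty_index, x$after$penalty_index, x$before$threshold
  ))
  invisible(x)
}

#' Back-translate a protein to a coding sequence
#'
#' @param protein Protein string over the 20 standard letters, optionally
#'   ending in `*`.
#' @param table Reference `codon_frequency_table`.
#' @param spec An [optimization_spec()] (codon choice per strategy).
#' @param id Identifier for the output sequence.
#' @param code Genetic code.
#' @return A [coding_sequence()] translating back to `protein`.
#' @export
back_translate <- function(protein, table, spec = optimization_spec(), id = "backtranslated",
                           code = standard_genetic_code()) {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) || !nzchar(protein)) {
    agam_abort("protein must be a non-empty string", "invalid_protein")
  }
  letters20 <- sort(unique(unname(code[code != "*"])))
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(chars, c(letters20, "*"))
  if (length(bad) > 0) {
    agam_abort(
      sprintf("unknown amino-acid letter(s): %s", paste(unique(bad), collapse = ", ")),
      "invalid_protein"
    )
  }
  if (any(chars == "*") && !(sum(chars == "*") == 1L && chars[length(chars)] == "*")) {
    agam_abort("'*' may only appear as a terminal stop", "invalid_protein")
  }
  codons <- with_seed(spec$seed, pick_codons(rep("", length(chars)), chars, table, spec, code))
  # for back-translation, threshold_swap has no input codon; treat as most_frequent
  mutable <- chars != "*"
  if (!all(mutable)) {
    # choose most frequent stop codon (or TAA) for '*'
    stop_choice <- suppressWarnings(synonym_choices("*", table, code))$codons[1]
    codons[!mutable] <- stop_choice
  }
  codons <- break_motifs(codons, chars, mutable, table, spec, code)
  out <- coding_sequence(id, paste0(codons, collapse = ""), code)
  stopifnot(identical(translate_cds(out, code), protein))
  out
}

#' Export a codon usage table in the per-1000 "usage" dialect
#'
#' Writes one line per codon as `codon<TAB>aa<TAB>per_1000<TAB>count` — the
#' compact representation that per-1000 preference tables are exchanged in as
#' input for external codon optimizers.
#'
#' @param table A `codon_frequency_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path) {
  write_codon_table(table, path, dialect = "usage")
}
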