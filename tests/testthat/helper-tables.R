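# Shared fixtures built in code.

# Toy leucine/methionine table: CTG 0.50, CTC 0.30, CTT 0.12, TTA 0.05,
# TTG 0.02, CTA 0.01; ATG 1.0.
toy_leu_table <- function() {
  codon_frequency_table(
    codon = c("CTG", "CTC", "CTT", "TTA", "TTG", "CTA", "ATG"),
    freq_within_aa = c(0.50, 0.30, 0.12, 0.05, 0.02, 0.01, 1.0)
  )
}

# The 10-codon scoring example: two rare codons (TTA, CTA).
toy_leu_cds <- function() {
  coding_sequence("toy", "ATGCTGCTGTTACTACTCCTTCTGCTCATG")
}

# Brute-force penalty oracle: classify every codon independently by direct
# table lookup. Deliberately naive and separate from the package scorer.
oracle_penalty <- function(seq, table, threshold = 0.10) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  rare <- 0L
  for (cod in codons) {
    f <- table$freq_within_aa[table$codon == cod]
    if (length(f) == 0 || is.na(f) || f < threshold) rare <- rare + 1L
  }
  1000 * rare / length(codons)
}

# Random coding sequence with no internal stop, for oracle comparisons.
random_cds <- function(n_codons, seed) {
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  seq <- withr_seed(seed, paste0(sample(sense, n_codons, replace = TRUE), collapse = ""))
  coding_sequence(sprintf("rand_%d", seed), seq)
}
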