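test_that("translation follows the standard code, with terminal stop as '*'", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_identical(translate_cds("ATGGCTTGGTAA"), "MAW*")
})

test_that("coding-sequence invariants are enforced", {
  expect_error(coding_sequence("x", "ATGA"), class = "agam_invalid_cds") # not triplet
  expect_error(coding_sequence("x", ""), class = "agam_invalid_cds")
  expect_error(coding_sequence("x", "ATGNNNTAA"), class = "agam_invalid_cds") # ambiguity
  expect_error(coding_sequence("x", "ATGTAAGCT"), class = "agam_invalid_cds") # internal stop
  expect_warning(coding_sequence("x", "atgtaa"), class = "agam_lowercase_input")
  expect_silent(coding_sequence("x", "ATGGCTTAA"))
})

test_that("codon counting accumulates, names offenders, and is order-invariant", {
  empty <- count_codons(list())
  expect_identical(sum(empty$counts), 0L)
  expect_identical(empty$total_codons, 0L)

  ct <- count_codons(list(coding_sequence("a", "ATGGCTGCTTAA")))
  expect_identical(unname(ct$counts[c("ATG", "GCT", "TAA")]), c(1L, 2L, 1L))
  expect_identical(ct$total_codons, 4L)

  set1 <- list(coding_sequence("a", "ATGGCTGCTTAA"), coding_sequence("b", "ATGCTGTAA"))
  expect_identical(count_codons(set1)$counts, count_codons(rev(set1))$counts)

  expect_error(
    count_codons(list(coding_sequence("a", "ATGTAA"), bad = "ATGA")),
    regexp = "bad", class = "agam_invalid_cds"
  )
})

test_that("frequency tables divide counts within amino acids and per 1000", {
  ft <- build_frequency_table(c(GCT = 5L))
  expect_equal(ft["GCT", "freq_within_aa"], 1.0)
  expect_equal(ft["GCT", "per_1000"], 1000)

  ft <- build_frequency_table(c(GCT = 3L, GCC = 1L, ATG = 4L))
  expect_equal(ft["GCT", "freq_within_aa"], 0.75)
  expect_equal(ft["GCC", "freq_within_aa"], 0.25)
  expect_equal(ft["ATG", "freq_within_aa"], 1.0)
  expect_equal(ft[c("GCT", "GCC", "ATG"), "per_1000"], c(375, 125, 500))
  # amino acids never observed are undefined
  expect_true(is.na(ft["TTA", "freq_within_aa"]))

  expect_error(build_frequency_table(structure(integer(0), names = character(0))),
    class = "agam_empty_table"
  )
})

test_that("frequency tables are invariant under count scaling", {
  counts <- c(GCT = 3L, GCC = 1L, CTG = 10L, TTA = 2L, ATG = 4L)
  f1 <- build_frequency_table(counts)
  f7 <- build_frequency_table(counts * 7L)
  expect_equal(f1$freq_within_aa, f7$freq_within_aa)
  expect_equal(f1$per_1000, f7$per_1000)
})

test_that("penalty index counts strictly-rare codons per 1000", {
  rep <- penalty_index(toy_leu_cds(), toy_leu_table(), threshold = 0.10)
  expect_identical(sort(rep$rare_hits$codon), c("CTA", "TTA"))
  expect_equal(rep$penalty_index, 200)
  expect_identical(rep$penalty_index_rounded, 200L)
  expect_equal(rep$raw_penalty, 2)
  expect_true(all(rep$rare_hits$freq_within_aa < 0.10))

  # ties at the threshold are not penalised
  tie <- codon_frequency_table(
    codon = c("CTG", "CTT", "ATG"), freq_within_aa = c(0.90, 0.10, 1.0)
  )
  expect_equal(penalty_index("ATGCTT", tie, threshold = 0.10)$penalty_index, 0)
})

test_that("most-frequent-only sequences always score zero", {
  tab <- agam_reference_table()
  code <- standard_genetic_code()
  best <- vapply(split(tab$codon, tab$aa), function(cods) {
    f <- tab[cods, "freq_within_aa"]
    cods[order(-f, cods)][1]
  }, character(1))
  seq <- paste0(c(best[c("M", "A", "L", "R", "S", "G", "V", "K")], best[["*"]]), collapse = "")
  expect_equal(penalty_index(coding_sequence("best", seq), tab)$penalty_index, 0)
})

test_that("penalty index never decreases as the threshold is raised", {
  tab <- agam_reference_table()
  cds <- random_cds(120, seed = 11)
  idx <- vapply(
    c(0.02, 0.05, 0.10, 0.20, 0.40),
    function(th) penalty_index(cds, tab, threshold = th)$penalty_index,
    numeric(1)
  )
  expect_true(all(diff(idx) >= 0))
})

test_that("penalty of a concatenation is the codon-weighted mean of the parts", {
  tab <- agam_reference_table()
  a <- random_cds(40, seed = 5)
  b <- random_cds(90, seed = 6)
  # strip nothing: neither random_cds carries a stop, so concatenation is valid
  ab <- coding_sequence("ab", paste0(a$sequence, b$sequence))
  pa <- penalty_index(a, tab)
  pb <- penalty_index(b, tab)
  pab <- penalty_index(ab, tab)
  expect_equal(
    pab$penalty_index,
    (pa$penalty_index * pa$n_codons + pb$penalty_index * pb$n_codons) / (pa$n_codons + pb$n_codons)
  )
})

test_that("penalty agrees with the brute-force oracle on random sequences", {
  tab <- agam_reference_table()
  for (seed in 1:25) {
    cds <- random_cds(sample.int(300, 1), seed = seed)
    expect_equal(
      penalty_index(cds, tab)$penalty_index,
      oracle_penalty(cds$sequence, tab),
      info = sprintf("seed %d", seed)
    )
  }
})

test_that("codons of amino acids missing from the table score as rare, with warning", {
  expect_warning(
    rep <- penalty_index("ATGGCTGCT", toy_leu_table()), # Ala absent from toy table
    class = "agam_unscored_amino_acid"
  )
  expect_identical(sort(rep$rare_hits$codon), c("GCT", "GCT"))
  expect_equal(rep$penalty_index, 1000 * 2 / 3)
})

test_that("a terminal stop is scored by default and dropped with exclude_stop", {
  tab <- agam_reference_table()
  cds <- coding_sequence("s", "ATGCTGTGA") # TGA is the rarest stop in the table
  with_stop <- penalty_index(cds, tab)
  without <- penalty_index(cds, tab, exclude_stop = TRUE)
  expect_identical(with_stop$n_codons, 3L)
  expect_identical(without$n_codons, 2L)
  expect_true(tab["TGA", "freq_within_aa"] > 0.10 || nrow(with_stop$rare_hits) > nrow(without$rare_hits))
})

test_that("the penalty weight hook changes raw penalty but not rare-hit calls", {
  rep1 <- penalty_index(toy_leu_cds(), toy_leu_table())
  rep2 <- penalty_index(toy_leu_cds(), toy_leu_table(), weight = function(f) 1 - f)
  expect_identical(rep1$rare_hits, rep2$rare_hits)
  expect_equal(rep2$raw_penalty, sum(1 - rep1$rare_hits$freq_within_aa))
})

test_that("rounding of the index is half away from zero", {
  # 3 rare codons in 8 -> 375; engineered halves round up
  tab <- toy_leu_table()
  cds <- coding_sequence("h", paste0(strrep("ATG", 3), "TTA")) # 1 rare of 4 -> 250
  expect_identical(penalty_index(cds, tab)$penalty_index_rounded, 250L)
  # 1 rare codon in 2000 codons -> 0.5 -> rounds to 1
  long <- coding_sequence("half", paste0(strrep("ATG", 1999), "TTA"))
  expect_identical(penalty_index(long, tab)$penalty_index_rounded, 1L)
})
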