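test_that("site finding reports both strands and honours circular origins", {
  expect_identical(nrow(find_sites(dna_molecule("a", "AAAAAA"))), 0L)

  hit <- find_sites(dna_molecule("m", "TTTGGTCTCAACTGAAA"))
  expect_identical(hit$position, 4L) # 0-based 3 in half-open convention
  expect_identical(hit$strand, "+")

  rc <- find_sites(dna_molecule("rc", revcomp("TTTGGTCTCAACTGAAA")))
  expect_identical(rc$strand, "-")
  expect_identical(rc$position, 17L - 6L - 3L + 1L) # mirrored

  # site spanning the origin of a circle
  circ <- dna_molecule("c", paste0("TCTCAAAAAAAAAAAAGG"), topology = "circular")
  expect_identical(nrow(find_sites(circ)), 1L)
})

test_that("BsaI digestion cuts at GGTCTC(1/5) leaving 4-nt top-strand labels", {
  frags <- digest(dna_molecule("m", "TTTGGTCTCAACTGAAA"))
  expect_length(frags, 2L)
  expect_identical(frags[[1]]$sequence, "TTTGGTCTCA")
  expect_identical(frags[[2]]$sequence, "ACTGAAA")
  expect_identical(frags[[1]]$right_overhang, "ACTG")
  expect_identical(frags[[2]]$left_overhang, "ACTG")
  expect_identical(frags[[1]]$left_overhang, "") # blunt outer end
})

test_that("a molecule with no site comes back as one uncut fragment", {
  mol <- generate_random_dna(200, seed = 2)
  mol$sequence <- gsub("GGTCTC|GAGACC", "AAAAAA", mol$sequence)
  frags <- digest(dna_molecule("clean", mol$sequence))
  expect_length(frags, 1L)
  expect_identical(frags[[1]]$sequence, mol$sequence)
})

test_that("digestion conserves nucleotide content; k sites give k or k+1 fragments", {
  for (seed in c(1, 4, 9)) {
    gg <- generate_goldengate_set(2, seed = seed)
    for (mol in c(list(gg$destination), gg$donors)) {
      frags <- digest(mol)
      k <- nrow(cut_sites <- find_sites(mol))
      expect_length(frags, if (mol$topology == "circular") k else k + 1L)
      expect_identical(
        sum(vapply(frags, function(f) nchar(f$sequence), integer(1))),
        nchar(mol$sequence)
      )
      # sorted base content is preserved, not just length
      expect_identical(
        sort(strsplit(paste0(vapply(frags, `[[`, character(1), "sequence"), collapse = ""), "")[[1]]),
        sort(strsplit(mol$sequence, "")[[1]])
      )
    }
  }
})

test_that("a single-site circle religates to the input up to rotation", {
  circ <- dna_molecule(
    "c", paste0("GGTCTCT", "AGTC", generate_random_dna(60, seed = 5)$sequence),
    topology = "circular"
  )
  frags <- digest(circ)
  expect_length(frags, 1L)
  expect_identical(frags[[1]]$left_overhang, frags[[1]]$right_overhang)
  expect_identical(nchar(frags[[1]]$sequence), nchar(circ$sequence))
  expect_true(grepl(frags[[1]]$sequence, strrep(circ$sequence, 2), fixed = TRUE))
})

test_that("cut coordinates outside a linear molecule are an error", {
  expect_error(
    digest(dna_molecule("edge", "AAAGGTCTCAA")), # cut beyond right end
    class = "agam_site_too_close_to_end"
  )
})

test_that("strand symmetry: digesting the reverse complement mirrors the labels", {
  gg <- generate_goldengate_set(2, seed = 8)
  fwd <- digest(gg$destination)
  rev <- digest(revcomp_molecule(gg$destination))
  expect_length(rev, length(fwd))
  fwd_labels <- sort(vapply(fwd, `[[`, character(1), "left_overhang"))
  rev_labels <- sort(vapply(rev, function(f) revcomp(f$left_overhang), character(1)))
  expect_identical(rev_labels, fwd_labels)
})

test_that("GoldenGate assembly reproduces the designed product", {
  for (seed in c(1, 7)) {
    for (n in c(1, 3, 5)) {
      gg <- generate_goldengate_set(n, seed = seed)
      product <- assemble(gg$destination, gg$donors)
      expect_identical(
        nchar(product$molecule$sequence), nchar(gg$designed_product$sequence),
        info = sprintf("n=%d seed=%d", n, seed)
      )
      expect_true(
        grepl(product$molecule$sequence, strrep(gg$designed_product$sequence, 2), fixed = TRUE)
      )
      # junction order as designed (product reported backbone-first)
      expect_identical(product$junction_labels, gg$junction_labels[c(seq_len(n), n + 1L)])
      # stuffer removed, no BsaI site retained
      expect_false(any(grepl("lacZ", product$molecule$features$name)))
      expect_identical(nrow(find_sites(product$molecule)), 0L)
    }
  }
})

test_that("mismatched or colliding overhangs are named assembly errors", {
  gg <- generate_goldengate_set(2, seed = 3)
  # destination alone: backbone right label dangles
  expect_error(assemble(gg$destination, list()), class = "agam_no_assembly")
  # two donors with the same left label
  expect_error(
    assemble(gg$destination, list(gg$donors[[1]], gg$donors[[1]])),
    class = "agam_ambiguous_assembly"
  )
  # donor that releases no insert
  blank <- dna_molecule("blank", generate_random_dna(100, seed = 1)$sequence, "circular")
  blank$sequence <- gsub("GGTCTC|GAGACC", "ACGTAA", blank$sequence)
  expect_error(
    assemble(gg$destination, list(gg$donors[[1]], blank)),
    class = "agam_bad_donor"
  )
})

test_that("in-silico PCR returns the unique exact-match amplicon", {
  tmpl <- generate_random_dna(80, seed = 7)
  fwd <- substr(tmpl$sequence, 11, 25)
  rev <- revcomp(substr(tmpl$sequence, 56, 70))
  amp <- simulate_pcr(tmpl, fwd, rev)
  expect_identical(amp$length, 60L) # 5' of fwd (11) to 5' of rev (70), inclusive
  expect_identical(amp$forward_start, 11L)
  expect_identical(amp$reverse_end, 70L)
  expect_identical(amp$sequence, substr(tmpl$sequence, 11, 70))

  expect_error(
    simulate_pcr(tmpl, strrep("ACGT", 4), rev),
    class = "agam_no_amplicon"
  )
  expect_error(simulate_pcr(tmpl, "ACGTACGTAC", rev), class = "agam_invalid_param") # < 15 nt
})

test_that("circular templates amplify across the origin", {
  lin <- generate_random_dna(100, seed = 12)
  # rotate so the amplicon spans the origin
  circ <- dna_molecule(
    "c", paste0(substr(lin$sequence, 51, 100), substr(lin$sequence, 1, 50)),
    topology = "circular"
  )
  fwd <- substr(lin$sequence, 31, 45) # near the new end of the circle
  rev <- revcomp(substr(lin$sequence, 66, 80)) # past the origin
  amp <- simulate_pcr(circ, fwd, rev)
  expect_identical(amp$length, 50L)
  expect_identical(amp$sequence, substr(lin$sequence, 31, 80))
})

test_that("multiple primer pairings are reported as ambiguous with all products", {
  base <- generate_random_dna(60, seed = 21)$sequence
  fwd_site <- substr(base, 1, 15)
  rev_site <- substr(base, 31, 45)
  tmpl <- dna_molecule("dup", paste0(base, base))
  err <- expect_error(
    simulate_pcr(tmpl, fwd_site, revcomp(rev_site)),
    class = "agam_ambiguous_pcr"
  )
  expect_gte(length(err$products), 2L)
})

test_that("palindromic overhang labels trigger a self-ligation warning", {
  expect_warning(
    digest(dna_molecule("p", "TTTGGTCTCAACGTAAAA")), # overhang ACGT
    class = "agam_palindromic_overhang"
  )
})
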