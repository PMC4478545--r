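test_that("site scanning calls attP/attB/attL/attR/loxP on both strands", {
  sites <- recombination_sites()
  none <- generate_random_dna(1000, seed = 31)
  hits <- find_recomb_sites(none, sites)
  expect_identical(nrow(hits), 0L)

  locus <- generate_docking_locus(seed = 3)
  hits <- find_recomb_sites(locus, sites)
  expect_identical(sum(hits$kind == "attP"), 1L)
  expect_identical(sum(hits$kind == "loxP"), 2L)
  expect_true(all(hits$strand[hits$kind == "loxP"] == "+")) # direct repeat

  # a site placed on the bottom strand is still found
  flipped <- dna_molecule(
    "f", paste0("AAAA", revcomp(sites$loxP_seq), "TTTT")
  )
  h <- find_recomb_sites(flipped, sites)
  expect_identical(h$kind, "loxP")
  expect_identical(h$strand, "-")
})

test_that("attP and attB must share their core", {
  expect_error(
    recombination_sites(
      attP = c("AAAA", "TTG", "CCCC"),
      attB = c("GGGG", "CTG", "AAAA")
    ),
    class = "agam_invalid_param"
  )
})

test_that("integration inserts the whole plasmid between attR and attL", {
  sites <- recombination_sites()
  locus <- generate_docking_locus(seed = 3)
  plasmid <- generate_attb_plasmid(seed = 4)
  product <- integrate_attB(locus, plasmid, sites)

  # conservation of nucleotide content
  expect_identical(
    nchar(product$sequence),
    nchar(locus$sequence) + nchar(plasmid$sequence)
  )
  hits <- find_recomb_sites(product, sites)
  expect_identical(sum(hits$kind == "attL"), 1L)
  expect_identical(sum(hits$kind == "attR"), 1L)
  expect_identical(sum(hits$kind %in% c("attP", "attB")), 0L)

  # symbolic layout: L1 . P_L core B_R . plasmid-rest . B_L core P_R . L2
  p_start <- find_recomb_sites(locus, sites)
  p_start <- p_start$position[p_start$kind == "attP"]
  expect_identical(substr(product$sequence, 1, p_start - 1), substr(locus$sequence, 1, p_start - 1))
  expect_identical(
    substr(product$sequence, p_start, p_start + nchar(sites$attR_seq) - 1),
    sites$attR_seq
  )
})

test_that("integration demands exactly one attP and one attB", {
  sites <- recombination_sites()
  plasmid <- generate_attb_plasmid(seed = 4)
  no_attp <- generate_random_dna(500, seed = 9)
  expect_error(integrate_attB(no_attp, plasmid, sites), class = "agam_site_count_error")

  locus <- generate_docking_locus(seed = 3)
  no_attb <- dna_molecule("p", generate_random_dna(300, seed = 10)$sequence, "circular")
  expect_error(integrate_attB(locus, no_attb, sites), class = "agam_site_count_error")
})

test_that("Cre excision keeps one loxP and circularises the cassette", {
  sites <- recombination_sites()
  lox <- sites$loxP_seq
  x <- generate_random_dna(120, seed = 14)$sequence
  cassette <- generate_random_dna(90, seed = 15)$sequence
  y <- generate_random_dna(60, seed = 16)$sequence
  mol <- dna_molecule("direct", paste0(x, lox, cassette, lox, y),
    features = data.frame(
      name = "cassette", start = 121 + 34, end = 120 + 34 + 90, strand = "+"
    )
  )
  out <- cre_recombine(mol, sites)
  expect_length(out, 1L)
  parent <- out[[1]][[1]]
  circle <- out[[1]][[2]]
  expect_identical(parent$sequence, paste0(x, lox, y))
  expect_identical(circle$sequence, paste0(cassette, lox))
  expect_identical(circle$topology, "circular")
  expect_identical(
    nchar(parent$sequence) + nchar(circle$sequence), nchar(mol$sequence)
  )
  expect_identical(sum(find_recomb_sites(parent, sites)$kind == "loxP"), 1L)
  expect_false(any(parent$features$name == "cassette"))
  expect_true(any(circle$features$name == "cassette"))
})

test_that("inverted loxP sites flip the intervening segment in place", {
  sites <- recombination_sites()
  lox <- sites$loxP_seq
  x <- generate_random_dna(50, seed = 17)$sequence
  mid <- generate_random_dna(70, seed = 18)$sequence
  y <- generate_random_dna(40, seed = 19)$sequence
  mol <- dna_molecule("inv", paste0(x, lox, mid, revcomp(lox), y))
  out <- cre_recombine(mol, sites)
  expect_length(out, 1L)
  flipped <- out[[1]][[1]]
  expect_length(out[[1]], 1L)
  expect_identical(flipped$sequence, paste0(x, lox, revcomp(mid), revcomp(lox), y))
  expect_identical(nchar(flipped$sequence), nchar(mol$sequence))
})

test_that("fewer than two loxP sites leaves the molecule unchanged with notice", {
  sites <- recombination_sites()
  mol <- dna_molecule("single", paste0("AAAA", sites$loxP_seq, "TTTT"))
  expect_message(out <- cre_recombine(mol, sites), "fewer than two loxP")
  expect_identical(out[[1]][[1]]$sequence, mol$sequence)
})

test_that("with more than two loxP sites all pairwise outcomes are enumerated", {
  sites <- recombination_sites()
  lox <- sites$loxP_seq
  mol <- dna_molecule("triple", paste0(
    "AAAAAAAAAA", lox, strrep("C", 20), lox, strrep("G", 20), lox, "TTTTTTTTTT"
  ))
  out <- cre_recombine(mol, sites)
  expect_length(out, 3L) # choose(3, 2)
  for (o in out) {
    expect_identical(
      sum(vapply(o, function(m) nchar(m$sequence), integer(1))),
      nchar(mol$sequence)
    )
  }
})

test_that("the full docking workflow ends marker-free with a single loxP", {
  sites <- recombination_sites()
  for (seed in c(0, 5, 11)) {
    locus <- generate_docking_locus(seed = seed)
    plasmid <- generate_attb_plasmid(seed = seed + 100)
    integrant <- integrate_attB(locus, plasmid, sites)
    out <- cre_recombine(integrant, sites)
    parent <- out[[1]][[1]]
    expect_identical(sum(find_recomb_sites(parent, sites)$kind == "loxP"), 1L)
    expect_false(any(grepl("marker", parent$features$name)))
    expect_true(any(grepl("marker", out[[1]][[2]]$features$name)))
    # the integrated cargo stays in the locus
    expect_true(any(parent$features$name == "cargo"))
  }
})
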