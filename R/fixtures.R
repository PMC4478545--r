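# Deterministic synthetic-fixture generators. Everything the test suite needs
# is generated here from a seed; no sequence download is ever required.

#' Generate a uniform random DNA molecule
#'
#' @param n Length in nucleotides (>= 0).
#' @param seed Integer seed; identical `(n, seed)` give identical output.
#' @param id Molecule identifier.
#' @param topology `"linear"` or `"circular"`.
#' @return A [dna_molecule()].
#' @export
generate_random_dna <- function(n, seed, id = sprintf("random_dna_%d_%d", n, seed),
                                topology = "linear") {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    agam_abort("n must be a non-negative integer", "invalid_param")
  }
  seq <- with_seed(seed, paste0(sample(DNA_ALPHABET, n, replace = TRUE), collapse = ""))
  structure(
    list(id = id, sequence = seq, topology = match.arg(topology, c("linear", "circular")),
         features = empty_features()),
    class = "dna_molecule"
  )
}

# Random DNA string free of the given motifs on both strands (rejection
# sampling of the offending windows).
random_dna_avoiding <- function(n, motifs = c("GGTCTC", "GAGACC")) {
  if (n == 0L) return("")
  seq <- paste0(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
  for (i in 1:100) {
    win <- forbidden_windows(seq, motifs)
    if (nrow(win) == 0) return(seq)
    p <- win[1, "start"]
    substr(seq, p, p) <- sample(DNA_ALPHABET, 1)
  }
  agam_abort("could not generate motif-free random DNA", "generator_failure")
}

#' Sample a coding sequence from a codon frequency table
#'
#' Draws `n_codons` sense codons: the amino acid of each position is drawn
#' from the table's per-1000 marginal (restricted to sense codons), then the
#' codon from `freq_within_aa` among that amino acid's synonyms. No internal
#' stop can occur; a terminal stop codon (the table's most frequent stop, TAA
#' if the table has none) is appended. Used as the parameter-recovery harness
#' for table building: tables rebuilt from large samples converge to the
#' sampling table.
#'
#' @param table A `codon_frequency_table`.
#' @param n_codons Number of sense codons to draw (>= 0).
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @param code Genetic code.
#' @return A [coding_sequence()] of `n_codons + 1` codons.
#' @export
generate_cds_from_table <- function(table, n_codons, seed, id = sprintf("synthetic_cds_%d", seed),
                                    code = standard_genetic_code()) {
  if (!inherits(table, "codon_frequency_table")) {
    agam_abort("table must be a codon_frequency_table", "invalid_param")
  }
  if (!is.numeric(n_codons) || length(n_codons) != 1L || is.na(n_codons) || n_codons < 0) {
    agam_abort("n_codons must be a non-negative integer", "invalid_param")
  }
  sense <- table[table$aa != "*", , drop = FALSE]
  # per-1000 marginal per amino acid; fall back to within-aa frequencies when
  # the table carries no per-1000 column (toy tables)
  wt <- sense$per_1000
  if (all(is.na(wt))) wt <- sense$freq_within_aa
  wt[is.na(wt)] <- 0
  aa_weight <- tapply(wt, sense$aa, sum)
  aa_weight <- aa_weight[aa_weight > 0]
  if (length(aa_weight) == 0) agam_abort("table carries no usable frequencies", "empty_table")

  stop_tab <- table[table$aa == "*", , drop = FALSE]
  stop_codon <- if (any(!is.na(stop_tab$freq_within_aa) & stop_tab$freq_within_aa > 0)) {
    f <- ifelse(is.na(stop_tab$freq_within_aa), 0, stop_tab$freq_within_aa)
    stop_tab$codon[order(-f, stop_tab$codon)][1]
  } else {
    "TAA"
  }

  seq <- with_seed(seed, {
    if (n_codons == 0) {
      stop_codon
    } else {
      aas <- sample(names(aa_weight), n_codons, replace = TRUE, prob = aa_weight)
      codons <- character(n_codons)
      for (a in unique(aas)) {
        syn <- sense[sense$aa == a, , drop = FALSE]
        f <- ifelse(is.na(syn$freq_within_aa), 0, syn$freq_within_aa)
        at <- which(aas == a)
        codons[at] <- if (nrow(syn) == 1L) syn$codon else sample(syn$codon, length(at), replace = TRUE, prob = f)
      }
      paste0(c(codons, stop_codon), collapse = "")
    }
  })
  coding_sequence(id, seq, code)
}

#' Generate a GoldenGate destination/donor fixture set
#'
#' Designs a circular destination vector (backbone plus a `lacZ` stuffer
#' flanked by two inward-cutting BsaI sites) and `n_donors` circular donor
#' plasmids, each releasing one insert with chained 4-nt junction labels, so
#' that [assemble()] has a unique solution. The designed assembled product is
#' returned alongside for oracle comparison.
#'
#' @param n_donors Number of donors (>= 1).
#' @param insert_lengths Insert lengths (recycled to `n_donors`; default 100).
#' @param seed Integer seed.
#' @param backbone_length,stuffer_length Backbone and stuffer core lengths.
#' @return A list with `destination`, `donors` (list), `designed_product`
#'   (circular [dna_molecule()]), and `junction_labels` (the `n_donors + 1`
#'   designed labels, backbone-to-first-insert first).
#' @export
generate_goldengate_set <- function(n_donors, insert_lengths = 100L, seed = 1L,
                                    backbone_length = 400L, stuffer_length = 300L) {
  if (!is.numeric(n_donors) || n_donors < 1L) {
    agam_abort("n_donors must be >= 1", "invalid_param")
  }
  n_donors <- as.integer(n_donors)
  insert_lengths <- rep_len(as.integer(insert_lengths), n_donors)
  if (any(insert_lengths < 1L)) agam_abort("insert lengths must be positive", "invalid_param")
  bsai_motifs <- c("GGTCTC", "GAGACC")

  with_seed(seed, {
    # unique, non-palindromic junction labels, mutually distinct also under
    # reverse complement so the junction graph has a single solution
    labels <- character(0)
    for (attempt in 1:1000) {
      cand <- paste0(sample(DNA_ALPHABET, 4L, replace = TRUE), collapse = "")
      if (is_palindromic(cand)) next
      if (cand %in% labels || revcomp(cand) %in% labels) next
      labels <- c(labels, cand)
      if (length(labels) == n_donors + 1L) break
    }
    if (length(labels) < n_donors + 1L) {
      agam_abort("could not draw distinct junction labels", "generator_failure")
    }

    build_vector <- function(payload_with_labels, carrier_core, id, payload_feats) {
      # circular: [payload] [x GAGACC] [carrier] [GGTCTC y], cuts regenerate
      # the payload with its designed left/right labels
      spacer1 <- sample(DNA_ALPHABET, 1)
      spacer2 <- sample(DNA_ALPHABET, 1)
      seq <- paste0(
        payload_with_labels, spacer1, "GAGACC", carrier_core, "GGTCTC", spacer2
      )
      mol <- dna_molecule(id, seq, "circular", payload_feats)
      # the designed cut arithmetic must yield exactly two sites
      if (nrow(find_sites(mol, bsai())) != 2L) return(NULL)
      mol
    }

    make_clean <- function(n) random_dna_avoiding(n, bsai_motifs)

    for (attempt in 1:50) {
      backbone_core <- make_clean(backbone_length)
      stuffer_core <- make_clean(stuffer_length)
      inserts <- lapply(insert_lengths, make_clean)

      # destination payload: J_last + backbone ... stuffer carries the sites
      backbone_payload <- paste0(labels[n_donors + 1L], backbone_core)
      dest_payload <- paste0(backbone_payload, labels[1])
      # destination circle: [J_n backbone J_0] x GAGACC [stuffer] GGTCTC y
      stuffer_feat_start <- nchar(dest_payload) + 8L # after spacer + GAGACC
      destination <- build_vector(
        dest_payload, stuffer_core, "gg_destination",
        data.frame(
          name = "lacZ_stuffer", start = stuffer_feat_start,
          end = stuffer_feat_start + nchar(stuffer_core) - 1L, strand = "+"
        )
      )
      donors <- vector("list", n_donors)
      ok <- !is.null(destination)
      if (ok) {
        for (i in seq_len(n_donors)) {
          donor_payload <- paste0(labels[i], inserts[[i]], labels[i + 1L])
          donor <- build_vector(
            donor_payload, make_clean(200L), sprintf("gg_donor_%d", i),
            data.frame(
              name = sprintf("insert_%d", i), start = 5L,
              end = 4L + nchar(inserts[[i]]), strand = "+"
            )
          )
          if (is.null(donor)) {
            ok <- FALSE
            break
          }
          donors[[i]] <- donor
        }
      }
      if (!ok) next

      designed_seq <- paste0(
        labels[n_donors + 1L], backbone_core,
        paste0(vapply(seq_len(n_donors), function(i) {
          paste0(labels[i], inserts[[i]])
        }, character(1)), collapse = "")
      )
      designed <- dna_molecule("gg_designed_product", designed_seq, "circular")
      if (nrow(find_sites(designed, bsai())) > 0) next # junction formed a site

      return(list(
        destination = destination,
        donors = donors,
        designed_product = designed,
        junction_labels = labels
      ))
    }
    agam_abort("could not design a consistent GoldenGate set", "generator_failure")
  })
}

#' Generate a synthetic docking locus
#'
#' Builds the linear genomic locus that docking-line derivation starts from:
#' `flank -- attP -- loxP -- fluorescent marker cassette -- loxP -- flank`,
#' with the attP, both loxP sites (direct repeat), and the marker annotated as
#' features. Integrating an attB plasmid at the attP and then excising the
#' lox cassette with Cre leaves a marker-free locus with a single loxP.
#'
#' @param seed Integer seed.
#' @param sites A [recombination_sites()] definition.
#' @param flank_length Length of each genomic flank.
#' @param marker_length Length of the marker cassette.
#' @return A linear [dna_molecule()].
#' @export
generate_docking_locus <- function(seed = 1L, sites = recombination_sites(),
                                   flank_length = 300L, marker_length = 250L) {
  with_seed(seed, {
    avoid <- c(sites$attP_seq, sites$attB_seq, sites$loxP_seq)
    clean <- function(n) random_dna_avoiding(n, avoid)
    flank1 <- clean(flank_length)
    flank2 <- clean(flank_length)
    marker <- clean(marker_length)
    spacer1 <- clean(20L)
    spacer2 <- clean(10L)
    spacer3 <- clean(10L)
    parts <- c(
      flank1, sites$attP_seq, spacer1, sites$loxP_seq, spacer2,
      marker, spacer3, sites$loxP_seq, flank2
    )
    seq <- paste0(parts, collapse = "")
    ends <- cumsum(nchar(parts))
    starts <- ends - nchar(parts) + 1L
    feats <- data.frame(
      name = c("attP", "loxP", "fluorescent_marker", "loxP"),
      start = starts[c(2, 4, 6, 8)],
      end = ends[c(2, 4, 6, 8)],
      strand = "+",
      stringsAsFactors = FALSE
    )
    mol <- dna_molecule(sprintf("docking_locus_%d", seed), seq, "linear", feats)
    found <- find_recomb_sites(mol, sites)
    if (sum(found$kind == "attP") != 1L || sum(found$kind == "loxP") != 2L) {
      agam_abort("docking locus fixture failed its own site audit", "generator_failure")
    }
    mol
  })
}

#' Generate a circular attB marker plasmid
#'
#' A minimal integration substrate: a circular plasmid carrying one attB site
#' and a cargo feature, free of loxP, for use with [integrate_attB()].
#'
#' @param seed Integer seed.
#' @param sites A [recombination_sites()] definition.
#' @param cargo_length Cargo length.
#' @return A circular [dna_molecule()].
#' @export
generate_attb_plasmid <- function(seed = 1L, sites = recombination_sites(),
                                  cargo_length = 400L) {
  with_seed(seed, {
    avoid <- c(sites$attP_seq, sites$attB_seq, sites$loxP_seq)
    cargo <- random_dna_avoiding(cargo_length, avoid)
    seq <- paste0(sites$attB_seq, cargo)
    dna_molecule(
      sprintf("attB_plasmid_%d", seed), seq, "circular",
      data.frame(
        name = c("attB", "cargo"),
        start = c(1L, nchar(sites$attB_seq) + 1L),
        end = c(nchar(sites$attB_seq), nchar(seq)),
        strand = "+"
      )
    )
  })
}
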